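#' Read an experiment configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON configuration into a named list.
#' All experiment functions accept their parameters directly; this helper
#' exists so a run can be reproduced from a serialized config plus seed.
#'
#' @param path Path to a YAML or JSON file.
#' @return Named list of configuration values.
#' @export
read_experiment_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the 'jsonlite' package is required to read JSON configs",
           call. = FALSE)
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: ", ext, call. = FALSE)
  }
}

# Has the 100-interval smoothed mse settled? Relative change between the two
# most recent 100-interval windows below `tol`.
mse_converged <- function(mse_trace, tol = 1e-3, window = 100) {
  if (length(mse_trace) < 2 * window) return(FALSE)
  m <- length(mse_trace)
  recent <- mean(mse_trace[(m - window + 1):m])
  before <- mean(mse_trace[(m - 2 * window + 1):(m - window)])
  abs(recent - before) / max(abs(before), .Machine$double.eps) < tol
}

# One training arm of an experiment: builds the paired components off a
# shared base seed so arms differing only in (epsilon, z, TR) see identical
# data order and identical initial weights.
run_arm <- function(dataset, epsilon, z, seed, epochs,
                    hidden_size = 16, n_vessels = 100, beta = 1,
                    TR = NULL, learning_rate = 1, batch_size = 20,
                    vascular_substeps = 100, economy = 0.02, alpha = 0.02,
                    N_ref = n_vessels / 4, vascular = list()) {
  ae <- autoencoder(dataset$height * dataset$width, hidden_size,
                    learning_rate = learning_rate, batch_size = batch_size,
                    seed = seed + 1L)
  conn <- vascular_connectivity(hidden_size, n_vessels, z, seed = seed + 2L)
  vp_args <- utils::modifyList(list(n = n_vessels, epsilon = epsilon),
                               vascular)
  vp <- do.call(vascular_params, vp_args)
  vasc <- vascular_network(vp, seed = seed + 3L)
  if (is.null(TR)) TR <- batch_size
  model <- neurovascular_model(ae, vasc, conn, beta = beta, TR = TR,
                               vascular_substeps = vascular_substeps,
                               economy = economy, alpha = alpha,
                               N_ref = N_ref)
  set.seed(seed + 4L)  # epoch shuffles shared across paired arms
  fit <- train_coupled(model, dataset, epochs = epochs)
  imgs <- weight_images(fit$model$ae, c(dataset$height, dataset$width))
  fm <- feature_metrics(imgs)
  last <- fit$log[fit$log$epoch == epochs, ]
  list(final_mse = fit$final_mse,
       mii_mean = fm$mii_mean,
       ssi_mean = fm$ssi_mean,
       q_mean = mean(last$q),
       N_d_final = fit$model$demand$N_d,
       localization = bar_localization(imgs),
       converged = mse_converged(fit$log$mse),
       metrics = fm,
       model = fit$model,
       log = fit$log)
}

#' Synchrony experiment: desynchronized vs. synchronized vascular input
#'
#' Trains two arms of the coupled model on the same bar-pattern dataset with
#' identical initial weights, data order and vessel-to-neuron connectivity
#' (one-to-one style, z = 1), differing only in the vascular coupling
#' balance: `epsilon = 0` (desynchronized, chaotic vessels) versus
#' `epsilon = 1` (synchronized vessels). Under desynchronized input the
#' hidden units are dropped out in a spatially random, time-varying pattern
#' and the network learns sparse single-bar features with a lower converged
#' reconstruction error; under synchronized input all units are gated
#' together and feature learning degrades.
#'
#' @param seed Base seed; the two arms are paired on it.
#' @param epochs Training epochs per arm.
#' @param count,size,max_bars Bar-dataset parameters (see [bar_patterns()]).
#' @param hidden_size Hidden units (16 pairs one unit per bar at size 8).
#' @param n_vessels Vessels in the ring.
#' @param epsilons The two coupling balances compared.
#' @param apc_duration Length of the stand-alone vascular characterization
#'   run used to report each arm's APC (time units).
#' @param ... Further arguments passed to the training arms (e.g. `beta`,
#'   `TR`, `learning_rate`, `batch_size`, `vascular`).
#' @return An object of class `synchrony_report`: per-arm results
#'   (`desync`, `sync`), their APCs, and the shared configuration.
#' @export
synchrony_experiment <- function(seed = 1, epochs = 150, count = 5000,
                                 size = 8, max_bars = 4, hidden_size = 16,
                                 n_vessels = 100, epsilons = c(0, 1),
                                 apc_duration = 200, ...) {
  stopifnot(length(epsilons) == 2)
  dataset <- bar_patterns(count, size, max_bars, seed = seed)
  arms <- lapply(epsilons, function(eps) {
    run_arm(dataset, epsilon = eps, z = 1, seed = seed, epochs = epochs,
            hidden_size = hidden_size, n_vessels = n_vessels, ...)
  })
  apcs <- vapply(seq_along(epsilons), function(i) {
    p <- arms[[i]]$model$vasc$params
    sim <- simulate_vascular(p, N_d = 0, duration = apc_duration,
                             burn_in = 100, seed = seed + 10L)
    compute_apc(sim$S_history)
  }, numeric(1))
  structure(list(desync = arms[[1]], sync = arms[[2]],
                 apc = stats::setNames(apcs, paste0("epsilon_", epsilons)),
                 epsilons = epsilons, seed = seed, epochs = epochs,
                 config = list(count = count, size = size,
                               max_bars = max_bars,
                               hidden_size = hidden_size,
                               n_vessels = n_vessels)),
            class = "synchrony_report")
}

#' @export
print.synchrony_report <- function(x, ...) {
  cat("Synchrony experiment (paired arms, z = 1)\n")
  cat(sprintf("  desynchronized (epsilon = %g): mse = %.4f, MII = %.4f, SSI = %.4f, APC = %.3f\n",
              x$epsilons[1], x$desync$final_mse, x$desync$mii_mean,
              x$desync$ssi_mean, x$apc[1]))
  cat(sprintf("  synchronized   (epsilon = %g): mse = %.4f, MII = %.4f, SSI = %.4f, APC = %.3f\n",
              x$epsilons[2], x$sync$final_mse, x$sync$mii_mean,
              x$sync$ssi_mean, x$apc[2]))
  cat(sprintf("  single-bar units (>= 80%% L1 on one bar): %d of %d\n",
              sum(x$desync$localization >= 0.8),
              length(x$desync$localization)))
  invisible(x)
}

#' Projective-field (connectivity) sweep
#'
#' Trains one desynchronized (`epsilon = 0`) arm per projective-field size
#' `z`, all paired on the same seed. As `z` grows from one-to-one toward
#' complete connectivity, neurons average more vessels, their gating becomes
#' increasingly shared, and feature independence degrades: mean MII rises
#' and mean SSI falls.
#'
#' @param seed Base seed shared by all arms.
#' @param z_values Projective-field sizes to sweep.
#' @param epochs Training epochs per arm.
#' @inheritParams synchrony_experiment
#' @return Data frame with one row per `z`: final mse, mean MII, mean SSI,
#'   mean dropout fraction `q`.
#' @export
connectivity_sweep <- function(seed = 1, z_values = c(1, 10, 25, 50, 100),
                               epochs = 40, count = 5000, size = 8,
                               max_bars = 4, hidden_size = 16,
                               n_vessels = 100, ...) {
  dataset <- bar_patterns(count, size, max_bars, seed = seed)
  rows <- lapply(z_values, function(z) {
    arm <- run_arm(dataset, epsilon = 0, z = z, seed = seed, epochs = epochs,
                   hidden_size = hidden_size, n_vessels = n_vessels, ...)
    data.frame(z = z, final_mse = arm$final_mse, mii_mean = arm$mii_mean,
               ssi_mean = arm$ssi_mean, q_mean = arm$q_mean,
               converged = arm$converged)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}

#' Temporal-ratio sweep
#'
#' Trains one desynchronized (`epsilon = 0`, z = 1) arm per temporal ratio
#' TR, all paired on the same seed. TR is the number of input patterns
#' presented under a single frozen dropout mask (one vascular interval); at
#' large TR the same units stay dropped for long stretches, the temporal
#' stochasticity of the gating is lost, and the learned features degrade as
#' in the synchronized regime.
#'
#' @param seed Base seed shared by all arms.
#' @param TR_values Temporal ratios to sweep (patterns per interval).
#' @param epochs Training epochs per arm.
#' @inheritParams synchrony_experiment
#' @return Data frame with one row per TR: final mse, mean MII, mean SSI,
#'   mean dropout fraction `q`.
#' @export
temporal_sweep <- function(seed = 1, TR_values = c(20, 100, 500, 2500),
                           epochs = 40, count = 5000, size = 8,
                           max_bars = 4, hidden_size = 16, n_vessels = 100,
                           ...) {
  dataset <- bar_patterns(count, size, max_bars, seed = seed)
  rows <- lapply(TR_values, function(tr) {
    arm <- run_arm(dataset, epsilon = 0, z = 1, seed = seed, epochs = epochs,
                   hidden_size = hidden_size, n_vessels = n_vessels,
                   TR = tr, ...)
    data.frame(TR = tr, final_mse = arm$final_mse, mii_mean = arm$mii_mean,
               ssi_mean = arm$ssi_mean, q_mean = arm$q_mean,
               converged = arm$converged)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}
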