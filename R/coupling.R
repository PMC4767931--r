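#' Random vessel-to-neuron connectivity
#'
#' Each hidden neuron receives input from exactly `z` of the `n` vessels,
#' sampled uniformly without replacement and independently per neuron. `z`
#' is the projective-field size: `z = 1` is one-to-one-style connectivity,
#' `z = n` is complete connectivity (every neuron averages the whole ring,
#' so all neurons receive identical feedback and the spatial stochasticity
#' of desynchronized vessels is lost).
#'
#' For `z = 1` with `hidden_size <= n` the assignment is one-to-one: each
#' neuron gets its own vessel, sampled without replacement across neurons,
#' so no two neurons share a gate. For `z > 1` the `z` vessels are sampled
#' independently per neuron.
#'
#' @param hidden_size Number of hidden neurons H.
#' @param n Number of vessels.
#' @param z Projective-field size, in `[1, n]`.
#' @param seed Optional seed.
#' @return An object of class `vascular_connectivity`: binary `H x n` matrix
#'   `A` with row sums `z`, plus `z` and dimensions.
#' @export
vascular_connectivity <- function(hidden_size, n, z, seed = NULL) {
  stopifnot(hidden_size >= 1, n >= 1)
  if (z < 1 || z > n)
    stop("`z` must lie in [1, n]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(0, hidden_size, n)
  if (z == 1 && hidden_size <= n) {
    vessels <- sample.int(n, hidden_size)
    A[cbind(seq_len(hidden_size), vessels)] <- 1
  } else {
    for (i in seq_len(hidden_size)) A[i, sample.int(n, z)] <- 1
  }
  structure(list(A = A, z = as.integer(z), hidden_size = as.integer(hidden_size),
                 n = as.integer(n)),
            class = "vascular_connectivity")
}

#' @export
print.vascular_connectivity <- function(x, ...) {
  cat(sprintf("Vessel-to-neuron connectivity: %d neurons x %d vessels, z = %d per neuron\n",
              x$hidden_size, x$n, x$z))
  invisible(x)
}

#' Dropout mask from vessel states
#'
#' Each neuron is ON when the mean state of its `z` connected vessels is
#' positive: `r_i = H((1/z) * sum_j a_ij S_j)` with the Heaviside convention
#' `H(0) = 0` (a neuron on an exact tie stays OFF).
#'
#' @param S Vessel state vector (length n).
#' @param connectivity A [vascular_connectivity()] object.
#' @return Binary mask vector of length H.
#' @export
neuron_mask <- function(S, connectivity) {
  stopifnot(inherits(connectivity, "vascular_connectivity"))
  if (length(S) != connectivity$n)
    stop("`S` length does not match the number of vessels", call. = FALSE)
  as.numeric(as.vector(connectivity$A %*% S) / connectivity$z > 0)
}

#' Neuronal demand state
#'
#' Tracks the scalar neuronal demand N_d that the vascular ring is asked to
#' supply, together with the smoothed reconstruction error and previous
#' demand needed for the finite-difference demand update. Demand starts at
#' the maximum possible value `n` (all vessels ON, zero dropout) and is
#' treated as a nonnegative energy need, clipped to `[0, n]`.
#'
#' @param n Number of vessels.
#' @param beta Perfusion-rate parameter: gain on the finite-difference error
#'   gradient (> 0).
#' @param economy Per-update relaxation of demand toward the homeostatic
#'   reference `N_ref` (>= 0; a constant step of this magnitude in the
#'   direction of `N_ref`). Models the premise that perfusion is costly:
#'   demand relaxes to its resting reference unless the error gradient
#'   resists. Set to 0 for a pure gradient update.
#' @param alpha Smoothing weight of the exponential moving average of the
#'   interval error that the controller differences (in (0, 1]; 1 disables
#'   smoothing). Raw interval errors jump with every mask refresh and data
#'   reshuffle, so the finite difference is taken on this smoothed trend.
#' @param N_ref Resting demand the economy term relaxes toward. Default
#'   `n / 4`, placing the desynchronized ring at a supply level where the
#'   hidden-unit gates are near their least correlated while dropout stays
#'   substantial (about 40 percent OFF).
#' @return An object of class `demand_state`.
#' @export
demand_state <- function(n, beta = 1, economy = 0.02, alpha = 0.02,
                         N_ref = n / 4) {
  stopifnot(n >= 1, beta > 0, economy >= 0, alpha > 0, alpha <= 1,
            N_ref >= 0, N_ref <= n)
  structure(list(N_d = n, n = n, beta = beta, economy = economy,
                 alpha = alpha, N_ref = N_ref, mse_smooth = NA_real_,
                 mse_prev = NA_real_, N_d_prev = NA_real_),
            class = "demand_state")
}

#' @export
print.demand_state <- function(x, ...) {
  cat(sprintf("Demand state: N_d = %.3f (range [0, %g], beta = %g, economy = %g)\n",
              x$N_d, x$n, x$beta, x$economy))
  invisible(x)
}

#' Finite-difference demand update
#'
#' Gradient-style descent of the reconstruction error with respect to the
#' demand: `N_d <- N_d - beta * (delta mse / delta N_d) - economy`. The
#' finite difference is taken on an exponentially smoothed error trend (see
#' [demand_state()]); the gradient step magnitude is capped at 10 per update
#' so one interval cannot swing the demand across its range. Safeguards: on
#' the very first interval there is no difference yet and a probe step of -1
#' nudges demand away from the all-ON start; when the previous demand change
#' is numerically zero the ratio is undefined and a probe of magnitude 0.1
#' against the error trend is used; when the smoothed error did not change
#' the gradient term is zero. The `economy` term is then added and the
#' result clipped to `[0, n]`.
#'
#' @param demand A [demand_state()].
#' @param mse_current Reconstruction error of the interval just completed.
#' @return The updated `demand_state`.
#' @export
update_demand <- function(demand, mse_current) {
  stopifnot(inherits(demand, "demand_state"))
  if (!is.finite(mse_current))
    stop("demand update received a non-finite mse", call. = FALSE)
  ema <- if (is.na(demand$mse_smooth)) mse_current else
    (1 - demand$alpha) * demand$mse_smooth + demand$alpha * mse_current
  d_mse <- ema - demand$mse_prev
  d_Nd <- demand$N_d - demand$N_d_prev
  if (is.na(d_mse)) {
    step <- -1                                  # first interval: probe down
  } else {
    grad_step <-
      if (d_mse == 0) 0                         # flat error: no gradient term
      else if (abs(d_Nd) < 1e-6) -0.1 * sign(d_mse)
      else {
        ratio <- d_mse / d_Nd
        -sign(ratio) * min(demand$beta * abs(ratio), 10)
      }
    relax <- -demand$economy * sign(demand$N_d - demand$N_ref)
    step <- grad_step + relax
  }
  if (!is.finite(step))
    stop("demand update diverged", call. = FALSE)
  demand$N_d_prev <- demand$N_d
  demand$mse_prev <- ema
  demand$mse_smooth <- ema
  demand$N_d <- min(max(demand$N_d + step, 0), demand$n)
  demand
}

#' Assemble a coupled neurovascular model
#'
#' Bundles an autoencoder, a vascular network, a vessel-to-neuron
#' connectivity and a demand state into one trainable object.
#'
#' @param ae An [autoencoder()].
#' @param vasc A [vascular_network()].
#' @param connectivity A [vascular_connectivity()] whose dimensions match
#'   `ae` and `vasc`.
#' @param beta Perfusion-rate parameter for the demand update.
#' @param TR Temporal ratio: input patterns presented per vascular interval
#'   (split into minibatches of the autoencoder's batch size).
#' @param vascular_substeps Euler steps of the vessel dynamics per interval.
#'   The default (100 steps of `dt = 0.01`, one time unit per interval)
#'   paces the vessels so a hidden unit's gate typically persists for a few
#'   intervals in the desynchronized regime.
#' @param economy,alpha,N_ref Demand-controller parameters (see
#'   [demand_state()]). `economy` and `alpha` are given per minibatch of
#'   presented patterns; they are scaled internally by the number of
#'   minibatches one vascular interval spans, so the demand trajectory as a
#'   function of training progress is comparable across temporal ratios.
#' @return An object of class `neurovascular_model`.
#' @export
neurovascular_model <- function(ae, vasc, connectivity, beta = 1, TR = 20,
                                vascular_substeps = 100, economy = 0.02,
                                alpha = 0.02, N_ref = vasc$params$n / 4) {
  stopifnot(inherits(ae, "autoencoder"),
            inherits(vasc, "vascular_network"),
            inherits(connectivity, "vascular_connectivity"),
            TR >= 1, vascular_substeps >= 1)
  if (connectivity$hidden_size != ae$hidden_size)
    stop("connectivity rows must match the hidden layer size", call. = FALSE)
  if (connectivity$n != vasc$params$n)
    stop("connectivity columns must match the number of vessels", call. = FALSE)
  k <- max(1, ceiling(TR / ae$batch_size))
  structure(list(ae = ae, vasc = vasc, connectivity = connectivity,
                 demand = demand_state(vasc$params$n, beta = beta,
                                       economy = min(economy * k, 1),
                                       alpha = min(alpha * k, 1),
                                       N_ref = N_ref),
                 TR = as.integer(TR),
                 vascular_substeps = as.integer(vascular_substeps)),
            class = "neurovascular_model")
}

#' @export
print.neurovascular_model <- function(x, ...) {
  cat("Coupled neurovascular model\n")
  cat(sprintf("  autoencoder %d-%d-%d; %d vessels (epsilon = %g); z = %d; TR = %d\n",
              x$ae$input_size, x$ae$hidden_size, x$ae$input_size,
              x$vasc$params$n, x$vasc$params$epsilon, x$connectivity$z, x$TR))
  cat(sprintf("  demand N_d = %.2f\n", x$demand$N_d))
  invisible(x)
}

#' Train a coupled model through one pass over a batch stream
#'
#' Runs the neurovascular loop over the supplied minibatches. Each vascular
#' interval consists of: (1) advancing the vessel dynamics by
#' `vascular_substeps` Euler steps under the current deficit signal I;
#' (2) freezing the dropout mask computed from the vessel states; (3)
#' presenting TR input patterns (consecutive minibatches from the stream)
#' under that mask, updating the weights and accumulating the masked
#' reconstruction error; (4) one deficit update `e = N_d - N_s`,
#' `E <- E + (dt_interval / tau_e) tanh(lambda_e e)`, `I = E - n/2`, where
#' `dt_interval` is the duration of the interval's vessel substeps; and (5)
#' the finite-difference demand update from the interval error.
#'
#' @param model A [neurovascular_model()].
#' @param batches List of `M x bt` minibatch matrices (see [batch_stream()]).
#' @return List with the updated `model` and `log`, a data frame with one
#'   row per vascular interval: `interval`, `mse`, `q` (dropout fraction),
#'   `N_d`, `N_s`, `E`, `I`.
#' @export
run_coupled_epoch <- function(model, batches) {
  stopifnot(inherits(model, "neurovascular_model"), length(batches) >= 1)
  ae <- model$ae
  vasc <- model$vasc
  demand <- model$demand
  conn <- model$connectivity
  bt <- ae$batch_size
  batches_per_interval <- max(1L, ceiling(model$TR / bt))
  n_intervals <- ceiling(length(batches) / batches_per_interval)
  dt_interval <- model$vascular_substeps * vasc$params$dt
  log_mse <- log_q <- log_Nd <- log_Ns <- log_E <- log_I <-
    numeric(n_intervals)
  b <- 1L
  p <- vasc$params
  for (iv in seq_len(n_intervals)) {
    sub <- .ring_substeps_cpp(vasc$g, vasc$u, vasc$T, vasc$I, p$dt,
                              p$tau_v, p$lambda_v, model$vascular_substeps)
    vasc$g <- sub$g; vasc$u <- sub$u; vasc$S <- sub$S
    mask <- neuron_mask(vasc$S, conn)
    mse_sum <- 0
    n_used <- 0L
    while (n_used < batches_per_interval && b <= length(batches)) {
      st <- ae_train_step(ae, batches[[b]], mask)
      ae <- st$net
      mse_sum <- mse_sum + st$mse
      n_used <- n_used + 1L
      b <- b + 1L
    }
    interval_mse <- mse_sum / n_used
    N_s <- compute_supply(vasc$S)
    vasc <- update_deficit(vasc, demand$N_d, N_s, dt = dt_interval)
    demand <- update_demand(demand, interval_mse)
    log_mse[iv] <- interval_mse
    log_q[iv] <- 1 - mean(mask)
    log_Nd[iv] <- demand$N_d
    log_Ns[iv] <- N_s
    log_E[iv] <- vasc$E
    log_I[iv] <- vasc$I
  }
  model$ae <- ae
  model$vasc <- vasc
  model$demand <- demand
  list(model = model,
       log = data.frame(interval = seq_len(n_intervals), mse = log_mse,
                        q = log_q, N_d = log_Nd, N_s = log_Ns,
                        E = log_E, I = log_I))
}

#' Train a coupled model for several epochs
#'
#' Repeatedly reshuffles the dataset into minibatches and runs
#' [run_coupled_epoch()], concatenating the per-interval logs. The converged
#' reconstruction error is summarized as the mean interval error over the
#' final epoch.
#'
#' @param model A [neurovascular_model()].
#' @param dataset An `image_dataset`.
#' @param epochs Number of passes over the dataset.
#' @param shuffle Reshuffle the image order each epoch?
#' @param anneal_from Fraction of epochs after which the learning rate is
#'   annealed (late-phase decay lowers the gradient-noise floor on the
#'   weights; set to 1 to disable).
#' @param anneal_factor Multiplicative learning-rate decay per epoch during
#'   the annealing phase.
#' @param verbose Print a line per epoch?
#' @return List with `model`, `log` (all intervals, with an `epoch` column)
#'   and `final_mse`, the converged reconstruction error: the mean interval
#'   mse over the final quarter of all intervals. (Averaging over a long
#'   tail window matters in the synchronized regime, where the collective
#'   gate alternates between slow all-ON and all-OFF stretches.)
#' @export
train_coupled <- function(model, dataset, epochs = 50, shuffle = TRUE,
                          anneal_from = 0.7, anneal_factor = 0.9,
                          verbose = FALSE) {
  stopifnot(inherits(dataset, "image_dataset"), epochs >= 1)
  logs <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    if (ep > ceiling(anneal_from * epochs))
      model$ae$learning_rate <- model$ae$learning_rate * anneal_factor
    batches <- batch_stream(dataset, model$ae$batch_size, shuffle = shuffle)
    res <- run_coupled_epoch(model, batches)
    model <- res$model
    res$log$epoch <- ep
    logs[[ep]] <- res$log
    if (verbose)
      message(sprintf("epoch %3d: mse = %.5f, q = %.2f, N_d = %.1f",
                      ep, mean(res$log$mse), mean(res$log$q),
                      model$demand$N_d))
  }
  log <- do.call(rbind, logs)
  tail_n <- max(1L, nrow(log) %/% 4L)
  list(model = model, log = log,
       final_mse = mean(utils::tail(log$mse, tail_n)))
}
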