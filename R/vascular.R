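#' Parameters of the vascular oscillator ring
#'
#' Bundles and validates the constants of the vascular network: `n` coupled
#' vessel units arranged on a ring of radius `rho`, interacting through a
#' distance-dependent lateral kernel of width `sigma` whose
#' excitation/inhibition balance is set by `epsilon`. Each vessel carries a
#' supporting variable g, an activity-history variable u (time constant
#' `tau_v`) and a perfusion state S = tanh(lambda_v * g) in (-1, 1). A scalar
#' deficit signal, accumulated with time constant `tau_e` through a
#' tanh(lambda_e * e) nonlinearity, drives all vessels identically.
#'
#' @param n Number of vessels (integer >= 2).
#' @param epsilon Excitation/inhibition balance in `[0, 2]`. `epsilon = 0`
#'   makes every lateral interaction inhibitory (desynchronized, chaotic
#'   regime); `epsilon` near 2 makes distant interactions excitatory
#'   (synchronized regime).
#' @param sigma Width of the lateral interaction kernel, in the same length
#'   units as inter-vessel distances. Interactions are cut off beyond
#'   `3 * sigma`.
#' @param rho Ring radius (length units, > 0).
#' @param lambda_v Slope of the vessel-state nonlinearity (> 0).
#' @param tau_v Time constant of the history variable u (> 0).
#' @param tau_e Time constant of deficit accumulation (> 0).
#' @param lambda_e Slope of the deficit nonlinearity (> 0).
#' @param dt Euler integration step (time units, > 0).
#' @param kernel `"printed"` uses exp(-d / sigma^2) in the lateral kernel;
#'   `"gaussian"` uses exp(-d^2 / sigma^2). Both variants are supported for
#'   sensitivity checks; `"printed"` is the default.
#' @param self_coupling If `TRUE`, a vessel couples to itself with weight
#'   `epsilon - 2` (the kernel evaluated at distance zero). The default
#'   `FALSE` treats the ring as mutually coupled with no self-interaction;
#'   the self term is strong enough to pin every vessel at a fixed point and
#'   suppresses the network's oscillatory regimes entirely.
#'
#' @return An object of class `vascular_params`.
#' @seealso [vascular_network()], [simulate_vascular()]
#' @export
#' @examples
#' p <- vascular_params(n = 10, epsilon = 0)
#' p$sigma
vascular_params <- function(n = 100, epsilon = 0, sigma = 0.25, rho = 1,
                            lambda_v = 5, tau_v = 5, tau_e = 10,
                            lambda_e = 1, dt = 0.01,
                            kernel = c("printed", "gaussian"),
                            self_coupling = FALSE) {
  kernel <- match.arg(kernel)
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n))
    stop("`n` must be a single integer >= 2", call. = FALSE)
  if (epsilon < 0 || epsilon > 2)
    stop("`epsilon` must lie in [0, 2]", call. = FALSE)
  pos <- c(sigma = sigma, rho = rho, lambda_v = lambda_v, tau_v = tau_v,
           tau_e = tau_e, lambda_e = lambda_e, dt = dt)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    stop("strictly positive values required for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(n = as.integer(n), epsilon = epsilon, sigma = sigma,
                 rho = rho, lambda_v = lambda_v, tau_v = tau_v,
                 tau_e = tau_e, lambda_e = lambda_e, dt = dt,
                 kernel = kernel, self_coupling = self_coupling),
            class = "vascular_params")
}

#' @export
print.vascular_params <- function(x, ...) {
  cat("Vascular ring parameters\n")
  cat(sprintf("  n = %d vessels, epsilon = %g, sigma = %g, rho = %g (%s kernel)\n",
              x$n, x$epsilon, x$sigma, x$rho, x$kernel))
  cat(sprintf("  lambda_v = %g, tau_v = %g, tau_e = %g, lambda_e = %g, dt = %g\n",
              x$lambda_v, x$tau_v, x$tau_e, x$lambda_e, x$dt))
  invisible(x)
}

#' Positions and pairwise distances of vessels on the ring
#'
#' Vessels are placed at evenly spaced angles `2 * pi * (j - 1) / n` on a
#' circle of radius `rho`; the distance between two vessels is the chord
#' length `rho * sqrt((cos a_j - cos a_k)^2 + (sin a_j - sin a_k)^2)`.
#'
#' @param n Number of vessels (>= 2).
#' @param rho Ring radius (> 0).
#' @return A list with `angles` (length `n`, radians in `[0, 2*pi)`) and
#'   `distances` (symmetric `n x n` chord-length matrix, zero diagonal).
#' @export
#' @examples
#' ring_geometry(4, 1)$distances
ring_geometry <- function(n, rho) {
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n))
    stop("`n` must be a single integer >= 2", call. = FALSE)
  if (length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("`rho` must be a single positive number", call. = FALSE)
  angles <- 2 * pi * (seq_len(n) - 1) / n
  dx <- outer(cos(angles), cos(angles), "-")
  dy <- outer(sin(angles), sin(angles), "-")
  distances <- rho * sqrt(dx^2 + dy^2)
  list(angles = angles, distances = distances)
}

#' Lateral coupling matrix of the vascular ring
#'
#' Interaction weights are `epsilon - 2 * exp(-d / sigma^2)` for vessel pairs
#' closer than `3 * sigma` and zero beyond the cutoff (with the
#' `"gaussian"` kernel variant substituting `d^2` for `d` in the exponent).
#' With `epsilon = 0` every nonzero weight is negative (mutual inhibition);
#' as `epsilon` grows, distant pairs within the cutoff become excitatory.
#'
#' @param distances Symmetric nonnegative distance matrix, e.g. from
#'   [ring_geometry()].
#' @param epsilon Excitation/inhibition balance in `[0, 2]`.
#' @param sigma Kernel width (> 0).
#' @inheritParams vascular_params
#' @return Symmetric coupling matrix of the same dimension as `distances`.
#' @export
#' @examples
#' geo <- ring_geometry(8, 1)
#' Tm <- coupling_matrix(geo$distances, epsilon = 1, sigma = 1)
coupling_matrix <- function(distances, epsilon, sigma,
                            kernel = c("printed", "gaussian"),
                            self_coupling = FALSE) {
  kernel <- match.arg(kernel)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  if (epsilon < 0 || epsilon > 2)
    stop("`epsilon` must lie in [0, 2]", call. = FALSE)
  if (!is.matrix(distances) || nrow(distances) != ncol(distances) ||
      any(distances < 0))
    stop("`distances` must be a square nonnegative matrix", call. = FALSE)
  expo <- if (kernel == "printed") distances / sigma^2 else distances^2 / sigma^2
  Tm <- ifelse(distances < 3 * sigma, epsilon - 2 * exp(-expo), 0)
  if (!self_coupling) diag(Tm) <- 0
  Tm
}

#' Initialize a vascular network
#'
#' Creates the ring geometry, the coupling matrix and the initial state: g
#' and u drawn uniformly from `[-0.01, 0.01]` (small random values that break
#' symmetry in the desynchronized regime), S = tanh(lambda_v * g), and the
#' accumulated deficit E started at `n / 2` so the deficit signal
#' I = E - n / 2 begins neutral at zero.
#'
#' @param params A [vascular_params()] object.
#' @param seed Optional integer seed for the initial conditions.
#' @return An object of class `vascular_network` with elements `params`,
#'   `geometry`, `T` (coupling matrix) and the state vectors `g`, `u`, `S`
#'   plus scalars `E` and `I`.
#' @export
vascular_network <- function(params, seed = NULL) {
  stopifnot(inherits(params, "vascular_params"))
  if (!is.null(seed)) set.seed(seed)
  geo <- ring_geometry(params$n, params$rho)
  Tm <- coupling_matrix(geo$distances, params$epsilon, params$sigma,
                        kernel = params$kernel,
                        self_coupling = params$self_coupling)
  g <- stats::runif(params$n, -0.01, 0.01)
  u <- stats::runif(params$n, -0.01, 0.01)
  structure(list(params = params, geometry = geo, T = Tm,
                 g = g, u = u, S = tanh(params$lambda_v * g),
                 E = params$n / 2, I = 0),
            class = "vascular_network")
}

#' @export
print.vascular_network <- function(x, ...) {
  cat(sprintf("Vascular ring network: %d vessels (epsilon = %g)\n",
              x$params$n, x$params$epsilon))
  cat(sprintf("  supply N_s = %.3f, accumulated deficit E = %.3f, I = %.3f\n",
              compute_supply(x$S), x$E, x$I))
  invisible(x)
}

#' One Euler step of the vessel dynamics
#'
#' Advances g and u by one explicit-Euler step of
#' `dg/dt = -g - u + T S + I` and `tau_v du/dt = -u + S`, then recomputes
#' `S = tanh(lambda_v g)`. The scalar deficit signal `I` is broadcast to all
#' vessels. The accumulated deficit E is not touched here; see
#' [update_deficit()].
#'
#' @param net A `vascular_network`.
#' @param I Deficit signal (scalar); defaults to the network's current value.
#' @return The updated network.
#' @export
step_vascular <- function(net, I = net$I) {
  p <- net$params
  g <- net$g + p$dt * (-net$g - net$u + as.vector(net$T %*% net$S) + I)
  u <- net$u + (p$dt / p$tau_v) * (-net$u + net$S)
  if (!all(is.finite(g)) || !all(is.finite(u)))
    stop("vascular state became non-finite; reduce `dt` or coupling strength",
         call. = FALSE)
  net$g <- g
  net$u <- u
  net$S <- tanh(p$lambda_v * g)
  net
}

#' Total vascular supply
#'
#' The supply delivered to the tissue is the sum of all vessel states,
#' a scalar in `(-n, n)`.
#'
#' @param S Vector of vessel states.
#' @return Scalar sum of `S`.
#' @export
compute_supply <- function(S) sum(S)

#' Update the accumulated energy deficit
#'
#' Computes the instantaneous deficit `e = N_d - N_s`, integrates the
#' accumulated deficit `tau_e dE/dt = tanh(lambda_e e)` by one Euler step of
#' length `dt`, and refreshes the deficit signal `I = E - n / 2` that drives
#' the vessels.
#'
#' @param net A `vascular_network`.
#' @param N_d Neuronal demand (scalar).
#' @param N_s Vascular supply; defaults to `compute_supply(net$S)`.
#' @param dt Integration step for the deficit accumulator; defaults to the
#'   vascular `dt`. The coupled training loop passes the duration of one
#'   vascular interval here so deficit time advances at the same rate as
#'   vessel time.
#' @return The network with updated `E` and `I`; the instantaneous deficit is
#'   attached as attribute `"e"` for logging.
#' @export
update_deficit <- function(net, N_d, N_s = compute_supply(net$S),
                           dt = net$params$dt) {
  p <- net$params
  e <- N_d - N_s
  net$E <- net$E + (dt / p$tau_e) * tanh(p$lambda_e * e)
  net$I <- net$E - p$n / 2
  attr(net, "e") <- e
  net
}

#' Simulate the vascular ring under constant demand
#'
#' Integrates the full vessel + deficit system for `duration` time units with
#' a fixed neuronal demand `N_d`, recording vessel states every `record_dt`
#' time units after an optional burn-in. This is the stand-alone vascular
#' experiment used to characterize synchrony regimes: with the default
#' parameters, `epsilon = 1` settles into a network-wide limit cycle
#' (average pairwise correlation near 1) while `epsilon = 0` sustains
#' desynchronized, chaotic activity (average pairwise correlation near 0).
#'
#' @param params A [vascular_params()] object.
#' @param N_d Constant neuronal demand (default 0: supply balanced between ON
#'   and OFF vessels).
#' @param duration Simulated time after burn-in (time units).
#' @param burn_in Initial stretch discarded from the record (time units).
#' @param record_dt Interval between recorded samples (time units).
#' @param seed Optional seed for the random initial conditions.
#' @param engine `"compiled"` runs the Euler loop in C++; `"reference"` is
#'   the plain-R loop over [step_vascular()] and [update_deficit()]. Both
#'   compute identical trajectories; the reference engine exists as the
#'   cross-check and is much slower.
#' @return An object of class `vascular_sim`: list with `S_history`
#'   (`n x n_samples` matrix), `times`, `params`, `N_d`, and the final
#'   `network`.
#' @export
#' @examples
#' p <- vascular_params(n = 20, epsilon = 1)
#' sim <- simulate_vascular(p, duration = 50, burn_in = 20, seed = 1)
#' compute_apc(sim$S_history)
simulate_vascular <- function(params, N_d = 0, duration = 200, burn_in = 100,
                              record_dt = 0.1, seed = NULL,
                              engine = c("compiled", "reference")) {
  stopifnot(inherits(params, "vascular_params"))
  engine <- match.arg(engine)
  net <- vascular_network(params, seed = seed)
  dt <- params$dt
  rec_every <- max(1L, round(record_dt / dt))
  n_steps <- round((duration + burn_in) / dt)
  skip <- round(burn_in / dt)
  n_rec <- (n_steps - skip) %/% rec_every
  if (engine == "compiled") {
    res <- .ring_run_cpp(net$g, net$u, net$E, net$T, N_d, dt, params$tau_v,
                         params$lambda_v, params$tau_e, params$lambda_e,
                         n_steps, skip, rec_every)
    net$g <- res$g; net$u <- res$u
    net$S <- tanh(params$lambda_v * res$g)
    net$E <- res$E; net$I <- res$E - params$n / 2
    S_history <- res$S_history
    times <- res$times
  } else {
    S_history <- matrix(NA_real_, params$n, n_rec)
    times <- numeric(n_rec)
    k <- 0L
    for (it in seq_len(n_steps)) {
      net <- step_vascular(net)
      net <- update_deficit(net, N_d)
      if (it > skip && (it - skip) %% rec_every == 0L) {
        k <- k + 1L
        S_history[, k] <- net$S
        times[k] <- it * dt
      }
    }
  }
  structure(list(S_history = S_history, times = times, params = params,
                 N_d = N_d, network = net),
            class = "vascular_sim")
}

#' @export
print.vascular_sim <- function(x, ...) {
  cat(sprintf("Vascular simulation: %d vessels, %d samples over %.1f time units (epsilon = %g)\n",
              nrow(x$S_history), ncol(x$S_history),
              diff(range(x$times)), x$params$epsilon))
  apc <- tryCatch(compute_apc(x$S_history), error = function(e) NA_real_)
  cat(sprintf("  APC = %s\n",
              if (is.na(apc)) "undefined (constant trace)" else sprintf("%.3f", apc)))
  invisible(x)
}

#' Export a simulated trajectory as CSV
#'
#' Writes one row per (time, vessel) pair with the recorded vessel state,
#' suitable for raster- or line-plot reconstruction of the synchrony regimes.
#'
#' @param sim A `vascular_sim` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(sim, path) {
  stopifnot(inherits(sim, "vascular_sim"))
  n <- nrow(sim$S_history)
  df <- data.frame(
    t = rep(sim$times, each = n),
    vessel = rep(seq_len(n), times = ncol(sim$S_history)),
    S = as.vector(sim$S_history)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Average pairwise correlation (APC) of vessel traces
#'
#' The synchrony measure of the ring: the Pearson correlation of every
#' ordered pair of distinct vessel time series, averaged over all
#' `n * (n - 1)` pairs. Near 1 for synchronized dynamics, near 0 for
#' desynchronized dynamics.
#'
#' @param S_history Matrix of vessel states, one row per vessel, one column
#'   per time sample (at least 2 of each).
#' @return Scalar APC in `[-1, 1]`.
#' @export
compute_apc <- function(S_history) {
  if (!is.matrix(S_history) || nrow(S_history) < 2 || ncol(S_history) < 2)
    stop("`S_history` must be a matrix with >= 2 vessels and >= 2 time points",
         call. = FALSE)
  v <- apply(S_history, 1, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    stop("correlation undefined: vessel(s) ",
         paste(bad, collapse = ", "), " have constant traces", call. = FALSE)
  }
  C <- stats::cor(t(S_history))
  n <- nrow(S_history)
  (sum(C) - n) / (n * (n - 1))
}
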