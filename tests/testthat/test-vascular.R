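test_that("ring geometry places vessels evenly and distances are chords", {
  geo <- ring_geometry(2, 1)
  expect_equal(geo$angles, c(0, pi))
  expect_equal(geo$distances[1, 2], 2)        # diametrically opposite points

  geo4 <- ring_geometry(4, 1)
  expect_equal(geo4$distances[1, 2], sqrt(2))
  for (n in c(3, 5, 8)) {
    rho <- 1.7
    geo <- ring_geometry(n, rho)
    expect_equal(diag(geo$distances), rep(0, n))
    expect_equal(geo$distances, t(geo$distances))
    for (j in 1:n) for (k in 1:n)
      expect_equal(geo$distances[j, k], oracle_chord(j, k, n, rho))
  }
  expect_error(ring_geometry(1, 1), "n")
  expect_error(ring_geometry(5, -1), "rho")
})

test_that("coupling matrix matches the kernel formula element-wise", {
  # beyond the cutoff the interaction vanishes
  d <- matrix(c(0, 4, 4, 0), 2)
  expect_equal(coupling_matrix(d, epsilon = 1, sigma = 1)[1, 2], 0)
  # at zero distance with epsilon = 0 the literal kernel gives -2
  expect_equal(coupling_matrix(matrix(0, 1, 1), 0, 1,
                               self_coupling = TRUE)[1, 1], -2)

  geo <- ring_geometry(8, 1)
  for (kern in c("printed", "gaussian")) {
    Tm <- coupling_matrix(geo$distances, epsilon = 1, sigma = 1,
                          kernel = kern, self_coupling = TRUE)
    for (j in 1:8) for (k in 1:8)
      expect_equal(Tm[j, k],
                   oracle_coupling_entry(geo$distances[j, k], 1, 1, kern))
  }
  expect_error(coupling_matrix(geo$distances, 1, -0.5), "sigma")
  expect_error(coupling_matrix(geo$distances, 3, 1), "epsilon")
})

test_that("coupling matrix is symmetric, cutoff-sparse, and sign-consistent", {
  geo <- ring_geometry(30, 1)
  for (eps in c(0, 1, 2)) {
    Tm <- coupling_matrix(geo$distances, eps, sigma = 0.25)
    expect_equal(Tm, t(Tm))
    expect_true(all(Tm[geo$distances > 3 * 0.25] == 0))
    inside <- geo$distances < 3 * 0.25 & geo$distances > 0
    if (eps == 0) expect_true(all(Tm[inside] < 0))   # mutual inhibition
    if (eps == 2) expect_true(all(Tm[inside] >= 0))
    # off-diagonal entries within the cutoff stay in [eps - 2, eps)
    expect_true(all(Tm[inside] >= eps - 2 & Tm[inside] < eps))
  }
})

test_that("the origin with zero deficit signal is a fixed point", {
  p <- vascular_params(n = 10, epsilon = 1)
  net <- vascular_network(p, seed = 1)
  net$g <- rep(0, 10); net$u <- rep(0, 10); net$S <- rep(0, 10)
  out <- step_vascular(net, I = 0)
  expect_equal(out$g, rep(0, 10))
  expect_equal(out$u, rep(0, 10))
  expect_equal(out$S, rep(0, 10))
})

test_that("an isolated vessel oscillates about the origin", {
  # no lateral coupling, no deficit input: the (g, u) system spirals through
  # repeated sign changes of g
  p <- vascular_params(n = 2, epsilon = 0, sigma = 0.01)  # cutoff kills T
  net <- vascular_network(p, seed = 1)
  expect_true(all(net$T == 0))
  net$g <- c(0.1, 0.1); net$u <- c(0, 0); net$S <- tanh(p$lambda_v * net$g)
  g_trace <- numeric(3000)
  for (it in 1:3000) {           # 30 time units
    net <- step_vascular(net, I = 0)
    g_trace[it] <- net$g[1]
  }
  sign_changes <- sum(diff(sign(g_trace[g_trace != 0])) != 0)
  expect_gte(sign_changes, 3)
})

test_that("the Euler integrator converges under step halving", {
  end_state <- function(dt) {
    p <- vascular_params(n = 6, epsilon = 1, sigma = 1, dt = dt)
    sim <- simulate_vascular(p, N_d = 0, duration = 10, burn_in = 0,
                             record_dt = 10, seed = 7)
    sim$S_history[, ncol(sim$S_history)]
  }
  s1 <- end_state(0.02)
  s2 <- end_state(0.01)
  s3 <- end_state(0.005)
  d12 <- max(abs(s1 - s2))
  d23 <- max(abs(s2 - s3))
  expect_lt(d23, d12)            # first-order error shrinks with the step
  expect_lt(d23, 0.05)
})

test_that("compiled and reference integration engines agree", {
  p <- vascular_params(n = 12, epsilon = 0)
  a <- simulate_vascular(p, N_d = 5, duration = 5, burn_in = 1, seed = 3)
  b <- simulate_vascular(p, N_d = 5, duration = 5, burn_in = 1, seed = 3,
                         engine = "reference")
  expect_equal(a$S_history, b$S_history, tolerance = 1e-12)
  expect_equal(a$network$E, b$network$E, tolerance = 1e-12)
})

test_that("vessel states remain inside (-1, 1) along trajectories", {
  p <- vascular_params(n = 20, epsilon = 0)
  sim <- simulate_vascular(p, N_d = 0, duration = 50, burn_in = 0, seed = 2)
  expect_true(all(abs(sim$S_history) < 1))
})

test_that("supply is the plain sum of vessel states", {
  expect_equal(compute_supply(c(0.9, -0.9)), 0)
  set.seed(1)
  S <- runif(17, -1, 1)
  acc <- 0; for (s in S) acc <- acc + s
  expect_equal(compute_supply(S), acc)
})

test_that("deficit accumulation follows its closed form under constant deficit", {
  p <- vascular_params(n = 10, epsilon = 0, tau_e = 10, lambda_e = 1)
  net <- vascular_network(p, seed = 1)
  net$E <- 2
  # N_d = N_s: deficit zero, E untouched, I = E - n/2
  out <- update_deficit(net, N_d = 3, N_s = 3)
  expect_equal(out$E, 2)
  expect_equal(out$I, 2 - 5)
  # saturated deficit: per-step increment approaches dt / tau_e
  out2 <- update_deficit(net, N_d = 1e6, N_s = 0)
  expect_equal(out2$E - net$E, p$dt / p$tau_e)
  # 100 steps at constant deficit e match E(t) = E0 + t * tanh(lambda_e e)/tau_e
  e <- 0.7
  net$E <- 0
  for (i in 1:100) net <- update_deficit(net, N_d = e, N_s = 0)
  expect_equal(net$E, 100 * p$dt * tanh(p$lambda_e * e) / p$tau_e,
               tolerance = 1e-12)
})

test_that("average pairwise correlation matches its pairwise oracle", {
  t <- seq(0, 4 * pi, length.out = 60)
  same <- matrix(rep(sin(t), 3), nrow = 3, byrow = TRUE)
  expect_equal(compute_apc(same), 1)
  anti <- rbind(sin(t), -sin(t))
  expect_equal(compute_apc(anti), -1)
  set.seed(42)
  S <- matrix(rnorm(5 * 50), 5, 50)
  expect_equal(compute_apc(S), oracle_apc(S), tolerance = 1e-12)
  expect_lte(abs(compute_apc(S)), 1)
  S[3, ] <- 1
  expect_error(compute_apc(S), "3")
  expect_error(compute_apc(matrix(1, 1, 5)), "2 vessels")
})

test_that("synchronized coupling yields higher APC than desynchronized", {
  for (seed in 1:5) {
    apc0 <- compute_apc(simulate_vascular(vascular_params(n = 40, epsilon = 0),
                                          duration = 80, burn_in = 60,
                                          seed = seed)$S_history)
    apc1 <- compute_apc(simulate_vascular(vascular_params(n = 40, epsilon = 1),
                                          duration = 80, burn_in = 60,
                                          seed = seed)$S_history)
    expect_gt(apc1, apc0)
  }
})

test_that("trajectory export writes a tidy CSV", {
  p <- vascular_params(n = 4, epsilon = 0)
  sim <- simulate_vascular(p, duration = 2, burn_in = 0, seed = 1)
  path <- tempfile(fileext = ".csv")
  export_trajectory(sim, path)
  df <- read.csv(path)
  expect_named(df, c("t", "vessel", "S"))
  expect_equal(nrow(df), 4 * ncol(sim$S_history))
  unlink(path)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(vascular_params(n = 1), "n")
  expect_error(vascular_params(epsilon = -0.1), "epsilon")
  expect_error(vascular_params(tau_v = 0), "tau_v")
  expect_error(vascular_params(dt = -0.01), "dt")
})
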