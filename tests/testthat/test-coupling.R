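test_that("connectivity rows always contain exactly z vessels", {
  conn <- vascular_connectivity(8, 10, 10, seed = 1)
  expect_true(all(conn$A == 1))                  # complete connectivity
  for (z in c(1, 3, 7)) {
    conn <- vascular_connectivity(6, 10, z, seed = z)
    expect_equal(unname(rowSums(conn$A)), rep(z, 6))
    expect_true(all(conn$A %in% c(0, 1)))
  }
  # one-to-one: distinct vessels per neuron
  conn1 <- vascular_connectivity(16, 100, 1, seed = 2)
  expect_equal(max(colSums(conn1$A)), 1)
  expect_error(vascular_connectivity(4, 10, 0), "z")
  expect_error(vascular_connectivity(4, 10, 11), "z")
})

test_that("neuron gating thresholds the mean of connected vessel states", {
  conn <- vascular_connectivity(3, 5, 2, seed = 1)
  expect_equal(neuron_mask(rep(1, 5), conn), rep(1, 3))
  expect_equal(neuron_mask(rep(-1, 5), conn), rep(0, 3))
  expect_equal(neuron_mask(rep(0, 5), conn), rep(0, 3))  # H(0) = 0: tie is OFF

  set.seed(8)
  conn <- vascular_connectivity(8, 10, 3, seed = 8)
  S <- runif(10, -1, 1)
  expected <- numeric(8)
  for (i in 1:8) {
    acc <- 0
    for (j in 1:10) acc <- acc + conn$A[i, j] * S[j]
    expected[i] <- as.numeric(acc / 3 > 0)
  }
  expect_equal(neuron_mask(S, conn), expected)
})

test_that("complete connectivity makes the mask spatially uniform", {
  conn <- vascular_connectivity(12, 20, 20, seed = 1)
  for (s in 1:5) {
    set.seed(s)
    S <- runif(20, -1, 1)
    m <- neuron_mask(S, conn)
    expect_equal(length(unique(m)), 1L)
  }
})

test_that("demand starts at the maximum and probes downward first", {
  dem <- demand_state(100)
  expect_equal(dem$N_d, 100)
  dem2 <- update_demand(dem, 0.5)
  expect_equal(dem2$N_d, 99)                     # first-interval probe of -1
})

test_that("a flat error contributes no gradient term to the demand update", {
  dem <- demand_state(100, economy = 0, alpha = 1)
  dem <- update_demand(dem, 0.5)
  n1 <- dem$N_d
  dem <- update_demand(dem, 0.5)                 # identical error: no move
  expect_equal(dem$N_d, n1)
})

test_that("demand descends a quadratic error surface toward its minimum", {
  c0 <- 40
  dem <- demand_state(100, beta = 1, economy = 0, alpha = 1)
  dist <- abs(dem$N_d - c0)
  for (i in 1:200) {
    dem <- update_demand(dem, (dem$N_d - c0)^2 / 100)
    d_new <- abs(dem$N_d - c0)
    expect_lte(d_new, dist + 1e-9)
    dist <- d_new
  }
  expect_lt(dist, 2)
})

test_that("demand stays clipped to its physical range", {
  dem <- demand_state(10, beta = 5, economy = 0.5, alpha = 1)
  for (i in 1:100) {
    dem <- update_demand(dem, runif(1, 0, 0.2))
    expect_gte(dem$N_d, 0)
    expect_lte(dem$N_d, 10)
  }
  expect_error(update_demand(dem, NaN), "finite")
})

test_that("model assembly enforces consistent dimensions", {
  ae <- autoencoder(16, 4, seed = 1)
  vasc <- vascular_network(vascular_params(n = 10, epsilon = 0), seed = 1)
  conn_bad_h <- vascular_connectivity(5, 10, 1, seed = 1)
  expect_error(neurovascular_model(ae, vasc, conn_bad_h), "hidden")
  conn_bad_n <- vascular_connectivity(4, 9, 1, seed = 1)
  expect_error(neurovascular_model(ae, vasc, conn_bad_n), "vessels")
})

test_that("coupled training is bit-reproducible under a fixed seed", {
  run_once <- function() {
    d <- bar_patterns(200, seed = 1)
    ae <- autoencoder(64, 16, learning_rate = 0.5, batch_size = 20, seed = 2)
    conn <- vascular_connectivity(16, 30, 1, seed = 3)
    vasc <- vascular_network(vascular_params(n = 30, epsilon = 0), seed = 4)
    model <- neurovascular_model(ae, vasc, conn)
    set.seed(5)
    train_coupled(model, d, epochs = 2)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$log, b$log)
  expect_identical(a$model$ae$W, b$model$ae$W)
  expect_true(all(a$log$q >= 0 & a$log$q <= 1))
  expect_true(all(a$log$N_d >= 0 & a$log$N_d <= 30))
})

test_that("desynchronized one-to-one gating is weakly correlated across neurons", {
  # at the operating demand level, per-neuron OFF events should be nearly
  # independent (mean absolute pairwise correlation below 0.2)
  p <- vascular_params(n = 100, epsilon = 0)
  sim <- simulate_vascular(p, N_d = 25, duration = 300, burn_in = 100,
                           record_dt = 0.5, seed = 4)
  conn <- vascular_connectivity(16, 100, 1, seed = 3)
  M <- apply(sim$S_history, 2, function(S) neuron_mask(S, conn))
  keep <- apply(M, 1, var) > 0
  C <- cor(t(M[keep, , drop = FALSE]))
  expect_lt(mean(abs(C[upper.tri(C)])), 0.2)
})
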