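# Independent brute-force oracles used to cross-check the implementation.
# Each is written as a plain scalar loop over the defining formula and never
# calls the package's own vectorized code paths.

# chord distance between ring positions j, k (1-based) for n vessels
oracle_chord <- function(j, k, n, rho) {
  aj <- 2 * pi * (j - 1) / n
  ak <- 2 * pi * (k - 1) / n
  rho * sqrt((cos(aj) - cos(ak))^2 + (sin(aj) - sin(ak))^2)
}

# lateral coupling weight for a single distance
oracle_coupling_entry <- function(d, epsilon, sigma, kernel = "printed") {
  ex <- if (kernel == "printed") d / sigma^2 else d^2 / sigma^2
  if (d < 3 * sigma) epsilon - 2 * exp(-ex) else 0
}

# mean pairwise Pearson correlation over all ordered pairs, scalar loops
oracle_apc <- function(S) {
  n <- nrow(S)
  total <- 0
  for (j in 1:n) for (k in 1:n) {
    if (j == k) next
    total <- total + stats::cor(S[j, ], S[k, ])
  }
  total / (n * (n - 1))
}

# batch reconstruction error by triple loop
oracle_mse <- function(X, Y) {
  bt <- ncol(X); M <- nrow(X)
  s <- 0
  for (p in 1:bt) for (m in 1:M) s <- s + (X[m, p] - Y[m, p])^2
  s / (2 * bt * M)
}

# histogram entropy by explicit binning loop (base 2)
oracle_entropy <- function(x, bins, range) {
  x <- as.vector(x)
  counts <- rep(0, bins)
  lo <- range[1]; w <- diff(range)
  for (v in x) {
    i <- if (w == 0) 1 else min(max(floor((v - lo) / w * bins) + 1, 1), bins)
    counts[i] <- counts[i] + 1
  }
  p <- counts / sum(counts)
  s <- 0
  for (pi in p) if (pi > 0) s <- s - pi * log2(pi)
  s
}

# mutual information index via explicit marginal + joint histograms
oracle_mii <- function(X, Y, bins) {
  pooled <- range(c(X, Y))
  sx <- oracle_entropy(X, bins, pooled)
  sy <- oracle_entropy(Y, bins, pooled)
  x <- as.vector(X); y <- as.vector(Y)
  lo <- pooled[1]; w <- diff(pooled)
  joint <- matrix(0, bins, bins)
  for (t in seq_along(x)) {
    i <- if (w == 0) 1 else min(max(floor((x[t] - lo) / w * bins) + 1, 1), bins)
    j <- if (w == 0) 1 else min(max(floor((y[t] - lo) / w * bins) + 1, 1), bins)
    joint[i, j] <- joint[i, j] + 1
  }
  p <- joint / sum(joint)
  sxy <- 0
  for (v in p) if (v > 0) sxy <- sxy - v * log2(v)
  sx + sy - sxy
}

# single-window structural similarity straight from its defining formula
oracle_ssi <- function(X, Y, C1 = NULL, C2 = NULL) {
  x <- as.vector(X); y <- as.vector(Y)
  L <- max(c(x, y)) - min(c(x, y)); if (L == 0) L <- 1
  if (is.null(C1)) C1 <- (0.01 * L)^2
  if (is.null(C2)) C2 <- (0.03 * L)^2
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  (2 * mx * my + C1) * (2 * cxy + C2) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

# loss of the masked autoencoder on a batch, for finite-difference checks
ae_loss <- function(net, X, mask) {
  fw <- ae_forward(net, X, mask)
  ae_mse(X, fw$y_new)
}

# central finite-difference gradient for one parameter block
oracle_fd_grad <- function(net, X, mask, block, h = 1e-6) {
  theta <- net[[block]]
  g <- array(0, dim = if (is.null(dim(theta))) length(theta) else dim(theta))
  for (i in seq_along(theta)) {
    np <- net; np[[block]][i] <- theta[i] + h
    nm <- net; nm[[block]][i] <- theta[i] - h
    g[i] <- (ae_loss(np, X, mask) - ae_loss(nm, X, mask)) / (2 * h)
  }
  g
}
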