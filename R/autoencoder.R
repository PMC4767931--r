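#' Rectified-linear activation
#'
#' `max(0, x)` element-wise, with `relu(0) = 0` and subgradient 0 taken at
#' the kink during training.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape with negative entries replaced by zero.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Construct a single-hidden-layer rectified-linear autoencoder
#'
#' A rate-coded network x -> h = W x + b -> v = relu(h) -> y = relu(Z v + B)
#' trained to reconstruct its input through the hidden bottleneck. Weights
#' are initialized uniformly in `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`, biases
#' at zero. During training the hidden activity is gated element-wise by an
#' external binary dropout mask (no inverted-dropout rescaling).
#'
#' @param input_size Number of input (and output) units M.
#' @param hidden_size Number of hidden units H (the bottleneck).
#' @param learning_rate SGD step size (> 0).
#' @param batch_size Default minibatch size bt (positive integer).
#' @param seed Optional seed for weight initialization.
#' @return An object of class `autoencoder` with weight matrices `W`
#'   (`H x M`), `Z` (`M x H`), bias vectors `b` (H) and `B` (M), and the
#'   training hyperparameters.
#' @export
#' @examples
#' ae <- autoencoder(64, 16, seed = 1)
autoencoder <- function(input_size, hidden_size, learning_rate = 0.05,
                        batch_size = 20, seed = NULL) {
  stopifnot(input_size >= 1, hidden_size >= 1, learning_rate > 0,
            batch_size >= 1)
  if (!is.null(seed)) set.seed(seed)
  lim_in <- 1 / sqrt(input_size)
  lim_hid <- 1 / sqrt(hidden_size)
  structure(list(
    W = matrix(stats::runif(hidden_size * input_size, -lim_in, lim_in),
               hidden_size, input_size),
    b = numeric(hidden_size),
    Z = matrix(stats::runif(input_size * hidden_size, -lim_hid, lim_hid),
               input_size, hidden_size),
    B = numeric(input_size),
    input_size = as.integer(input_size),
    hidden_size = as.integer(hidden_size),
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size)
  ), class = "autoencoder")
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf("Rectified-linear autoencoder: %d-%d-%d\n",
              x$input_size, x$hidden_size, x$input_size))
  cat(sprintf("  learning rate %g, batch size %d\n",
              x$learning_rate, x$batch_size))
  invisible(x)
}

#' Bernoulli dropout mask
#'
#' The conventional (non-vascular) dropout baseline: each of the H hidden
#' units is kept ON independently with probability `p`.
#'
#' @param hidden_size Number of hidden units H.
#' @param p Keep probability, strictly inside (0, 1).
#' @param seed Optional seed.
#' @return Binary vector of length H (1 = unit active).
#' @export
bernoulli_mask <- function(hidden_size, p, seed = NULL) {
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  as.numeric(stats::runif(hidden_size) < p)
}

#' Forward pass with an external dropout mask
#'
#' Propagates a batch of inputs through the network: pre-activations
#' `h = W x + b`, hidden activity `v = relu(h)`, gated activity
#' `v_new = v * r` (element-wise over units, broadcast across the batch) and
#' the rectified reconstruction `y_new = relu(Z v_new + B)`.
#'
#' @param net An [autoencoder()].
#' @param X Input matrix, `M x bt` (one column per pattern); a vector is
#'   treated as a single pattern.
#' @param mask Binary dropout mask of length H; defaults to all-ones.
#' @return List with `h`, `v`, `v_new`, `y_new` (all `. x bt` matrices).
#' @export
ae_forward <- function(net, X, mask = rep(1, net$hidden_size)) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (nrow(X) != net$input_size)
    stop(sprintf("input has %d rows; network expects %d", nrow(X),
                 net$input_size), call. = FALSE)
  if (length(mask) != net$hidden_size)
    stop(sprintf("mask has length %d; hidden layer has %d units",
                 length(mask), net$hidden_size), call. = FALSE)
  h <- net$W %*% X + net$b
  v <- relu(h)
  v_new <- v * mask
  y_new <- relu(net$Z %*% v_new + net$B)
  list(h = h, v = v, v_new = v_new, y_new = y_new)
}

#' Batch reconstruction error
#'
#' Mean squared reconstruction error over a minibatch,
#' `sum((X - Y)^2) / (2 * bt * M)` for `bt` patterns of `M` pixels each.
#'
#' @param X Target (input) matrix `M x bt`.
#' @param Y Reconstruction matrix of the same shape.
#' @return Scalar mse (>= 0).
#' @export
ae_mse <- function(X, Y) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  if (!all(dim(X) == dim(Y)))
    stop("`X` and `Y` must have identical dimensions", call. = FALSE)
  if (ncol(X) == 0L) stop("empty batch", call. = FALSE)
  sum((X - Y)^2) / (2 * ncol(X) * nrow(X))
}

#' One minibatch gradient step
#'
#' Backpropagates the batch reconstruction error through the masked network
#' and applies one vanilla SGD update to W, b, Z and B. The mask sits inside
#' the computational graph, so hidden units that are dropped receive exactly
#' zero gradient in their incoming and outgoing weights. Returns the
#' post-update batch error, evaluated under the same mask.
#'
#' @param net An [autoencoder()].
#' @param X Input minibatch, `M x bt`.
#' @param mask Binary dropout mask of length H, frozen for the whole batch.
#' @return List with the updated `net` and the post-update `mse`.
#' @export
ae_train_step <- function(net, X, mask = rep(1, net$hidden_size)) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  bt <- ncol(X)
  M <- nrow(X)
  fw <- ae_forward(net, X, mask)
  # d mse / d y_new, through the output rectifier (subgradient 0 at the kink)
  d_out <- ((fw$y_new - X) / (bt * M)) * (fw$y_new > 0)
  grad_Z <- d_out %*% t(fw$v_new)
  grad_B <- rowSums(d_out)
  d_vnew <- t(net$Z) %*% d_out
  d_h <- d_vnew * mask * (fw$h > 0)
  grad_W <- d_h %*% t(X)
  grad_b <- rowSums(d_h)
  grads <- list(W = grad_W, b = grad_b, Z = grad_Z, B = grad_B)
  bad <- names(grads)[!vapply(grads, function(g) all(is.finite(g)), logical(1))]
  if (length(bad))
    stop("non-finite gradient in parameter block(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  lr <- net$learning_rate
  net$W <- net$W - lr * grad_W
  net$b <- net$b - lr * grad_b
  net$Z <- net$Z - lr * grad_Z
  net$B <- net$B - lr * grad_B
  post <- ae_forward(net, X, mask)
  list(net = net, mse = ae_mse(X, post$y_new))
}

#' Hidden-unit weight images
#'
#' Reshapes each hidden unit's incoming weight vector into the input image
#' shape (row-major, matching the flattening used by [batch_stream()]).
#'
#' @param net An [autoencoder()].
#' @param image_dim Integer vector `c(height, width)` with
#'   `prod(image_dim) == input_size`.
#' @return Array `H x height x width`.
#' @export
weight_images <- function(net, image_dim) {
  stopifnot(length(image_dim) == 2, prod(image_dim) == net$input_size)
  H <- net$hidden_size
  out <- array(NA_real_, c(H, image_dim[1], image_dim[2]))
  for (i in seq_len(H))
    out[i, , ] <- matrix(net$W[i, ], image_dim[1], image_dim[2], byrow = TRUE)
  out
}

#' Plot hidden-unit weight images as a tile grid
#'
#' @param net An [autoencoder()].
#' @param image_dim `c(height, width)` of the input images.
#' @param ncol Number of tiles per row.
#' @return Invisibly, the weight-image array.
#' @export
plot_weight_images <- function(net, image_dim, ncol = ceiling(sqrt(net$hidden_size))) {
  imgs <- weight_images(net, image_dim)
  H <- dim(imgs)[1]
  nrow_grid <- ceiling(H / ncol)
  op <- graphics::par(mfrow = c(nrow_grid, ncol), mar = c(0.3, 0.3, 0.3, 0.3))
  on.exit(graphics::par(op))
  for (i in seq_len(H)) {
    m <- imgs[i, , ]
    graphics::image(t(m[nrow(m):1, ]), axes = FALSE,
                    col = grDevices::grey.colors(64), useRaster = TRUE)
  }
  invisible(imgs)
}
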