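# Shared equal-width binning over a fixed range; values at the top edge fall
# in the last bin. A degenerate (zero-width) range puts everything in bin 1.
bin_index <- function(x, bins, range) {
  if (diff(range) == 0) return(rep(1L, length(x)))
  idx <- floor((x - range[1]) / diff(range) * bins) + 1L
  pmin(pmax(idx, 1L), bins)
}

#' Histogram entropy of an image
#'
#' Shannon entropy (base 2) of the pixel-value histogram over `bins`
#' equal-width bins spanning `range`. A constant image occupies a single bin
#' and has zero entropy.
#'
#' @param x Numeric image (vector, matrix or array).
#' @param bins Number of histogram bins (>= 2).
#' @param range Binning range; defaults to the range of `x`. Pairwise
#'   metrics pass the pooled range of both images so marginal and joint
#'   histograms share one binning.
#' @return Entropy in bits (>= 0).
#' @export
image_entropy <- function(x, bins = 16, range = base::range(x)) {
  if (!length(x)) stop("empty image", call. = FALSE)
  if (bins < 2) stop("`bins` must be >= 2", call. = FALSE)
  p <- tabulate(bin_index(as.vector(x), bins, range), nbins = bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information index between two images
#'
#' `MII = S(X) + S(Y) - S(X, Y)`: the marginal histogram entropies of the
#' two images minus their joint histogram entropy, all computed on a shared
#' equal-width binning over the pooled value range of the pair. Low MII
#' between hidden-unit weight images indicates independent features.
#'
#' @param X,Y Images of identical shape.
#' @param bins Number of bins per axis.
#' @return MII in bits (nonnegative up to floating-point tolerance);
#'   `mii(X, X)` equals `image_entropy(X)`.
#' @export
mii <- function(X, Y, bins = 16) {
  if (!all(dim(as.array(X)) == dim(as.array(Y))) ||
      length(X) != length(Y))
    stop("`X` and `Y` must have identical shape", call. = FALSE)
  pooled <- range(c(X, Y))
  sx <- image_entropy(X, bins, pooled)
  sy <- image_entropy(Y, bins, pooled)
  ix <- bin_index(as.vector(X), bins, pooled)
  iy <- bin_index(as.vector(Y), bins, pooled)
  joint <- tabulate((ix - 1L) * bins + iy, nbins = bins * bins)
  p <- joint / sum(joint)
  p <- p[p > 0]
  sxy <- -sum(p * log2(p))
  sx + sy - sxy
}

#' Single-window structural similarity between two images
#'
#' The global (one-window) structural similarity index
#' `SSI = (2 mu_X mu_Y + C1)(2 cov_XY + C2) /
#' ((mu_X^2 + mu_Y^2 + C1)(var_X + var_Y + C2))`
#' computed from the means, variances and cross covariance over all pixels
#' (population moments, i.e. normalized by the pixel count). The stabilizing
#' constants default to `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with `L` the
#' pooled dynamic range of the pair.
#'
#' @param X,Y Images of identical shape.
#' @param C1,C2 Positive stabilizing constants; defaults derived from the
#'   pooled range as above.
#' @return SSI in `[-1, 1]`; exactly 1 for identical images.
#' @export
ssi <- function(X, Y, C1 = NULL, C2 = NULL) {
  if (!all(dim(as.array(X)) == dim(as.array(Y))) ||
      length(X) != length(Y))
    stop("`X` and `Y` must have identical shape", call. = FALSE)
  x <- as.vector(X); y <- as.vector(Y)
  L <- diff(range(c(x, y)))
  if (L == 0) L <- 1
  if (is.null(C1)) C1 <- (0.01 * L)^2
  if (is.null(C2)) C2 <- (0.03 * L)^2
  if (C1 <= 0 || C2 <= 0) stop("`C1` and `C2` must be positive", call. = FALSE)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

# Min-max normalize one image to [0, 1]; constant images map to all zeros.
normalize01 <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(x * 0)
  (x - r[1]) / diff(r)
}

#' Pairwise feature-quality metrics over hidden-unit weight images
#'
#' Computes the full `H x H` matrices of pairwise mutual information index
#' and structural similarity over a set of weight images, after min-max
#' normalizing each image to `[0, 1]` (raw weights are unbounded). The
#' off-diagonal means are the scalar summaries used to compare runs: low
#' mean MII indicates mutually independent features; mean SSI tracks how
#' structurally alike the features are.
#'
#' @param images `H x height x width` array (e.g. from [weight_images()]),
#'   or a list of H equally shaped matrices.
#' @param bins Histogram bins for the MII.
#' @param C1,C2 Optional SSI constants (see [ssi()]).
#' @return An object of class `feature_metrics`: `mii_matrix`, `ssi_matrix`,
#'   `mii_mean`, `ssi_mean`.
#' @export
feature_metrics <- function(images, bins = 16, C1 = NULL, C2 = NULL) {
  if (is.list(images)) {
    H <- length(images)
    imgs <- lapply(images, normalize01)
  } else {
    H <- dim(images)[1]
    imgs <- lapply(seq_len(H), function(i) normalize01(images[i, , ]))
  }
  if (H < 2) stop("need at least 2 images", call. = FALSE)
  mii_m <- diag(vapply(imgs, image_entropy, numeric(1), bins = bins))
  ssi_m <- diag(1, H)
  for (i in seq_len(H - 1)) {
    for (j in (i + 1):H) {
      mii_m[i, j] <- mii_m[j, i] <- mii(imgs[[i]], imgs[[j]], bins)
      ssi_m[i, j] <- ssi_m[j, i] <- ssi(imgs[[i]], imgs[[j]], C1, C2)
    }
  }
  off <- upper.tri(mii_m)
  structure(list(mii_matrix = mii_m, ssi_matrix = ssi_m,
                 mii_mean = mean(mii_m[off]), ssi_mean = mean(ssi_m[off])),
            class = "feature_metrics")
}

#' @export
print.feature_metrics <- function(x, ...) {
  cat(sprintf("Pairwise feature metrics over %d images\n", nrow(x$mii_matrix)))
  cat(sprintf("  mean MII = %.4f bits, mean SSI = %.4f\n",
              x$mii_mean, x$ssi_mean))
  invisible(x)
}

#' Localization of weight images on single bars
#'
#' For each hidden unit, the largest fraction of the weight image's L1 mass
#' that falls on the pixels of a single horizontal or vertical bar. A unit
#' that has learned a clean one-bar feature scores near 1.
#'
#' @param images `H x size x size` weight-image array.
#' @return Numeric vector of length H with the per-unit best-bar L1
#'   fractions.
#' @export
bar_localization <- function(images) {
  H <- dim(images)[1]
  size <- dim(images)[2]
  stopifnot(dim(images)[3] == size)
  vapply(seq_len(H), function(i) {
    w <- abs(images[i, , ])
    tot <- sum(w)
    if (tot == 0) return(0)
    max(c(rowSums(w), colSums(w))) / tot
  }, numeric(1))
}
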