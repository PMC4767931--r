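#' Synthetic bar-pattern images
#'
#' Generates binary images each containing a random number of full-width
#' horizontal (1 x size) or full-height vertical (size x 1) bars. The bar
#' count per image is uniform on `{1, ..., max_bars}`; the bars themselves
#' are drawn uniformly without replacement from the `2 * size` candidates
#' (all rows plus all columns), so horizontal and vertical bars may co-occur
#' and crossings saturate at pixel value 1.
#'
#' With 16 hidden units and 8 x 8 images this dataset has an unambiguous
#' sparse code: one unit per bar.
#'
#' @param count Number of images (default 5000).
#' @param size Image side length (default 8).
#' @param max_bars Maximum bars per image (default 4; must not exceed
#'   `2 * size`).
#' @param seed Optional seed.
#' @return An object of class `image_dataset`: list with `images`
#'   (`count x size x size` array of 0/1), `height`, `width`, `count`.
#' @export
#' @examples
#' d <- bar_patterns(count = 10, seed = 1)
#' range(d$images)
bar_patterns <- function(count = 5000, size = 8, max_bars = 4, seed = NULL) {
  stopifnot(count >= 1, size >= 1)
  if (max_bars < 1 || max_bars > 2 * size)
    stop("`max_bars` must lie in [1, 2 * size]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  images <- array(0, c(count, size, size))
  n_candidates <- 2L * size
  for (i in seq_len(count)) {
    k <- sample.int(max_bars, 1L)
    bars <- sample.int(n_candidates, k)
    for (bar in bars) {
      if (bar <= size) images[i, bar, ] <- 1 else images[i, , bar - size] <- 1
    }
  }
  structure(list(images = images, height = size, width = size, count = count),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf("Image dataset: %d images of %d x %d, pixel range [%g, %g]\n",
              x$count, x$height, x$width, min(x$images), max(x$images)))
  invisible(x)
}

read_idx_header <- function(con, expect_magic, path) {
  magic <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  if (!length(magic) || magic != expect_magic)
    stop(sprintf("'%s' is not an IDX file of the expected type (magic 0x%08x, expected 0x%08x)",
                 path, if (length(magic)) magic else 0L, expect_magic),
         call. = FALSE)
  invisible(magic)
}

#' Read an MNIST-style IDX image file
#'
#' Parses the big-endian IDX binary format (magic number 2051 for unsigned
#' byte image tensors, 2049 for label vectors) and scales pixel values to
#' `[0, 1]` by dividing by 255.
#'
#' @param images_path Path to the IDX image file.
#' @param labels_path Optional path to the matching IDX label file.
#' @return An `image_dataset`; if labels were supplied they are attached as
#'   element `labels`.
#' @export
read_mnist_idx <- function(images_path, labels_path = NULL) {
  con <- file(images_path, "rb")
  on.exit(close(con), add = TRUE)
  read_idx_header(con, 2051L, images_path)
  dims <- readBin(con, "integer", n = 3, size = 4, endian = "big")
  if (length(dims) < 3 || any(dims <= 0))
    stop(sprintf("truncated IDX header in '%s'", images_path), call. = FALSE)
  count <- dims[1]; height <- dims[2]; width <- dims[3]
  n_pix <- count * height * width
  raw_px <- readBin(con, "integer", n = n_pix, size = 1, signed = FALSE)
  if (length(raw_px) != n_pix)
    stop(sprintf("truncated IDX data in '%s': expected %d pixels, got %d",
                 images_path, n_pix, length(raw_px)), call. = FALSE)
  # IDX stores images row-major: image, then row, then column fastest
  images <- aperm(array(raw_px / 255, c(width, height, count)), c(3, 2, 1))
  out <- structure(list(images = images, height = height, width = width,
                        count = count), class = "image_dataset")
  if (!is.null(labels_path)) {
    lcon <- file(labels_path, "rb")
    on.exit(close(lcon), add = TRUE)
    read_idx_header(lcon, 2049L, labels_path)
    n_lab <- readBin(lcon, "integer", n = 1, size = 4, endian = "big")
    labels <- readBin(lcon, "integer", n = n_lab, size = 1, signed = FALSE)
    if (length(labels) != n_lab || n_lab != count)
      stop("label file does not match image file", call. = FALSE)
    out$labels <- labels
  }
  out
}

#' Flatten an image dataset into training minibatches
#'
#' Images are flattened row-major (an 8 x 8 image becomes a length-64 vector
#' reading across each row) and split into minibatches of `batch_size`
#' columns; a final short batch is kept. With `shuffle = TRUE` the image
#' order is permuted first.
#'
#' @param dataset An `image_dataset`.
#' @param batch_size Patterns per minibatch (bt, >= 1).
#' @param shuffle Permute image order before batching?
#' @param seed Optional seed for the permutation.
#' @return List of `M x bt` matrices (M = height * width), one column per
#'   flattened image.
#' @export
batch_stream <- function(dataset, batch_size, shuffle = TRUE, seed = NULL) {
  stopifnot(inherits(dataset, "image_dataset"), batch_size >= 1)
  if (dataset$count == 0) stop("empty dataset", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ord <- if (shuffle) sample.int(dataset$count) else seq_len(dataset$count)
  # row-major flatten: transpose each image before unrolling
  flat <- apply(dataset$images, 1, function(img) as.vector(t(img)))
  flat <- flat[, ord, drop = FALSE]
  starts <- seq(1, dataset$count, by = batch_size)
  lapply(starts, function(s) {
    flat[, s:min(s + batch_size - 1, dataset$count), drop = FALSE]
  })
}
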