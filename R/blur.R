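#' Linear-motion blur kernel
#'
#' Linear motion at constant velocity smears each pixel uniformly along
#' the motion axis; its point-spread function is a 1-D box kernel of
#' length `size` with weights `1/size` (summing to 1, so the image mean
#' is conserved).  `size = 1` is the identity blur.
#'
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param size integer kernel length in pixels, at least 1.
#' @return a `blur_kernel` object: a `1 x size` (horizontal) or
#'   `size x 1` (vertical) matrix of weights with attributes
#'   `orientation` and `size`.
#' @examples
#' make_blur_kernel("horizontal", 5)
#' @export
make_blur_kernel <- function(orientation = c("horizontal", "vertical"),
                             size) {
  orientation <- match.arg(orientation)
  size <- as.integer(size)
  if (is.na(size) || size < 1L)
    stop("blur size must be an integer >= 1", call. = FALSE)
  w <- rep(1 / size, size)
  k <- if (orientation == "horizontal") matrix(w, nrow = 1L) else matrix(w, ncol = 1L)
  structure(k, orientation = orientation, size = size,
            class = c("blur_kernel", class(matrix())))
}

#' @export
print.blur_kernel <- function(x, ...) {
  cat(sprintf("<blur_kernel: %s, size %d, weight %.4g each>\n",
              attr(x, "orientation"), attr(x, "size"), x[[1]]))
  invisible(x)
}

## Valid box blur of the margin field, cropped back to the core.
## Core column c averages field columns (c + margin - floor(size/2)) ..
## (+ size - 1): the crop offset is floor(size/2) from the left/top, so
## for margin >= floor(size/2) every averaged pixel is a real source
## pixel.  Vertical blur is the exact transpose of horizontal blur.
blur_core <- function(field, window_size, margin, size, orientation) {
  if (orientation == "vertical")
    return(t(blur_core(t(field), window_size, margin, size, "horizontal")))
  s <- ncol(field)
  B <- matrix(0, s, window_size)
  start <- seq_len(window_size) + margin - size %/% 2L
  for (cc in seq_len(window_size))
    B[start[cc]:(start[cc] + size - 1L), cc] <- 1 / size
  rows <- (margin + 1L):(margin + window_size)
  out <- field[rows, , drop = FALSE] %*% B
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Apply motion blur to a window sample
#'
#' Convolves the sample's margin field with a box blur kernel and
#' returns the central core crop, so every blurred pixel is an average
#' of genuine source pixels (no padding artefacts).  Averaging along an
#' axis of constant intensity leaves the window unchanged: vertical
#' blur preserves vertical stripes and horizontal blur preserves
#' horizontal stripes — the asymmetry the benchmark classifies.
#'
#' @param sample a `window_sample` from [sample_windows()].
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param size blur size in pixels; requires `sample$margin >= floor(size/2)`.
#' @return the blurred core as a `window_size x window_size` matrix with
#'   intensities in `[0, 1]`.
#' @export
apply_blur <- function(sample, orientation = c("horizontal", "vertical"),
                       size) {
  orientation <- match.arg(orientation)
  size <- as.integer(size)
  if (size < 1L) stop("blur size must be >= 1", call. = FALSE)
  if (sample$margin < size %/% 2L)
    stop(sprintf("margin %d too small for blur size %d (need >= %d)",
                 sample$margin, size, size %/% 2L), call. = FALSE)
  blur_core(sample$field, sample$window_size, sample$margin, size,
            orientation)
}

#' Build the labelled two-class motion-blur dataset
#'
#' Splits the window samples into two disjoint halves (sizes differing
#' by at most 1): one half receives horizontal blur and label 0, the
#' other vertical blur and label 1.  Each physical window contributes
#' exactly one labelled sample, so no near-duplicate image can appear
#' on both sides of a later train/test split.
#'
#' @param samples a `window_set` with at least 2 windows.
#' @param size blur size in pixels.
#' @param seed integer seed controlling the half assignment.
#' @return a `blur_dataset` object: list with `x` (`n x window_size^2`
#'   matrix, blurred cores as rows), `orig` (unblurred cores as rows),
#'   `labels` (integer 0 = horizontal, 1 = vertical), `blur_size`,
#'   `window_size` and a `manifest` data frame.
#' @examples
#' img <- generate_surrogate_image(64, 64, 1, seed = 1)
#' ws <- sample_windows(img, 4, margin = 4, seed = 2)
#' ds <- build_dataset(ws, size = 5, seed = 3)
#' table(ds$labels)
#' @export
build_dataset <- function(samples, size, seed = NULL) {
  n <- length(samples)
  if (n < 2L) stop("need at least 2 window samples", call. = FALSE)
  size <- as.integer(size)
  perm <- with_seed(seed, sample.int(n))
  n_h <- (n + 1L) %/% 2L
  orientation <- rep("vertical", n)
  orientation[perm[seq_len(n_h)]] <- "horizontal"
  p <- samples[[1]]$window_size^2
  x <- matrix(0, n, p)
  orig <- matrix(0, n, p)
  for (i in seq_len(n)) {
    x[i, ] <- as.vector(apply_blur(samples[[i]], orientation[i], size))
    orig[i, ] <- as.vector(samples[[i]]$core)
  }
  manifest <- data.frame(
    sample_id = seq_len(n),
    label = as.integer(orientation == "vertical"),
    orientation = orientation,
    blur_size = size,
    source_id = vapply(samples, function(w) w$source_id, 0L),
    top_left_row = vapply(samples, function(w) w$top_left[["row"]], 0L),
    top_left_col = vapply(samples, function(w) w$top_left[["col"]], 0L))
  structure(list(x = x, orig = orig,
                 labels = manifest$label,
                 blur_size = size,
                 window_size = samples[[1]]$window_size,
                 manifest = manifest),
            class = "blur_dataset")
}

#' @export
print.blur_dataset <- function(x, ...) {
  cat(sprintf(
    "<blur_dataset: %d windows of %dx%d, blur size %d px (%d horizontal / %d vertical)>\n",
    nrow(x$x), x$window_size, x$window_size, x$blur_size,
    sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

#' Save a labelled blur dataset as PNG windows plus a CSV manifest
#'
#' @param dataset a `blur_dataset` from [build_dataset()].
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ws <- dataset$window_size
  for (i in seq_len(nrow(dataset$x)))
    png::writePNG(matrix(dataset$x[i, ], ws, ws),
                  file.path(dir, sprintf("sample_%05d.png", i)))
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dataset$manifest)
}
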