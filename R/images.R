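#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of pixel intensities in `[0, 1]`,
#' row = image row, column = image column (1-based indexing throughout
#' the package).  It is the universal carrier between pipeline stages.
#'
#' @param pixels numeric matrix with all values in `[0, 1]`.
#' @return a `gray_image` object (a classed matrix).
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image dimensions must be at least 1x1", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("pixel intensities must lie in [0, 1]", call. = FALSE)
  structure(pixels, class = c("gray_image", class(matrix())))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, intensity range [%.3f, %.3f]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @export
plot.gray_image <- function(x, ...) {
  op <- graphics::par(mar = c(1, 1, 2, 1)); on.exit(graphics::par(op))
  graphics::image(t(unclass(x))[, nrow(x):1], col = grDevices::gray.colors(256, 0, 1),
                  zlim = c(0, 1), axes = FALSE, asp = nrow(x) / ncol(x), ...)
  invisible(x)
}

## discrete Fourier frequencies in cycles/pixel, numpy fftfreq convention
fft_freq <- function(n) {
  k <- 0:(n - 1L)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

#' Generate an isotropic 1/f-spectrum surrogate natural image
#'
#' Natural photographs share a characteristic power spectrum whose
#' amplitude falls off roughly as 1/f with spatial frequency.  This
#' generator produces grayscale surrogates with that second-order
#' statistic: a white Gaussian field is shaped in the Fourier domain by
#' an amplitude filter `1/f^spectral_exponent` (DC removed) and the
#' result is rescaled affinely so intensities span `[0, 1]` exactly.
#' The construction is orientation-isotropic: frequencies are measured
#' in cycles/pixel on both axes, so no axis is privileged even for
#' non-square images.
#'
#' @param width,height image dimensions in pixels (each at least 32).
#' @param spectral_exponent exponent of the radial amplitude falloff;
#'   0 gives white noise, 1 (default) the natural-image-like spectrum.
#' @param seed integer seed; identical seeds give bit-identical images.
#' @return a [gray_image()] of size `height x width` with min 0, max 1.
#' @examples
#' img <- generate_surrogate_image(64, 64, 1, seed = 1)
#' range(img)
#' @export
generate_surrogate_image <- function(width, height, spectral_exponent = 1,
                                     seed = NULL) {
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 32L || height < 32L)
    stop("width and height must be integers >= 32", call. = FALSE)
  if (spectral_exponent < 0)
    stop("spectral_exponent must be >= 0", call. = FALSE)
  with_seed(seed, {
    z <- matrix(stats::rnorm(height * width), height, width)
    f <- sqrt(outer(fft_freq(height)^2, fft_freq(width)^2, `+`))
    amp <- matrix(0, height, width)
    amp[f > 0] <- f[f > 0]^(-spectral_exponent)
    img <- Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / (height * width)
    rng <- range(img)
    gray_image((img - rng[1]) / (rng[2] - rng[1]))
  })
}

#' Read and write grayscale images
#'
#' Supported formats are PNG and PGM (portable graymap, ASCII `P2` or
#' binary `P5`), selected by file extension.  Colour PNG input is
#' converted to grayscale with the ITU-R BT.601 luma transform
#' (0.299 R + 0.587 G + 0.114 B); 8-bit sample values map to intensity
#' by division by the format's maximum value, so a write/read round
#' trip reproduces an image to within 1/255 per pixel.
#'
#' @param path file path ending in `.png`, `.pgm` or `.pnm`.
#' @param image a [gray_image()] (or plain matrix in `[0, 1]`).
#' @return `read_image()` returns a [gray_image()]; `write_image()`
#'   returns `path` invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) {
      nch <- dim(px)[3]
      px <- if (nch >= 3L)
        0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
      else px[, , 1]
    }
    px[px < 0] <- 0
    px[px > 1] <- 1
    gray_image(px)
  } else if (ext %in% c("pgm", "pnm")) {
    read_pgm(path)
  } else {
    stop("unsupported image format: .", ext, " (use PNG or PGM)", call. = FALSE)
  }
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  image <- gray_image(unclass(as.matrix(image)))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(unclass(image), path)
  } else if (ext %in% c("pgm", "pnm")) {
    write_pgm(image, path)
  } else {
    stop("unsupported image format: .", ext, " (use PNG or PGM)", call. = FALSE)
  }
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) break
      if (ch == "#") {                     # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) { if (nzchar(tok)) break else next }
      tok <- paste0(tok, ch)
    }
    tok
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM file (magic ", magic, "): ", path, call. = FALSE)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (anyNA(c(w, h, maxval)) || maxval < 1L)
    stop("malformed PGM header: ", path, call. = FALSE)
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "integer", n = w * h, size = 1L, signed = FALSE))
  } else {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  if (length(vals) < w * h) stop("truncated PGM data: ", path, call. = FALSE)
  gray_image(matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE))
}

write_pgm <- function(image, path) {
  vals <- as.integer(round(t(unclass(image)) * 255))   # row-major pixel order
  con <- file(path, "wb"); on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(image), nrow(image)), con,
            eos = NULL)
  writeBin(vals, con, size = 1L)
  invisible(path)
}

#' Sample random windows (with a blur margin) from images
#'
#' Draws `n` windows uniformly over source images and over all valid
#' positions.  Each sample carries two views: the `core`
#' (`window_size x window_size`, the patch the models see) and the
#' `field` (`(window_size + 2*margin)` square), the core plus a border
#' wide enough that motion blur of any size up to `2*margin` can be
#' computed from real source pixels only — no padding ever enters the
#' core.
#'
#' @param images a [gray_image()] or list of them.
#' @param n number of windows to draw (sampling is with replacement
#'   across images and positions).
#' @param window_size side of the core window in pixels (default 25).
#' @param margin extra border in pixels on each side (default 8, the
#'   largest blur size swept by the default benchmark).
#' @param seed integer seed for reproducible sampling.
#' @return a list of class `window_set`; each element is a
#'   `window_sample` with fields `core`, `field`, `source_id`,
#'   `top_left` (1-based (row, col) of the core in source coordinates),
#'   `window_size` and `margin`.
#' @examples
#' img <- generate_surrogate_image(64, 64, 1, seed = 1)
#' ws <- sample_windows(img, 10, window_size = 25, margin = 4, seed = 2)
#' dim(ws[[1]]$core)
#' @export
sample_windows <- function(images, n, window_size = 25L, margin = 8L,
                           seed = NULL) {
  if (inherits(images, "gray_image") || (is.matrix(images) && is.numeric(images)))
    images <- list(images)
  n <- as.integer(n); window_size <- as.integer(window_size)
  margin <- as.integer(margin)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  field_size <- window_size + 2L * margin
  for (i in seq_along(images)) {
    d <- dim(images[[i]])
    if (d[1] < field_size || d[2] < field_size)
      stop(sprintf(
        "image %d (%dx%d) is too small for window %d + 2*margin %d",
        i, d[1], d[2], window_size, margin), call. = FALSE)
  }
  with_seed(seed, {
    src <- sample.int(length(images), n, replace = TRUE)
    out <- vector("list", n)
    for (s in seq_len(n)) {
      im <- images[[src[s]]]
      top <- sample.int(nrow(im) - field_size + 1L, 1L)   # field top row
      left <- sample.int(ncol(im) - field_size + 1L, 1L)
      field <- unclass(im)[top:(top + field_size - 1L),
                           left:(left + field_size - 1L), drop = FALSE]
      core <- field[(margin + 1L):(margin + window_size),
                    (margin + 1L):(margin + window_size), drop = FALSE]
      out[[s]] <- structure(
        list(core = core, field = field, source_id = src[s],
             top_left = c(row = top + margin, col = left + margin),
             window_size = window_size, margin = margin),
        class = "window_sample")
    }
    structure(out, class = c("window_set", "list"))
  })
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set: %d windows of %dx%d (margin %d)>\n",
              length(x), x[[1]]$window_size, x[[1]]$window_size,
              x[[1]]$margin))
  invisible(x)
}

#' Save a window set as PNG cores plus a CSV manifest
#'
#' @param windows a `window_set` from [sample_windows()].
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
save_window_set <- function(windows, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(
    sample_id = seq_along(windows),
    source_id = vapply(windows, function(w) w$source_id, 0L),
    top_left_row = vapply(windows, function(w) w$top_left[["row"]], 0L),
    top_left_col = vapply(windows, function(w) w$top_left[["col"]], 0L),
    window_size = vapply(windows, function(w) w$window_size, 0L),
    margin = vapply(windows, function(w) w$margin, 0L))
  for (i in seq_along(windows))
    png::writePNG(windows[[i]]$core,
                  file.path(dir, sprintf("window_%05d.png", i)))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
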