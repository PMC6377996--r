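#' Difference-of-Gaussians receptive-field profile
#'
#' Centre-surround receptive field of a thalamic (LGN) relay neuron: a
#' narrow positive Gaussian minus a broader negative one, both of unit
#' mass, evaluated at the Euclidean distance D from the field centre:
#'
#' \deqn{RF(D) = \frac{1}{2\pi\sigma_c^2} e^{-D^2/2\sigma_c^2}
#'            - \frac{1}{2\pi\sigma_s^2} e^{-D^2/2\sigma_s^2}}
#'
#' Defaults are `sigma_center = 0.833` px with surround ratio 3
#' (`sigma_surround = 2.499` px), giving a positive central region about
#' 4 px across (zero-crossing diameter) and a total field diameter of
#' roughly 16 px.  Space constants are in pixel units.
#'
#' @param sigma_center centre Gaussian space constant in pixels (> 0).
#' @param surround_ratio `sigma_surround / sigma_center` (> 1).
#' @param support half-width of the square discrete support in pixels;
#'   defaults to `ceiling(3 * sigma_surround)` so the surround is
#'   contained.
#' @return a `dog_profile` object with fields `sigma_center`,
#'   `sigma_surround`, `support` and `kernel` (the
#'   `(2*support+1)`-square discretized kernel, for inspection).
#' @examples
#' p <- dog_profile()
#' dog_value(0, p)                 # ~0.204 at the centre
#' 2 * dog_zero_crossing(p)        # ~3.7 px positive-centre diameter
#' @export
dog_profile <- function(sigma_center = 0.833, surround_ratio = 3,
                        support = NULL) {
  if (sigma_center <= 0) stop("sigma_center must be > 0", call. = FALSE)
  if (surround_ratio <= 1)
    stop("surround_ratio must be > 1", call. = FALSE)
  sigma_surround <- surround_ratio * sigma_center
  support <- as.integer(support %||% ceiling(3 * sigma_surround))
  if (support < ceiling(3 * sigma_surround))
    stop("support must contain the surround (>= ceiling(3*sigma_surround))",
         call. = FALSE)
  obj <- structure(list(sigma_center = sigma_center,
                        sigma_surround = sigma_surround,
                        support = support, kernel = NULL),
                   class = "dog_profile")
  d <- seq(-support, support)
  D <- sqrt(outer(d^2, d^2, `+`))
  obj$kernel <- dog_value(D, obj)
  obj
}

#' @rdname dog_profile
#' @param r distance(s) from the field centre, in pixels.
#' @param profile a `dog_profile`.
#' @export
dog_value <- function(r, profile) {
  sc <- profile$sigma_center; ss <- profile$sigma_surround
  exp(-r^2 / (2 * sc^2)) / (2 * pi * sc^2) -
    exp(-r^2 / (2 * ss^2)) / (2 * pi * ss^2)
}

#' @rdname dog_profile
#' @details `dog_zero_crossing()` finds, by 1-D root finding, the radius
#'   at which the profile changes sign — the edge of the excitatory
#'   centre.
#' @export
dog_zero_crossing <- function(profile) {
  stats::uniroot(function(r) dog_value(r, profile),
                 interval = c(1e-9, 3 * profile$sigma_surround),
                 tol = 1e-10)$root
}

#' @export
print.dog_profile <- function(x, ...) {
  cat(sprintf(
    "<dog_profile: sigma_center %.3f px, sigma_surround %.3f px, support +/-%d px>\n",
    x$sigma_center, x$sigma_surround, x$support))
  cat(sprintf("  centre value %.4f, zero-crossing radius %.2f px\n",
              dog_value(0, x), dog_zero_crossing(x)))
  invisible(x)
}

#' Hexagonal receptive-field mosaic
#'
#' Places LGN receptive-field centres on a centred hexagonal lattice
#' over an image window (ON- and OFF-centre mosaics share the same
#' positions).  A lattice of `rings` rings has
#' `3*rings*(rings+1) + 1` centres: the default `rings = 5` gives the
#' 91 centres per polarity used by the thalamic representation, and the
#' default spacing 2.4 px makes the lattice span 24 px, tiling a 25x25
#' window.
#'
#' @param rings number of hexagonal rings around the central point
#'   (>= 0).
#' @param spacing nearest-neighbour distance in pixels (> 0).
#' @param window_size side of the target window in pixels.
#' @return an `lgn_mosaic` object with `centers` (an `n x 2` matrix of
#'   1-based (row, col) positions, possibly fractional), `rings`,
#'   `spacing` and `window_size`.
#' @examples
#' nrow(hex_mosaic(5)$centers)    # 91
#' @export
hex_mosaic <- function(rings = 5L, spacing = 2.4, window_size = 25L) {
  rings <- as.integer(rings)
  if (rings < 0L) stop("rings must be >= 0", call. = FALSE)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  centre <- (window_size + 1) / 2
  qr <- do.call(rbind, lapply(seq(-rings, rings), function(q) {
    r <- seq(max(-rings, -q - rings), min(rings, -q + rings))
    cbind(q = q, r = r)
  }))
  col <- centre + spacing * (qr[, "q"] + qr[, "r"] / 2)
  row <- centre + spacing * (qr[, "r"] * sqrt(3) / 2)
  extent <- max(abs(c(row - centre, col - centre)))
  if (extent > (window_size - 1) / 2 + spacing / 2)
    warning("mosaic extends more than spacing/2 beyond the window",
            call. = FALSE)
  structure(list(centers = cbind(row = row, col = col),
                 rings = rings, spacing = spacing,
                 window_size = as.integer(window_size)),
            class = "lgn_mosaic")
}

#' @export
print.lgn_mosaic <- function(x, ...) {
  cat(sprintf(
    "<lgn_mosaic: %d centres (%d rings, spacing %.2f px) in a %dx%d window>\n",
    nrow(x$centers), x$rings, x$spacing, x$window_size, x$window_size))
  invisible(x)
}

#' Linear filter matrix of the mosaic
#'
#' Precomputes, for each mosaic centre, the DoG kernel re-centred at
#' that position and clipped at the window borders (out-of-window
#' pixels are simply omitted — no padding), flattened over the window
#' pixels.  The matrix maps a vectorized window to the vector of raw
#' filter responses `s`, one per centre, and is the workhorse behind
#' [lgn_response()] / [lgn_represent()].
#'
#' @param mosaic an [hex_mosaic()].
#' @param profile a [dog_profile()].
#' @return an `n_centers x window_size^2` matrix.
#' @export
lgn_weights <- function(mosaic, profile) {
  ws <- mosaic$window_size
  px_row <- rep(seq_len(ws), times = ws)        # column-major vectorization
  px_col <- rep(seq_len(ws), each = ws)
  k <- nrow(mosaic$centers)
  W <- matrix(0, k, ws * ws)
  for (i in seq_len(k)) {
    dr <- px_row - mosaic$centers[i, "row"]
    dc <- px_col - mosaic$centers[i, "col"]
    in_support <- abs(dr) <= profile$support & abs(dc) <= profile$support
    W[i, in_support] <- dog_value(sqrt(dr[in_support]^2 + dc[in_support]^2),
                                  profile)
  }
  W
}

#' Thalamic (LGN) activity vector of an image window
#'
#' Each mosaic centre filters the window with its re-centred DoG kernel
#' to give a raw response `s = sum(RF * PI)` over the window pixels,
#' then splits it into a rectified ON/OFF pair around a resting
#' baseline of 0.1:
#' `ON = max(0, 0.1 + s)`, `OFF = max(0, 0.1 - s)`.
#' The result is the concatenation of all ON activities followed by all
#' OFF activities in fixed mosaic order — with the default 91-centre
#' mosaic, a 182-dimensional non-negative vector.  Wherever both
#' channels are positive, `ON + OFF = 0.2` and `ON - OFF = 2*s`.
#'
#' @param window a `window_size x window_size` matrix in `[0, 1]`.
#' @param mosaic an [hex_mosaic()].
#' @param profile a [dog_profile()].
#' @param weights optional precomputed [lgn_weights()] matrix (avoids
#'   recomputation in loops).
#' @param baseline resting activity added/subtracted before
#'   rectification (default 0.1).
#' @return a numeric vector of length `2 * n_centers`.
#' @export
lgn_response <- function(window, mosaic, profile,
                         weights = lgn_weights(mosaic, profile),
                         baseline = 0.1) {
  window <- unclass(as.matrix(window))
  if (nrow(window) != mosaic$window_size || ncol(window) != mosaic$window_size)
    stop(sprintf("window must be %dx%d to match the mosaic",
                 mosaic$window_size, mosaic$window_size), call. = FALSE)
  s <- as.vector(weights %*% as.vector(window))
  c(pmax(0, baseline + s), pmax(0, baseline - s))
}

#' Thalamic representation of a dataset
#'
#' Vectorized [lgn_response()] over many windows at once.
#'
#' @param x an `n x window_size^2` matrix of vectorized windows (e.g.
#'   the `x` field of a [build_dataset()] result), or a `blur_dataset`.
#' @inheritParams lgn_response
#' @return an `n x (2 * n_centers)` matrix, one LGN vector per row.
#' @export
lgn_represent <- function(x, mosaic = hex_mosaic(), profile = dog_profile(),
                          weights = lgn_weights(mosaic, profile),
                          baseline = 0.1) {
  if (inherits(x, "blur_dataset")) x <- x$x
  if (ncol(x) != ncol(weights))
    stop("window pixel count does not match the mosaic window size",
         call. = FALSE)
  s <- x %*% t(weights)                       # n x k raw filter responses
  on <- baseline + s; on[on < 0] <- 0
  off <- baseline - s; off[off < 0] <- 0
  cbind(on, off)
}
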