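#' Construct a Layer-4 network object
#'
#' Bundles the parameters of the recurrent Layer-4 model.  Each of the
#' `n_units` units is RBF-like: its afferent weight vector `w_i` (unit
#' Euclidean norm) is a prototype in LGN space, and its feedforward
#' drive is a thresholded cosine similarity to the input (see
#' [feedforward_drive()]).  Units are laterally coupled through `u_ik`,
#' the correlation coefficients between unit outputs, scaled by
#' `lambda`.  Activities evolve by the rate dynamics
#'
#' \deqn{\tau \frac{dF_i}{dt} = -F_i +
#'   \Big[\frac{w_i \cdot x - \theta \lVert x \rVert}{1-\theta}
#'        + \lambda \sum_{k \ne i} u_{ik} F_k\Big]_+}
#'
#' integrated to steady state by [l4_steady_state()].
#'
#' @param afferent `n_units x input_dim` matrix; rows are normalized to
#'   unit Euclidean norm.
#' @param lateral `n_units x n_units` symmetric matrix of output
#'   correlations; diagonal is zeroed, entries clipped to `[-1, 1]`.
#' @param theta cosine threshold in (0, 1); default 0.975.  The
#'   threshold must sit inside the upper tail of the cosine distribution
#'   between inputs and prototypes for the units to be selective: LGN
#'   vectors share a large baseline component, so typical cosines are
#'   high (~0.88-0.97 for natural inputs) and a low threshold would
#'   leave every unit permanently supra-threshold, i.e. effectively
#'   linear.
#' @param lambda lateral scaling factor (>= 0); default 0.2.  Clipped
#'   (with a warning) if it violates the spectral stability condition
#'   `lambda * max|eig(lateral)| < 1`.
#' @param tau membrane time constant in ms; default 4.
#' @return an `l4_network` object.
#' @export
l4_network <- function(afferent, lateral = NULL, theta = 0.975, lambda = 0.2,
                       tau = 4) {
  if (!is.matrix(afferent)) stop("afferent must be a matrix", call. = FALSE)
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  nu <- nrow(afferent)
  nrm <- sqrt(rowSums(afferent^2))
  if (any(nrm == 0)) stop("afferent rows must be nonzero", call. = FALSE)
  afferent <- afferent / nrm
  if (is.null(lateral)) lateral <- matrix(0, nu, nu)
  if (!is.matrix(lateral) || nrow(lateral) != nu || ncol(lateral) != nu)
    stop("lateral must be a square matrix matching afferent rows",
         call. = FALSE)
  lateral <- (lateral + t(lateral)) / 2
  diag(lateral) <- 0
  lateral[lateral > 1] <- 1
  lateral[lateral < -1] <- -1
  rho <- if (nu > 1L)
    max(abs(eigen(lateral, symmetric = TRUE, only.values = TRUE)$values))
  else 0
  if (lambda * rho >= 1) {
    lambda_new <- 0.9 / rho
    warning(sprintf(
      "lambda = %.3g violates stability (max |eig| = %.3g); rescaled to %.3g",
      lambda, rho, lambda_new), call. = FALSE)
    lambda <- lambda_new
  }
  structure(list(afferent = afferent, lateral = lateral, theta = theta,
                 lambda = lambda, tau = tau, spectral_radius = rho),
            class = "l4_network")
}

#' @export
print.l4_network <- function(x, ...) {
  cat(sprintf(
    "<l4_network: %d units over %d-dim LGN input>\n  theta %.3g, lambda %.3g (lateral spectral radius %.3g), tau %.3g ms\n",
    nrow(x$afferent), ncol(x$afferent), x$theta, x$lambda,
    x$spectral_radius, x$tau))
  invisible(x)
}

#' Feedforward drive of the Layer-4 units
#'
#' For input vector `x` the drive of unit `i` is
#' `g_i = (w_i . x - theta * ||x||) / (1 - theta)`
#' `     = ||x|| * (cos(w_i, x) - theta) / (1 - theta)`:
#' positive only when the input points within a cosine `theta` of the
#' unit's prototype, equal to `||x||` at a perfect match, and positively
#' homogeneous of degree 1 in `x`.
#'
#' @param network an [l4_network()].
#' @param x a length-`input_dim` vector or an `n x input_dim` matrix of
#'   row vectors.
#' @return a length-`n_units` vector, or an `n x n_units` matrix when
#'   `x` is a matrix.
#' @export
feedforward_drive <- function(network, x) {
  if (is.matrix(x)) {
    if (ncol(x) != ncol(network$afferent))
      stop("input dimension mismatch", call. = FALSE)
    nrm <- sqrt(rowSums(x^2))
    (x %*% t(network$afferent) - outer(nrm, rep(network$theta,
                                                nrow(network$afferent)))) /
      (1 - network$theta)
  } else {
    if (length(x) != ncol(network$afferent))
      stop("input dimension mismatch", call. = FALSE)
    as.vector(network$afferent %*% x - network$theta * sqrt(sum(x^2))) /
      (1 - network$theta)
  }
}

## Greedy k-means++ seeding over unit-norm rows with multiplicity
## weights; distance = 1 - cosine.  At every step several candidates
## are drawn distance-weighted and the one that shrinks the total
## potential most is kept, so well-separated clusters each receive a
## seed with high probability.
kmeanspp_init <- function(X, k, w = rep(1, nrow(X))) {
  n <- nrow(X)
  n_cand <- 2L + as.integer(floor(log(max(k, 2))))
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L, prob = w)
  d2 <- 1 - as.vector(X %*% X[idx[1], ])
  d2[d2 < 0] <- 0
  for (j in seq_len(k - 1L) + 1L) {
    p <- w * d2
    if (sum(p) <= 0) p <- w
    cand <- sample.int(n, min(n_cand, sum(p > 0)), prob = p)
    pots <- vapply(cand, function(ci) {
      dc <- 1 - as.vector(X %*% X[ci, ])
      sum(w * pmin(d2, pmax(dc, 0)))
    }, 0)
    idx[j] <- cand[which.min(pots)]
    d2 <- pmin(d2, 1 - as.vector(X %*% X[idx[j], ]))
    d2[d2 < 0] <- 0
  }
  X[idx, , drop = FALSE]
}

## Batch steady-state solver: explicit Euler on F (n_units x n_samples)
## from F = 0 until the fixed-point residual max |[G + lambda U F]+ - F|
## drops below tol.
steady_state_mat <- function(network, G_t, dt = 0.5, tol = 1e-6,
                             max_steps = 2000L) {
  lam <- network$lambda; U <- network$lateral
  a <- dt / network$tau
  F_t <- matrix(0, nrow(G_t), ncol(G_t))
  converged <- FALSE
  steps <- 0L
  for (steps in seq_len(max_steps)) {
    R <- G_t + lam * (U %*% F_t)
    R[R < 0] <- 0
    delta <- max(abs(R - F_t))
    F_t <- F_t + a * (R - F_t)
    if (delta < tol) { converged <- TRUE; break }
  }
  list(activities = F_t, converged = converged, iterations = steps)
}

#' Steady-state Layer-4 activity for one input
#'
#' Integrates the rate dynamics (see [l4_network()]) by explicit Euler
#' from `F = 0` until the rectified fixed-point equation
#' `F_i = [g_i + lambda * sum_k u_ik F_k]_+` is satisfied to within
#' `tol`, or `max_steps` is reached (in which case a warning is issued
#' and the state is flagged unconverged).  With `lambda = 0` the units
#' decouple and the steady state is the closed form `max(0, g_i)`.
#'
#' @param network an [l4_network()].
#' @param x input vector of length `input_dim`.
#' @param dt Euler step in ms; must be smaller than `tau`.
#' @param tol fixed-point residual tolerance.
#' @param max_steps iteration cap.
#' @return an `l4_state` list: `activities` (non-negative vector),
#'   `converged` flag and `iterations` count.
#' @export
l4_steady_state <- function(network, x, dt = 0.5, tol = 1e-6,
                            max_steps = 2000L) {
  if (dt >= network$tau) stop("dt must be < tau", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  g <- feedforward_drive(network, x)
  res <- steady_state_mat(network, matrix(g, ncol = 1L), dt, tol, max_steps)
  if (!res$converged)
    warning(sprintf("steady state not converged after %d steps", max_steps),
            call. = FALSE)
  structure(list(activities = as.vector(res$activities),
                 converged = res$converged, iterations = res$iterations),
            class = "l4_state")
}

#' Train the Layer-4 network on natural-image statistics
#'
#' Adapts the afferent prototypes by correlation-based competitive
#' learning, a k-means-style procedure: each training LGN vector is
#' assigned to the prototype with which its *centered* direction (the
#' vector minus the ensemble mean, normalized — i.e. Pearson
#' similarity) correlates best, and each prototype is then replaced by
#' the centroid of its assigned vectors.  Centering the similarity
#' matters: raw LGN vectors share a large common baseline that
#' dominates plain cosine distances, which would make the partition
#' essentially random and average all structure out of the centroids;
#' the correlation metric groups windows by their actual spatial
#' pattern, so centroids retain the oriented structure of their
#' members.  Prototypes are stored as renormalized raw-space centroids
#' (unit Euclidean norm).
#'
#' Lateral couplings are then the Pearson correlations of unit outputs
#' (rectified feedforward drives, i.e. steady states at `lambda = 0`)
#' across the training set, with zeroed diagonal, clipped to `[-1, 1]`;
#' `lambda` is rescaled downward if the spectral stability condition
#' would be violated (warning).
#'
#' @param training an `n x input_dim` matrix of LGN vectors (rows), `n
#'   >= n_units`.  All-zero rows are dropped with a warning.
#' @param n_units number of Layer-4 units (default 182, matching the
#'   thalamic representation width).
#' @param theta,lambda,tau model parameters, see [l4_network()].
#' @param seed integer seed for prototype initialization.
#' @param epochs maximum number of Lloyd iterations (default 20; stops
#'   early when assignments stabilize).
#' @return a trained [l4_network()] with an extra `training` field
#'   (`n_vectors`, `epochs_run`, `seed`).
#' @export
l4_train <- function(training, n_units = 182L, theta = 0.975, lambda = 0.2,
                     tau = 4, seed = NULL, epochs = 20L) {
  if (!is.matrix(training)) stop("training must be a matrix", call. = FALSE)
  nrm <- sqrt(rowSums(training^2))
  if (any(nrm == 0)) {
    warning(sprintf("dropping %d all-zero training vector(s)", sum(nrm == 0)),
            call. = FALSE)
    training <- training[nrm > 0, , drop = FALSE]
    nrm <- nrm[nrm > 0]
  }
  if (nrow(training) < n_units)
    stop("need at least n_units non-degenerate training vectors",
         call. = FALSE)
  mu <- colMeans(training)
  Xc <- sweep(training, 2, mu)
  cn <- sqrt(rowSums(Xc^2))
  Xn <- Xc / pmax(cn, .Machine$double.eps)    # Pearson directions
  Xu <- unique(Xn)
  if (nrow(Xu) < n_units)
    stop("fewer than n_units distinct training directions", call. = FALSE)
  # multiplicity of each distinct direction, so that duplicating the
  # corpus leaves the (weighted) initialization untouched
  key <- apply(Xn, 1, function(r) paste(r, collapse = "\r"))
  mult <- as.vector(table(key)[apply(Xu, 1, function(r)
    paste(r, collapse = "\r"))])
  P <- with_seed(seed, kmeanspp_init(Xu, n_units, mult))
  assign_old <- integer(nrow(Xn))
  assign <- assign_old
  epochs_run <- 0L
  for (e in seq_len(epochs)) {
    assign <- max.col(Xn %*% t(P), ties.method = "first")
    epochs_run <- e
    if (identical(assign, assign_old)) break
    assign_old <- assign
    got <- rowsum(Xn, assign)
    sums <- matrix(0, n_units, ncol(Xn))
    sums[as.integer(rownames(got)), ] <- got
    sn <- sqrt(rowSums(sums^2))
    keep <- sn > 0
    P[keep, ] <- sums[keep, , drop = FALSE] / sn[keep]
  }
  counts <- tabulate(assign, nbins = n_units)
  raw <- rowsum(training, assign)
  W <- matrix(mu, n_units, ncol(training), byrow = TRUE) +
    mean(cn) * P                                # fallback for empty clusters
  W[as.integer(rownames(raw)), ] <- raw / counts[counts > 0]
  net <- l4_network(W, lateral = NULL, theta = theta, lambda = 0, tau = tau)
  F0 <- feedforward_drive(net, training)              # n x n_units outputs
  F0[F0 < 0] <- 0                                     # lambda = 0 steady state
  U <- suppressWarnings(stats::cor(F0))
  U[!is.finite(U)] <- 0
  net <- l4_network(net$afferent, lateral = U, theta = theta,
                    lambda = lambda, tau = tau)
  net$training <- list(n_vectors = nrow(training), epochs_run = epochs_run,
                       seed = seed)
  net
}

#' Layer-4 representation of a dataset of LGN vectors
#'
#' Row `r` of the result holds the steady-state activities of all units
#' for input `dataset[r, ]`; computation is vectorized across rows.
#' Non-convergence of any column triggers a single summary warning.
#'
#' @param network a trained [l4_network()].
#' @param dataset an `n x input_dim` matrix of LGN vectors.
#' @inheritParams l4_steady_state
#' @return an `n x n_units` matrix of non-negative activities.
#' @export
l4_represent <- function(network, dataset, dt = 0.5, tol = 1e-6,
                         max_steps = 2000L) {
  if (!is.matrix(dataset)) dataset <- matrix(dataset, nrow = 1L)
  G <- feedforward_drive(network, dataset)     # n x n_units
  res <- steady_state_mat(network, t(G), dt, tol, max_steps)
  if (!res$converged)
    warning(sprintf(
      "steady states not fully converged after %d steps (residual > %g)",
      max_steps, tol), call. = FALSE)
  t(res$activities)
}

#' @export
#' @rdname l4_represent
#' @param object a trained [l4_network()].
#' @param newdata an `n x input_dim` matrix of LGN vectors.
#' @param ... passed on to [l4_represent()].
predict.l4_network <- function(object, newdata, ...) {
  l4_represent(object, newdata, ...)
}

#' Render a unit's afferent prototype on the mosaic
#'
#' Draws the ON-channel weights in red and the OFF-channel weights in
#' blue at their mosaic positions — the standard visualization of what
#' pattern a trained Layer-4 unit prefers.
#'
#' @param network a trained [l4_network()].
#' @param unit unit index.
#' @param mosaic the [hex_mosaic()] the LGN vectors were computed on.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, a data frame of centre positions and ON/OFF
#'   weights.
#' @export
plot_afferent <- function(network, unit, mosaic = hex_mosaic(), ...) {
  k <- nrow(mosaic$centers)
  w <- network$afferent[unit, ]
  stopifnot(length(w) == 2L * k)
  on <- w[seq_len(k)]; off <- w[k + seq_len(k)]
  sc <- max(abs(w))
  graphics::plot(mosaic$centers[, "col"], -mosaic$centers[, "row"],
                 asp = 1, pch = 16, cex = 2.2,
                 col = grDevices::rgb(pmax(0, on) / sc, 0, pmax(0, off) / sc),
                 xlab = "col", ylab = "-row",
                 main = sprintf("L4 unit %d afferent pattern", unit), ...)
  invisible(data.frame(row = mosaic$centers[, "row"],
                       col = mosaic$centers[, "col"], on = on, off = off))
}

#' Save / load a Layer-4 network checkpoint as plain text
#'
#' The checkpoint is a directory holding the afferent and lateral
#' matrices as CSV plus a JSON header with the scalar parameters.
#'
#' @param network a trained [l4_network()].
#' @param dir checkpoint directory.
#' @return `save_l4_network()` returns `dir` invisibly;
#'   `load_l4_network()` returns the reconstructed [l4_network()].
#' @export
save_l4_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(network$afferent, file.path(dir, "afferent.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(network$lateral, file.path(dir, "lateral.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(theta = network$theta, lambda = network$lambda, tau = network$tau,
         n_units = nrow(network$afferent), input_dim = ncol(network$afferent)),
    file.path(dir, "header.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_l4_network
#' @export
load_l4_network <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "header.json"),
                             simplifyVector = TRUE)
  aff <- as.matrix(utils::read.table(file.path(dir, "afferent.csv"),
                                     sep = ","))
  lat <- as.matrix(utils::read.table(file.path(dir, "lateral.csv"),
                                     sep = ","))
  dimnames(aff) <- NULL; dimnames(lat) <- NULL
  l4_network(aff, lat, theta = as.numeric(hdr$theta),
             lambda = as.numeric(hdr$lambda), tau = as.numeric(hdr$tau))
}
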