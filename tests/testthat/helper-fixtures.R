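# Fixtures are generated in code; small sizes keep the default run fast.

fx_image <- function(seed = 1, width = 96, height = 96, alpha = 1) {
  generate_surrogate_image(width, height, alpha, seed = seed)
}

fx_windows <- function(n = 30, seed = 2, margin = 4, window_size = 25) {
  sample_windows(fx_image(1), n, window_size, margin, seed = seed)
}

rand_window <- function(seed, ws = 25) {
  set.seed(seed)
  matrix(stats::runif(ws * ws), ws, ws)
}

# greedy one-to-one matching of learned rows to planted prototypes by
# descending cosine; returns the matched cosines
match_prototypes <- function(learned, planted) {
  ln <- learned / sqrt(rowSums(learned^2))
  pn <- planted / sqrt(rowSums(planted^2))
  cs <- pn %*% t(ln)
  out <- numeric(nrow(pn))
  for (k in seq_len(nrow(pn))) {
    ij <- arrayInd(which.max(cs), dim(cs))
    out[ij[1]] <- cs[ij[1], ij[2]]
    cs[ij[1], ] <- -Inf
    cs[, ij[2]] <- -Inf
  }
  out
}

# independent damped fixed-point solver for the rectified recurrent
# steady state, used as an oracle against the Euler integrator
damped_fixed_point <- function(g, U, lambda, damping = 0.35, tol = 1e-10,
                               max_iter = 50000L) {
  f <- rep(0, length(g))
  for (i in seq_len(max_iter)) {
    target <- pmax(0, g + lambda * as.vector(U %*% f))
    f_new <- (1 - damping) * f + damping * target
    if (max(abs(f_new - f)) < tol * damping) return(f_new)
    f <- f_new
  }
  f
}

# synthetic planted-cluster training set: vectors scattered tightly
# around n_proto random non-negative prototypes (LGN-like layout)
planted_training <- function(n_proto, dim, per_cluster, noise = 0.001,
                             seed = 99) {
  set.seed(seed)
  protos <- matrix(stats::runif(n_proto * dim), n_proto, dim)
  protos <- protos / sqrt(rowSums(protos^2))
  X <- protos[rep(seq_len(n_proto), each = per_cluster), ] +
    matrix(stats::rnorm(n_proto * per_cluster * dim, sd = noise),
           n_proto * per_cluster, dim)
  X[X < 0] <- 0
  list(x = X, prototypes = protos)
}
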