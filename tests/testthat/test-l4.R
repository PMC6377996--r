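test_that("network construction enforces the model invariants", {
  set.seed(1)
  A <- matrix(stats::runif(12 * 20), 12, 20)
  U <- matrix(stats::rnorm(144, sd = 2), 12, 12)
  net <- suppressWarnings(l4_network(A, U, theta = 0.5, lambda = 0.1))
  expect_equal(rowSums(net$afferent^2), rep(1, 12))
  expect_identical(diag(net$lateral), rep(0, 12))
  expect_true(all(abs(net$lateral) <= 1))
  expect_equal(net$lateral, t(net$lateral))
  expect_true(net$lambda * net$spectral_radius < 1)
  # stability rescale is warned about
  Ubig <- matrix(0.9, 12, 12); diag(Ubig) <- 0
  expect_warning(l4_network(A, Ubig, theta = 0.5, lambda = 0.5),
                 "stability")
  expect_error(l4_network(A, U, theta = 1.2), "theta")
  expect_error(l4_network(A, U[1:3, 1:3]), "square")
})

test_that("feedforward drive is a thresholded cosine similarity", {
  set.seed(2)
  A <- matrix(stats::runif(6 * 10), 6, 10)
  net <- l4_network(A, theta = 0.6, lambda = 0)
  w1 <- net$afferent[1, ]
  # perfect prototype match of magnitude c gives drive exactly c
  expect_equal(feedforward_drive(net, 2.7 * w1)[1], 2.7)
  # input at cosine exactly theta gives zero drive
  v <- stats::rnorm(10)
  v <- v - sum(v * w1) * w1
  v <- v / sqrt(sum(v^2))
  x <- 0.6 * w1 + sqrt(1 - 0.6^2) * v
  expect_equal(feedforward_drive(net, x)[1], 0, tolerance = 1e-12)
  # zero input gives zero drive everywhere
  expect_identical(feedforward_drive(net, rep(0, 10)), rep(0, 6))
  # positive homogeneity
  y <- stats::runif(10)
  expect_equal(feedforward_drive(net, 3 * y), 3 * feedforward_drive(net, y))
  # batch form agrees with the vector form
  X <- rbind(x, y)
  G <- feedforward_drive(net, X)
  expect_equal(G[2, ], feedforward_drive(net, y))
  expect_error(feedforward_drive(net, rep(1, 4)), "dimension")
})

test_that("lambda = 0 steady states equal the rectified closed form", {
  set.seed(3)
  A <- matrix(stats::runif(8 * 14), 8, 14)
  net <- l4_network(A, theta = 0.5, lambda = 0)
  for (s in 1:5) {
    x <- stats::runif(14)
    st <- l4_steady_state(net, x, tol = 1e-8)
    expect_true(st$converged)
    expect_equal(st$activities, pmax(0, feedforward_drive(net, x)),
                 tolerance = 1e-6)
  }
  # the origin is the fixed point for zero input, any lambda
  netL <- suppressWarnings(l4_network(A, matrix(0.2, 8, 8), theta = 0.5,
                                      lambda = 0.3))
  expect_identical(l4_steady_state(netL, rep(0, 14))$activities, rep(0, 8))
})

test_that("recurrent steady states match an independent damped fixed-point oracle", {
  set.seed(4)
  A <- matrix(stats::runif(12 * 18), 12, 18)
  U <- stats::cor(matrix(stats::rnorm(40 * 12), 40, 12))
  diag(U) <- 0
  net <- l4_network(A, U, theta = 0.5, lambda = 0.25)
  tol <- 1e-8
  for (s in 1:5) {
    x <- stats::runif(18)
    st <- l4_steady_state(net, x, tol = tol, max_steps = 10000L)
    expect_true(st$converged)
    oracle <- damped_fixed_point(feedforward_drive(net, x), net$lateral,
                                 net$lambda)
    expect_equal(st$activities, oracle, tolerance = 10 * tol)
    # the state satisfies the rectified fixed-point equation
    resid <- pmax(0, feedforward_drive(net, x) +
                    net$lambda * as.vector(net$lateral %*% st$activities)) -
      st$activities
    expect_lt(max(abs(resid)), tol)
  }
  expect_warning(l4_steady_state(net, stats::runif(18), max_steps = 3L),
                 "not converged")
})

test_that("training recovers planted prototypes and builds a valid lateral matrix", {
  pt <- planted_training(20, 30, per_cluster = 15)
  net <- l4_train(pt$x, n_units = 20, theta = 0.5, lambda = 0.2, seed = 5)
  cs <- match_prototypes(net$afferent, pt$prototypes)
  expect_true(all(cs >= 0.99))
  expect_equal(net$lateral, t(net$lateral))
  expect_identical(diag(net$lateral), rep(0, 20))
  expect_true(all(abs(net$lateral) <= 1))
  expect_true(net$lambda * net$spectral_radius < 1)
})

test_that("training is invariant to duplicating the corpus and rejects degenerate input", {
  pt <- planted_training(6, 12, per_cluster = 10, seed = 8)
  n1 <- l4_train(pt$x, n_units = 6, theta = 0.5, seed = 3)
  n2 <- l4_train(rbind(pt$x, pt$x), n_units = 6, theta = 0.5, seed = 3)
  expect_equal(n1$afferent, n2$afferent)
  expect_equal(n1$lateral, n2$lateral)
  withzero <- rbind(pt$x, 0)
  expect_warning(l4_train(withzero, n_units = 6, theta = 0.5, seed = 3),
                 "all-zero")
  expect_error(l4_train(pt$x[1:4, ], n_units = 6), "at least")
})

test_that("batch representation is consistent, homogeneous and handles zeros", {
  set.seed(6)
  A <- matrix(stats::runif(10 * 16), 10, 16)
  net <- l4_network(A, theta = 0.5, lambda = 0)
  X <- matrix(stats::runif(3 * 16), 3, 16)
  R <- l4_represent(net, X)
  expect_identical(dim(R), c(3L, 10L))
  expect_equal(R[2, ], l4_steady_state(net, X[2, ])$activities,
               tolerance = 1e-6)
  # degree-1 homogeneity at lambda = 0
  expect_equal(l4_represent(net, 2 * X), 2 * R, tolerance = 1e-5)
  expect_identical(l4_represent(net, matrix(0, 1, 16))[1, ], rep(0, 10))
  expect_equal(predict(net, X), R)
})

test_that("network checkpoints round-trip through plain-text files", {
  pt <- planted_training(5, 9, per_cluster = 8, seed = 12)
  net <- l4_train(pt$x, n_units = 5, theta = 0.5, lambda = 0.1, seed = 2)
  dir <- withr::local_tempdir()
  save_l4_network(net, dir)
  back <- load_l4_network(dir)
  expect_equal(back$afferent, net$afferent, tolerance = 1e-12)
  expect_equal(back$lateral, net$lateral, tolerance = 1e-12)
  expect_identical(back$theta, net$theta)
  expect_identical(back$tau, net$tau)
})
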