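test_that("DoG profile matches its closed form at the centre and at the zero crossing", {
  p <- dog_profile()
  sc <- 0.833; ss <- 3 * 0.833
  # independent closed forms
  expect_equal(dog_value(0, p), 1 / (2 * pi * sc^2) - 1 / (2 * pi * ss^2),
               tolerance = 1e-12)
  expect_equal(dog_value(0, p), 0.2039, tolerance = 1e-4)
  r0 <- sqrt(2 * log(9) / (1 / sc^2 - 1 / ss^2))
  expect_equal(dog_zero_crossing(p), r0, tolerance = 1e-6)
  expect_equal(2 * dog_zero_crossing(p), 3.704, tolerance = 1e-3)
  expect_identical(round(2 * dog_zero_crossing(p)), 4)
})

test_that("DoG changes sign exactly once along a radial ray", {
  p <- dog_profile()
  r <- seq(0, p$support, by = 0.01)
  v <- dog_value(r, p)
  expect_identical(sum(diff(sign(v)) != 0), 1L)
  expect_gt(v[1], 0)
  # near-zero total mass (difference of two unit-mass Gaussians):
  # discrete sum over a generous support
  big <- dog_profile(support = 30)
  expect_lt(abs(sum(big$kernel)), 5e-3)
  expect_error(dog_profile(surround_ratio = 1), "surround_ratio")
  expect_error(dog_profile(sigma_center = -1), "sigma_center")
})

test_that("hexagonal mosaic has centred hexagonal counts and symmetry", {
  expect_identical(nrow(hex_mosaic(0)$centers), 1L)
  expect_identical(nrow(hex_mosaic(1)$centers), 7L)
  expect_identical(nrow(hex_mosaic(5)$centers), 91L)
  m0 <- hex_mosaic(0)
  expect_equal(as.vector(m0$centers), c(13, 13))
  # 60-degree rotational symmetry about the window centre
  m <- hex_mosaic(5)
  ctr <- (m$window_size + 1) / 2
  z <- complex(real = m$centers[, "col"] - ctr,
               imaginary = m$centers[, "row"] - ctr)
  rot <- z * exp(1i * pi / 3)
  for (k in seq_along(z)) {
    d <- min(Mod(rot[k] - z))
    expect_lt(d, 1e-9)
  }
  expect_warning(hex_mosaic(5, spacing = 4, window_size = 25), "beyond")
})

test_that("LGN responses obey the ON/OFF baseline algebra", {
  mo <- hex_mosaic(); pr <- dog_profile()
  W <- lgn_weights(mo, pr)
  for (s in 1:5) {
    win <- rand_window(s)
    v <- lgn_response(win, mo, pr, weights = W)
    expect_length(v, 182L)
    expect_gte(min(v), 0)
    on <- v[1:91]; off <- v[92:182]
    both <- on > 0 & off > 0
    expect_true(any(both))
    expect_equal(on[both] + off[both], rep(0.2, sum(both)))
    # antisymmetry around the baseline wherever neither side rectifies
    raw <- as.vector(W %*% as.vector(win))
    small <- abs(raw) <= 0.1
    expect_equal((on - off)[small], 2 * raw[small])
  }
})

test_that("uniform windows give near-baseline activity at interior units", {
  mo <- hex_mosaic(); pr <- dog_profile()
  v <- lgn_response(matrix(0.5, 25, 25), mo, pr)
  centre_unit <- which.min(rowSums(sweep(mo$centers, 2, c(13, 13))^2))
  expect_equal(v[centre_unit], 0.1, tolerance = 0.02)
  expect_equal(v[91 + centre_unit], 0.1, tolerance = 0.02)
  # a bright spot on a dark background excites ON and silences OFF
  spot <- matrix(0, 25, 25)
  spot[13, 13] <- 1
  vs <- lgn_response(spot, mo, pr)
  expect_gt(vs[centre_unit], 0.1)
  expect_lt(vs[91 + centre_unit], 0.1)
  expect_error(lgn_response(matrix(0.5, 10, 10), mo, pr), "match")
})

test_that("raw filter responses are linear in the window pixels", {
  mo <- hex_mosaic(); pr <- dog_profile()
  W <- lgn_weights(mo, pr)
  for (s in 1:3) {
    a <- rand_window(s); b <- rand_window(s + 10)
    sa <- W %*% as.vector(a); sb <- W %*% as.vector(b)
    sab <- W %*% as.vector(0.3 * a + 0.7 * b)
    expect_equal(as.vector(sab), as.vector(0.3 * sa + 0.7 * sb),
                 tolerance = 1e-12)
  }
})

test_that("180-degree rotation permutes the LGN vector exactly", {
  mo <- hex_mosaic(); pr <- dog_profile()
  W <- lgn_weights(mo, pr)
  ctr <- (mo$window_size + 1) / 2
  # permutation mapping each centre to its point reflection
  rc <- cbind(2 * ctr - mo$centers[, "row"], 2 * ctr - mo$centers[, "col"])
  perm <- apply(rc, 1, function(p)
    which.min((mo$centers[, "row"] - p[1])^2 + (mo$centers[, "col"] - p[2])^2))
  win <- rand_window(21)
  rot <- win[25:1, 25:1]
  v <- lgn_response(win, mo, pr, weights = W)
  vr <- lgn_response(rot, mo, pr, weights = W)
  expect_equal(vr[seq_len(91)], v[perm], tolerance = 1e-10)
  expect_equal(vr[91 + seq_len(91)], v[91 + perm], tolerance = 1e-10)
})

test_that("batch representation matches the single-window response", {
  mo <- hex_mosaic(); pr <- dog_profile()
  X <- rbind(as.vector(rand_window(1)), as.vector(rand_window(2)))
  R <- lgn_represent(X, mo, pr)
  expect_identical(dim(R), c(2L, 182L))
  expect_equal(R[1, ], lgn_response(rand_window(1), mo, pr))
  expect_equal(R[2, ], lgn_response(rand_window(2), mo, pr))
})
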