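test_that("surrogate images span [0,1] exactly and are seed-reproducible", {
  img <- generate_surrogate_image(500, 335, 1, seed = 7)
  expect_identical(dim(img), c(335L, 500L))
  expect_identical(min(img), 0)
  expect_identical(max(img), 1)
  img2 <- generate_surrogate_image(500, 335, 1, seed = 7)
  expect_identical(unclass(img), unclass(img2))
  expect_false(identical(unclass(img),
                         unclass(generate_surrogate_image(500, 335, 1,
                                                          seed = 8))))
  expect_error(generate_surrogate_image(10, 64), "32")
  expect_error(generate_surrogate_image(64, 64, -1), "spectral_exponent")
})

test_that("zero spectral exponent gives white noise (no serial correlation)", {
  img <- generate_surrogate_image(64, 64, 0, seed = 1)
  v <- as.vector(unclass(img))
  expect_lt(abs(stats::cor(v[-1], v[-length(v)])), 0.05)
})

test_that("surrogate construction is orientation-isotropic", {
  # mean horizontal / vertical gradient-energy ratio over many seeds
  ratios <- vapply(1:50, function(s) {
    m <- unclass(generate_surrogate_image(64, 64, 1, seed = s))
    mean((m[, -1] - m[, -ncol(m)])^2) / mean((m[-1, ] - m[-nrow(m), ])^2)
  }, 0)
  expect_gt(mean(ratios), 0.9)
  expect_lt(mean(ratios), 1.1)
})

test_that("PNG and PGM round trips preserve intensities to 1/255", {
  img <- generate_surrogate_image(40, 32, 1, seed = 3)
  for (ext in c("png", "pgm")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_image(img, path)
    back <- read_image(path)
    expect_identical(dim(back), dim(img))
    expect_lt(max(abs(unclass(back) - unclass(img))), 1 / 255 + 1e-12)
  }
  zero <- gray_image(matrix(0, 10, 10))
  p <- withr::local_tempfile(fileext = ".png")
  write_image(zero, p)
  expect_identical(unclass(read_image(p)), matrix(0, 10, 10))
})

test_that("8-bit values map to intensity by division by 255", {
  m <- matrix(c(255, 51, 0, 128) / 255, 2, 2)
  p <- withr::local_tempfile(fileext = ".pgm")
  write_image(gray_image(m), p)
  back <- read_image(p)
  expect_equal(back[1, 1], 1.0)
  expect_equal(back[2, 1], 51 / 255)   # = 0.2
  expect_equal(back[2, 1], 0.2)
  expect_equal(back[1, 2], 0)
})

test_that("colour PNG input is converted with BT.601 luma weights", {
  arr <- array(0, c(4, 5, 3))
  arr[, , 1] <- 0.6; arr[, , 2] <- 0.2; arr[, , 3] <- 0.9
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(arr, p)
  lum <- 0.299 * 0.6 + 0.587 * 0.2 + 0.114 * 0.9
  expect_equal(as.vector(unclass(read_image(p))), rep(lum, 20),
               tolerance = 1 / 255)
  expect_error(read_image(withr::local_tempfile(fileext = ".tif")),
               "not found|format")
  expect_error(read_image("no/such/file.png"), "not found")
})

test_that("window sampling stays in bounds and honours the margin", {
  imgs <- list(fx_image(1), fx_image(2, 80, 64))
  ws <- sample_windows(imgs, 50, window_size = 25, margin = 4, seed = 5)
  expect_length(ws, 50)
  for (w in ws) {
    expect_identical(dim(w$core), c(25L, 25L))
    expect_identical(dim(w$field), c(33L, 33L))
    src <- imgs[[w$source_id]]
    expect_gte(w$top_left[["row"]] - w$margin, 1L)
    expect_gte(w$top_left[["col"]] - w$margin, 1L)
    expect_lte(w$top_left[["row"]] + 24L + w$margin, nrow(src))
    expect_lte(w$top_left[["col"]] + 24L + w$margin, ncol(src))
    # core is the centre of the field and matches the source
    expect_identical(w$core, w$field[5:29, 5:29])
    expect_identical(
      w$core,
      unclass(src)[w$top_left[["row"]]:(w$top_left[["row"]] + 24L),
                   w$top_left[["col"]]:(w$top_left[["col"]] + 24L)])
  }
})

test_that("window sampling is deterministic and handles the unique placement", {
  ws1 <- fx_windows(seed = 11)
  ws2 <- fx_windows(seed = 11)
  expect_identical(ws1, ws2)
  tiny <- gray_image(matrix(stats::runif(625), 25, 25))
  w <- sample_windows(tiny, 1, window_size = 25, margin = 0, seed = 1)[[1]]
  expect_identical(w$top_left, c(row = 1L, col = 1L))
  expect_identical(w$core, unclass(tiny))
  expect_error(sample_windows(tiny, 1, window_size = 25, margin = 1),
               "too small")
})

test_that("window sets serialize to PNG cores plus a CSV manifest", {
  ws <- fx_windows(n = 4)
  dir <- withr::local_tempdir()
  man <- save_window_set(ws, dir)
  expect_identical(nrow(man), 4L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_length(list.files(dir, pattern = "\\.png$"), 4L)
  back <- read_image(file.path(dir, "window_00001.png"))
  expect_lt(max(abs(unclass(back) - ws[[1]]$core)), 1 / 255 + 1e-12)
})
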