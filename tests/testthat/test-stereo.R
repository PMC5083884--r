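test_that("identical images give zero disparity at textured plant pixels", {
  img <- noise_raster(40, 60, seed = 2)
  mask <- matrix(FALSE, 40, 60); mask[10:30, 10:50] <- TRUE
  d <- compute_disparity(img, img, mask, search = c(-4, 12))
  expect_gt(sum(d$valid), 0.9 * sum(mask))
  # subpixel refinement can move an exact integer optimum by a fraction
  expect_true(all(abs(d$values[d$valid]) <= 0.25))
})

test_that("a pure horizontal shift is recovered to subpixel tolerance", {
  img <- noise_raster(50, 120, seed = 13)
  right <- shift_left(img, 8)
  mask <- matrix(FALSE, 50, 120); mask[15:35, 30:90] <- TRUE
  d <- compute_disparity(img, right, mask, search = c(2, 20))
  expect_gt(sum(d$valid), 0.9 * sum(mask))
  expect_true(all(abs(d$values[d$valid] - 8) <= 0.25))

  # exhaustive integer-disparity scan oracle at a few interior pixels
  gl <- gray_of(img); gr <- gray_of(right)
  for (p in list(c(20, 40), c(25, 60), c(33, 85))) {
    expect_identical(oracle_zncc_scan(gl, gr, p[1], p[2], 2:20), 8L)
  }
})

test_that("disparity is computed only at masked pixels (work bound)", {
  img <- noise_raster(40, 80, seed = 4)
  right <- shift_left(img, 6)
  mask <- matrix(FALSE, 40, 80); mask[12:28, 25:55] <- TRUE
  search <- c(2, 14)
  d <- compute_disparity(img, right, mask, search = search, lr_check = FALSE)
  expect_lte(d$cost_evals, sum(mask) * (search[2] - search[1] + 1))
  expect_true(all(!d$valid[!mask]))
})

test_that("left-right symmetry: a mirrored, swapped pair gives the mirrored map", {
  img <- noise_raster(40, 90, seed = 6)
  right <- shift_left(img, 7)
  mask <- matrix(FALSE, 40, 90); mask[12:30, 25:65] <- TRUE
  fwd <- compute_disparity(img, right, mask, search = c(2, 14), lr_check = FALSE)
  mir <- function(a) if (length(dim(a)) == 3) a[, rev(seq_len(dim(a)[2])), , drop = FALSE] else a[, rev(seq_len(ncol(a))), drop = FALSE]
  swp <- compute_disparity(mir(right), mir(img), mir(mask),
                           search = c(2, 14), lr_check = FALSE)
  both <- fwd$valid & mir(swp$valid)
  expect_gt(sum(both), 0.8 * sum(mask))
  expect_true(all(abs(fwd$values[both] - mir(swp$values)[both]) <= 0.5))
})

test_that("input validation rejects malformed matching requests", {
  img <- noise_raster(20, 30, seed = 1)
  mask <- matrix(TRUE, 20, 30)
  expect_error(compute_disparity(img, noise_raster(20, 29, seed = 1), mask),
               "shape")
  expect_error(compute_disparity(img, img, mask, search = c(2, 10),
                                 block = 8), "odd")
  expect_error(compute_disparity(img, img, mask, search = c(10, 4)), "empty")
  expect_error(compute_disparity(img, img, mask, search = c(0, 40)), "width")
})

test_that("pinhole triangulation matches the closed form and is monotone", {
  rig <- bench_rig()
  expect_equal(focal_px(rig), 1280 * 5 / 6.79, tolerance = 1e-12)
  mk <- function(d) structure(list(values = matrix(d, 1, 1),
                                   valid = matrix(TRUE, 1, 1)),
                              class = "disparity_map")
  # soil plane: disparity f_px * b / Z at Z = 500
  h0 <- disparity_to_height(mk(103.68), rig)
  expect_equal(h0$heights_mm[1, 1], 0, tolerance = 0.1)
  h100 <- disparity_to_height(mk(129.60), rig)
  expect_equal(h100$heights_mm[1, 1], 100, tolerance = 0.1)
  # strictly increasing in disparity
  ds <- seq(104, 200, by = 2.5)
  hs <- vapply(ds, function(d) disparity_to_height(mk(d), rig)$heights_mm[1, 1], 0)
  expect_true(all(diff(hs) > 0))
  # non-positive disparity never throws, just invalidates
  expect_false(disparity_to_height(mk(0), rig)$valid[1, 1])
  expect_false(disparity_to_height(mk(-3), rig)$valid[1, 1])
})

test_that("height summary statistics match a sort-based oracle", {
  const <- structure(list(heights_mm = matrix(40, 5, 20),
                          valid = matrix(TRUE, 5, 20)),
                     class = "height_field")
  s <- summarize_height(const)
  expect_equal(s$plant_height_mm, 40)
  expect_equal(s$mean_mm, 40)
  expect_equal(s$median_mm, 40)

  vals <- c(rep(10, 100), rep(50, 100))
  two <- structure(list(heights_mm = matrix(vals, 10, 20),
                        valid = matrix(TRUE, 10, 20)),
                   class = "height_field")
  s2 <- summarize_height(two)
  srt <- sort(vals)
  expect_equal(s2$median_mm, (srt[100] + srt[101]) / 2)
  expect_equal(s2$p95_mm, 50)
  expect_gte(s2$p95_mm, s2$median_mm)

  empty <- structure(list(heights_mm = matrix(NA_real_, 3, 3),
                          valid = matrix(FALSE, 3, 3)),
                     class = "height_field")
  expect_warning(se <- summarize_height(empty), "no valid")
  expect_identical(se$n_valid, 0L)
  expect_true(is.na(se$plant_height_mm))
})

test_that("height PNG encoding round-trips validity exactly and heights to 0.05 mm", {
  set.seed(31)
  h <- matrix(runif(600, 0, 120), 20, 30)
  valid <- matrix(runif(600) > 0.3, 20, 30)
  h[!valid] <- NA_real_
  field <- structure(list(heights_mm = h, valid = valid), class = "height_field")
  f <- withr::local_tempfile(fileext = ".png")
  write_height_png(field, f)
  back <- read_height_png(f)
  expect_identical(back$valid, valid)
  expect_lte(max(abs(back$heights_mm[valid] - h[valid])), 0.05)
  # encoding definition: 0 mm stores as 1, invalid as 0
  one <- structure(list(heights_mm = matrix(0, 1, 2),
                        valid = matrix(c(TRUE, FALSE), 1, 2)),
                   class = "height_field")
  f2 <- withr::local_tempfile(fileext = ".png")
  write_height_png(one, f2)
  raw16 <- round(png::readPNG(f2) * 65535)
  expect_equal(as.vector(raw16), c(1, 0))
  # out-of-range heights are refused with the offending value named
  big <- structure(list(heights_mm = matrix(7000, 1, 1),
                        valid = matrix(TRUE, 1, 1)), class = "height_field")
  expect_error(write_height_png(big, withr::local_tempfile(fileext = ".png")),
               "7000")
})
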