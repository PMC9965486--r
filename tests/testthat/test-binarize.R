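test_that("local stats on a constant image are the value and zero", {
  ls <- local_stats(matrix(0.4, 40, 40), 5)
  expect_equal(ls$mean, matrix(0.4, 40, 40), tolerance = 1e-10)
  expect_equal(ls$sd, matrix(0, 40, 40), tolerance = 1e-7)
})

test_that("local stats match brute-force enumeration incl. mirrored corners", {
  x <- matrix(0, 9, 9); x[5, 5] <- 1            # one bright pixel
  ls <- local_stats(x, 2)
  br <- brute_local_stats(x, 2)
  expect_equal(ls$mean, br$mean, tolerance = 1e-8)
  expect_equal(ls$sd, br$sd, tolerance = 1e-6)   # sqrt amplifies FFT rounding

  set.seed(14)
  for (rad in c(1, 3)) {
    y <- matrix(runif(15 * 15), 15, 15)
    lsy <- local_stats(y, rad)
    bry <- brute_local_stats(y, rad)
    expect_equal(lsy$mean, bry$mean, tolerance = 1e-8)
    expect_equal(lsy$sd, bry$sd, tolerance = 1e-6)
  }
})

test_that("thresholding matches a per-pixel reference on random images", {
  set.seed(3)
  pp <- phansalkar_params(radius_px = 4)
  for (rep in 1:3) {
    x <- matrix(runif(64 * 64), 64, 64)
    fm <- phansalkar_threshold(x, pp)
    br <- brute_local_stats(x, 4)
    thr <- br$mean * (1 + 2 * exp(-10 * br$mean) + 0.25 * (br$sd / 0.5 - 1))
    expect_identical(fm$pixels, matrix(as.integer(x > thr), 64, 64))
  }
})

test_that("constant images hit the closed-form threshold", {
  # m = 0.5, s = 0: T = 0.5 * (1 + 2 exp(-5) - 0.25) = 0.38174
  expect_equal(round(0.5 * (1 + 2 * exp(-5) - 0.25), 5), 0.38174)
  fm <- phansalkar_threshold(matrix(0.5, 54, 54))
  expect_equal(ccfa_ratio(fm), 100)
  # all-zero image: T = 0 and 0 > 0 is false everywhere
  fm0 <- phansalkar_threshold(matrix(0, 54, 54))
  expect_equal(ccfa_ratio(fm0), 0)
})

test_that("well-separated two-valued textures are recovered within 2 points", {
  p <- image_gen_params(width_px = 180, height_px = 180, tile_sd = 0.05,
                        texture_corr_len = 0, flow_intensity_sd = 0,
                        bg_intensity_sd = 0, seed = 6)
  fm <- generate_flow_map(p)
  sl <- render_grayscale(fm, p)
  rec <- phansalkar_threshold(sl, phansalkar_params(radius_px = 10))
  expect_lt(abs(ccfa_ratio(rec) - ccfa_ratio(fm)), 2)
})

test_that("block images are recovered exactly away from the value boundary", {
  # dark background (m < ln(8)/10) keeps T above m, bright foreground below:
  # both homogeneous regions classify correctly; only the window-width band
  # straddling the boundary is uncertain
  rad <- 8
  truth <- matrix(0L, 120, 120); truth[, 61:120] <- 1L
  img <- ifelse(truth == 1L, 0.7, 0.1)
  rec <- phansalkar_threshold(img, phansalkar_params(radius_px = rad))
  away <- col(truth) < 61 - rad | col(truth) > 60 + rad
  expect_identical(rec$pixels[away], truth[away])
  expect_lt(abs(ccfa_ratio(rec) - ccfa_ratio(truth)), 2)
})

test_that("raising foreground intensity never decreases the flow fraction", {
  p <- image_gen_params(width_px = 90, height_px = 90, tile_sd = 0.05,
                        texture_corr_len = 0, flow_intensity_sd = 0,
                        bg_intensity_sd = 0, seed = 9)
  fm <- generate_flow_map(p)
  fracs <- vapply(c(0.55, 0.65, 0.75, 0.85, 0.95), function(fg) {
    img <- ifelse(fm$pixels == 1L, fg, 0.35)
    ccfa_ratio(phansalkar_threshold(img, phansalkar_params(radius_px = 8)))
  }, 1)
  expect_true(all(diff(fracs) >= 0))
})

test_that("input validation: normalization, radius bounds", {
  expect_error(phansalkar_threshold(matrix(2, 30, 30)), "normalized")
  expect_error(local_stats(matrix(0.5, 20, 20), 11), "half the image")
  expect_error(phansalkar_params(radius_px = 0), "radius")
  expect_error(phansalkar_params(r = 0), "r must")
})
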