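test_that("quantile thresholding conserves the per-tile target area", {
  p <- image_gen_params(width_px = 180, height_px = 180,
                        true_flow_fraction = 0.5, tile_sd = 0,
                        texture_corr_len = 0, seed = 11)
  fm <- generate_flow_map(p)
  # tile_sd = 0 forces every tile to the exact target count
  expect_equal(unname(split_tiles(fm)$ratios), matrix(50, 18, 18))
  expect_equal(mean(fm$pixels), 0.5)

  p2 <- image_gen_params(true_flow_fraction = 0.581, tile_sd = 0.08,
                         texture_corr_len = 0, seed = 12)
  fm2 <- generate_flow_map(p2)
  npx <- prod(dim(fm2$pixels)) / 18^2
  expect_true(all(abs(fm2$tile_realized - fm2$tile_targets) <= 1 / npx))
  expect_equal(split_tiles(fm2)$ratios / 100, fm2$tile_realized)
})

test_that("near-saturated flow fraction yields an all-foreground map", {
  p <- image_gen_params(width_px = 90, height_px = 90,
                        true_flow_fraction = 0.999, tile_sd = 0,
                        texture_corr_len = 0, seed = 2)
  fm <- generate_flow_map(p)
  # round(0.999 * 25) = 25 px per 5x5 tile
  expect_equal(ccfa_ratio(fm), 100)
})

test_that("replicate whole-map fractions recover the generating fraction", {
  set.seed(41)
  p <- image_gen_params(true_flow_fraction = 0.581, tile_sd = 0.05,
                        texture_corr_len = 0)
  fr <- replicate(100, mean(generate_flow_map(p)$pixels))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.581), 3 * se)
})

test_that("drawn tile fractions match the logit-normal calibration", {
  cal <- logit_normal_calibrate(0.581, 0.106)
  set.seed(5)
  x <- plogis(cal[["mu"]] + cal[["sigma"]] * rnorm(2e5))
  expect_lt(abs(mean(x) - 0.581), 3 * sd(x) / sqrt(length(x)))
  expect_lt(abs(sd(x) - 0.106), 0.001)
  expect_equal(unname(logit_normal_calibrate(0.3, 0)),
               c(qlogis(0.3), 0))
  expect_error(logit_normal_calibrate(0.5, 0.6), "too large")
})

test_that("increasing tile dispersion increases the downstream CV", {
  set.seed(77)
  mk <- function(tsd) {
    p <- image_gen_params(width_px = 180, height_px = 180, tile_sd = tsd,
                          texture_corr_len = 0)
    mean(replicate(50, cv_of_ccfa(split_tiles(generate_flow_map(p)))))
  }
  expect_gt(mk(0.08), mk(0.03))
})

test_that("generation is bit-identical under a fixed seed", {
  p <- image_gen_params(seed = 99, texture_corr_len = 1.5)
  a <- generate_flow_map(p); b <- generate_flow_map(p)
  expect_identical(a$pixels, b$pixels)
  ra <- render_grayscale(a, p); rb <- render_grayscale(b, p)
  expect_identical(ra$pixels, rb$pixels)
})

test_that("two-valued rendering is exactly recoverable by any mid threshold", {
  p <- image_gen_params(width_px = 90, height_px = 90, tile_sd = 0.05,
                        texture_corr_len = 0, flow_intensity_sd = 0,
                        bg_intensity_sd = 0, seed = 8)
  fm <- generate_flow_map(p)
  sl <- render_grayscale(fm, p)
  expect_setequal(unique(as.vector(sl$pixels)), c(0.35, 0.75))
  expect_identical(matrix(as.integer(sl$pixels > 0.55), 90, 90), fm$pixels)
})

test_that("poor intensity separability triggers a warning", {
  p <- image_gen_params(width_px = 90, height_px = 90, seed = 3,
                        flow_intensity_mean = 0.5, bg_intensity_mean = 0.45,
                        flow_intensity_sd = 0.2, bg_intensity_sd = 0.2)
  fm <- generate_flow_map(p)
  expect_warning(render_grayscale(fm, p), "separability")
})

test_that("generator parameter validation catches bad inputs", {
  expect_error(image_gen_params(true_flow_fraction = 1.2), "inside")
  expect_error(image_gen_params(width_px = 100), "divisible")
  expect_error(image_gen_params(flow_intensity_mean = 0.3,
                                bg_intensity_mean = 0.4), "exceed")
  p <- image_gen_params()
  expect_error(generate_flow_map(p, base_fraction = matrix(0.5, 4, 4)),
               "18 x 18")
})

test_that("tile base matrices encode region and side offsets", {
  m <- tile_base_matrix(0.55, region_tiles = NULL, thin_side = "upper",
                        thin_side_offset = -0.017)
  expect_equal(mean(m[1:6, ]), 0.55 - 0.0085)
  expect_equal(mean(m[7:12, ]), 0.55)
  expect_equal(mean(m[13:18, ]), 0.55 + 0.0085)
  expect_equal(mean(m), 0.55)
  msk <- faf_rectangle_mask(540, 540, coverage = 0.15, random = FALSE)
  tiles <- attr(msk, "tiles")
  expect_equal(sum(tiles), 49)                  # 7x7 tiles ~ 15% of 324
  expect_equal(sum(msk), 49 * 30 * 30)          # snapped to tile boundaries
  m2 <- tile_base_matrix(0.528, region_tiles = tiles, region_offset = -0.051)
  expect_equal(mean(m2[tiles]), 0.477)
  expect_equal(mean(m2[!tiles]), 0.528)
})
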