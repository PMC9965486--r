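test_that("CCFA ratio is the exact pixel-count ratio", {
  expect_equal(ccfa_ratio(matrix(1L, 54, 54)), 100)
  checker <- matrix(rep_len(c(0L, 1L), 54 * 54), 54, 54)
  expect_equal(ccfa_ratio(checker), 50)
  # 169420 of 291600 pixels = 58.10%, the AMD-group mean level
  p <- matrix(0L, 540, 540)
  p[seq_len(169420)] <- 1L
  expect_equal(ccfa_ratio(p), 100 * 169420 / 291600, tolerance = 0)
  expect_equal(round(ccfa_ratio(p), 2), 58.10)
  mask <- matrix(FALSE, 54, 54); mask[1:10, 1:10] <- TRUE
  expect_equal(ccfa_ratio(checker, mask), 50)
  expect_error(ccfa_ratio(checker, matrix(FALSE, 54, 54)), "empty")
})

test_that("tile grids match brute-force pixel counting exactly", {
  expect_equal(unname(split_tiles(matrix(1L, 54, 54))$ratios),
               matrix(100, 18, 18))
  one <- matrix(0L, 54, 54); one[1:3, 1:3] <- 1L
  g <- split_tiles(one)
  expect_equal(g$ratios[1, 1], 100)
  expect_equal(sum(g$ratios), 100)
  set.seed(19)
  for (i in 1:10) {
    p <- matrix(rbinom(54 * 54, 1, runif(1, 0.2, 0.8)), 54, 54)
    expect_identical(split_tiles(p)$ratios, brute_tile_ratios(p, 18))
  }
  expect_error(split_tiles(matrix(0L, 50, 50)), "divisible")
})

test_that("CV of tile ratios uses the sample SD over the mean", {
  expect_equal(cv_of_ccfa(matrix(50, 18, 18)), 0)
  # two-point grid {40, 60}: mean 50, sample SD sqrt(324/323)*10
  two <- matrix(rep_len(c(40, 60), 324), 18, 18)
  expect_equal(cv_of_ccfa(two), sqrt(100 * 324 / 323) / 50, tolerance = 1e-12)
  expect_equal(round(cv_of_ccfa(two), 4), 0.2003)
  expect_error(cv_of_ccfa(matrix(0, 18, 18)), "undefined")
})

test_that("simulated CV calibration is recovered by the tile statistic", {
  set.seed(23)
  p <- image_gen_params(true_flow_fraction = 0.581,
                        tile_sd = 0.182 * 0.581, texture_corr_len = 0)
  cvs <- replicate(50, cv_of_ccfa(split_tiles(generate_flow_map(p))))
  se <- sd(cvs) / sqrt(length(cvs))
  expect_lt(abs(mean(cvs) - 0.182), 3 * se)
})

test_that("whole-image ratio equals the mean of equal-area tile ratios", {
  set.seed(31)
  for (i in 1:5) {
    p <- matrix(rbinom(540 * 540, 1, 0.6), 540, 540)
    expect_equal(ccfa_ratio(p), mean(split_tiles(p)$ratios),
                 tolerance = 1e-9)
  }
})

test_that("ratios are additive over disjoint masks and CV is scale-free", {
  set.seed(37)
  p <- matrix(rbinom(108 * 108, 1, 0.55), 108, 108)
  a <- matrix(runif(108 * 108) < 0.4, 108, 108)
  b <- !a
  whole <- ccfa_ratio(p)
  combined <- (sum(a) * ccfa_ratio(p, a) + sum(b) * ccfa_ratio(p, b)) /
    (sum(a) + sum(b))
  expect_equal(whole, combined, tolerance = 1e-9)
  g <- split_tiles(p)
  expect_equal(cv_of_ccfa(g$ratios * 3), cv_of_ccfa(g$ratios),
               tolerance = 1e-12)
})

test_that("thirds partition the image and recombine to the whole ratio", {
  set.seed(43)
  p <- matrix(rbinom(540 * 540, 1, 0.6), 540, 540)
  th <- region_thirds(p)
  expect_equal(sum(th$upper) + sum(th$middle) + sum(th$lower), 540 * 540)
  expect_equal(sum(th$upper), 180 * 540)
  expect_false(any(th$upper & th$middle))
  band_ratios <- vapply(th, function(m) ccfa_ratio(p, m), 1)
  expect_equal(mean(band_ratios), ccfa_ratio(p), tolerance = 1e-9)
  expect_error(region_thirds(matrix(0L, 100, 100)), "divisible by 3")
})

test_that("side metrics respect the thicker-side label", {
  p <- image_gen_params(true_flow_fraction = 0.55, tile_sd = 0.05,
                        texture_corr_len = 0, seed = 47)
  fm <- generate_flow_map(p)
  up <- side_metrics(fm, "upper")
  lo <- side_metrics(fm, "lower")
  # relabeling swaps the outputs
  expect_equal(up$thicker, lo$thinner)
  expect_equal(up$thinner, lo$thicker)
  # symmetric generation: sides agree within sampling noise
  set.seed(48)
  p_rep <- image_gen_params(true_flow_fraction = 0.55, tile_sd = 0.05,
                            texture_corr_len = 0)  # unseeded replicates
  diffs <- replicate(40, {
    s <- side_metrics(generate_flow_map(p_rep), "upper")
    s$thicker[["ccfa"]] - s$thinner[["ccfa"]]
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
  expect_error(side_metrics(fm, NA, subject = "eye007"), "eye007")
})

test_that("an injected side offset is recovered from the bands", {
  set.seed(53)
  p <- image_gen_params(true_flow_fraction = 0.555, tile_sd = 0.03,
                        texture_corr_len = 0)
  base <- tile_base_matrix(0.5465, thin_side = "lower",
                           thin_side_offset = -0.017)
  d <- replicate(40, {
    s <- side_metrics(generate_flow_map(p, base_fraction = base), "upper")
    s$thinner[["ccfa"]] - s$thicker[["ccfa"]]
  })
  expect_lt(abs(mean(d) - (-1.7)), 3 * sd(d) / sqrt(length(d)))
})

test_that("risk classification applies the printed boundary semantics", {
  expect_true(classify_risk(58.4, 0.165))
  expect_false(classify_risk(58.5, 0.30))   # ratio at the cutoff: excluded
  expect_false(classify_risk(40.0, 0.10))   # CV below cutoff: conjunction
  expect_true(classify_risk(58.49999, 0.165))
  expect_false(classify_risk(58.4, 0.16499))
  expect_equal(classify_risk(c(50, 60), c(0.2, 0.2)), c(TRUE, FALSE))
})

test_that("region-restricted tile CV uses the half-coverage rule", {
  set.seed(59)
  p <- matrix(rbinom(180 * 180, 1, 0.5), 180, 180)
  mask <- matrix(FALSE, 180, 180)
  mask[1:45, 1:60] <- TRUE   # covers tiles (1:4, 1:6) at >= 50% on row 4?
  # tile height 10: rows 41-45 cover half of tile row 5 -> included at 50%
  cv_reg <- region_tile_cv(p, mask, 18)
  g <- split_tiles(p)
  cover <- split_tiles(matrix(as.integer(mask), 180, 180))
  expect_equal(cv_reg, cv_of_ccfa(g$ratios[cover$ratios >= 50]))
})

test_that("quantify_slab assembles whole, region and side results", {
  p <- image_gen_params(seed = 61, texture_corr_len = 0,
                        flow_intensity_sd = 0.05, bg_intensity_sd = 0.05)
  fm <- generate_flow_map(p)
  sl <- render_grayscale(fm, p)
  mask <- faf_rectangle_mask(540, 540, random = FALSE)
  res <- quantify_slab(sl, masks = list(faf_abnormal = mask),
                       thicker_side = "upper")
  expect_s3_class(res, "ccfa_result")
  expect_true(all(c("faf_abnormal", "faf_normal") %in%
                    names(res$region_ratios)))
  w <- sum(mask) / length(mask)
  expect_equal(w * res$region_ratios$faf_abnormal +
                 (1 - w) * res$region_ratios$faf_normal,
               res$ccfa_ratio, tolerance = 1e-9)
  expect_named(res$sides, c("thicker", "thinner"))
  expect_identical(res$high_risk,
                   unname(classify_risk(res$ccfa_ratio, res$cv)))
})
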