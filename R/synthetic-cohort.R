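#' Parameters for synthetic cohort generation
#'
#' Group-wise covariate and metric distributions for a synthetic cohort of
#' AMD fellow eyes and controls.  Defaults are calibrated to the published
#' cohort this pipeline targets: 38 AMD fellow eyes (26 men, age
#' 71.7 +/- 1.9 SE years, 9 with FAF abnormality, 18 with asymmetric
#' choroidal vasculature) versus 22 controls (11 men, 69.4 +/- 1.8, 0 FAF
#' abnormal, 7 asymmetric); CCFA ratio 58.1 +/- 1.0 vs 62.9 +/- 1.4 %,
#' CV 0.182 +/- 0.007 vs 0.152 +/- 0.0061; FAF-abnormal-region offset
#' 47.7 - 52.8 = -5.1 percentage points; thinner-minus-thicker side offsets
#' -1.7 percentage points (CCFA) and +0.017 (CV); side RPE volumes
#' 0.020 / 0.022 um^3.  Printed +/- values are standard errors, so the
#' generator's per-subject SDs default to SE * sqrt(n).
#'
#' @param n_amd,n_control Eyes per group (>= 2 each).
#' @param age_mean_by_group,age_sd_by_group Named (`amd_fellow`, `control`)
#'   age distributions in years; ages are clamped to [40, 100].
#' @param male_prob_by_group Probability of male sex per group.
#' @param axial_length_mean,axial_length_sd Axial length (mm) distribution
#'   shared by both groups.
#' @param ccfa_mean_by_group,ccfa_sd_by_group CCFA ratio (%) per group.
#' @param cv_mean_by_group,cv_sd_by_group CV of the CCFA ratio per group.
#' @param age_slope_ccfa CCFA-vs-age slope in %/year (<= 0); applied around
#'   the group mean age so group means are preserved.
#' @param age_slope_cv CV-vs-age slope in 1/year (>= 0).
#' @param faf_prob_by_group Probability of FAF abnormality per group.
#' @param asym_prob_by_group Probability of asymmetric choroidal
#'   vasculature per group.
#' @param faf_region_ccfa_offset CCFA offset (percentage points, < 0) of
#'   the FAF-abnormal region relative to the FAF-normal remainder.
#' @param faf_coverage Fraction of the field covered by the FAF-abnormal
#'   rectangle (default 0.15).
#' @param thin_side_ccfa_offset Thinner-minus-thicker side CCFA difference
#'   (percentage points, < 0).
#' @param thin_side_cv_offset Thinner-minus-thicker side CV difference
#'   (> 0).
#' @param region_ccfa_noise_sd,region_cv_noise_sd Within-eye region/side
#'   measurement noise SDs for the tabulated metrics.
#' @param rpe_vol_mean_by_side Named (`thicker`, `thinner`) RPE volume
#'   means in um^3.
#' @param rpe_vol_sd RPE volume SD.
#' @param seed Optional integer seed.
#' @return An object of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(
    n_amd = 38L, n_control = 22L,
    age_mean_by_group = c(amd_fellow = 71.7, control = 69.4),
    age_sd_by_group = c(amd_fellow = 1.9 * sqrt(38), control = 1.8 * sqrt(22)),
    male_prob_by_group = c(amd_fellow = 26 / 38, control = 11 / 22),
    axial_length_mean = 24.10, axial_length_sd = 1.2,
    ccfa_mean_by_group = c(amd_fellow = 58.1, control = 62.9),
    ccfa_sd_by_group = c(amd_fellow = 1.0 * sqrt(38), control = 1.4 * sqrt(22)),
    cv_mean_by_group = c(amd_fellow = 0.182, control = 0.152),
    cv_sd_by_group = c(amd_fellow = 0.007 * sqrt(38), control = 0.0061 * sqrt(22)),
    age_slope_ccfa = -0.2, age_slope_cv = 0.002,
    faf_prob_by_group = c(amd_fellow = 9 / 38, control = 0),
    asym_prob_by_group = c(amd_fellow = 18 / 38, control = 7 / 22),
    faf_region_ccfa_offset = -5.1, faf_coverage = 0.15,
    thin_side_ccfa_offset = -1.7, thin_side_cv_offset = 0.017,
    region_ccfa_noise_sd = 1.5, region_cv_noise_sd = 0.012,
    rpe_vol_mean_by_side = c(thicker = 0.022, thinner = 0.020),
    rpe_vol_sd = 0.003,
    seed = NULL) {
  p <- as.list(environment())
  grp <- c("amd_fellow", "control")
  for (nm in c("age_mean_by_group", "age_sd_by_group", "male_prob_by_group",
               "ccfa_mean_by_group", "ccfa_sd_by_group", "cv_mean_by_group",
               "cv_sd_by_group", "faf_prob_by_group", "asym_prob_by_group")) {
    v <- p[[nm]]
    if (!all(grp %in% names(v)))
      stop(sprintf("%s must be named with groups {amd_fellow, control}", nm))
  }
  probs <- c(p$male_prob_by_group, p$faf_prob_by_group, p$asym_prob_by_group)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  sds <- c(p$age_sd_by_group, p$ccfa_sd_by_group, p$cv_sd_by_group,
           p$axial_length_sd, p$rpe_vol_sd,
           p$region_ccfa_noise_sd, p$region_cv_noise_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (p$n_amd < 2L || p$n_control < 2L)
    stop("need at least 2 subjects per group (downstream tests undefined)")
  if (p$age_slope_ccfa > 0) stop("age_slope_ccfa must be <= 0")
  if (p$age_slope_cv < 0) stop("age_slope_cv must be >= 0")
  if (p$faf_region_ccfa_offset >= 0) stop("faf_region_ccfa_offset must be < 0")
  if (p$thin_side_ccfa_offset >= 0) stop("thin_side_ccfa_offset must be < 0")
  if (p$thin_side_cv_offset <= 0) stop("thin_side_cv_offset must be > 0")
  if (!all(c("thicker", "thinner") %in% names(p$rpe_vol_mean_by_side)))
    stop("rpe_vol_mean_by_side must be named with {thicker, thinner}")
  p$n_amd <- as.integer(p$n_amd); p$n_control <- as.integer(p$n_control)
  class(p) <- "cohort_gen_params"
  p
}

#' Generate a synthetic subject cohort
#'
#' Draws per-subject covariates (age, sex, axial length), labels (FAF
#' abnormality, choroidal-vasculature asymmetry, thicker-side), latent
#' CCFA/CV metrics with the configured group differences and age trends,
#' within-eye region and side metrics, RPE volumes per side, and the
#' per-subject image-generation parameters needed to realize each eye as a
#' synthetic slab image.
#'
#' Latent metrics follow
#' `metric = group_mean + slope * (age - group_age_mean) + noise`, so the
#' group means are preserved for any slope.  FAF-positive subjects carry a
#' tile-aligned rectangular abnormal region with the configured CCFA
#' offset; asymmetric subjects get a thicker-side label (upper/lower with
#' equal probability) and symmetric +/- half offsets on the two bands.
#'
#' @param params A [cohort_gen_params()] object.
#' @param image_params An [image_gen_params()] template for per-subject
#'   image generation.
#' @return An object of class `ccfa_cohort`: list with `subjects` (one row
#'   per eye) and `image_params` (per-subject list: `params`,
#'   `base_fraction`, `faf_mask`, `thicker_side`).
#' @export
generate_cohort <- function(params = cohort_gen_params(),
                            image_params = image_gen_params()) {
  stopifnot(inherits(params, "cohort_gen_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  groups <- c(rep("amd_fellow", params$n_amd), rep("control", params$n_control))
  n <- length(groups)
  o <- image_params$tile_order
  subj <- data.frame(
    id = sprintf("eye%03d", seq_len(n)),
    group = groups,
    stringsAsFactors = FALSE)
  subj$age <- pmin(pmax(stats::rnorm(n, params$age_mean_by_group[groups],
                                     params$age_sd_by_group[groups]), 40), 100)
  subj$sex <- ifelse(stats::runif(n) < params$male_prob_by_group[groups],
                     "male", "female")
  subj$axial_length <- pmin(pmax(stats::rnorm(n, params$axial_length_mean,
                                              params$axial_length_sd), 21), 27)
  subj$faf_abnormal <- stats::runif(n) < params$faf_prob_by_group[groups]
  subj$asymmetric_vasculature <- stats::runif(n) < params$asym_prob_by_group[groups]
  subj$thicker_side <- ifelse(subj$asymmetric_vasculature,
                              ifelse(stats::runif(n) < 0.5, "upper", "lower"),
                              "none")

  age_c <- subj$age - params$age_mean_by_group[groups]
  subj$ccfa_ratio <- params$ccfa_mean_by_group[groups] +
    params$age_slope_ccfa * age_c +
    stats::rnorm(n, 0, params$ccfa_sd_by_group[groups])
  subj$ccfa_ratio <- pmin(pmax(subj$ccfa_ratio, 5), 95)
  subj$cv <- params$cv_mean_by_group[groups] +
    params$age_slope_cv * age_c +
    stats::rnorm(n, 0, params$cv_sd_by_group[groups])
  subj$cv <- pmin(pmax(subj$cv, 0.02), 0.8)

  # within-eye FAF region metrics: whole = cov*abnormal + (1-cov)*normal
  cov <- params$faf_coverage
  off <- params$faf_region_ccfa_offset
  nz <- function(sd) stats::rnorm(n, 0, sd)
  subj$ccfa_faf_normal <- ifelse(subj$faf_abnormal,
                                 subj$ccfa_ratio - cov * off +
                                   nz(params$region_ccfa_noise_sd), NA_real_)
  subj$ccfa_faf_abnormal <- ifelse(subj$faf_abnormal,
                                   subj$ccfa_faf_normal + off +
                                     nz(params$region_ccfa_noise_sd), NA_real_)

  asym <- subj$asymmetric_vasculature
  half <- params$thin_side_ccfa_offset / 2
  subj$ccfa_thinner <- ifelse(asym, subj$ccfa_ratio + half +
                                nz(params$region_ccfa_noise_sd), NA_real_)
  subj$ccfa_thicker <- ifelse(asym, subj$ccfa_ratio - half +
                                nz(params$region_ccfa_noise_sd), NA_real_)
  halfcv <- params$thin_side_cv_offset / 2
  subj$cv_thinner <- ifelse(asym, pmax(subj$cv + halfcv +
                                         nz(params$region_cv_noise_sd), 0.01),
                            NA_real_)
  subj$cv_thicker <- ifelse(asym, pmax(subj$cv - halfcv +
                                         nz(params$region_cv_noise_sd), 0.01),
                            NA_real_)
  subj$rpe_vol_thicker <- ifelse(asym,
                                 pmax(stats::rnorm(n, params$rpe_vol_mean_by_side[["thicker"]],
                                                   params$rpe_vol_sd), 0.001),
                                 NA_real_)
  subj$rpe_vol_thinner <- ifelse(asym,
                                 pmax(stats::rnorm(n, params$rpe_vol_mean_by_side[["thinner"]],
                                                   params$rpe_vol_sd), 0.001),
                                 NA_real_)
  rownames(subj) <- NULL

  img <- vector("list", n)
  base_seed <- params$seed %||% 0L
  for (i in seq_len(n)) {
    f <- min(max(subj$ccfa_ratio[i] / 100, 0.10), 0.90)
    tsd <- min(max(subj$cv[i] * f, 1e-4), 0.9 * sqrt(f * (1 - f)))
    ip <- image_params
    ip$true_flow_fraction <- f
    ip$tile_sd <- tsd
    ip$seed <- derive_seed(base_seed, i)
    faf_mask <- NULL
    region_tiles <- NULL
    if (subj$faf_abnormal[i]) {
      faf_mask <- faf_rectangle_mask(ip$width_px, ip$height_px,
                                     coverage = cov, tile_order = o)
      region_tiles <- attr(faf_mask, "tiles")
    }
    thin_side <- if (asym[i]) {
      if (subj$thicker_side[i] == "upper") "lower" else "upper"
    } else NULL
    base_fraction <- tile_base_matrix(
      f, tile_order = o,
      region_tiles = region_tiles, region_offset = off / 100,
      thin_side = thin_side,
      thin_side_offset = if (asym[i]) params$thin_side_ccfa_offset / 100 else 0)
    img[[i]] <- list(params = ip, base_fraction = base_fraction,
                     faf_mask = faf_mask, thicker_side = subj$thicker_side[i])
  }

  structure(list(subjects = subj, image_params = img, params = params),
            class = "ccfa_cohort")
}

#' @export
print.ccfa_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("ccfa_cohort: %d eyes (%s)\n", nrow(x$subjects),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
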