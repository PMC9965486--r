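#' Parameters for synthetic choriocapillaris slab generation
#'
#' Bundles the geometry, flow fraction, per-tile dispersion and intensity
#' model used by [generate_flow_map()] and [render_grayscale()].  The
#' defaults describe the analyzed field of a 3x3 mm OCTA scan after
#' magnification correction and cropping: a 540x540 px raster at
#' 0.005 mm/px (2.7x2.7 mm), divisible by the 18x18 tile grid of the
#' heterogeneity statistic.
#'
#' @param width_px,height_px Raster dimensions in pixels; both must be
#'   divisible by `tile_order`.
#' @param pixel_scale Physical pixel size in mm/px.
#' @param true_flow_fraction Ground-truth flow-signal fraction in (0,1);
#'   the whole-image CCFA ratio is 100 times this value.
#' @param tile_sd Standard deviation of the per-tile flow fraction around
#'   `true_flow_fraction` (fraction units, >= 0).  Tile fractions are drawn
#'   logit-normally; see [logit_normal_calibrate()].
#' @param texture_corr_len Gaussian smoothing length (px) of the random
#'   vascular texture; 0 disables smoothing.
#' @param flow_intensity_mean,flow_intensity_sd Grayscale intensity model
#'   of flow pixels, in [0,1].
#' @param bg_intensity_mean,bg_intensity_sd Intensity model of non-flow
#'   pixels; `flow_intensity_mean` must exceed `bg_intensity_mean`.
#' @param tile_order Tile-grid order (default 18, matching the 18x18 split
#'   used by the CV statistic).
#' @param seed Optional integer seed; when set, generation is fully
#'   reproducible and repeated calls are bit-identical.
#' @return An object of class `image_gen_params` (a validated list).
#' @seealso [generate_flow_map()], [render_grayscale()]
#' @export
image_gen_params <- function(width_px = 540L, height_px = 540L,
                             pixel_scale = 0.005,
                             true_flow_fraction = 0.581,
                             tile_sd = 0.02,
                             texture_corr_len = 2,
                             flow_intensity_mean = 0.75,
                             flow_intensity_sd = 0.08,
                             bg_intensity_mean = 0.35,
                             bg_intensity_sd = 0.08,
                             tile_order = 18L,
                             seed = NULL) {
  p <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
            pixel_scale = pixel_scale, true_flow_fraction = true_flow_fraction,
            tile_sd = tile_sd, texture_corr_len = texture_corr_len,
            flow_intensity_mean = flow_intensity_mean,
            flow_intensity_sd = flow_intensity_sd,
            bg_intensity_mean = bg_intensity_mean,
            bg_intensity_sd = bg_intensity_sd,
            tile_order = as.integer(tile_order), seed = seed)
  if (p$true_flow_fraction <= 0 || p$true_flow_fraction >= 1)
    stop("true_flow_fraction must lie strictly inside (0, 1)")
  if (p$tile_sd < 0) stop("tile_sd must be >= 0")
  if (p$pixel_scale <= 0) stop("pixel_scale must be positive")
  if (p$flow_intensity_mean <= p$bg_intensity_mean)
    stop("flow_intensity_mean must exceed bg_intensity_mean")
  if (p$tile_order < 2L) stop("tile_order must be >= 2")
  if (p$width_px %% p$tile_order != 0L || p$height_px %% p$tile_order != 0L)
    stop(sprintf("image dimensions must be divisible by the tile-grid order (%d)",
                 p$tile_order))
  class(p) <- "image_gen_params"
  p
}

.calib_cache <- new.env(parent = emptyenv())

.logitnorm_moment <- function(mu, sigma, pow = 1) {
  stats::integrate(function(z) stats::plogis(mu + sigma * z)^pow * stats::dnorm(z),
                   -8, 8, rel.tol = 1e-11)$value
}

#' Calibrate a logit-normal distribution to a target mean and SD
#'
#' Solves for `(mu, sigma)` such that `plogis(mu + sigma * Z)`, with
#' `Z ~ N(0,1)`, has exactly the requested mean and standard deviation
#' (to quadrature precision).  Tile-level flow fractions are drawn from
#' this distribution, so the generator's mean calibration is exact rather
#' than relying on the small-variance delta approximation, and the
#' coefficient of variation of the drawn fractions is exactly `sd/mean`.
#'
#' @param mean Target mean in (0,1).
#' @param sd Target standard deviation; must be achievable, i.e. smaller
#'   than `sqrt(mean * (1 - mean))`.
#' @return Named numeric vector `c(mu, sigma)` on the logit scale.
#' @examples
#' cal <- logit_normal_calibrate(0.581, 0.106)
#' x <- stats::plogis(cal["mu"] + cal["sigma"] * stats::rnorm(1e4))
#' c(mean(x), stats::sd(x))
#' @export
logit_normal_calibrate <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop("mean must lie in (0, 1)")
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) return(c(mu = stats::qlogis(mean), sigma = 0))
  if (sd >= 0.98 * sqrt(mean * (1 - mean)))
    stop("sd too large for a logit-normal with this mean")
  key <- sprintf("%.12g|%.12g", mean, sd)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  mu_for <- function(sigma)
    stats::uniroot(function(mu) .logitnorm_moment(mu, sigma) - mean,
                   c(-30, 30), tol = 1e-12)$root
  sd_gap <- function(sigma) {
    mu <- mu_for(sigma)
    sqrt(max(.logitnorm_moment(mu, sigma, 2) - mean^2, 0)) - sd
  }
  sigma <- stats::uniroot(sd_gap, c(1e-8, 40), tol = 1e-12)$root
  out <- c(mu = mu_for(sigma), sigma = sigma)
  .calib_cache[[key]] <- out
  out
}

#' Generate a ground-truth binary flow map
#'
#' Draws a per-tile target flow fraction around the base fraction (scalar
#' `true_flow_fraction` or a per-tile matrix), then thresholds a smoothed
#' Gaussian random field within each tile at the exact sample quantile so
#' that the realized foreground fraction equals the drawn target to within
#' one pixel's worth of area.  This is the ground-truth stand-in for a
#' binarized choriocapillaris slab: downstream CCFA/CV recovery can be
#' checked against known generating values.
#'
#' @param params An [image_gen_params()] object.
#' @param base_fraction Optional scalar or `tile_order x tile_order` matrix
#'   of base flow fractions overriding `params$true_flow_fraction`; used to
#'   inject region (FAF rectangle) and band (thicker/thinner side) effects.
#' @return An object of class `flow_map`: a list with `pixels` (binary
#'   integer matrix), `tile_targets` and `tile_realized` (per-tile
#'   fractions), `tile_order` and `pixel_scale`.
#' @export
generate_flow_map <- function(params, base_fraction = NULL) {
  stopifnot(inherits(params, "image_gen_params"))
  o <- params$tile_order
  w <- params$width_px; h <- params$height_px
  if (!is.null(params$seed)) set.seed(params$seed)
  base <- base_fraction %||% params$true_flow_fraction
  if (is.matrix(base)) {
    if (!all(dim(base) == c(o, o)))
      stop(sprintf("base_fraction matrix must be %d x %d", o, o))
  } else {
    base <- matrix(base, o, o)
  }
  if (any(base <= 0 | base >= 1))
    stop("base flow fractions must lie strictly inside (0, 1)")

  targets <- base
  if (params$tile_sd > 0) {
    z <- matrix(stats::rnorm(o * o), o, o)
    for (b in unique(as.vector(base))) {
      cal <- logit_normal_calibrate(b, params$tile_sd)
      idx <- base == b
      targets[idx] <- stats::plogis(cal[["mu"]] + cal[["sigma"]] * z[idx])
    }
  }

  field <- matrix(stats::rnorm(h * w), h, w)
  if (params$texture_corr_len > 0)
    field <- conv2_mirror(field, gaussian_kernel(params$texture_corr_len))

  th <- h %/% o; tw <- w %/% o; npx <- th * tw
  # reshape to one column per tile (row-major tile order within the grid)
  tiles <- matrix(aperm(array(field, c(th, o, tw, o)), c(1L, 3L, 2L, 4L)),
                  nrow = npx)
  k <- as.integer(round(as.vector(targets) * npx))
  bin <- matrix(0L, npx, o * o)
  for (j in seq_len(o * o)) {
    kk <- k[j]
    if (kk == 0L) next
    v <- tiles[, j]
    # threshold at the (npx-kk+1)-th order statistic; exact count via the
    # order permutation only in the (measure-zero) tied case
    thr <- sort.int(v, partial = npx - kk + 1L)[npx - kk + 1L]
    sel <- v >= thr
    if (sum(sel) != kk)
      sel <- seq_len(npx) %in% order(v, decreasing = TRUE)[seq_len(kk)]
    bin[sel, j] <- 1L
  }
  pix <- array(bin, c(th, tw, o, o))
  pix <- matrix(aperm(pix, c(1L, 3L, 2L, 4L)), h, w)
  realized <- matrix(k / npx, o, o)

  structure(list(pixels = pix, tile_targets = targets,
                 tile_realized = realized, tile_order = o,
                 pixel_scale = params$pixel_scale, params = params),
            class = "flow_map")
}

#' @export
print.flow_map <- function(x, ...) {
  cat(sprintf("flow_map: %d x %d px, flow fraction %.4f (tile grid %d x %d)\n",
              nrow(x$pixels), ncol(x$pixels), mean(x$pixels),
              x$tile_order, x$tile_order))
  invisible(x)
}

#' Render a grayscale slab image from a binary flow map
#'
#' Gives flow and background pixels intensities from two normal
#' distributions and clips to [0,1].  `texture_corr_len` sets the spatial
#' correlation length of the intensity noise (a unit-variance Gaussian
#' random field smoothed with that width, then scaled by each class's SD);
#' class mean levels are untouched, so spatially correlated speckle does
#' not erode the flow/background contrast that local thresholding relies
#' on.  With zero intensity SDs the output is two-valued and any threshold
#' strictly between the two values recovers the flow map exactly.  When
#' the class separability `(mean gap)/(pooled sd)` falls below
#' `min_separability` a warning is issued: local thresholding is not
#' guaranteed to recover the ground truth from such an image.
#'
#' @param flow_map A [generate_flow_map()] result.
#' @param params The [image_gen_params()] carrying the intensity model.
#'   When `params$seed` is set, rendering uses a secondary stream derived
#'   from it and repeated calls are bit-identical.
#' @param axial_length Axial length (mm) recorded in the output metadata,
#'   or `NA` when magnification correction is not intended.
#' @param min_separability Separability floor below which a warning is
#'   raised (default 2).
#' @return A [slab_image()] object.
#' @export
render_grayscale <- function(flow_map, params, axial_length = NA_real_,
                             min_separability = 2) {
  stopifnot(inherits(flow_map, "flow_map"), inherits(params, "image_gen_params"))
  pooled <- sqrt((params$flow_intensity_sd^2 + params$bg_intensity_sd^2) / 2)
  if (pooled > 0) {
    sep <- (params$flow_intensity_mean - params$bg_intensity_mean) / pooled
    if (sep < min_separability)
      warning(sprintf(paste0("intensity separability %.2f below floor %.2f; ",
                             "binarization recovery is not guaranteed"),
                      sep, min_separability))
  }
  if (!is.null(params$seed)) set.seed(derive_seed(params$seed, 1L))
  fg <- flow_map$pixels == 1L
  noise <- matrix(stats::rnorm(length(fg)), nrow(fg), ncol(fg))
  if (params$texture_corr_len > 0) {
    k <- gaussian_kernel(params$texture_corr_len)
    noise <- conv2_mirror(noise, k) / sqrt(sum(k^2))  # back to unit variance
  }
  img <- ifelse(fg, params$flow_intensity_mean +
                  params$flow_intensity_sd * noise,
                params$bg_intensity_mean + params$bg_intensity_sd * noise)
  img[img < 0] <- 0
  img[img > 1] <- 1
  slab_image(img, pixel_scale = params$pixel_scale, axial_length = axial_length)
}

#' Tile-aligned rectangular region mask
#'
#' Builds an axis-aligned rectangular mask snapped to the tile grid,
#' covering approximately `coverage` of the field.  Used as the synthetic
#' stand-in for a graded FAF-abnormal area; snapping to tile boundaries
#' makes region-level flow offsets exact under the tile-wise generator.
#'
#' @param width_px,height_px Raster dimensions.
#' @param coverage Target fraction of the field covered (default 0.15).
#' @param tile_order Tile-grid order (default 18).
#' @param random Logical; place the rectangle at a random tile offset
#'   (default) or at the grid center.
#' @return A logical matrix mask of the raster dimensions, with attribute
#'   `"tiles"` giving the covered tile index matrix (logical, order x order).
#' @export
faf_rectangle_mask <- function(width_px, height_px, coverage = 0.15,
                               tile_order = 18L, random = TRUE) {
  o <- as.integer(tile_order)
  if (width_px %% o != 0L || height_px %% o != 0L)
    stop(sprintf("image dimensions must be divisible by the tile-grid order (%d)", o))
  side <- max(1L, round(sqrt(coverage) * o))
  side <- min(side, o)
  if (random) {
    r0 <- sample.int(o - side + 1L, 1L) - 1L
    c0 <- sample.int(o - side + 1L, 1L) - 1L
  } else {
    r0 <- (o - side) %/% 2L
    c0 <- (o - side) %/% 2L
  }
  tiles <- matrix(FALSE, o, o)
  tiles[r0 + seq_len(side), c0 + seq_len(side)] <- TRUE
  th <- height_px %/% o; tw <- width_px %/% o
  mask <- matrix(FALSE, height_px, width_px)
  mask[r0 * th + seq_len(side * th), c0 * tw + seq_len(side * tw)] <- TRUE
  attr(mask, "tiles") <- tiles
  mask
}

#' Per-tile base-fraction matrix with region and side effects
#'
#' Starting from a uniform base fraction, applies an additive offset inside
#' a tile-aligned region (e.g. a FAF-abnormal rectangle) and/or symmetric
#' band offsets to the upper and lower thirds of the tile grid (the
#' thicker/thinner choroidal-vasculature sides; the middle third carries no
#' side effect).  Offsets are in fraction units.
#'
#' @param base Scalar base flow fraction.
#' @param tile_order Tile-grid order; must be divisible by 3 when side
#'   offsets are used.
#' @param region_tiles Optional logical tile matrix (as from
#'   [faf_rectangle_mask()]'s `"tiles"` attribute).
#' @param region_offset Additive fraction offset inside `region_tiles`.
#' @param thin_side `"upper"`, `"lower"` or `NULL`; which band is the
#'   thinner choroidal side.
#' @param thin_side_offset Total thinner-minus-thicker fraction difference
#'   (applied as +/- half to each band so the whole-image mean is
#'   preserved).
#' @return A `tile_order x tile_order` numeric matrix of base fractions.
#' @export
tile_base_matrix <- function(base, tile_order = 18L, region_tiles = NULL,
                             region_offset = 0, thin_side = NULL,
                             thin_side_offset = 0) {
  o <- as.integer(tile_order)
  m <- matrix(base, o, o)
  if (!is.null(thin_side) && thin_side_offset != 0) {
    if (o %% 3L != 0L) stop("tile_order must be divisible by 3 for side effects")
    band <- o %/% 3L
    upper <- seq_len(band); lower <- (2L * band + 1L):o
    if (thin_side == "upper") {
      m[upper, ] <- m[upper, ] + thin_side_offset / 2
      m[lower, ] <- m[lower, ] - thin_side_offset / 2
    } else if (thin_side == "lower") {
      m[lower, ] <- m[lower, ] + thin_side_offset / 2
      m[upper, ] <- m[upper, ] - thin_side_offset / 2
    } else stop("thin_side must be 'upper' or 'lower'")
  }
  if (!is.null(region_tiles) && region_offset != 0) {
    if (!all(dim(region_tiles) == c(o, o)))
      stop(sprintf("region_tiles must be %d x %d", o, o))
    m[region_tiles] <- m[region_tiles] + region_offset
  }
  if (any(m <= 0 | m >= 1))
    stop("offsets push tile fractions outside (0, 1)")
  m
}
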