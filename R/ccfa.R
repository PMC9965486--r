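#' Choriocapillaris flow area (CCFA) ratio
#'
#' The CCFA ratio is the flow-signal pixel area divided by the analyzed
#' area, in percent.  With a region mask, only pixels inside the mask are
#' analyzed.
#'
#' @param flow A `flow_map` or binary matrix.
#' @param mask Optional logical (or 0/1) matrix of the same geometry; the
#'   analyzed region.  `NULL` analyzes the whole image.
#' @return CCFA ratio in percent (0-100).
#' @export
ccfa_ratio <- function(flow, mask = NULL) {
  p <- as_flow_pixels(flow)
  if (is.null(mask)) return(100 * sum(p) / length(p))
  if (!all(dim(mask) == dim(p)))
    stop("mask geometry does not match the flow map")
  m <- mask > 0
  if (!any(m)) stop("empty region mask: CCFA ratio undefined")
  100 * sum(p[m]) / sum(m)
}

#' Split a flow map into an equal-area tile grid of CCFA ratios
#'
#' Splits the binarized image into an `order x order` grid of equal tiles
#' (324 tiles at the default order 18) and computes the CCFA ratio of each
#' tile.  The tile grid is the support of the heterogeneity statistic
#' [cv_of_ccfa()].
#'
#' @param flow A `flow_map` or binary matrix; both dimensions must be
#'   divisible by `order`.
#' @param order Tile-grid order (default 18).
#' @return An object of class `tile_grid`: list with `ratios`
#'   (`order x order` matrix, percent) and `order`.
#' @export
split_tiles <- function(flow, order = 18L) {
  p <- as_flow_pixels(flow)
  o <- as.integer(order)
  if (o < 2L) stop("tile-grid order must be >= 2")
  if (nrow(p) %% o != 0L || ncol(p) %% o != 0L)
    stop(sprintf("image dimensions must be divisible by the tile-grid order (%d)", o))
  th <- nrow(p) %/% o; tw <- ncol(p) %/% o
  tiles <- matrix(aperm(array(p, c(th, o, tw, o)), c(1L, 3L, 2L, 4L)),
                  nrow = th * tw)
  ratios <- matrix(100 * colSums(tiles) / (th * tw), o, o)
  structure(list(ratios = ratios, order = o, tile_px = c(th, tw)),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile_grid: %d x %d tiles of %d x %d px; mean ratio %.2f%%, CV %.4f\n",
              x$order, x$order, x$tile_px[1], x$tile_px[2],
              mean(x$ratios), stats::sd(x$ratios) / mean(x$ratios)))
  invisible(x)
}

#' Coefficient of variation of per-tile CCFA ratios
#'
#' The heterogeneity statistic of choriocapillaris flow: the sample
#' standard deviation (n-1 denominator) of the per-tile CCFA ratios
#' divided by their mean.  Higher values mean more heterogeneous flow
#' deficits.  The statistic is scale-free: multiplying all tile ratios by
#' a positive constant leaves it unchanged.
#'
#' @param grid A [split_tiles()] result (or numeric matrix/vector of tile
#'   ratios).
#' @return Unitless CV (>= 0).
#' @export
cv_of_ccfa <- function(grid) {
  r <- if (inherits(grid, "tile_grid")) grid$ratios else grid
  r <- as.numeric(r)
  m <- mean(r)
  if (m <= 0) stop("tile-ratio mean is zero: CV undefined")
  stats::sd(r) / m
}

#' Split a flow map into upper, middle and lower thirds
#'
#' @param flow A `flow_map` or binary matrix whose height is divisible
#'   by 3.
#' @return Named list of logical masks `upper`, `middle`, `lower` (equal
#'   horizontal bands; row 1 is the top of the image).
#' @export
region_thirds <- function(flow) {
  p <- as_flow_pixels(flow)
  h <- nrow(p)
  if (h %% 3L != 0L) stop("image height must be divisible by 3")
  b <- h %/% 3L
  mk <- function(rows) {
    m <- matrix(FALSE, h, ncol(p)); m[rows, ] <- TRUE; m
  }
  list(upper = mk(seq_len(b)),
       middle = mk(b + seq_len(b)),
       lower = mk(2L * b + seq_len(b)))
}

#' Per-side CCFA ratio and CV for asymmetric choroidal vasculature
#'
#' Maps the upper and lower thirds of the image to the thicker and thinner
#' choroidal-vasculature sides according to the grading label, and computes
#' each side's CCFA ratio and CV.  Side CVs are computed over the band's
#' own tile subgrid (`order/3 x order` tiles, i.e. 6 x 18 at the default
#' order); the middle band carries no side assignment and is excluded.
#'
#' @param flow A `flow_map` or binary matrix.
#' @param thicker_side `"upper"` or `"lower"`: the side graded as having
#'   the thicker choroidal vasculature.
#' @param order Tile-grid order (default 18; must be divisible by 3).
#' @param subject Optional subject identifier used in error messages.
#' @return List with elements `thicker` and `thinner`, each
#'   `c(ccfa = , cv = )`.
#' @export
side_metrics <- function(flow, thicker_side, order = 18L, subject = NULL) {
  if (is.null(thicker_side) || is.na(thicker_side) ||
      !thicker_side %in% c("upper", "lower"))
    stop(sprintf("missing or invalid thicker-side label%s",
                 if (is.null(subject)) "" else paste0(" for subject ", subject)))
  p <- as_flow_pixels(flow)
  o <- as.integer(order)
  if (o %% 3L != 0L) stop("tile-grid order must be divisible by 3")
  grid <- split_tiles(p, o)
  thirds <- region_thirds(p)
  band <- o %/% 3L
  band_stats <- function(which) {
    rows <- if (which == "upper") seq_len(band) else (2L * band + 1L):o
    tiles <- grid$ratios[rows, , drop = FALSE]
    c(ccfa = ccfa_ratio(p, thirds[[which]]), cv = cv_of_ccfa(tiles))
  }
  up <- band_stats("upper"); lo <- band_stats("lower")
  if (thicker_side == "upper") list(thicker = up, thinner = lo)
  else list(thicker = lo, thinner = up)
}

#' Dual-cutoff high-risk classification
#'
#' An eye is classified high risk for being an AMD fellow eye when its
#' CCFA ratio is strictly below the ratio cutoff AND its CV of the CCFA
#' ratio is at or above the CV cutoff (boundary semantics exactly as the
#' clinical rule `< 58.5\%` and `>= 0.165`).
#'
#' @param ccfa_ratio CCFA ratio(s) in percent.
#' @param cv CV value(s); recycled against `ccfa_ratio`.
#' @param cutoffs Named numeric `c(ccfa = 58.5, cv = 0.165)`.
#' @return Logical vector: `TRUE` = high risk.
#' @export
classify_risk <- function(ccfa_ratio, cv, cutoffs = c(ccfa = 58.5, cv = 0.165)) {
  ccfa_ratio < cutoffs[["ccfa"]] & cv >= cutoffs[["cv"]]
}

#' CV of tile ratios restricted to a region
#'
#' Tiles straddling the mask boundary count toward the region only when at
#' least half the tile's pixels lie inside the region.
#'
#' @param flow A `flow_map` or binary matrix.
#' @param mask Logical region mask, same geometry.
#' @param order Tile-grid order.
#' @return Unitless CV over the region's tiles.
#' @export
region_tile_cv <- function(flow, mask, order = 18L) {
  p <- as_flow_pixels(flow)
  if (!all(dim(mask) == dim(p))) stop("mask geometry does not match the flow map")
  grid <- split_tiles(p, order)
  cover <- split_tiles(matrix(as.integer(mask > 0), nrow(p), ncol(p)), order)
  sel <- cover$ratios >= 50
  if (sum(sel) < 2L) stop("fewer than two tiles lie (>=50%) inside the region")
  cv_of_ccfa(grid$ratios[sel])
}

#' Quantify one slab image end-to-end
#'
#' Binarizes a (preprocessed) slab image with the Phansalkar rule and
#' computes the whole-area CCFA ratio, the tile grid, the CV of the CCFA
#' ratio, optional region-masked ratios (e.g. a FAF-abnormal mask, with the
#' complementary FAF-normal region), optional thicker/thinner side metrics,
#' and the dual-cutoff risk flag.
#'
#' @param image A [slab_image()].
#' @param phansalkar A [phansalkar_params()] object.
#' @param tile_order Tile-grid order (default 18).
#' @param masks Named list of logical region masks (name `faf_abnormal`
#'   additionally produces the complementary `faf_normal` region).
#' @param thicker_side `"upper"`, `"lower"` or `NULL`.
#' @param cutoffs Risk cutoffs, see [classify_risk()].
#' @return An object of class `ccfa_result`.
#' @export
quantify_slab <- function(image, phansalkar = phansalkar_params(),
                          tile_order = 18L, masks = list(),
                          thicker_side = NULL,
                          cutoffs = c(ccfa = 58.5, cv = 0.165)) {
  stopifnot(inherits(image, "slab_image"))
  flow <- phansalkar_threshold(image, phansalkar)
  grid <- split_tiles(flow, tile_order)
  whole <- ccfa_ratio(flow)
  cv <- cv_of_ccfa(grid)
  region_ratios <- list()
  for (nm in names(masks)) {
    region_ratios[[nm]] <- ccfa_ratio(flow, masks[[nm]])
    if (nm == "faf_abnormal")
      region_ratios[["faf_normal"]] <- ccfa_ratio(flow, !(masks[[nm]] > 0))
  }
  sides <- if (!is.null(thicker_side) && !is.na(thicker_side) &&
               thicker_side %in% c("upper", "lower"))
    side_metrics(flow, thicker_side, tile_order) else NULL
  structure(list(ccfa_ratio = whole, cv = cv, tile_grid = grid,
                 region_ratios = region_ratios, sides = sides,
                 high_risk = unname(classify_risk(whole, cv, cutoffs)),
                 provenance = list(phansalkar = unclass(phansalkar),
                                   tile_order = as.integer(tile_order),
                                   cutoffs = as.list(cutoffs),
                                   pixel_scale = image$pixel_scale,
                                   field_mm = image$field_mm,
                                   axial_length = image$axial_length)),
            class = "ccfa_result")
}

#' @export
print.ccfa_result <- function(x, ...) {
  cat(sprintf("ccfa_result: CCFA ratio %.2f%%, CV %.4f (%s risk)\n",
              x$ccfa_ratio, x$cv, if (x$high_risk) "HIGH" else "low"))
  if (length(x$region_ratios))
    cat("  regions:",
        paste(sprintf("%s=%.2f%%", names(x$region_ratios),
                      unlist(x$region_ratios)), collapse = ", "), "\n")
  if (!is.null(x$sides))
    cat(sprintf("  thicker side: %.2f%% (CV %.4f); thinner side: %.2f%% (CV %.4f)\n",
                x$sides$thicker[["ccfa"]], x$sides$thicker[["cv"]],
                x$sides$thinner[["ccfa"]], x$sides$thinner[["cv"]]))
  invisible(x)
}

#' Plot the tile grid of a quantified slab
#'
#' Displays the per-tile CCFA ratios as an image (top row of tiles at the
#' top of the plot).
#'
#' @param x A `ccfa_result`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.ccfa_result <- function(x, ...) {
  r <- x$tile_grid$ratios
  graphics::image(t(r)[, rev(seq_len(nrow(r))), drop = FALSE],
                  axes = FALSE, useRaster = TRUE,
                  main = sprintf("CCFA %.1f%%, CV %.3f", x$ccfa_ratio, x$cv),
                  ...)
  invisible(x)
}
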