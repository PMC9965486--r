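#' En-face choriocapillaris slab image
#'
#' Container for a square en-face slab raster with its physical scale and
#' the eye's axial length.  Pixel values must be normalized to [0,1]
#' (images read from 8-/16-bit files are divided by the bit-depth maximum,
#' not by the observed maximum).
#'
#' @param pixels Numeric matrix of intensities in [0,1]; must be square.
#' @param pixel_scale Physical pixel size in mm/px (post-correction when
#'   [correct_magnification()] has been applied).
#' @param axial_length Axial length in mm (15-40), or `NA` when unknown.
#' @param field_mm Physical field width in mm; defaults to
#'   `ncol(pixels) * pixel_scale`.
#' @return An object of class `slab_image`.
#' @export
slab_image <- function(pixels, pixel_scale, axial_length = NA_real_,
                       field_mm = ncol(pixels) * pixel_scale) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) != ncol(pixels))
    stop("slab images must be square")
  if (min(pixels) < -1e-12 || max(pixels) > 1 + 1e-12)
    stop("pixel values must be normalized to [0,1]; divide by the bit-depth maximum")
  if (pixel_scale <= 0) stop("pixel_scale must be positive")
  if (!is.na(axial_length) && (axial_length < 15 || axial_length > 40))
    stop("axial_length outside physiologic bounds (15-40 mm)")
  structure(list(pixels = pixels, pixel_scale = pixel_scale,
                 axial_length = axial_length, field_mm = field_mm),
            class = "slab_image")
}

#' @export
print.slab_image <- function(x, ...) {
  cat(sprintf("slab_image: %d x %d px, %.3f mm field (%.4g mm/px), axial length %s mm\n",
              nrow(x$pixels), ncol(x$pixels), x$field_mm, x$pixel_scale,
              ifelse(is.na(x$axial_length), "NA",
                     sprintf("%.2f", x$axial_length))))
  invisible(x)
}

#' Ocular magnification factor from axial length
#'
#' Ratio form of the modified Bennett ocular magnification term
#' `q = 0.01306 * (AL - 1.82)` used in Littmann's method: the device
#' constant 0.01306 cancels, leaving
#' `(axial_length - 1.82) / (reference_axial_length - 1.82)`.
#' The true pixel scale of an image acquired at a nominal scale is the
#' nominal scale multiplied by this factor.
#'
#' @param axial_length Axial length of the imaged eye in mm.
#' @param reference_axial_length Axial length of the device's reference eye
#'   in mm (default 24.46, a common device assumption; the reference eye is
#'   configurable because devices differ).
#' @return Unitless scale factor (1 when `axial_length` equals the
#'   reference).
#' @examples
#' magnification_factor(26.28, 24.46) # 1.0804
#' @export
magnification_factor <- function(axial_length, reference_axial_length = 24.46) {
  for (al in c(axial_length, reference_axial_length)) {
    if (al <= 1.82)
      stop("axial length <= 1.82 mm: modified Bennett formula undefined")
    if (al < 15 || al > 40)
      stop("axial length outside physiologic bounds (15-40 mm)")
  }
  (axial_length - 1.82) / (reference_axial_length - 1.82)
}

#' Apply magnification correction to a slab image
#'
#' Rescales the image's pixel scale (and hence its physical field) by the
#' axial-length magnification factor.  The raster itself is not resampled:
#' correction is pure metadata rescaling, so binarization later operates on
#' unaltered intensities, and the corrected field is then cropped in
#' physical units by [crop_to_field()].
#'
#' @param image A [slab_image()] with a non-`NA` axial length.
#' @param reference_axial_length Reference axial length in mm.
#' @return The corrected `slab_image`.
#' @export
correct_magnification <- function(image, reference_axial_length = 24.46) {
  stopifnot(inherits(image, "slab_image"))
  if (is.na(image$axial_length))
    stop("axial_length missing: cannot correct magnification")
  f <- magnification_factor(image$axial_length, reference_axial_length)
  image$pixel_scale <- image$pixel_scale * f
  image$field_mm <- ncol(image$pixels) * image$pixel_scale
  image
}

#' Center-crop a slab image to the analyzed field
#'
#' Crops the (corrected) slab to a centered square of the target physical
#' size.  The target width in pixels is rounded to the nearest even integer
#' when fractional (symmetric centering), then trimmed by at most
#' `tile_order - 1` px so the output dimensions are evenly divisible by the
#' tile-grid order.  Pixel scale is unchanged.  Cropping is idempotent: a
#' second crop to the same target returns the raster unchanged.
#'
#' @param image A [slab_image()].
#' @param target_field_mm Target physical width in mm (default 2.7, the
#'   analyzed field of a corrected 3x3 mm scan).
#' @param tile_order Tile-grid order the output must be divisible by
#'   (default 18).
#' @return The cropped `slab_image`.
#' @export
crop_to_field <- function(image, target_field_mm = 2.7, tile_order = 18L) {
  stopifnot(inherits(image, "slab_image"))
  o <- as.integer(tile_order)
  n <- nrow(image$pixels)
  # a previous crop to this target may sit up to one tile-order of pixels
  # below the nominal target (rounding + divisibility trim); only a larger
  # deficit violates the precondition
  if (image$field_mm < target_field_mm - o * image$pixel_scale - 1e-9) {
    stop(sprintf("corrected field %.3f mm is smaller than target %.3f mm (shortfall %.3f mm)",
                 image$field_mm, target_field_mm,
                 target_field_mm - image$field_mm))
  }
  raw <- target_field_mm / image$pixel_scale
  px <- if (abs(raw - round(raw)) < 1e-9) as.integer(round(raw))
        else 2L * as.integer(round(raw / 2))
  px <- px - px %% o
  if (px < o) stop("target field too small for one tile")
  if (px >= n) return(image)  # already at (or within one trim of) the target
  r0 <- (n - px) %/% 2L
  image$pixels <- image$pixels[r0 + seq_len(px), r0 + seq_len(px), drop = FALSE]
  image$field_mm <- px * image$pixel_scale
  image
}
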