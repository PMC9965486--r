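#' Phansalkar local-threshold parameters
#'
#' Parameters of the Phansalkar local adaptive threshold
#' `T = m * (1 + p_amp * exp(-q_decay * m) + k * ((s / r) - 1))`
#' where `m` and `s` are the local mean and (population) standard deviation
#' over a circular window.  Defaults follow the original method and the
#' common ImageJ implementation: `radius_px = 15`, `k = 0.25`, `r = 0.5`,
#' `p_amp = 2`, `q_decay = 10`.
#'
#' @param radius_px Window radius in pixels (>= 1).
#' @param k Weight of the normalized local SD term.
#' @param r SD normalization constant (grayscale units in [0,1], > 0).
#' @param p_amp Amplitude of the exponential low-mean boost.
#' @param q_decay Decay rate of the exponential term.
#' @return An object of class `phansalkar_params`.
#' @export
phansalkar_params <- function(radius_px = 15L, k = 0.25, r = 0.5,
                              p_amp = 2.0, q_decay = 10.0) {
  if (radius_px < 1) stop("radius_px must be >= 1")
  if (r <= 0) stop("r must be > 0")
  structure(list(radius_px = as.integer(radius_px), k = k, r = r,
                 p_amp = p_amp, q_decay = q_decay),
            class = "phansalkar_params")
}

#' Windowed local mean and standard deviation
#'
#' Computes the mean and population-normalized (denominator n) standard
#' deviation of intensities over a circular window of the given radius at
#' every pixel.  Image borders are handled by mirror reflection (the edge
#' pixel is repeated, then the image reflected).
#'
#' @param image A [slab_image()] or numeric matrix.
#' @param radius_px Window radius in pixels.
#' @return List with matrices `mean` and `sd`, same shape as the image.
#' @export
local_stats <- function(image, radius_px) {
  x <- if (inherits(image, "slab_image")) image$pixels else image
  if (!is.matrix(x)) stop("image must be a slab_image or a matrix")
  if (radius_px < 1) stop("radius_px must be >= 1")
  if (radius_px > min(dim(x)) %/% 2L)
    stop("radius_px larger than half the image extent")
  kern <- disc_kernel(radius_px)
  n <- sum(kern)
  m <- conv2_mirror(x, kern) / n
  ex2 <- conv2_mirror(x * x, kern) / n
  s <- sqrt(pmax(ex2 - m * m, 0))
  list(mean = m, sd = s)
}

#' Phansalkar local adaptive binarization
#'
#' Binarizes a normalized slab image into a flow / non-flow map.  At each
#' pixel the threshold is
#' `T = m * (1 + p_amp * exp(-q_decay * m) + k * ((s / r) - 1))`
#' with `m`, `s` the local mean and SD over a circular window (mirror
#' boundary).  A pixel is flow iff its intensity strictly exceeds `T`
#' (ties are background, so an all-zero image maps to zero flow).  The
#' Phansalkar rule adapts to variable illumination and contrast, which is
#' why it is preferred over a global threshold for OCTA slabs.
#'
#' @param image A [slab_image()] or numeric matrix with values in [0,1].
#' @param params A [phansalkar_params()] object.
#' @return A `flow_map` object (binary `pixels`, parameter echo in
#'   `$params`).
#' @examples
#' img <- matrix(0.5, 64, 64)
#' fm <- phansalkar_threshold(img, phansalkar_params())
#' mean(fm$pixels)  # 1: constant 0.5 exceeds its own threshold 0.38174
#' @export
phansalkar_threshold <- function(image, params = phansalkar_params()) {
  stopifnot(inherits(params, "phansalkar_params"))
  x <- if (inherits(image, "slab_image")) image$pixels else image
  if (!is.matrix(x)) stop("image must be a slab_image or a matrix")
  if (max(x) > 1 + 1e-12 || min(x) < -1e-12)
    stop("image not normalized to [0,1]; divide by the bit-depth maximum first")
  ls <- local_stats(x, params$radius_px)
  thr <- ls$mean * (1 + params$p_amp * exp(-params$q_decay * ls$mean) +
                      params$k * (ls$sd / params$r - 1))
  pix <- matrix(as.integer(x > thr), nrow(x), ncol(x))
  structure(list(pixels = pix,
                 tile_order = NA_integer_,
                 pixel_scale = if (inherits(image, "slab_image"))
                   image$pixel_scale else NA_real_,
                 params = params),
            class = "flow_map")
}
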