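#' Construct a MaskedROI
#'
#' @param image Numeric 3D array of voxel intensities.
#' @param mask Logical 3D array (the GTV), same dimensions as \code{image};
#'   anything coercible to logical is accepted.
#' @param voxelSize Numeric length-3 voxel size in mm; the native grid of
#'   the setup sequence is 1.5 x 1.5 x 3.0 mm.
#' @return A [MaskedROI-class].
#' @export
maskedROI <- function(image, mask, voxelSize = c(1.5, 1.5, 3.0)) {
  image <- array(as.numeric(image), dim = dim(image))
  mask <- array(as.logical(mask), dim = dim(mask))
  methods::new("MaskedROI", image = image, mask = mask,
               voxelSize = as.numeric(voxelSize))
}

#' Limit the ROI dynamic range to mean +/- k standard deviations
#'
#' Intensity normalization before quantization: the in-mask mean \eqn{\mu}
#' and sample standard deviation \eqn{\sigma} are computed, and in-mask
#' intensities are clipped to \eqn{[\mu - k\sigma, \mu + k\sigma]}
#' (default \eqn{k = 3}). Voxels are clipped, never excluded, so the ROI
#' geometry seen by the texture matrices is unchanged. A constant ROI
#' (\eqn{\sigma = 0}) is returned unchanged with a warning.
#'
#' @param roi A [MaskedROI-class] with at least 2 in-mask voxels.
#' @param kSigma Clipping width in standard deviations, default 3.
#' @return A [MaskedROI-class] with clipped in-mask intensities.
#' @export
limitDynamicRange <- function(roi, kSigma = 3) {
  stopifnot(methods::is(roi, "MaskedROI"))
  v <- roi@image[roi@mask]
  if (length(v) < 2L) stop("need at least 2 in-mask voxels")
  mu <- mean(v)
  sd_ <- stats::sd(v)            # sample (n - 1) standard deviation
  if (sd_ == 0) {
    warning("constant ROI: dynamic-range limiting is a no-op")
    return(roi)
  }
  lo <- mu - kSigma * sd_
  hi <- mu + kSigma * sd_
  img <- roi@image
  img[roi@mask] <- pmin(pmax(v, lo), hi)
  methods::initialize(roi, image = img)
}

#' Quantize a masked ROI to G gray levels by histogram equalization
#'
#' Each in-mask voxel with intensity \eqn{x} is mapped to
#' \eqn{\lceil G \hat F(x) \rceil} clamped to \eqn{[1, G]}, where
#' \eqn{\hat F} is the empirical CDF of the in-mask intensities. The map is
#' monotone in intensity and distributes voxels as evenly across levels as
#' ties permit; tied intensities share the level of their common CDF value.
#'
#' @param roi A [MaskedROI-class].
#' @param nLevels Number of gray levels G, default 64.
#' @return A [QuantizedROI-class]; out-of-mask voxels are \code{NA}.
#' @export
quantizeHistEq <- function(roi, nLevels = 64) {
  stopifnot(methods::is(roi, "MaskedROI"))
  nLevels <- as.integer(nLevels)
  if (nLevels < 2L) stop("nLevels must be >= 2")
  v <- roi@image[roi@mask]
  # empirical CDF with ties sharing their common value: F(x) = #{y <= x}/n
  Fhat <- rank(v, ties.method = "max") / length(v)
  lev <- as.integer(pmin(pmax(ceiling(nLevels * Fhat), 1L), nLevels))
  levels <- array(NA_integer_, dim = dim(roi@image))
  levels[roi@mask] <- lev
  methods::new("QuantizedROI", levels = levels, nLevels = nLevels,
               voxelSize = roi@voxelSize)
}

#' Build a QuantizedROI directly from an integer level array
#'
#' Mostly for tests and synthetic examples where the gray levels are
#' constructed rather than measured.
#'
#' @param levels Integer 3D array, \code{NA} outside the mask.
#' @param nLevels Number of gray levels G; defaults to \code{max(levels)}.
#' @param voxelSize Numeric length-3 voxel size in mm.
#' @return A [QuantizedROI-class].
#' @export
quantizedROI <- function(levels, nLevels = max(levels, na.rm = TRUE),
                         voxelSize = c(1.5, 1.5, 3.0)) {
  levels <- array(as.integer(levels), dim = dim(levels))
  methods::new("QuantizedROI", levels = levels,
               nLevels = as.integer(max(2L, nLevels)),
               voxelSize = as.numeric(voxelSize))
}
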