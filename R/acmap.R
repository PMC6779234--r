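#' Bilinear HU to attenuation-coefficient parameters
#'
#' Parameters of the bilinear conversion from CT numbers to linear
#' attenuation coefficients at 511 keV: water attenuation `mu_water`
#' (cm^-1), the HU `breakpoint` separating the soft-tissue and bone
#' branches, and the `bone_slope` (cm^-1 per HU) above the breakpoint.
#' Defaults are the conventional values for ~120 kVp CT.
#'
#' @param mu_water water attenuation at 511 keV (cm^-1).
#' @param breakpoint_hu branch point (HU).
#' @param bone_slope slope above the breakpoint (cm^-1 / HU).
#' @return a `bilinear_params` object.
#' @export
bilinear_params <- function(mu_water = 0.096, breakpoint_hu = 0,
                            bone_slope = 5.1e-5) {
  if (mu_water <= 0) stop("mu_water must be positive")
  if (bone_slope <= 0) stop("bone_slope must be positive")
  structure(list(mu_water = mu_water, breakpoint_hu = breakpoint_hu,
                 bone_slope = bone_slope), class = "bilinear_params")
}

#' Convert Hounsfield units to 511 keV attenuation coefficients
#'
#' Below the breakpoint `mu = mu_water * (HU + 1000) / 1000` (clipped at
#' zero); above it the bone branch continues with slope `bone_slope`. The
#' transform is continuous and monotone non-decreasing.
#'
#' @param hu a `zteac_volume` in HU.
#' @param params a [bilinear_params()].
#' @param provenance method tag recorded on the result (`"ct"`, `"zte"`,
#'   `"unet"`, ...).
#' @return an `ac_map`: list with `mu` (`zteac_volume`, cm^-1),
#'   `provenance` and `smoothing_fwhm_mm` (0 until smoothed).
#' @export
hu_to_mu <- function(hu, params = bilinear_params(), provenance = "ct") {
  stopifnot_volume(hu)
  x <- hu$data
  if (any(!is.finite(x))) stop("HU volume contains non-finite values")
  p <- params
  mu <- ifelse(x <= p$breakpoint_hu,
               pmax(p$mu_water * (x + 1000) / 1000, 0),
               p$mu_water * (p$breakpoint_hu + 1000) / 1000 +
                 p$bone_slope * (x - p$breakpoint_hu))
  dim(mu) <- dim(x)
  structure(list(mu = volume(mu, hu$spacing, "mu"), provenance = provenance,
                 smoothing_fwhm_mm = 0), class = "ac_map")
}

#' @export
print.ac_map <- function(x, ...) {
  cat(sprintf("<ac_map> provenance '%s', smoothing FWHM %.1f mm\n",
              x$provenance, x$smoothing_fwhm_mm))
  print(x$mu)
  invisible(x)
}

#' Smooth an attenuation map with a Gaussian kernel
#'
#' Separable per-axis Gaussian with `sigma_vox = fwhm / (2 sqrt(2 ln 2)) /
#' spacing` and reflective boundaries (totals preserved up to boundary
#' effects). `fwhm_mm = 0` is the identity.
#'
#' @param ac an `ac_map`.
#' @param fwhm_mm full width at half maximum in mm (default 10, the
#'   smoothing applied to AC maps before reconstruction).
#' @return the smoothed `ac_map`.
#' @export
smooth_ac <- function(ac, fwhm_mm = 10) {
  if (!inherits(ac, "ac_map")) stop("ac must be an ac_map")
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(ac)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / ac$mu$spacing
  sm <- .gauss3d(ac$mu$data, dim(ac$mu$data), sigma_vox)
  ac$mu <- volume(pmax(array(sm, dim(ac$mu$data)), 0), ac$mu$spacing, "mu")
  ac$smoothing_fwhm_mm <- fwhm_mm
  ac
}

#' Bone mask of a CT-like volume
#'
#' Bone is every voxel at or above `threshold` HU (closed comparison: a
#' voxel at exactly 200 HU is bone).
#'
#' @param hu a `zteac_volume` in HU.
#' @param threshold HU threshold (default 200).
#' @return logical array of the same shape.
#' @export
bone_mask <- function(hu, threshold = 200) {
  stopifnot_volume(hu)
  array(hu$data >= threshold, dim(hu$data))
}
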