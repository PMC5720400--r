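#' Parametric scatter model
#'
#' Scatter at the detector is modelled as a smooth, low-frequency field
#' driven by the fluence that actually traverses the object: a normalized
#' 2D Gaussian blur of the (masked) primary plus a flat pedestal, scaled so
#' that the scatter-to-primary ratio of the unmasked anterior-posterior view
#' hits `spr` at the detector centre.  This emulates the regime the slit
#' method targets - an object far enough from the detector that scatter is
#' nearly flat across it.
#'
#' @param spr Target scatter-to-primary ratio at the centre of the unmasked
#'   AP view (dimensionless, >= 0).
#' @param kernel_sigma Gaussian kernel width at the detector plane (mm).
#' @param pedestal_fraction Portion of the scatter modelled as a flat offset
#'   proportional to the mean traversing fluence, in `[0, 1]`.
#' @return An object of class `scatter_params`.
#' @export
scatter_params <- function(spr = 0.5, kernel_sigma = 30, pedestal_fraction = 0.3) {
  if (!(spr >= 0)) stop("spr must be >= 0")
  if (!(kernel_sigma > 0)) stop("kernel_sigma must be > 0")
  if (pedestal_fraction < 0 || pedestal_fraction > 1)
    stop("pedestal_fraction must be in [0, 1]")
  structure(list(spr = spr, kernel_sigma = kernel_sigma,
                 pedestal_fraction = pedestal_fraction),
            class = "scatter_params")
}

# Row-stochastic 1D Gaussian blur operator on pixel centres `x` (mm).
# Truncating the kernel at the detector edge and renormalizing each row
# keeps the operator mean-preserving for a constant field.
blur_operator_1d <- function(x, sigma) {
  k <- exp(-outer(x, x, "-")^2 / (2 * sigma^2))
  k / rowSums(k)
}

# Separable renormalized-truncation Gaussian blur of a detector image.
detector_blur <- function(img, geometry, sigma) {
  cc <- detector_coords(geometry)
  bu <- blur_operator_1d(cc$u, sigma)
  bv <- blur_operator_1d(cc$v, sigma)
  bu %*% img %*% t(bv)
}

# Unscaled scatter field: blur + pedestal mixture of a primary plane.
scatter_unit <- function(primary, geometry, params) {
  (1 - params$pedestal_fraction) * detector_blur(primary, geometry, params$kernel_sigma) +
    params$pedestal_fraction * mean(primary)
}

#' Simulate the scatter plane for one projection
#'
#' `scatter = scale * ((1 - pedestal) * G_sigma * primary +
#' pedestal * mean(primary))`, with `G_sigma` a normalized 2D Gaussian at the
#' detector plane (renormalized truncation at the edges).  During a
#' collimated acquisition the *masked* primary is supplied, so slit
#' collimation physically reduces the generated scatter.
#'
#' @param primary `n_u` x `n_v` primary-intensity matrix (or a
#'   [project_primary()] result).
#' @param geometry A [cone_beam_geometry()].
#' @param params A [scatter_params()].
#' @param scale Calibration factor from [calibrate_scatter_scale()].
#' @return `n_u` x `n_v` scatter-intensity matrix.
#' @export
simulate_scatter <- function(primary, geometry, params, scale) {
  if (inherits(primary, "projection")) primary <- primary$primary
  stopifnot(all(is.finite(primary)))
  if (scale == 0 || params$spr == 0) return(array(0, dim(primary)))
  scale * scatter_unit(primary, geometry, params)
}

#' Calibrate the scatter scale to the target SPR
#'
#' Finds the factor such that, on the unmasked angle-0 (anterior-posterior)
#' view, `mean(scatter) / mean(primary)` over the central 16 x 16 pixel
#' patch equals `params$spr`.
#'
#' @param phantom A [phantom()].
#' @param geometry A [cone_beam_geometry()].
#' @param params A [scatter_params()].
#' @param i0 Incident fluence per pixel.
#' @return The scale factor (0 when `spr = 0`).
#' @export
calibrate_scatter_scale <- function(phantom, geometry, params, i0 = 1) {
  if (params$spr == 0) return(0)
  pr <- project_primary(phantom, geometry, angle = 0, i0 = i0)$primary
  iu <- centre_patch_idx(geometry$n_u)
  iv <- centre_patch_idx(geometry$n_v)
  mp <- mean(pr[iu, iv])
  if (!(mp > 0)) stop("zero primary in the calibration patch")
  ms <- mean(scatter_unit(pr, geometry, params)[iu, iv])
  params$spr * mp / ms
}

# indices of the central 16 x 16 (or smaller) pixel patch
centre_patch_idx <- function(n, size = 16L) {
  size <- min(size, n)
  lo <- floor((n - size) / 2) + 1L
  seq.int(lo, lo + size - 1L)
}
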