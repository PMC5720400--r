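#' Cone-beam acquisition geometry
#'
#' Describes a circular-orbit cone-beam system: a point source at distance
#' `sad` (source-to-axis distance) from the rotation axis and a flat detector
#' at distance `sdd` (source-to-detector distance), with an `n_u` x `n_v`
#' pixel lattice.  The `u` axis is the lateral detector axis (in the axial
#' plane), the `v` axis is parallel to the rotation axis (the patient/z
#' axis).  Defaults reproduce a 100 cm SAD / 150 cm SDD system with a
#' 30 x 30 cm^2, 128 x 128 pixel panel (pixel pitch 2.34 mm) and a full
#' 360-view circular orbit.
#'
#' @param sad Source-to-rotation-axis distance (mm).
#' @param sdd Source-to-detector distance (mm); must exceed `sad`.
#' @param det_size_u,det_size_v Physical detector size (mm) along u and v.
#' @param n_u,n_v Pixel counts along u and v.
#' @param n_views Number of projection views over `arc`.
#' @param arc Angular range of the orbit in degrees (default 360).
#' @return An object of class `cone_beam_geometry`.
#' @examples
#' g <- cone_beam_geometry()
#' g$pitch_u   # 2.34375 mm
#' @export
cone_beam_geometry <- function(sad = 1000, sdd = 1500,
                               det_size_u = 300, det_size_v = 300,
                               n_u = 128L, n_v = 128L,
                               n_views = 360L, arc = 360) {
  n_u <- as.integer(n_u); n_v <- as.integer(n_v); n_views <- as.integer(n_views)
  if (!(is.finite(sad) && sad > 0)) stop("sad must be > 0")
  if (!(is.finite(sdd) && sdd > sad)) stop("sdd must exceed sad")
  if (n_u < 1L || n_v < 1L) stop("pixel counts must be >= 1")
  if (det_size_u <= 0 || det_size_v <= 0) stop("detector size must be positive")
  if (n_views < 1L) stop("n_views must be >= 1")
  if (!(is.finite(arc) && arc > 0)) stop("arc must be positive")
  structure(list(
    sad = sad, sdd = sdd,
    det_size_u = det_size_u, det_size_v = det_size_v,
    n_u = n_u, n_v = n_v,
    pitch_u = det_size_u / n_u, pitch_v = det_size_v / n_v,
    n_views = n_views, arc = arc
  ), class = "cone_beam_geometry")
}

#' @export
print.cone_beam_geometry <- function(x, ...) {
  cat(sprintf("Cone-beam geometry: SAD %.1f mm, SDD %.1f mm (magnification %.3f)\n",
              x$sad, x$sdd, x$sdd / x$sad))
  cat(sprintf("  detector %g x %g mm, %d x %d pixels (pitch %.5g x %.5g mm)\n",
              x$det_size_u, x$det_size_v, x$n_u, x$n_v, x$pitch_u, x$pitch_v))
  cat(sprintf("  %d views over %g degrees\n", x$n_views, x$arc))
  invisible(x)
}

#' Detector pixel-centre coordinates
#'
#' Pixel centres on the detector plane, in mm, centred on the detector
#' midpoint: pixel `i` (1-based) lies at `-det_size/2 + (i - 0.5) * pitch`.
#'
#' @param geometry A [cone_beam_geometry()].
#' @return A list with numeric vectors `u` (length `n_u`) and `v`
#'   (length `n_v`).
#' @export
detector_coords <- function(geometry) {
  stopifnot(inherits(geometry, "cone_beam_geometry"))
  list(
    u = -geometry$det_size_u / 2 + (seq_len(geometry$n_u) - 0.5) * geometry$pitch_u,
    v = -geometry$det_size_v / 2 + (seq_len(geometry$n_v) - 0.5) * geometry$pitch_v
  )
}

#' View angles of the orbit
#'
#' @param geometry A [cone_beam_geometry()].
#' @return Angles in degrees, `k * arc / n_views` for `k = 0 .. n_views - 1`.
#' @export
view_angles <- function(geometry) {
  (seq_len(geometry$n_views) - 1L) * geometry$arc / geometry$n_views
}

#' Multi-slit collimator specification
#'
#' The collimator consists of alternating open and closed lead septa on a
#' circular track centred on the source, in the central sagittal plane, so
#' each septum subtends a fixed angle at the source and projects onto a
#' constant-`v` band of the detector.  The open-septum width is specified at
#' the isocenter plane: a slit of width `w` passes a beam stripe of width `w`
#' through the rotation axis, i.e. an angular half-width
#' `beta = atan(w / 2 / sad)`.  Phase A has an open septum centred on the
#' central ray; phase B is phase A rotated along the track by one septum
#' interval, so for `pitch_ratio = 1` the two phases' open bands tile the
#' detector exactly.
#'
#' Septa are treated as perfect absorbers (10 mm of lead at 40 keV transmits
#' a negligible fraction); `septum_thickness` is informational only.
#'
#' @param slit_width_iso Open-septum width at the isocenter plane (mm).
#' @param pitch_ratio Closed-to-open septum width ratio (default 1).
#' @param septum_thickness Lead thickness (mm); informational.
#' @param soft_edge_sigma Gaussian edge softness at the detector plane (mm);
#'   0 gives ideal binary edges.
#' @return An object of class `msc_spec`.
#' @export
msc_spec <- function(slit_width_iso, pitch_ratio = 1, septum_thickness = 10,
                     soft_edge_sigma = 0) {
  if (!(is.finite(slit_width_iso) && slit_width_iso > 0))
    stop("slit_width_iso must be > 0")
  if (!(is.finite(pitch_ratio) && pitch_ratio > 0))
    stop("pitch_ratio must be > 0")
  if (soft_edge_sigma < 0) stop("soft_edge_sigma must be >= 0")
  structure(list(
    slit_width_iso = slit_width_iso,
    pitch_ratio = pitch_ratio,
    septum_thickness = septum_thickness,
    soft_edge_sigma = soft_edge_sigma
  ), class = "msc_spec")
}

#' @export
print.msc_spec <- function(x, ...) {
  cat(sprintf("MSC: slit width %g mm at isocenter, pitch ratio %g, soft edge sigma %g mm\n",
              x$slit_width_iso, x$pitch_ratio, x$soft_edge_sigma))
  invisible(x)
}

# Angular phase offset of phase B relative to phase A: one open-septum
# interval (2 * beta), which for pitch_ratio = 1 swaps open and closed bands.
msc_phase_shift <- function(msc, geometry) {
  2 * atan(msc$slit_width_iso / 2 / geometry$sad)
}

#' Septa band boundaries on the detector
#'
#' Computes the ordered open/closed band edges of the collimator as projected
#' onto the detector.  The open septum of phase A is centred on the central
#' ray; band edges sit at source angles `theta` that map to detector
#' coordinates `v = sdd * tan(theta)`.  Enough septa are emitted to cover the
#' detector height.  Bands use the half-open convention `[v_lo, v_hi)`.
#'
#' @param msc An [msc_spec()].
#' @param geometry A [cone_beam_geometry()].
#' @param phase `"A"` or `"B"` (phase B shifted by one septum interval).
#' @return A data frame with columns `theta_lo`, `theta_hi` (radians),
#'   `v_lo`, `v_hi` (mm on the detector) and `open` (logical), ordered by
#'   increasing `v`.
#' @export
septa_boundaries <- function(msc, geometry, phase = c("A", "B")) {
  stopifnot(inherits(msc, "msc_spec"), inherits(geometry, "cone_beam_geometry"))
  phase <- match.arg(phase)
  beta <- atan(msc$slit_width_iso / 2 / geometry$sad)
  period <- 2 * beta * (1 + msc$pitch_ratio)
  shift <- if (phase == "B") msc_phase_shift(msc, geometry) else 0
  # cover the detector plus one pixel of margin (soft edges sampled wider)
  v_max <- geometry$det_size_v / 2 + geometry$pitch_v + 4 * msc$soft_edge_sigma
  theta_max <- atan(v_max / geometry$sdd)
  k_max <- ceiling((theta_max + beta + abs(shift)) / period) + 1L
  k <- seq.int(-k_max, k_max)
  centres <- k * period + shift
  open_lo <- centres - beta
  open_hi <- centres + beta
  # closed bands fill the gaps between consecutive open bands
  closed_lo <- open_hi[-length(open_hi)]
  closed_hi <- open_lo[-1L]
  bands <- rbind(
    data.frame(theta_lo = open_lo, theta_hi = open_hi, open = TRUE),
    data.frame(theta_lo = closed_lo, theta_hi = closed_hi, open = FALSE)
  )
  bands <- bands[order(bands$theta_lo), , drop = FALSE]
  keep <- bands$theta_hi > -theta_max & bands$theta_lo < theta_max
  bands <- bands[keep, , drop = FALSE]
  bands$v_lo <- geometry$sdd * tan(bands$theta_lo)
  bands$v_hi <- geometry$sdd * tan(bands$theta_hi)
  rownames(bands) <- NULL
  bands[, c("theta_lo", "theta_hi", "v_lo", "v_hi", "open")]
}

#' Rasterize the collimator into a detector mask
#'
#' Produces the per-pixel transmission of one collimator phase on the
#' detector lattice.  With ideal edges (`soft_edge_sigma = 0`) a pixel is 1
#' when its `v` centre falls in an open band (half-open `[lo, hi)`
#' convention) and 0 otherwise; with soft edges the binary profile is
#' replaced by its Gaussian-smoothed counterpart.  The mask is constant along
#' `u` and independent of gantry angle (the collimator is static relative to
#' the source).
#'
#' @param msc An [msc_spec()].
#' @param geometry A [cone_beam_geometry()].
#' @param phase `"A"` or `"B"`.
#' @return An object of class `detector_mask`: a list with `values`
#'   (`n_u` x `n_v` matrix in `[0, 1]`), `open_bands` / `closed_bands`
#'   (data frames of `v` intervals in mm, clipped to the detector), and
#'   `phase`.
#' @export
build_mask <- function(msc, geometry, phase = c("A", "B")) {
  phase <- match.arg(phase)
  bands <- septa_boundaries(msc, geometry, phase)
  cc <- detector_coords(geometry)
  if (msc$soft_edge_sigma > 0) {
    open <- bands[bands$open, , drop = FALSE]
    s <- msc$soft_edge_sigma
    prof <- rep(0, geometry$n_v)
    for (b in seq_len(nrow(open)))
      prof <- prof + stats::pnorm((open$v_hi[b] - cc$v) / s) -
        stats::pnorm((open$v_lo[b] - cc$v) / s)
    prof <- pmin(pmax(prof, 0), 1)
  } else {
    # classify by angular position within the septa period: exact partition
    beta <- atan(msc$slit_width_iso / 2 / geometry$sad)
    period <- 2 * beta * (1 + msc$pitch_ratio)
    shift <- if (phase == "B") msc_phase_shift(msc, geometry) else 0
    theta <- atan(cc$v / geometry$sdd)
    phi <- (theta - shift + beta) %% period
    prof <- as.numeric(phi < 2 * beta)
  }
  half <- geometry$det_size_v / 2
  clip <- function(df) {
    df <- df[df$v_hi > -half & df$v_lo < half, , drop = FALSE]
    df$v_lo <- pmax(df$v_lo, -half); df$v_hi <- pmin(df$v_hi, half)
    rownames(df) <- NULL
    df[, c("v_lo", "v_hi")]
  }
  structure(list(
    values = matrix(prof, nrow = geometry$n_u, ncol = geometry$n_v, byrow = TRUE),
    open_bands = clip(bands[bands$open, , drop = FALSE]),
    closed_bands = clip(bands[!bands$open, , drop = FALSE]),
    phase = phase,
    soft_edge_sigma = msc$soft_edge_sigma
  ), class = "detector_mask")
}

#' @export
print.detector_mask <- function(x, ...) {
  cat(sprintf("Detector mask, phase %s: %d open / %d closed bands, open fraction %.3f\n",
              x$phase, nrow(x$open_bands), nrow(x$closed_bands), mean(x$values)))
  invisible(x)
}
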