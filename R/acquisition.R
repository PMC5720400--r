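#' Projection stack container
#'
#' A stack of per-view detector images sharing one geometry: a 3D array of
#' shape `n_u` x `n_v` x `n_views` plus the view angles and the plane type
#' (`"line_integral"`, `"primary_intensity"`, `"scatter_intensity"`,
#' `"total_intensity"` or `"corrected_intensity"`).
#'
#' @param values 3D numeric array (`n_u` x `n_v` x `n_views`).
#' @param angles View angles in degrees (length `n_views`).
#' @param plane Plane type string.
#' @param i0 Incident fluence per pixel.
#' @return An object of class `projection_stack`.
#' @export
projection_stack <- function(values, angles, plane, i0 = 1) {
  stopifnot(length(dim(values)) == 3, dim(values)[3] == length(angles))
  structure(list(values = values, angles = angles, plane = plane, i0 = i0),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Projection stack (%s): %d x %d pixels, %d view(s), i0 = %g\n",
              x$plane, d[1], d[2], d[3], x$i0))
  invisible(x)
}

#' Two-phase slit-collimated acquisition
#'
#' Simulates the full two-rotation acquisition: for every gantry angle and
#' each collimator phase, the detector records
#' `total = mask * primary + scatter(mask * primary)` - the collimator blocks
#' primary fluence before the object, so under closed septa the signal is
#' scatter only, which is the premise of the correction.  The scatter scale
#' is calibrated once on the unmasked AP view (see
#' [calibrate_scatter_scale()]).  Optionally an unmasked reference stack
#' (`primary + scatter(primary)`) and the noiseless truth planes are
#' retained.  With `noise = TRUE` each recorded total is replaced by a
#' Poisson draw with the intensity (in units of `i0` counts) as its mean.
#'
#' @param phantom A [phantom()].
#' @param geometry A [cone_beam_geometry()].
#' @param msc An [msc_spec()].
#' @param params A [scatter_params()].
#' @param i0 Incident fluence (counts) per pixel.
#' @param angles View angles in degrees; defaults to the geometry's uniform
#'   orbit `k * arc / n_views`.
#' @param noise Add Poisson counting noise to the recorded totals.
#' @param reference Also simulate the unmasked (no-collimator) stack.
#' @param keep_truth Retain noiseless primary-only and scatter-only planes.
#' @return An object of class `acquisition_pair`: `stack_a` / `stack_b`
#'   (total-intensity [projection_stack()]s), `masks` (list `A`, `B`),
#'   `reference` (or `NULL`), `truth` (list of primary / scatter stacks, or
#'   `NULL`), `scatter_scale`, and the input specs.
#' @export
acquire <- function(phantom, geometry, msc, params = scatter_params(),
                    i0 = 1, angles = NULL, noise = FALSE,
                    reference = TRUE, keep_truth = TRUE) {
  if (is.null(angles)) angles <- view_angles(geometry)
  mask_a <- build_mask(msc, geometry, "A")
  mask_b <- build_mask(msc, geometry, "B")
  scale <- calibrate_scatter_scale(phantom, geometry, params, i0 = i0)
  nv <- length(angles)
  dm <- c(geometry$n_u, geometry$n_v, nv)
  tot_a <- array(0, dm); tot_b <- array(0, dm)
  ref <- if (reference) array(0, dm) else NULL
  tr_p <- if (keep_truth) array(0, dm) else NULL
  tr_sa <- if (keep_truth) array(0, dm) else NULL
  tr_sb <- if (keep_truth) array(0, dm) else NULL
  tr_sref <- if (keep_truth && reference) array(0, dm) else NULL
  for (k in seq_len(nv)) {
    pr <- project_primary(phantom, geometry, angles[k], i0 = i0)$primary
    pa <- mask_a$values * pr
    pb <- mask_b$values * pr
    sa <- simulate_scatter(pa, geometry, params, scale)
    sb <- simulate_scatter(pb, geometry, params, scale)
    tot_a[, , k] <- pa + sa
    tot_b[, , k] <- pb + sb
    if (reference) {
      sr <- simulate_scatter(pr, geometry, params, scale)
      ref[, , k] <- pr + sr
      if (keep_truth) tr_sref[, , k] <- sr
    }
    if (keep_truth) {
      tr_p[, , k] <- pr
      tr_sa[, , k] <- sa
      tr_sb[, , k] <- sb
    }
  }
  if (noise) {
    tot_a[] <- stats::rpois(length(tot_a), tot_a)
    tot_b[] <- stats::rpois(length(tot_b), tot_b)
    if (reference) ref[] <- stats::rpois(length(ref), ref)
  }
  truth <- NULL
  if (keep_truth) {
    truth <- list(
      primary = projection_stack(tr_p, angles, "primary_intensity", i0),
      scatter_a = projection_stack(tr_sa, angles, "scatter_intensity", i0),
      scatter_b = projection_stack(tr_sb, angles, "scatter_intensity", i0)
    )
    if (reference)
      truth$scatter_reference <- projection_stack(tr_sref, angles,
                                                  "scatter_intensity", i0)
  }
  structure(list(
    stack_a = projection_stack(tot_a, angles, "total_intensity", i0),
    stack_b = projection_stack(tot_b, angles, "total_intensity", i0),
    masks = list(A = mask_a, B = mask_b),
    reference = if (reference) projection_stack(ref, angles, "total_intensity", i0),
    truth = truth,
    scatter_scale = scale,
    geometry = geometry, msc = msc, params = params,
    phantom_name = phantom$name, noise = noise
  ), class = "acquisition_pair")
}

#' @export
print.acquisition_pair <- function(x, ...) {
  cat(sprintf("Two-phase slit acquisition of '%s': %d view(s), slit width %g mm, scatter scale %.4g%s\n",
              x$phantom_name, length(x$stack_a$angles), x$msc$slit_width_iso,
              x$scatter_scale, if (x$noise) ", Poisson noise" else ""))
  invisible(x)
}
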