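#' Region specifications for image metrics
#'
#' Axis-aligned rectangle or disk in physical coordinates (detector mm for
#' projection images, volume mm for reconstructed slices).
#'
#' @param center Length-2 centre (mm).
#' @param width,height Rectangle edge lengths (mm).
#' @param radius Disk radius (mm).
#' @param label Region label.
#' @return An object of class `region_spec`.
#' @export
region_rect <- function(center, width, height = width, label = "") {
  structure(list(shape = "rect", center = center, width = width,
                 height = height, label = label), class = "region_spec")
}

#' @rdname region_rect
#' @export
region_disk <- function(center, radius, label = "") {
  structure(list(shape = "disk", center = center, radius = radius,
                 label = label), class = "region_spec")
}

# logical pixel mask of a region on the lattice given coordinate vectors
region_mask <- function(region, xs, ys) {
  if (region$shape == "rect") {
    mx <- abs(xs - region$center[1]) <= region$width / 2
    my <- abs(ys - region$center[2]) <= region$height / 2
    outer(mx, my, "&")
  } else {
    outer((xs - region$center[1])^2, (ys - region$center[2])^2, "+") <=
      region$radius^2
  }
}

#' Contrast ratio between a region and its surround
#'
#' `CR = |I_P - I_W| / I_P`, where `I_P` is the mean over the surrounding
#' region and `I_W` the mean over the insert region.
#'
#' @param image 2D matrix (projection plane or volume slice).
#' @param region_p Surrounding-region [region_rect()]/[region_disk()].
#' @param region_w Insert-region spec.
#' @param xs,ys Physical coordinates of the image lattice (mm): detector
#'   `u`/`v` for projections, grid `x`/`y` for volume slices.
#' @return An object of class `contrast_report`: `i_p`, `i_w`, `cr`,
#'   and the region labels.
#' @export
contrast_ratio <- function(image, region_p, region_w, xs, ys) {
  mp <- region_mask(region_p, xs, ys)
  mw <- region_mask(region_w, xs, ys)
  if (!any(mp) || !any(mw)) stop("empty contrast region after rasterization")
  i_p <- mean(image[mp])
  i_w <- mean(image[mw])
  if (i_p == 0) stop("undefined contrast: surrounding-region mean is zero")
  structure(list(i_p = i_p, i_w = i_w, cr = abs(i_p - i_w) / i_p,
                 label_p = region_p$label, label_w = region_w$label),
            class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat(sprintf("CR = |%.5g - %.5g| / %.5g = %.4f\n", x$i_p, x$i_w, x$i_p, x$cr))
  invisible(x)
}

#' Contrast-ratio improvement factor
#'
#' Ratio of the corrected image's contrast ratio to the uncorrected one's.
#'
#' @param cr_corrected,cr_uncorrected Contrast ratios (numbers or
#'   [contrast_ratio()] reports).
#' @return The factor `cr_corrected / cr_uncorrected`.
#' @export
cr_improvement <- function(cr_corrected, cr_uncorrected) {
  if (inherits(cr_corrected, "contrast_report")) cr_corrected <- cr_corrected$cr
  if (inherits(cr_uncorrected, "contrast_report")) cr_uncorrected <- cr_uncorrected$cr
  if (!(cr_uncorrected > 0)) stop("undefined improvement factor: uncorrected CR is zero")
  cr_corrected / cr_uncorrected
}

#' Percent relative-error profile
#'
#' `100 * (test - reference) / reference` per sample.  Samples whose
#' reference falls at or below `min_ref_frac * max(reference)` are excluded
#' (returned as `NA`) and counted.
#'
#' @param test,reference Equal-length numeric profiles.
#' @param min_ref_frac Exclusion threshold as a fraction of the reference
#'   maximum (default 0: exclude only non-positive references).
#' @return A list with `errors` (percent, `NA` where excluded), `max_abs`,
#'   and `n_excluded`.
#' @export
relative_error_profile <- function(test, reference, min_ref_frac = 0) {
  stopifnot(length(test) == length(reference))
  if (all(reference <= 0)) stop("all-zero reference profile")
  thr <- max(min_ref_frac * max(reference), 0)
  ok <- reference > thr
  err <- rep(NA_real_, length(test))
  err[ok] <- 100 * (test[ok] - reference[ok]) / reference[ok]
  list(errors = err, max_abs = max(abs(err[ok])), n_excluded = sum(!ok))
}

#' Detector energy profiles along v
#'
#' For each supplied stack, the detected intensity integrated across the
#' lateral (`u`) axis per detector row `v`, for one view: the proxy used to
#' compare the energy the detector receives with and without the
#' collimator.
#'
#' @param stacks Named list of [projection_stack()]s sharing one lattice.
#' @param view View index (1-based).
#' @return Matrix with one column per stack and `n_v` rows.
#' @export
detector_energy_profile <- function(stacks, view = 1L) {
  dims <- lapply(stacks, function(s) dim(s$values)[1:2])
  if (length(unique(dims)) != 1) stop("stacks do not share a detector lattice")
  sapply(stacks, function(s) colSums(s$values[, , view]))
}
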