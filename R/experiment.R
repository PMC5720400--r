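# End-to-end orchestration: the anterior-posterior projection bench used
# for the residual-error and 2D contrast studies, and the full
# simulate - correct - reconstruct - evaluate pipeline.

#' Central z-axis profile of a detector image
#'
#' The image column at the central `u` pixel (index `n_u %/% 2 + 1`),
#' running along `v` (the axis parallel to the rotation/z axis).
#'
#' @param image `n_u` x `n_v` matrix.
#' @param geometry A [cone_beam_geometry()].
#' @return A list with `v` (mm) and `values`.
#' @export
central_column_profile <- function(image, geometry) {
  iu <- geometry$n_u %/% 2L + 1L
  list(v = detector_coords(geometry)$v, values = image[iu, ])
}

#' Single-view projection bench at the AP angle
#'
#' Runs the full two-phase acquisition and correction for one gantry angle
#' (default 0, the anterior-posterior view) and returns every plane needed
#' for the projection-domain evaluation: the corrected view, the true
#' primary, the unmasked uncorrected view (primary + scatter), and the raw
#' phase sum.
#'
#' @param phantom A [phantom()].
#' @param geometry A [cone_beam_geometry()].
#' @param msc An [msc_spec()].
#' @param params A [scatter_params()].
#' @param angle Gantry angle (degrees).
#' @param i0 Incident fluence per pixel.
#' @param method,extrapolation,spacing,u_smooth Correction options, see
#'   [correct_stack()].
#' @return A list with matrices `corrected`, `primary`, `uncorrected`
#'   (unmasked primary + scatter), `raw_sum` (phase A + phase B totals),
#'   the `pair`, and `n_clipped`.
#' @export
ap_projection_bench <- function(phantom, geometry, msc,
                                params = scatter_params(), angle = 0, i0 = 1,
                                method = "monotone", extrapolation = "slope",
                                spacing = NULL, u_smooth = 0) {
  pair <- acquire(phantom, geometry, msc, params, i0 = i0, angles = angle,
                  noise = FALSE, reference = TRUE, keep_truth = TRUE)
  corr <- correct_stack(pair, method = method, extrapolation = extrapolation,
                        spacing = spacing, u_smooth = u_smooth)
  list(corrected = corr$stack$values[, , 1],
       primary = pair$truth$primary$values[, , 1],
       uncorrected = pair$reference$values[, , 1],
       raw_sum = pair$stack_a$values[, , 1] + pair$stack_b$values[, , 1],
       pair = pair,
       n_clipped = corr$n_clipped[1])
}

# default contrast regions for a projection image (detector mm):
# insert at the centre, surround offset laterally (magnified from the
# isocenter offset)
projection_cr_regions <- function(geometry, cfg_eval) {
  mag <- geometry$sdd / geometry$sad
  size <- cfg_eval$region_size
  list(p = region_rect(c(cfg_eval$surround_offset_iso * mag, 0),
                       size, size, label = "surround"),
       w = region_rect(c(0, 0), size, size, label = "insert"))
}

# analogous regions in an axial volume slice (volume mm, unmagnified)
volume_cr_regions <- function(cfg_eval) {
  size <- cfg_eval$region_size
  list(p = region_rect(c(cfg_eval$surround_offset_iso, 0), size, size,
                       label = "surround"),
       w = region_rect(c(0, 0), size, size, label = "insert"))
}

#' Run the full evaluation experiment
#'
#' For each configured slit width: run the AP projection bench, report the
#' z-axis residual-error profile against the true primary, the 2D contrast
#' ratios (corrected / uncorrected / primary-only) with their improvement
#' factors, and the detector-energy profiles.  With `recon$enabled`, also
#' acquire the full orbit, correct it, reconstruct corrected / uncorrected /
#' primary volumes by FDK and report 3D contrast ratios at the central and
#' peripheral slices.  Artifacts (profiles as CSV, summary as JSON,
#' stacks/volumes as MetaImage, masks and views as TIFF, profile figures as
#' PNG) are written under `out_dir`.
#'
#' @param config Configuration list, see [default_config()] /
#'   [read_config()].
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   all file output.
#' @param seed RNG seed recorded in the summary and applied before any
#'   noisy acquisition.
#' @return The evaluation summary (nested list), invisibly when writing.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL,
                           seed = NULL) {
  geometry <- config_geometry(config)
  phantom <- config_phantom(config)
  params <- config_scatter(config)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  regions2d <- projection_cr_regions(geometry, config$evaluation)
  cc <- detector_coords(geometry)
  summary <- list(config = config, seed = seed, slit_widths = list())

  for (w in config$msc$slit_widths) {
    msc <- config_msc(config, w)
    bench <- ap_projection_bench(phantom, geometry, msc, params,
                                 i0 = config$acquisition$i0,
                                 method = config$correction$method,
                                 extrapolation = config$correction$extrapolation,
                                 spacing = config$correction$spacing,
                                 u_smooth = config$correction$u_smooth)
    prof_c <- central_column_profile(bench$corrected, geometry)
    prof_p <- central_column_profile(bench$primary, geometry)
    prof_u <- central_column_profile(bench$uncorrected, geometry)
    rel <- relative_error_profile(prof_c$values, prof_p$values,
                                  min_ref_frac = 0.01)
    cr_c <- contrast_ratio(bench$corrected, regions2d$p, regions2d$w, cc$u, cc$v)
    cr_u <- contrast_ratio(bench$uncorrected, regions2d$p, regions2d$w, cc$u, cc$v)
    cr_p <- contrast_ratio(bench$primary, regions2d$p, regions2d$w, cc$u, cc$v)
    energy <- detector_energy_profile(list(
      phase_a = bench$pair$stack_a, phase_b = bench$pair$stack_b,
      raw_sum = projection_stack(array(bench$raw_sum,
                                       c(dim(bench$raw_sum), 1)),
                                 0, "total_intensity"),
      reference = bench$pair$reference))
    res <- list(
      slit_width = w,
      max_abs_rel_error_pct = rel$max_abs,
      n_profile_excluded = rel$n_excluded,
      n_clipped = bench$n_clipped,
      cr_2d = list(corrected = cr_c$cr, uncorrected = cr_u$cr,
                   primary = cr_p$cr,
                   improvement = cr_improvement(cr_c, cr_u)),
      energy_ratio_range = range(energy[, "raw_sum"] / energy[, "reference"])
    )

    if (isTRUE(config$recon$enabled)) {
      pair <- acquire(phantom, geometry, msc, params,
                      i0 = config$acquisition$i0,
                      noise = isTRUE(config$acquisition$noise),
                      reference = TRUE, keep_truth = TRUE)
      corr <- correct_stack(pair, method = config$correction$method,
                            extrapolation = config$correction$extrapolation,
                            spacing = config$correction$spacing,
                            u_smooth = config$correction$u_smooth)
      grid <- recon_grid(config$recon$n_x, config$recon$n_y, config$recon$n_z,
                         config$recon$voxel_size)
      vol_c <- fdk_reconstruct(log_normalize(corr$stack), geometry, grid,
                               filter = config$recon$filter)
      vol_u <- fdk_reconstruct(log_normalize(pair$reference), geometry, grid,
                               filter = config$recon$filter)
      vol_p <- fdk_reconstruct(log_normalize(pair$truth$primary), geometry,
                               grid, filter = config$recon$filter)
      gx <- grid_coords(grid)
      r3 <- volume_cr_regions(config$evaluation)
      half_len <- max(vapply(phantom$elements, `[[`, numeric(1), "z_hi"))
      iz_c <- (grid$n_z + 1L) %/% 2L
      iz_p <- which.min(abs(gx$z - config$evaluation$peripheral_slice_frac * half_len))
      cr3 <- function(vol, iz) contrast_ratio(vol$values[, , iz], r3$p, r3$w,
                                              gx$x, gx$y)$cr
      res$cr_3d <- list(
        central = list(corrected = cr3(vol_c, iz_c),
                       uncorrected = cr3(vol_u, iz_c),
                       primary = cr3(vol_p, iz_c),
                       improvement = cr3(vol_c, iz_c) / cr3(vol_u, iz_c)),
        peripheral = list(corrected = cr3(vol_c, iz_p),
                          uncorrected = cr3(vol_u, iz_p),
                          primary = cr3(vol_p, iz_p),
                          improvement = cr3(vol_c, iz_p) / cr3(vol_u, iz_p)))
      if (!is.null(out_dir)) {
        tag <- sprintf("w%02.0fmm", w)
        write_volume_mhd(vol_c, file.path(out_dir, paste0("volume_corrected_", tag, ".mhd")))
        write_volume_mhd(vol_u, file.path(out_dir, paste0("volume_uncorrected_", tag, ".mhd")))
        pc <- central_profile(vol_c, "x"); pu <- central_profile(vol_u, "x")
        pp <- central_profile(vol_p, "x")
        utils::write.csv(data.frame(x_mm = pc$pos, corrected = pc$values,
                                    uncorrected = pu$values, primary = pp$values),
                         file.path(out_dir, paste0("recon_profile_", tag, ".csv")),
                         row.names = FALSE)
      }
    }

    if (!is.null(out_dir)) {
      tag <- sprintf("w%02.0fmm", w)
      utils::write.csv(
        data.frame(v_mm = prof_p$v, primary = prof_p$values,
                   corrected = prof_c$values, uncorrected = prof_u$values,
                   rel_error_pct = rel$errors),
        file.path(out_dir, paste0("z_profile_", tag, ".csv")),
        row.names = FALSE)
      utils::write.csv(
        data.frame(v_mm = cc$v, energy),
        file.path(out_dir, paste0("detector_energy_", tag, ".csv")),
        row.names = FALSE)
      write_image_tiff(bench$pair$masks$A, file.path(out_dir, paste0("mask_a_", tag, ".tif")),
                       range = c(0, 1))
      write_image_tiff(bench$corrected,
                       file.path(out_dir, paste0("corrected_ap_", tag, ".tif")))
      grDevices::png(file.path(out_dir, paste0("z_profile_", tag, ".png")),
                     width = 700, height = 500)
      graphics::matplot(prof_p$v, cbind(prof_p$values, prof_u$values, prof_c$values),
                        type = "l", lty = 1, col = c("black", "red", "blue"),
                        xlab = "v (mm)", ylab = "intensity",
                        main = sprintf("AP z-profile, slit width %g mm", w))
      graphics::legend("topright", c("primary", "uncorrected", "corrected"),
                       col = c("black", "red", "blue"), lty = 1)
      grDevices::dev.off()
    }
    summary$slit_widths[[sprintf("w%g", w)]] <- res
  }

  if (!is.null(out_dir))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(out_dir)) summary else invisible(summary)
}
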