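#' Default bench configuration
#'
#' The full study conditions as nested lists: geometry (SAD 1000 mm,
#' SDD 1500 mm, 30 x 30 cm^2 128 x 128 detector, 360 views), collimator
#' (slit widths 10/20/30 mm at the isocenter, ideal edges), scatter model
#' (SPR 0.5, kernel sigma 30 mm, pedestal fraction 0.3, noiseless),
#' correction (monotone interpolation), reconstruction (Ram-Lak,
#' 128^3 grid at 1.5 mm) and evaluation regions.  Any field can be
#' overridden by a YAML file, see [read_config()].
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    geometry = list(sad = 1000, sdd = 1500, det_size_u = 300, det_size_v = 300,
                    n_u = 128L, n_v = 128L, n_views = 360L, arc = 360),
    msc = list(slit_widths = c(10, 20, 30), pitch_ratio = 1,
               septum_thickness = 10, soft_edge_sigma = 0),
    scatter = list(spr = 0.5, kernel_sigma = 30, pedestal_fraction = 0.3),
    acquisition = list(i0 = 1, noise = FALSE),
    phantom = "simple",
    correction = list(method = "monotone", extrapolation = "slope",
                      spacing = NULL, u_smooth = 0),
    recon = list(enabled = FALSE, filter = "ramlak",
                 n_x = 128L, n_y = 128L, n_z = 128L, voxel_size = 1.5),
    evaluation = list(
      # 20 x 20 mm regions: insert at the centre, surround 45 mm lateral at
      # the isocenter (magnified on the detector for 2D)
      region_size = 20, surround_offset_iso = 45,
      peripheral_slice_frac = 0.75
    )
  )
}

# recursively override defaults with user-supplied fields
merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      merge_config(base[[k]], override[[k]])
    else override[[k]]
  }
  base
}

#' Read a YAML bench configuration
#'
#' Fields present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  cfg
}

# constructors from a configuration
config_geometry <- function(cfg) do.call(cone_beam_geometry, cfg$geometry)

config_phantom <- function(cfg, materials = default_materials()) {
  switch(cfg$phantom,
         simple = build_simple_phantom(materials),
         lungbone = build_lung_bone_phantom(materials),
         stop("unknown phantom: ", cfg$phantom))
}

config_scatter <- function(cfg) do.call(scatter_params, cfg$scatter)

config_msc <- function(cfg, slit_width) {
  msc_spec(slit_width_iso = slit_width,
           pitch_ratio = cfg$msc$pitch_ratio,
           septum_thickness = cfg$msc$septum_thickness,
           soft_edge_sigma = cfg$msc$soft_edge_sigma)
}
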