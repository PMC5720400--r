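#' Imaging material
#'
#' A material is described by its density and its linear attenuation
#' coefficient at the bench's 40 keV monoenergetic beam.  `mu` may be given
#' directly (1/cm) or derived from a mass attenuation coefficient
#' `mu_over_rho` (cm^2/g) as `mu = density * mu_over_rho`.
#'
#' @param name Material name.
#' @param density Density in g/cm^3 (must be positive).
#' @param mu Linear attenuation coefficient at 40 keV (1/cm).
#' @param mu_over_rho Mass attenuation coefficient at 40 keV (cm^2/g);
#'   used when `mu` is missing.
#' @return An object of class `material`.
#' @export
material <- function(name, density, mu = NULL, mu_over_rho = NULL) {
  if (!(is.finite(density) && density > 0)) stop("density must be > 0")
  if (is.null(mu)) {
    if (is.null(mu_over_rho)) stop("supply mu or mu_over_rho")
    mu <- density * mu_over_rho
  }
  if (!(is.finite(mu) && mu >= 0)) stop("mu must be >= 0")
  structure(list(name = name, density = density, mu = mu), class = "material")
}

#' Default 40 keV material table
#'
#' Materials of the two bench phantoms: PMMA (1.19 g/cm^3) and paraffin wax
#' (0.93 g/cm^3) for the simple phantom, plus lung-equivalent polyurethane
#' foam (0.26 g/cm^3) and PTFE / Teflon (2.2 g/cm^3) as lung and bone
#' surrogates.  Mass attenuation coefficients at 40 keV are taken from
#' NIST-tabulated values (mixture rule over elemental coefficients for the
#' plastics; a water-like value scaled for the polyurethane foam):
#' PMMA 0.2351, paraffin 0.2283, PTFE 0.2627, polyurethane 0.2550 cm^2/g.
#' Every value can be overridden by constructing materials directly.
#'
#' @return Named list of [material()] objects:
#'   `pmma`, `paraffin`, `polyurethane`, `teflon`.
#' @export
default_materials <- function() {
  list(
    pmma         = material("PMMA",         1.19, mu_over_rho = 0.2351),
    paraffin     = material("paraffin wax", 0.93, mu_over_rho = 0.2283),
    polyurethane = material("polyurethane (lung)", 0.26, mu_over_rho = 0.2550),
    teflon       = material("PTFE (bone surrogate)", 2.20, mu_over_rho = 0.2627)
  )
}

#' Cylindrical phantom element
#'
#' An axis-aligned circular cylinder (axis parallel to z, the rotation axis)
#' filled with one material.  Where elements overlap, the element with the
#' higher `priority` defines the local attenuation.  Membership uses the
#' half-open convention: a point belongs to the element when its radial
#' distance is strictly less than `radius` and `z_lo <= z < z_hi`.
#'
#' @param center_x,center_y Axis position in the axial plane (mm).
#' @param radius Cylinder radius (mm).
#' @param z_lo,z_hi Axial extent (mm), `z_hi > z_lo`.
#' @param material A [material()].
#' @param priority Integer; higher overrides lower in overlaps.
#' @return An object of class `cylinder_element`.
#' @export
cylinder_element <- function(center_x, center_y, radius, z_lo, z_hi,
                             material, priority = 1L) {
  if (!(radius > 0)) stop("radius must be > 0")
  if (!(z_hi > z_lo)) stop("z_hi must exceed z_lo")
  stopifnot(inherits(material, "material"))
  structure(list(center_x = center_x, center_y = center_y, radius = radius,
                 z_lo = z_lo, z_hi = z_hi, material = material,
                 priority = as.integer(priority)),
            class = "cylinder_element")
}

#' Analytic phantom
#'
#' An ordered list of [cylinder_element()]s in air (background attenuation
#' zero).  Overlaps are resolved by element priority; elements sharing a
#' priority are assumed disjoint.
#'
#' @param elements List of [cylinder_element()]s.
#' @param name Optional label.
#' @return An object of class `phantom`.
#' @export
phantom <- function(elements = list(), name = "phantom") {
  stopifnot(all(vapply(elements, inherits, logical(1), "cylinder_element")))
  structure(list(elements = elements, name = name), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Phantom '%s' with %d cylindrical element(s):\n",
              x$name, length(x$elements)))
  for (e in x$elements)
    cat(sprintf("  %-24s r %5.1f mm at (%6.1f, %6.1f), z [%g, %g] mm, mu %.4f /cm, priority %d\n",
                e$material$name, e$radius, e$center_x, e$center_y,
                e$z_lo, e$z_hi, e$material$mu, e$priority))
  invisible(x)
}

#' Simple two-region phantom
#'
#' A PMMA outer cylinder of 15 cm diameter with a coaxial paraffin-wax inner
#' cylinder of 5 cm diameter, both 15 cm long and centred on the isocenter.
#'
#' @param materials Material table as from [default_materials()]; must
#'   provide `pmma` and `paraffin`.
#' @return A [phantom()].
#' @export
build_simple_phantom <- function(materials = default_materials()) {
  need <- c("pmma", "paraffin")
  if (!all(need %in% names(materials)))
    stop("material table must provide: ", paste(need, collapse = ", "))
  phantom(list(
    cylinder_element(0, 0, 75, -75, 75, materials$pmma, priority = 1L),
    cylinder_element(0, 0, 25, -75, 75, materials$paraffin, priority = 2L)
  ), name = "simple")
}

#' Lung-and-bone phantom
#'
#' A PMMA outer cylinder (15 cm diameter, 20 cm long) containing two
#' lung-equivalent polyurethane cylinders (5 cm diameter, 9 cm long) placed
#' symmetrically left and right of centre, and a PTFE cylinder (2 cm
#' diameter, 20 cm long) as a bone surrogate.  Insert lateral positions are
#' a configurable default mimicking a thorax-like layout: lungs at
#' (+-40, 0) mm, bone at (0, -25) mm.
#'
#' @param materials Material table; must provide `pmma`, `polyurethane`,
#'   `teflon`.
#' @param lung_offset Lateral lung-axis offset from the midline (mm).
#' @param bone_center Axial-plane position of the bone cylinder (mm, length 2).
#' @return A [phantom()].
#' @export
build_lung_bone_phantom <- function(materials = default_materials(),
                                    lung_offset = 40,
                                    bone_center = c(0, -25)) {
  need <- c("pmma", "polyurethane", "teflon")
  if (!all(need %in% names(materials)))
    stop("material table must provide: ", paste(need, collapse = ", "))
  phantom(list(
    cylinder_element(0, 0, 75, -100, 100, materials$pmma, priority = 1L),
    cylinder_element(-lung_offset, 0, 25, -45, 45, materials$polyurethane, priority = 2L),
    cylinder_element(lung_offset, 0, 25, -45, 45, materials$polyurethane, priority = 2L),
    cylinder_element(bone_center[1], bone_center[2], 10, -100, 100,
                     materials$teflon, priority = 2L)
  ), name = "lung-n-bone")
}

#' Attenuation coefficient at points
#'
#' Evaluates the phantom's linear attenuation (1/cm) at one or more points:
#' the material of the highest-priority element containing each point, or 0
#' (air) outside all elements.
#'
#' @param phantom A [phantom()].
#' @param points Numeric matrix with columns x, y, z (mm), or a length-3
#'   vector for a single point.
#' @return Numeric vector of attenuation coefficients (1/cm).
#' @export
mu_at <- function(phantom, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  mu <- rep(0, nrow(points))
  pri <- rep(-Inf, nrow(points))
  for (e in phantom$elements) {
    r2 <- (points[, 1] - e$center_x)^2 + (points[, 2] - e$center_y)^2
    inside <- r2 < e$radius^2 & points[, 3] >= e$z_lo & points[, 3] < e$z_hi
    take <- inside & e$priority > pri
    mu[take] <- e$material$mu
    pri[take] <- e$priority
  }
  mu
}
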