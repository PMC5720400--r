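# Ray-traced monoenergetic forward projector.
#
# Rays are parameterised p(t) = src + t * (det - src), t in [0, 1].  Each
# cylinder element contributes a chord [t_lo, t_hi] from the ray-cylinder
# quadratic in the axial plane, clipped by the element's z extent.  Overlaps
# are priority-resolved exactly by subtracting, from each element's chord,
# its intersection with every higher-priority element's chord (elements of
# equal priority are assumed disjoint, as in the supplied phantoms).

# Per-element chord intervals for a bundle of rays from one source point.
# Returns a list of data-frame-like lists (t_lo, t_hi) per element.
ray_intervals <- function(phantom, src, det) {
  d <- sweep(det, 2, src)             # n x 3 direction (det - src)
  lapply(phantom$elements, function(e) {
    fx <- src[1] - e$center_x
    fy <- src[2] - e$center_y
    a <- d[, 1]^2 + d[, 2]^2
    b <- 2 * (d[, 1] * fx + d[, 2] * fy)
    cc <- fx^2 + fy^2 - e$radius^2
    disc <- b^2 - 4 * a * cc
    hit <- disc > 0 & a > 0
    sq <- sqrt(pmax(disc, 0))
    t1 <- (-b - sq) / (2 * a)
    t2 <- (-b + sq) / (2 * a)
    # clip by the element's z-slab
    dz <- d[, 3]
    tz1 <- ifelse(dz != 0, (e$z_lo - src[3]) / dz, -Inf)
    tz2 <- ifelse(dz != 0, (e$z_hi - src[3]) / dz, Inf)
    zin <- dz != 0 | (src[3] >= e$z_lo & src[3] < e$z_hi)
    lo <- pmax(t1, pmin(tz1, tz2), 0)
    hi <- pmin(t2, pmax(tz1, tz2), 1)
    lo[!(hit & zin)] <- 0
    hi[!(hit & zin)] <- 0
    list(t_lo = lo, t_hi = pmax(hi, lo))
  })
}

#' Line integral of attenuation along source-to-detector rays
#'
#' Exact analytic path integral of the phantom's linear attenuation along
#' each ray, summing material-weighted chord lengths from the ray-cylinder
#' quadratic of every element with priority-resolved overlaps.  The result
#' is dimensionless (mu in 1/cm times path in cm).
#'
#' @param phantom A [phantom()].
#' @param src Source point, length-3 (mm).
#' @param det Detector points: n x 3 matrix or length-3 vector (mm).
#' @return Numeric vector of path-integrated attenuation, one per ray.
#' @export
line_integral <- function(phantom, src, det) {
  if (is.null(dim(det))) det <- matrix(det, ncol = 3)
  if (length(phantom$elements) == 0) return(rep(0, nrow(det)))
  d <- sweep(det, 2, src)
  len <- sqrt(rowSums(d^2))
  ints <- ray_intervals(phantom, src, det)
  pri <- vapply(phantom$elements, `[[`, integer(1), "priority")
  total <- rep(0, nrow(det))
  for (i in seq_along(ints)) {
    eff <- ints[[i]]$t_hi - ints[[i]]$t_lo
    higher <- which(pri > pri[i])
    for (j in higher) {
      ov <- pmin(ints[[i]]$t_hi, ints[[j]]$t_hi) -
        pmax(ints[[i]]$t_lo, ints[[j]]$t_lo)
      eff <- eff - pmax(ov, 0)
    }
    # mu is 1/cm, path lengths mm: divide by 10
    total <- total + (phantom$elements[[i]]$material$mu / 10) * pmax(eff, 0) * len
  }
  total
}

# Source position at a gantry angle (degrees).  Angle 0 is the
# anterior-posterior view with the source on the +y axis; rotation is
# right-handed about +z.
source_position <- function(geometry, angle) {
  b <- angle * pi / 180
  c(-geometry$sad * sin(b), geometry$sad * cos(b), 0)
}

# Detector pixel-centre positions in world coordinates (n_u*n_v x 3),
# u fastest.  The detector midpoint lies on the source-axis line extended to
# distance sdd; u spans the axial plane, v is parallel to the rotation axis.
detector_pixel_positions <- function(geometry, angle) {
  b <- angle * pi / 180
  cc <- detector_coords(geometry)
  centre <- c((geometry$sdd - geometry$sad) * sin(b),
              -(geometry$sdd - geometry$sad) * cos(b), 0)
  uhat <- c(cos(b), sin(b), 0)
  u <- rep(cc$u, times = geometry$n_v)
  v <- rep(cc$v, each = geometry$n_u)
  cbind(centre[1] + u * uhat[1],
        centre[2] + u * uhat[2],
        v)
}

#' Primary projection of a phantom at one gantry angle
#'
#' Beer-Lambert monoenergetic primary: per pixel,
#' `intensity = i0 * exp(-line_integral)` along the ray from the source to
#' the pixel centre.  The line-integral plane is retained alongside the
#' intensity plane.
#'
#' @param phantom A [phantom()].
#' @param geometry A [cone_beam_geometry()].
#' @param angle Gantry angle in degrees (0 = anterior-posterior).
#' @param i0 Incident fluence per pixel (arbitrary units).
#' @return An object of class `projection`: list with `angle`, `i0`,
#'   `line_integral` and `primary` (`n_u` x `n_v` matrices).
#' @export
project_primary <- function(phantom, geometry, angle, i0 = 1) {
  src <- source_position(geometry, angle)
  det <- detector_pixel_positions(geometry, angle)
  p <- line_integral(phantom, src, det)
  li <- matrix(p, nrow = geometry$n_u, ncol = geometry$n_v)
  structure(list(angle = angle, i0 = i0,
                 line_integral = li,
                 primary = i0 * exp(-li)),
            class = "projection")
}
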