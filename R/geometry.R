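# Analytic geometry of the simulated cells: oblate spheroids resting on the
# substrate, optionally carrying a nucleus sub-ellipsoid.

#' Construct a cell geometry
#'
#' @param semi_axes numeric (a, b, c) in um; c is the vertical (optical-axis)
#'   semi-axis, so the analytic thickness T = 1.5 V / A equals 2c for any
#'   ellipsoid (V/A = (4/3 pi a b c)/(pi a b) = 4c/3).
#' @param center numeric (x, y, z) in um, in the field-of-view frame.
#' @param nucleus_fraction linear scale of the nucleus sub-ellipsoid relative
#'   to the cell (0 disables it); the nucleus is concentric.
#' @return object of class `cell_geometry` with analytic `volume`, `surface`,
#'   `footprint`, `thickness` and `sphericity` fields.
#' @export
cell_geometry <- function(semi_axes, center = c(0, 0, 0), nucleus_fraction = 0.6) {
  stopifnot(length(semi_axes) == 3L, all(semi_axes > 0),
            length(center) == 3L,
            nucleus_fraction >= 0, nucleus_fraction < 1)
  a <- semi_axes[1]; b <- semi_axes[2]; c <- semi_axes[3]
  V <- 4 / 3 * pi * a * b * c
  S <- ellipsoid_surface(a, b, c)
  A <- pi * a * b
  structure(list(
    semi_axes = semi_axes,
    center = center,
    nucleus_fraction = nucleus_fraction,
    volume = V,
    surface = S,
    footprint = A,
    thickness = 1.5 * V / A,
    sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / S
  ), class = "cell_geometry")
}

#' Ellipsoid surface area
#'
#' Exact closed form for spheroids (two equal semi-axes, covering every
#' geometry the cohort sampler produces); Thomsen's approximation
#' (relative error < 1.1%) for the general triaxial case.
#'
#' @param a,b,c semi-axes.
#' @return surface area in squared input units.
#' @export
ellipsoid_surface <- function(a, b, c) {
  eps <- 1e-12
  if (abs(a - b) < eps && abs(b - c) < eps) return(4 * pi * a^2)
  if (abs(a - b) < eps) {
    r <- a
    if (c < r) { # oblate
      e <- sqrt(1 - c^2 / r^2)
      return(2 * pi * r^2 * (1 + (1 - e^2) / e * atanh(e)))
    }
    e <- sqrt(1 - r^2 / c^2) # prolate
    return(2 * pi * r^2 * (1 + c / (r * e) * asin(e)))
  }
  p <- 1.6075
  4 * pi * ((a^p * b^p + a^p * c^p + b^p * c^p) / 3)^(1 / p)
}

#' Solve the footprint radius of an oblate spheroid from sphericity and
#' thickness
#'
#' Given target sphericity `phi` and thickness `T` (so vertical semi-axis
#' c = T/2), returns the equatorial radius r with
#' sphericity(r, r, c) = phi. Sphericity decreases monotonically in r for
#' r > c, so the root is unique.
#'
#' @param phi target sphericity in (0, 1].
#' @param thickness target thickness in um.
#' @return equatorial radius r in um (r >= c).
#' @export
solve_footprint_radius <- function(phi, thickness) {
  stopifnot(phi > 0, phi <= 1, thickness > 0)
  c <- thickness / 2
  sph <- function(r) {
    V <- 4 / 3 * pi * r^2 * c
    pi^(1 / 3) * (6 * V)^(2 / 3) / ellipsoid_surface(r, r, c)
  }
  if (phi >= 1 - 1e-9) return(c)
  upper <- c * 2
  while (sph(upper) > phi) upper <- upper * 2
  stats::uniroot(function(r) sph(r) - phi, c(c * (1 + 1e-9), upper),
                 tol = 1e-10)$root
}

#' Mean confocally sampled thickness over the footprint
#'
#' Average over the footprint of min(local projected thickness, cap): the
#' per-pixel signal depth a focal volume of axial extent `cap` samples. For
#' an ellipsoid with maximum thickness Tmax = 2c and ratio q = cap/Tmax < 1
#' the closed form is cap (1 - q^2) + (2/3) Tmax q^3; without a cap it is
#' V/A = (2/3) Tmax.
#'
#' @param geometry [cell_geometry()].
#' @param cap confocal depth in um (Inf = full projection).
#' @return mean sampled thickness in um.
#' @export
mean_sampled_thickness <- function(geometry, cap = 1.5) {
  t_max <- geometry$thickness
  if (!is.finite(cap) || cap >= t_max) return(geometry$volume / geometry$footprint)
  q <- cap / t_max
  cap * (1 - q^2) + (2 / 3) * t_max * q^3
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "<cell_geometry> semi-axes (%.2f, %.2f, %.2f) um at (%.1f, %.1f, %.1f)\n",
    x$semi_axes[1], x$semi_axes[2], x$semi_axes[3],
    x$center[1], x$center[2], x$center[3]))
  cat(sprintf("  V = %.1f um^3, S = %.1f um^2, A = %.1f um^2, T = %.2f um, phi = %.3f\n",
              x$volume, x$surface, x$footprint, x$thickness, x$sphericity))
  invisible(x)
}
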