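# Grain-size statistics, surface-to-volume ratio, cell-density conversions
# and convex-hull surface roughness.

#' Surface-to-volume ratio of a sand sample
#'
#' For a grain-size sample the total grain surface area per unit sediment
#' volume is
#'   S_VT = 6 (1 - theta) * E[1 / d_g],
#' where theta is the porosity and the expectation runs over the grain-size
#' distribution.  The default path evaluates the empirical mean of `1/d_g`
#' over the supplied diameters; alternatively a fitted probability density
#' `p(d)` can be integrated numerically.
#'
#' @param diameters_um grain diameters in micrometres (sample list), or
#'   `NULL` when a `density` function is supplied.
#' @param porosity sediment porosity, in (0, 1).
#' @param density optional probability density function of the diameter in
#'   micrometres (normalised to integrate to 1 over `support`).
#' @param support numeric length-2 integration range (um) for `density`.
#' @return surface-to-volume ratio in cm^2 cm^-3.
#' @examples
#' surface_to_volume(290, porosity = 0.4)   # monodisperse: ~124 cm2/cm3
#' @export
surface_to_volume <- function(diameters_um = NULL, porosity,
                              density = NULL, support = NULL) {
  if (!is.numeric(porosity) || length(porosity) != 1L ||
      porosity <= 0 || porosity >= 1)
    stop("`porosity` must lie strictly between 0 and 1", call. = FALSE)
  if (is.null(diameters_um) && is.null(density))
    stop("supply either `diameters_um` or `density`", call. = FALSE)
  if (!is.null(density)) {
    if (is.null(support) || length(support) != 2L)
      stop("`support` (um) is required with a fitted density", call. = FALSE)
    norm <- stats::integrate(density, support[1], support[2],
                             rel.tol = 1e-8)$value
    if (abs(norm - 1) > 1e-6)
      stop("`density` must integrate to 1 over `support` (got ",
           signif(norm, 6), ")", call. = FALSE)
    mean_inv_um <- stats::integrate(function(d) density(d) / d,
                                    support[1], support[2],
                                    rel.tol = 1e-8)$value
  } else {
    if (length(diameters_um) == 0L)
      stop("empty grain-size distribution", call. = FALSE)
    if (any(!is.finite(diameters_um)) || any(diameters_um <= 0))
      stop("all diameters must be positive and finite", call. = FALSE)
    mean_inv_um <- mean(1 / diameters_um)
  }
  # 1/um -> 1/cm
  6 * (1 - porosity) * mean_inv_um * UM_PER_CM
}

#' Porosity from a wet/dry drying measurement
#'
#' The void volume is the evaporated water mass divided by the water density;
#' porosity is void volume over total sample volume.
#'
#' @param total_volume_ml total saturated sample volume, ml.
#' @param wet_mass_g,dry_mass_g sample mass before and after drying, g.
#' @param water_density_g_per_ml water density, g ml^-1.
#' @return porosity (dimensionless fraction in (0, 1)).
#' @export
porosity_from_drying <- function(total_volume_ml, wet_mass_g, dry_mass_g,
                                 water_density_g_per_ml = 1.0) {
  stopifnot_scalar_positive(total_volume_ml, "total_volume_ml")
  if (wet_mass_g < dry_mass_g)
    stop("wet mass must be >= dry mass", call. = FALSE)
  theta <- ((wet_mass_g - dry_mass_g) / water_density_g_per_ml) /
    total_volume_ml
  if (theta <= 0 || theta >= 1)
    stop("invalid measurement: porosity ", signif(theta, 4),
         " outside (0, 1)", call. = FALSE)
  theta
}

#' Volumetric cell density from areal density
#'
#' @param areal_cells_per_cm2 cells per cm^2 of grain surface.
#' @param surface_to_volume_cm2_cm3 grain surface per sediment volume.
#' @return cells per cm^3 of sediment.
#' @export
cells_per_volume <- function(areal_cells_per_cm2, surface_to_volume_cm2_cm3) {
  if (any(areal_cells_per_cm2 < 0) || any(surface_to_volume_cm2_cm3 < 0))
    stop("densities must be non-negative", call. = FALSE)
  areal_cells_per_cm2 * surface_to_volume_cm2_cm3
}

#' Cell-specific O2 rate from a bulk volumetric rate
#'
#' Converts a pore-water volumetric rate (umol O2 L^-1 h^-1, negative for
#' consumption) into a per-cell rate by dividing by the volumetric cell
#' density; 1 umol L^-1 = 1e-9 mol cm^-3.
#'
#' @param bulk_rate_umol_L_h volumetric rate, umol O2 L^-1 h^-1.
#' @param cells_per_cm3 volumetric cell density, cells cm^-3.
#' @return cell-specific rate in fmol O2 cell^-1 h^-1 (sign preserved).
#' @examples
#' cell_specific_rate(-46, 1.3e8)   # about -0.35 fmol/cell/h
#' @export
cell_specific_rate <- function(bulk_rate_umol_L_h, cells_per_cm3) {
  stopifnot_scalar_positive(cells_per_cm3, "cells_per_cm3")
  # umol/L/h = 1e-9 mol cm^-3 h^-1; /cells -> mol cell^-1 h^-1; *1e15 -> fmol
  bulk_rate_umol_L_h * 1e-9 / cells_per_cm3 * 1e15
}

#' Colony volumetric rate from a cell-specific rate
#'
#' Divides a cell-specific rate by the characteristic cell biovolume, giving
#' the rate per litre of colony biovolume (densely packed cells).
#'
#' @param cell_rate_fmol_h cell-specific rate, fmol O2 cell^-1 h^-1.
#' @param biovolume_um3 characteristic cell biovolume, um^3 (default 0.4).
#' @return volumetric colony rate in mmol O2 L^-1 h^-1.
#' @examples
#' colony_volumetric_rate(-0.354)   # about -885 mmol/L/h
#' @export
colony_volumetric_rate <- function(cell_rate_fmol_h, biovolume_um3 = 0.4) {
  stopifnot_scalar_positive(biovolume_um3, "biovolume_um3")
  # fmol / um^3 = 1e-12 mmol / 1e-15 L = 1e3 mmol L^-1
  cell_rate_fmol_h / biovolume_um3 * 1e3
}

# --- convex-hull roughness --------------------------------------------------

# area centroid of a simple polygon (vertices as two-column matrix, not closed)
polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  area <- sum(cross) / 2
  if (abs(area) < .Machine$double.eps)
    stop("degenerate polygon with zero area", call. = FALSE)
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * area)
}

# TRUE when two closed segments properly intersect (shared endpoints excluded
# by the caller's adjacency filter)
segments_intersect <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

is_simple_polygon <- function(xy) {
  n <- nrow(xy)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (shared vertex) including the wrap-around pair
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(xy[idx[i, 1], ], xy[idx[i, 2], ],
                             xy[idx[j, 1], ], xy[idx[j, 2], ]))
        return(FALSE)
    }
  }
  TRUE
}

# radial distance from `origin` to the convex hull boundary along angle phi
hull_radius_at <- function(hull_xy, origin, phi) {
  u <- cbind(cos(phi), sin(phi))
  n <- nrow(hull_xy)
  nxt <- c(seq_len(n)[-1], 1L)
  out <- numeric(length(phi))
  for (k in seq_along(phi)) {
    best <- NA_real_
    for (e in seq_len(n)) {
      a <- hull_xy[e, ] - origin
      b <- hull_xy[nxt[e], ] - origin
      # solve a + s (b - a) = t u, s in [0,1], t > 0
      det <- (b[1] - a[1]) * (-u[k, 2]) - (b[2] - a[2]) * (-u[k, 1])
      if (abs(det) < 1e-300) next
      s <- (-a[1] * (-u[k, 2]) - (-a[2]) * (-u[k, 1])) / det
      t <- ((b[1] - a[1]) * (-a[2]) - (b[2] - a[2]) * (-a[1])) / det
      if (s >= -1e-12 && s <= 1 + 1e-12 && t > 0)
        best <- if (is.na(best)) t else max(best, t)
    }
    out[k] <- best
  }
  out
}

#' Convex-hull surface roughness of a grain outline
#'
#' Roughness is the radial difference between the grain outline and its
#' convex hull: from the outline's area centroid, each vertex's radial
#' distance is subtracted from the hull boundary's radial distance at the
#' same polar angle (hull edges interpolated linearly).  Deviations are
#' reported as magnitudes; they are identically zero for convex outlines.
#'
#' @param outline two-column matrix or data frame of vertex coordinates in
#'   micrometres (open ring, first vertex not repeated).
#' @return an object of class `roughness_profile`: list with per-vertex
#'   `deviation_um`, vertex `angle_rad`, and `mean_um`, `max_um` summaries.
#' @export
grain_roughness <- function(outline) {
  xy <- as.matrix(outline[, 1:2])
  storage.mode(xy) <- "double"
  # drop a repeated closing vertex if present
  n <- nrow(xy)
  if (n >= 2L && all(abs(xy[n, ] - xy[1, ]) < 1e-12)) xy <- xy[-n, , drop = FALSE]
  if (nrow(xy) < 3L) stop("outline needs at least 3 vertices", call. = FALSE)
  if (!is_simple_polygon(xy))
    stop("outline polygon is self-intersecting", call. = FALSE)
  ctr <- polygon_centroid(xy)
  rel <- sweep(xy, 2, ctr)
  r_v <- sqrt(rowSums(rel^2))
  phi <- atan2(rel[, 2], rel[, 1])
  hull <- xy[grDevices::chull(xy[, 1], xy[, 2]), , drop = FALSE]
  r_h <- hull_radius_at(hull, ctr, phi)
  dev <- pmax(r_h - r_v, 0)
  dev[dev < 1e-9] <- 0  # clip numerical residue on hull vertices
  structure(list(deviation_um = dev, angle_rad = phi,
                 mean_um = mean(dev), max_um = max(dev)),
            class = "roughness_profile")
}

#' @export
print.roughness_profile <- function(x, ...) {
  cat(sprintf(
    "Grain roughness profile: %d vertices, mean %.2f um, max %.2f um\n",
    length(x$deviation_um), x$mean_um, x$max_um))
  invisible(x)
}
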