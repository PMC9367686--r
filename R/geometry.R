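# Attached-cell irradiation geometry and the geometric sampling/scoring
# kernels of the Monte Carlo: uniform source positions in the medium,
# isotropic directions, and ray-ellipsoid chord lengths.

MEV_TO_J <- 1.602176e-13
UM3_TO_ML <- 1e-12  # 1 um^3 = 1e-12 cm^3 = 1e-12 ml

#' Attached-cell culture-well geometry
#'
#' A cell attached to the bottom of a culture well, modelled as a
#' semi-ellipsoid (the upper half of an ellipsoid cut at the well bottom,
#' z = 0) containing a full-ellipsoid nucleus, inside a cylindrical volume
#' of culture medium. Default dimensions: cell 20 um lateral diameter and
#' 7.8 um height, nucleus 6 um lateral diameter and 3 um height centred on
#' the cell axis at half the cell height, medium cylinder 200 um diameter
#' and 100 um height. All lengths in um; all media are water at 1.0 g/cm^3.
#'
#' @param cell_diameter_um,cell_height_um Lateral diameter and height of the
#'   semi-ellipsoidal cell.
#' @param nucleus_diameter_um,nucleus_height_um Lateral diameter and full
#'   height of the ellipsoidal nucleus.
#' @param nucleus_center_z_um Height of the nucleus centre above the well
#'   bottom; defaults to `cell_height_um / 2` ("centred at the middle of
#'   the cell").
#' @param well_diameter_um,well_height_um Diameter and height of the
#'   cylindrical medium volume.
#' @return Object of class `cell_geometry` with derived fields:
#'   `nucleus_volume_um3`, `nucleus_mass_kg`, `well_volume_um3`,
#'   `well_volume_ml`, `cell_volume_um3`, and the semi-axis vectors.
#' @examples
#' geom <- cell_geometry()
#' geom$nucleus_volume_um3  # (4/3) * pi * 3 * 3 * 1.5
#' @export
cell_geometry <- function(cell_diameter_um = 20, cell_height_um = 7.8,
                          nucleus_diameter_um = 6, nucleus_height_um = 3,
                          nucleus_center_z_um = cell_height_um / 2,
                          well_diameter_um = 200, well_height_um = 100) {
  stopifnot(cell_diameter_um > 0, cell_height_um > 0,
            nucleus_diameter_um > 0, nucleus_height_um > 0,
            well_diameter_um > 0, well_height_um > 0)
  cell_semi <- c(cell_diameter_um / 2, cell_diameter_um / 2, cell_height_um)
  nuc_semi <- c(nucleus_diameter_um / 2, nucleus_diameter_um / 2,
                nucleus_height_um / 2)
  nuc_center <- c(0, 0, nucleus_center_z_um)

  # nucleus fully inside the cell: check the worst-case scaled support
  # function of the nucleus ellipsoid against the cell ellipsoid
  corners <- rbind(
    nuc_center + c(nuc_semi[1], 0, 0), nuc_center - c(nuc_semi[1], 0, 0),
    nuc_center + c(0, nuc_semi[2], 0), nuc_center - c(0, nuc_semi[2], 0),
    nuc_center + c(0, 0, nuc_semi[3]), nuc_center - c(0, 0, nuc_semi[3]))
  q <- (corners[, 1] / cell_semi[1])^2 + (corners[, 2] / cell_semi[2])^2 +
    (corners[, 3] / cell_semi[3])^2
  if (any(corners[, 3] < 0) || any(q > 1)) {
    stop("nucleus is not fully contained in the cell semi-ellipsoid")
  }
  if (cell_diameter_um / 2 > well_diameter_um / 2 ||
      cell_height_um > well_height_um) {
    stop("cell is not contained in the well cylinder")
  }

  structure(list(
    cell_semi_axes_um = cell_semi,
    nucleus_semi_axes_um = nuc_semi,
    nucleus_center_um = nuc_center,
    well_radius_um = well_diameter_um / 2,
    well_height_um = well_height_um,
    cell_volume_um3 = 2 / 3 * pi * prod(cell_semi),
    nucleus_volume_um3 = 4 / 3 * pi * prod(nuc_semi),
    nucleus_mass_kg = 4 / 3 * pi * prod(nuc_semi) * 1e-15,  # um^3 x 1 g/cm^3
    well_volume_um3 = pi * (well_diameter_um / 2)^2 * well_height_um,
    well_volume_ml = pi * (well_diameter_um / 2)^2 * well_height_um * UM3_TO_ML),
    class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("Attached-cell well geometry (lengths in um)\n")
  cat(sprintf("  cell semi-axes: %s | nucleus semi-axes: %s at z = %.2f\n",
              paste(signif(x$cell_semi_axes_um, 3), collapse = " x "),
              paste(signif(x$nucleus_semi_axes_um, 3), collapse = " x "),
              x$nucleus_center_um[3]))
  cat(sprintf("  medium cylinder: r = %.0f, h = %.0f (%.3g ml); nucleus mass %.3g kg\n",
              x$well_radius_um, x$well_height_um, x$well_volume_ml,
              x$nucleus_mass_kg))
  invisible(x)
}

#' Check that the well boundary cannot truncate tracks reaching the nucleus
#'
#' The dose factor reconstruction drops particles at the cylinder boundary;
#' this is loss-free for the nucleus provided the lateral and vertical
#' clearance between nucleus and boundary exceeds the maximum alpha range.
#'
#' @param geometry A [cell_geometry()].
#' @param max_range_um Maximum CSDA range of the emitted alphas, um.
#' @return `TRUE` (invisibly) if loss-free; otherwise a warning is raised
#'   and `FALSE` returned.
#' @export
validate_geometry <- function(geometry, max_range_um) {
  stopifnot(inherits(geometry, "cell_geometry"))
  lateral <- geometry$well_radius_um -
    max(geometry$nucleus_semi_axes_um[1:2])
  vertical <- geometry$well_height_um -
    (geometry$nucleus_center_um[3] + geometry$nucleus_semi_axes_um[3])
  ok <- lateral > max_range_um && vertical > max_range_um
  if (!ok) {
    warning("well boundary is within alpha range of the nucleus; ",
            "dose factor may be truncated")
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

#' Test whether points lie inside the cell semi-ellipsoid
#'
#' @param points Numeric `n x 3` matrix of coordinates in um.
#' @param geometry A [cell_geometry()].
#' @return Logical vector.
#' @export
point_in_cell <- function(points, geometry) {
  points <- rbind(points)
  a <- geometry$cell_semi_axes_um
  points[, 3] >= 0 &
    (points[, 1] / a[1])^2 + (points[, 2] / a[2])^2 + (points[, 3] / a[3])^2 <= 1
}

#' Sample uniform source positions in the medium outside the cell
#'
#' Decay positions are uniform over the cylindrical medium volume with the
#' cell region excluded (emissions only occur outside the cell), drawn by
#' rejection sampling; the acceptance probability is
#' `1 - V_cell / V_well` (~99.97% for the defaults).
#'
#' @param n Number of positions.
#' @param geometry A [cell_geometry()].
#' @return Numeric `n x 3` matrix of positions in um.
#' @export
sample_source_position <- function(n, geometry = cell_geometry()) {
  stopifnot(n >= 1)
  out <- matrix(NA_real_, nrow = n, ncol = 3)
  filled <- 0L
  while (filled < n) {
    m <- n - filled
    r <- geometry$well_radius_um * sqrt(stats::runif(m))
    th <- stats::runif(m, 0, 2 * pi)
    p <- cbind(r * cos(th), r * sin(th),
               stats::runif(m, 0, geometry$well_height_um))
    keep <- !point_in_cell(p, geometry)
    k <- sum(keep)
    if (k > 0) {
      out[(filled + 1L):(filled + k), ] <- p[keep, , drop = FALSE]
      filled <- filled + k
    }
  }
  out
}

#' Sample isotropic unit direction vectors
#'
#' Uniform on the unit sphere: cos(theta) uniform on [-1, 1], azimuth
#' uniform on [0, 2*pi).
#'
#' @param n Number of directions.
#' @return Numeric `n x 3` matrix of unit vectors.
#' @export
sample_isotropic_direction <- function(n) {
  stopifnot(n >= 1)
  cz <- stats::runif(n, -1, 1)
  sz <- sqrt(pmax(1 - cz^2, 0))
  phi <- stats::runif(n, 0, 2 * pi)
  cbind(sz * cos(phi), sz * sin(phi), cz)
}

#' Forward chord of rays through an ellipsoid
#'
#' Intersects rays `origin + s * direction`, `s >= 0`, with an axis-aligned
#' ellipsoid by solving the quadratic in ellipsoid-scaled coordinates.
#' Returns the forward-directed intersection interval clipped at `s = 0`;
#' degenerate tangential grazes with chord shorter than `tangent_eps_um`
#' are treated as misses.
#'
#' @param origin,direction Numeric `n x 3` matrices (directions must be
#'   unit vectors so that `s` is a path length in um).
#' @param center Length-3 centre of the ellipsoid, um.
#' @param semi_axes Length-3 semi-axes, um.
#' @param tangent_eps_um Minimum chord length counted as a hit (default
#'   1 nm).
#' @return `n x 2` matrix with columns `s_entry`, `s_exit` (um); both `NA`
#'   where the ray misses.
#' @export
ray_ellipsoid_chord <- function(origin, direction, center, semi_axes,
                                tangent_eps_um = 1e-3) {
  origin <- rbind(origin)
  direction <- rbind(direction)
  ox <- (origin[, 1] - center[1]) / semi_axes[1]
  oy <- (origin[, 2] - center[2]) / semi_axes[2]
  oz <- (origin[, 3] - center[3]) / semi_axes[3]
  dx <- direction[, 1] / semi_axes[1]
  dy <- direction[, 2] / semi_axes[2]
  dz <- direction[, 3] / semi_axes[3]
  A <- dx^2 + dy^2 + dz^2
  B <- 2 * (ox * dx + oy * dy + oz * dz)
  C <- ox^2 + oy^2 + oz^2 - 1
  disc <- B^2 - 4 * A * C
  hit <- disc > 0
  s1 <- s2 <- rep(NA_real_, nrow(origin))
  sq <- sqrt(disc[hit])
  s1[hit] <- (-B[hit] - sq) / (2 * A[hit])
  s2[hit] <- (-B[hit] + sq) / (2 * A[hit])
  s1 <- pmax(s1, 0)
  miss <- !is.na(s2) & (s2 <= 0 | (s2 - s1) < tangent_eps_um)
  s1[miss] <- NA_real_
  s2[miss] <- NA_real_
  cbind(s_entry = s1, s_exit = s2)
}
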