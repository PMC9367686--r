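# Shared fixtures and independent numerical oracles. The oracles
# deliberately avoid the package's interpolation/grid machinery: adaptive
# quadrature for ranges, fixed-step Euler integration for slowing-down,
# and inside/outside stepping for chords.

spm <- stopping_power_model()
geom <- cell_geometry()
cascade <- ra223_cascade()

# CSDA range by adaptive quadrature of 1/S (um); the sub-anchor tail
# S = S_min * sqrt(E/E_min) integrates in closed form to 2*E_min/S_min
oracle_range <- function(E, model = spm) {
  e_min <- model$e_min
  tail_um <- 2 * e_min / model$s_of_e(e_min)
  1000 * (tail_um +
            stats::integrate(function(e) 1 / model$s_of_e(e), e_min, E,
                             subdivisions = 2000L, rel.tol = 1e-9)$value)
}

# residual energy after path s by fixed-step Euler integration of
# dE = -S(E) ds (step in um; default 1 nm)
oracle_energy_after_path <- function(E0, s, model = spm, step = 1e-3) {
  E <- E0
  n <- ceiling(s / step)
  ds <- s / n
  for (i in seq_len(n)) {
    E <- E - model$s_of_e(E) * ds / 1000  # keV/um * um -> MeV
    if (E <= model$e_min) return(0)
  }
  E
}

# entry/exit path lengths through an ellipsoid by inside/outside stepping
oracle_chord <- function(origin, direction, center, semi_axes,
                         s_max, step = 0.01) {
  s <- seq(0, s_max, by = step)
  p <- cbind(origin[1] + s * direction[1],
             origin[2] + s * direction[2],
             origin[3] + s * direction[3])
  inside <- ((p[, 1] - center[1]) / semi_axes[1])^2 +
    ((p[, 2] - center[2]) / semi_axes[2])^2 +
    ((p[, 3] - center[3]) / semi_axes[3])^2 <= 1
  if (!any(inside)) return(c(NA_real_, NA_real_))
  c(s[which(inside)[1]], s[rev(which(inside))[1]])
}
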