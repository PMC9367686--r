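test_that("geometry derives volumes, masses and containment", {
  expect_equal(geom$nucleus_volume_um3, 4 / 3 * pi * 3 * 3 * 1.5)
  expect_equal(geom$nucleus_mass_kg, geom$nucleus_volume_um3 * 1e-15)
  expect_equal(geom$well_volume_ml, pi * 100^2 * 100 * 1e-12)
  expect_equal(geom$nucleus_center_um[3], 3.9)
  # nucleus outside the cell is rejected
  expect_error(cell_geometry(nucleus_center_z_um = 7.5), "contained")
  # boundary-loss-free for the default geometry at the longest alpha range
  expect_true(validate_geometry(geom, csda_range(7.45, spm)))
  expect_warning(validate_geometry(geom, 99), "boundary")
})

test_that("source positions are uniform in the medium and never in the cell", {
  set.seed(5)
  p <- sample_source_position(1e5, geom)
  expect_false(any(point_in_cell(p, geom)))
  expect_true(all(p[, 1]^2 + p[, 2]^2 <= geom$well_radius_um^2))
  expect_true(all(p[, 3] >= 0 & p[, 3] <= geom$well_height_um))
  # z uniform outside the cell-occupied strata (lateral radius > cell)
  far <- sqrt(p[, 1]^2 + p[, 2]^2) > geom$cell_semi_axes_um[1]
  ks <- suppressWarnings(ks.test(p[far, 3], "punif", 0, 100))
  expect_gt(ks$p.value, 0.01)
  # squared radius uniform -> areal uniformity (above the cell stratum,
  # where the full disk is source volume)
  above <- p[, 3] > geom$cell_semi_axes_um[3]
  ks2 <- suppressWarnings(ks.test((p[, 1]^2 + p[, 2]^2)[above], "punif",
                                  0, geom$well_radius_um^2))
  expect_gt(ks2$p.value, 0.001)
})

test_that("with a negligible cell the mean position is the cylinder centroid", {
  tiny <- cell_geometry(cell_diameter_um = 0.02, cell_height_um = 0.02,
                        nucleus_diameter_um = 0.008,
                        nucleus_height_um = 0.008,
                        nucleus_center_z_um = 0.01)
  set.seed(6)
  p <- sample_source_position(2e4, tiny)
  se_xy <- sd(p[, 1]) / sqrt(nrow(p))
  expect_lt(abs(mean(p[, 1])), 3 * se_xy)
  expect_lt(abs(mean(p[, 2])), 3 * se_xy)
  expect_lt(abs(mean(p[, 3]) - 50), 3 * sd(p[, 3]) / sqrt(nrow(p)))
})

test_that("directions are unit vectors uniform on the sphere", {
  set.seed(7)
  d <- sample_isotropic_direction(1e5)
  expect_equal(max(abs(rowSums(d^2) - 1)), 0, tolerance = 1e-12)
  for (j in 1:3) {
    expect_lt(abs(mean(d[, j])), 3 / sqrt(3 * 1e5))  # sd of a comp ~ 1/sqrt(3)
  }
  # cos(theta) flat: chi-square over 20 bins
  h <- table(cut(d[, 3], seq(-1, 1, length.out = 21)))
  chi <- chisq.test(h)
  expect_gt(chi$p.value, 0.01)
})

test_that("ray-ellipsoid chords solve the forward intersection", {
  # central ray through a sphere: chord = 2r
  ch <- ray_ellipsoid_chord(c(-10, 0, 0), c(1, 0, 0), c(0, 0, 0), c(3, 3, 3))
  expect_equal(unname(ch[1, 2] - ch[1, 1]), 6, tolerance = 1e-12)
  expect_equal(unname(ch[1, 1]), 7, tolerance = 1e-12)
  # parallel ray offset beyond the semi-axis misses
  miss <- ray_ellipsoid_chord(c(-10, 3.5, 0), c(1, 0, 0), c(0, 0, 0),
                              c(3, 3, 3))
  expect_true(all(is.na(miss)))
  # ray pointing away (backward intersection only) misses
  back <- ray_ellipsoid_chord(c(-10, 0, 0), c(-1, 0, 0), c(0, 0, 0),
                              c(3, 3, 3))
  expect_true(all(is.na(back)))
  # origin inside: entry clipped to 0
  inside <- ray_ellipsoid_chord(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0),
                                c(3, 3, 3))
  expect_equal(unname(inside[1, 1]), 0)
  expect_equal(unname(inside[1, 2]), 3, tolerance = 1e-12)
})

test_that("chords agree with an inside/outside stepping oracle", {
  set.seed(8)
  n <- 1000
  center <- geom$nucleus_center_um
  axes <- geom$nucleus_semi_axes_um
  # origins on a shell, directions biased at the nucleus so many rays hit
  org <- sample_source_position(n, geom)
  aim <- center + matrix(runif(3 * n, -4, 4), ncol = 3)
  dir <- aim - org
  dir <- dir / sqrt(rowSums(dir^2))
  ch <- ray_ellipsoid_chord(org, dir, center, axes)
  n_hit <- 0
  for (i in seq_len(n)) {
    s_max <- sqrt(sum((org[i, ] - center)^2)) + 10
    oc <- oracle_chord(org[i, ], dir[i, ], center, axes, s_max)
    if (is.na(oc[1])) {
      # stepping can only miss chords shorter than its own step
      if (!is.na(ch[i, 1])) expect_lt(ch[i, 2] - ch[i, 1], 0.02)
    } else {
      n_hit <- n_hit + 1
      expect_lt(abs(ch[i, 1] - oc[1]), 0.02)
      expect_lt(abs(ch[i, 2] - oc[2]), 0.02)
    }
  }
  expect_gt(n_hit, 100)  # the aiming scheme must actually exercise hits
})
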