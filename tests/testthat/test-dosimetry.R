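test_that("cascades beyond alpha range deposit nothing", {
  # positions > 75 um from the nucleus centre (max range ~70 um)
  set.seed(21)
  for (i in 1:50) {
    u <- sample_isotropic_direction(1)[1, ]
    pos <- geom$nucleus_center_um + u * runif(1, 75, 95)
    pos[3] <- abs(pos[3])  # keep in upper half-space
    dep <- score_cascade(pos, sample_cascade(1, cascade)[1, ], geom, spm)
    expect_identical(dep, 0)
  }
})

test_that("deposits never exceed the cascade energy", {
  set.seed(22)
  n <- 500
  org <- sample_source_position(n, geom)
  # pull the emission points near the cell so hits are common
  org[, 1:2] <- org[, 1:2] * 0.15
  org[, 3] <- org[, 3] * 0.15
  keep <- !point_in_cell(org, geom)
  org <- org[keep, , drop = FALSE]
  E <- sample_cascade(nrow(org), cascade)
  deps <- vapply(seq_len(nrow(org)), function(i) {
    score_cascade(org[i, ], E[i, ], geom, spm)
  }, 0)
  expect_true(all(deps >= 0))
  expect_true(all(deps <= rowSums(E) + 1e-12))
  expect_gt(sum(deps > 0), 0)
})

test_that("a fully stopping alpha deposits its full residual entry energy", {
  # straight down the axis from above the cell; a 2 MeV alpha (range
  # ~12.6 um) never survives the 14.6 um approach to the nucleus, while a
  # 2.4 MeV alpha (~15.6 um) enters and stops inside it
  pos <- c(0, 0, 20)
  dir <- matrix(c(0, 0, -1), 1)
  s_entry <- 20 - (3.9 + 1.5)
  e_entry <- energy_after_path(2.4, s_entry, spm)
  expect_gt(e_entry, 0)
  expect_lt(csda_range(2.4, spm), 20 - (3.9 - 1.5))  # stops before exit
  dep <- score_cascade(pos, 2.4, geom, spm, directions = dir)
  expect_equal(dep, e_entry, tolerance = 1e-9)
  expect_identical(score_cascade(pos, 2.0, geom, spm, directions = dir), 0)
})

test_that("a central chord deposit matches the quadrature/stepping oracle", {
  pos <- c(0, 0, 20)
  dir <- matrix(c(0, 0, -1), 1)
  s_entry <- 20 - (3.9 + 1.5)
  s_exit <- 20 - (3.9 - 1.5)
  dep <- score_cascade(pos, 6.0, geom, spm, directions = dir)
  e_in <- oracle_energy_after_path(6.0, s_entry)
  e_out <- oracle_energy_after_path(6.0, s_exit)
  expect_equal(dep, e_in - e_out, tolerance = 5e-3)
})

test_that("the simulation is reproducible and batch-structured", {
  r1 <- run_dosimetry(n_cascades = 2e4, n_batches = 3, geometry = geom,
                      physics = spm, seed = 123)
  r2 <- run_dosimetry(n_cascades = 2e4, n_batches = 3, geometry = geom,
                      physics = spm, seed = 123)
  expect_identical(r1$dose_factor_Gy_per_decay_ml,
                   r2$dose_factor_Gy_per_decay_ml)
  expect_identical(r1$batch_dose_factors, r2$batch_dose_factors)
  expect_length(r1$batch_dose_factors, 3)
  expect_gte(r1$nucleus_hit_fraction, 0)
  expect_lte(r1$nucleus_hit_fraction, 1)
  expect_gt(r1$dose_factor_Gy_per_decay_ml, 0)
  expect_warning(run_dosimetry(n_cascades = 1e4, n_batches = 1,
                               geometry = geom, physics = spm, seed = 1),
                 "standard error")
})

test_that("the dose factor has the right order of magnitude at small n", {
  r <- run_dosimetry(n_cascades = 1e5, n_batches = 5, geometry = geom,
                     physics = spm, seed = 31)
  # infinite-medium equilibrium bound: c*E_tot/rho = 4.28e-9 Gy per
  # decay/ml; the half-space value is about half of that
  expect_gt(r$dose_factor_Gy_per_decay_ml, 1e-9)
  expect_lt(r$dose_factor_Gy_per_decay_ml, 4.3e-9)
  # mean nucleus energy per cascade ~ 250 eV
  e_mean_eV <- r$dose_factor_Gy_per_decay_ml * geom$nucleus_mass_kg /
    geom$well_volume_ml / 1.602176e-19
  expect_gt(e_mean_eV, 100)
  expect_lt(e_mean_eV, 600)
})

test_that("added medium beyond alpha range does not change the dose factor", {
  tall <- cell_geometry(well_height_um = 200)
  r1 <- run_dosimetry(n_cascades = 2e5, n_batches = 5, geometry = geom,
                      physics = spm, seed = 17)
  r2 <- run_dosimetry(n_cascades = 4e5, n_batches = 5, geometry = tall,
                      physics = spm, seed = 18)
  tol <- 2 * sqrt(r1$standard_error^2 + r2$standard_error^2)
  expect_lt(abs(r1$dose_factor_Gy_per_decay_ml -
                  r2$dose_factor_Gy_per_decay_ml), tol)
})

test_that("batch spread shrinks with batch size", {
  r_small <- run_dosimetry(n_cascades = 2e4, n_batches = 5, geometry = geom,
                           physics = spm, seed = 41)
  r_big <- run_dosimetry(n_cascades = 2e5, n_batches = 5, geometry = geom,
                         physics = spm, seed = 42)
  expect_lt(r_big$standard_error, r_small$standard_error)
})

test_that("dosimetry results serialise to JSON with all fields", {
  r <- run_dosimetry(n_cascades = 1e4, n_batches = 2, geometry = geom,
                     physics = spm, seed = 2)
  path <- tempfile(fileext = ".json")
  write_dosimetry_json(r, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$dose_factor_Gy_per_decay_ml,
               r$dose_factor_Gy_per_decay_ml)
  expect_length(parsed$batch_dose_factors, 2)
  expect_equal(parsed$seed, 2)
})
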