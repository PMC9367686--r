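test_that("clonogenic counts have the LQ-Poisson structure", {
  set.seed(101)
  d <- gen_clonogenic(1.97, 0, doses_Gy = c(0, 0.5), n_replicates = 1e4,
                      pe = 0.5, n_seeded = 1000)
  # unirradiated wells: expected colonies = seeded * PE
  c0 <- d$colonies[d$dose == 0]
  expect_lt(abs(mean(c0) - 500), 3 * sd(c0) / sqrt(length(c0)))
  # mean SF at 0.5 Gy matches the closed form exp(-0.985) = 0.373
  sf <- surviving_fraction(d$colonies[d$dose == 0.5], 1000, 0.5)
  expect_lt(abs(mean(sf) - exp(-0.985)), 3 * sd(sf) / sqrt(length(sf)))
})

test_that("adaptive seeding keeps expected colony counts near target", {
  set.seed(102)
  d <- gen_clonogenic(0.47, 0.05, doses_Gy = c(0, 2, 4, 8),
                      target_colonies = 100)
  mean_by_dose <- tapply(d$colonies, d$dose, mean)
  expect_true(all(mean_by_dose > 30 & mean_by_dose < 300))
})

test_that("foci counts decay to background plus plateau", {
  set.seed(103)
  tab <- gen_foci_timecourse(dose_Gy = 1, n0_per_Gy = 20,
                             plateau_fraction = 0.2, k = 0.36,
                             background = 3.1, times_h = c(1, 200),
                             n_cells = 1e4)
  late <- tab$foci[tab$time_h == 200]
  expect_lt(abs(mean(late) - (3.1 + 0.2 * 20)),
            3 * sd(late) / sqrt(length(late)))
  early <- tab$foci[tab$time_h == 1]
  mu1 <- 3.1 + (20 - 4) * exp(-0.36) + 4
  expect_lt(abs(mean(early) - mu1), 3 * sd(early) / sqrt(length(early)))
})

test_that("modality scaling reduces induction for alpha emitters", {
  set.seed(104)
  mk <- function(mod) {
    tab <- gen_foci_timecourse(dose_Gy = 1, modality = mod, n_cells = 2000,
                               times_h = 1)
    mean(tab$foci)
  }
  x <- mk("xray"); ra <- mk("ra223"); al <- mk("alpha")
  expect_gt(x, ra)
  expect_gt(ra, al)
})

test_that("generated control cohorts classify as nearly all normal", {
  set.seed(105)
  frac_normal <- replicate(20, {
    rec <- gen_nuclei(200)
    mean(classify_nucleus(rec$area_um2, exp(log(120) + 0.25^2 / 2),
                          rec$lobes) == "normal")
  })
  expect_true(all(frac_normal >= 0.97))
  # planted zero fractions stay zero
  rec <- gen_nuclei(500, giant_fraction = 0, aberrant_fraction = 0)
  out <- morphology_rates(rec, control_mean_area = exp(log(120) + 0.25^2 / 2),
                          by = "dose")
  expect_equal(out$pct_aberrant, 0)
})

test_that("generators are deterministic under a fixed seed", {
  set.seed(7); a <- gen_clonogenic(0.47, 0.05)
  set.seed(7); b <- gen_clonogenic(0.47, 0.05)
  expect_identical(a, b)
  s1 <- synthetic_study("U2OS", seed = 3)
  s2 <- synthetic_study("U2OS", seed = 3)
  expect_identical(s1, s2)
})

test_that("a full synthetic study reproduces the headline orderings", {
  study <- synthetic_study("PC-3", seed = 1)
  sv <- study$survival
  fx <- fit_lq(sv[sv$modality == "xray", ])
  fa <- fit_lq(sv[sv$modality == "alpha", ])
  fr <- fit_lq(sv[sv$modality == "ra223", ])
  rbe_ra <- rbe(fx, fr)$rbe
  rbe_al <- rbe(fx, fa)$rbe
  expect_gt(rbe_ra, rbe_al)
  expect_gt(rbe_al, 1)

  bg <- reference_baseline_foci()
  bg <- bg$baseline[bg$cell_line == "PC-3"]
  resid <- sapply(c("xray", "alpha", "ra223"), function(mod) {
    m <- foci_means(study$foci[study$foci$condition == mod, ])
    fit_repair(m$time_h, m$mean_foci, baseline = bg)$residual_fraction
  })
  expect_gt(resid["alpha"], resid["xray"])
  expect_gt(resid["ra223"], resid["xray"])
})
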