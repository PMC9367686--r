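test_that("surviving fraction corrects colony counts for plating efficiency", {
  expect_equal(surviving_fraction(50, 100, 0.5), 1.0)
  expect_equal(surviving_fraction(10, 1000, 0.5), 0.02)
  # unirradiated control with PE computed from itself is 1 by construction
  pe <- 37 / 100
  expect_equal(surviving_fraction(37, 100, pe), 1.0)
  expect_error(surviving_fraction(5, 0, 0.5), "seeded")
  expect_error(surviving_fraction(5, 100, 1.5), "efficiency")
})

test_that("noiseless LQ curves are recovered to numerical precision", {
  doses <- c(0, 0.5, 1, 2, 4, 6, 8)
  d <- data.frame(dose = doses, sf = sf_lq(doses, 0.47, 0.05))
  fit <- fit_lq(d)
  expect_equal(fit$alpha, 0.47, tolerance = 1e-6)
  expect_equal(fit$beta, 0.05, tolerance = 1e-6)
  expect_false(fit$beta_near_zero)
  # pure exponential survival reports beta as effectively zero
  d2 <- data.frame(dose = doses, sf = sf_lq(doses, 1.97, 0))
  fit2 <- fit_lq(d2)
  expect_equal(fit2$alpha, 1.97, tolerance = 1e-6)
  expect_true(fit2$beta_near_zero)
})

test_that("fit_lq validates its inputs", {
  expect_error(fit_lq(data.frame(dose = c(1, 2), sf = c(0.5, 0.2))),
               "3 distinct doses")
  d <- data.frame(dose = c(0, 1, 2, 4), sf = c(1, 0.5, 0, 0.1))
  expect_warning(fit <- fit_lq(d), "SF <= 0")
  expect_s3_class(fit, "lq_fit")
})

test_that("LQ fits on Poisson colony data cover the truth", {
  set.seed(314)
  alpha_t <- 0.47
  beta_t <- 0.05
  hits <- 0
  for (i in 1:100) {
    d <- gen_clonogenic(alpha_t, beta_t, doses_Gy = c(0, 0.5, 1, 2, 4, 6, 8))
    fit <- fit_lq(d)
    if (abs(fit$alpha - alpha_t) <= 2 * fit$alpha_se) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("D50 solves the iso-survival quadratic", {
  expect_equal(lq_d50(log(2), 0), 1.0)
  expect_equal(lq_d50(0.47, 0.05), 1.296, tolerance = 1e-3)
  expect_equal(lq_d50(4.01, 1.15), 0.165, tolerance = 1e-2)
  # self-consistency: SF at D50 is exactly the target level
  set.seed(9)
  for (i in 1:20) {
    a <- runif(1, 0.1, 5)
    b <- runif(1, 0, 1.5)
    expect_equal(sf_lq(lq_d50(a, b), a, b), 0.5, tolerance = 1e-10)
  }
  expect_error(lq_d50(0, 0), "not both zero")
})

test_that("RBE at 50% survival reproduces the published cell-line values", {
  pc3 <- rbe(list(alpha = 0.47, beta = 0.05), list(alpha = 4.01, beta = 1.15))
  expect_lt(abs(pc3$rbe - 7.8), 0.4)
  sjsa <- rbe(list(alpha = 0.28, beta = 0.03), list(alpha = 5.37, beta = 0))
  expect_lt(abs(sjsa$rbe - 15.8), 0.7)
  # identical fits give RBE 1; antisymmetry
  f <- list(alpha = 0.4, beta = 0.02)
  g <- list(alpha = 2.5, beta = 0)
  expect_equal(rbe(f, f)$rbe, 1.0)
  expect_equal(rbe(f, g)$rbe * rbe(g, f)$rbe, 1.0, tolerance = 1e-12)
})

test_that("all ten published RBE values are contained in their printed bands", {
  lq <- reference_lq_params()
  xr <- lq[lq$modality == "xray", ]
  hi <- lq[lq$modality != "xray", ]
  for (i in seq_len(nrow(hi))) {
    ref <- xr[xr$cell_line == hi$cell_line[i], ]
    r <- rbe(list(alpha = ref$alpha, beta = ref$beta),
             list(alpha = hi$alpha[i], beta = hi$beta[i]))
    expect_lte(abs(r$rbe - hi$rbe50[i]), hi$rbe50_unc[i])
  }
})
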