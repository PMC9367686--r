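# Linear-quadratic clonogenic survival: SF = exp(-(alpha*D + beta*D^2)),
# fitted in log space with non-negativity bounds, plus the iso-survival
# dose D50 and the relative biological effectiveness at 50% survival.

#' Surviving fraction from colony counts
#'
#' `SF = colonies / (seeded * plating_efficiency)`: colonies formed after
#' treatment divided by cells seeded, corrected for the plating efficiency
#' of unirradiated cells. Zero colonies give `SF = 0`, which log-space
#' fitting excludes with a warning.
#'
#' @param colonies Colony count (>= 50 cells per colony by convention).
#' @param seeded Number of cells seeded (> 0).
#' @param plating_efficiency Plating efficiency of unirradiated controls,
#'   in (0, 1].
#' @return Surviving fraction (vectorised).
#' @examples
#' surviving_fraction(50, 100, 0.5)  # 1
#' @export
surviving_fraction <- function(colonies, seeded, plating_efficiency) {
  if (any(seeded <= 0)) stop("seeded must be positive")
  if (any(plating_efficiency <= 0 | plating_efficiency > 1)) {
    stop("plating efficiency must lie in (0, 1]")
  }
  if (any(colonies < 0)) stop("colony counts must be non-negative")
  colonies / (seeded * plating_efficiency)
}

#' Linear-quadratic surviving fraction
#' @param dose_Gy Dose in Gy.
#' @param alpha,beta LQ parameters, 1/Gy and 1/Gy^2.
#' @return `exp(-(alpha*dose + beta*dose^2))`.
#' @export
sf_lq <- function(dose_Gy, alpha, beta = 0) {
  exp(-(alpha * dose_Gy + beta * dose_Gy^2))
}

#' Fit the linear-quadratic survival model
#'
#' Fits `ln SF = -(alpha*D + beta*D^2)` by bounded nonlinear least squares
#' (`alpha >= 0`, `beta >= 0`, Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]). Replicates at each dose are aggregated to the
#' mean log-survival. When `weighted = TRUE` and every dose carries at
#' least `weight_min_replicates` replicates with non-degenerate spread,
#' points are weighted by the reciprocal squared standard error of the
#' mean log-survival; otherwise the fit is unweighted. (Per-point standard
#' errors estimated from the usual two or three replicates are too noisy
#' to make stable weights - they inflate the spread of the standardised
#' parameter errors well past nominal - so inverse-variance weighting only
#' engages when the replication actually supports it.) Points with
#' `SF <= 0` are excluded with a warning. A fitted `beta` below
#' `beta_zero_tol` is flagged as effectively zero (`beta_near_zero`), the
#' conventional "~0" of published parameter tables for pure-exponential
#' high-LET survival.
#'
#' @param data Data frame with columns `dose` (Gy) and either `sf` or the
#'   triple `colonies`, `seeded`, `pe`. An optional `replicate` column
#'   identifies replicates.
#' @param weighted Allow inverse-variance weights when replicate spread is
#'   available and stable (default `TRUE`).
#' @param weight_min_replicates Minimum replicates per dose before
#'   replicate-based weights are trusted (default 5).
#' @param beta_zero_tol Threshold (1/Gy^2) below which `beta` is reported
#'   as effectively zero. Default 1e-3.
#' @return Object of class `lq_fit`: `alpha`, `beta`, `alpha_se`,
#'   `beta_se`, `d50_Gy`, `beta_near_zero`, the aggregated points, and the
#'   underlying `nls` fit.
#' @examples
#' d <- data.frame(dose = c(0, 1, 2, 4, 6),
#'                 sf = sf_lq(c(0, 1, 2, 4, 6), 0.47, 0.05))
#' fit <- fit_lq(d)
#' c(fit$alpha, fit$beta)
#' @export
fit_lq <- function(data, weighted = TRUE, beta_zero_tol = 1e-3,
                   weight_min_replicates = 5L) {
  stopifnot(is.data.frame(data), "dose" %in% names(data))
  if (!"sf" %in% names(data)) {
    if (!all(c("colonies", "seeded", "pe") %in% names(data))) {
      stop("need either an 'sf' column or colonies/seeded/pe columns")
    }
    data$sf <- surviving_fraction(data$colonies, data$seeded, data$pe)
  }
  bad <- data$sf <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d point(s) with SF <= 0 from the log-space fit",
                    sum(bad)))
    data <- data[!bad, , drop = FALSE]
  }
  if (length(unique(data$dose)) < 3 || !any(data$dose == 0)) {
    stop("need >= 3 distinct doses including an unirradiated control")
  }
  lsf <- log(data$sf)
  agg <- data.frame(
    dose = sort(unique(data$dose)),
    lsf = as.numeric(tapply(lsf, data$dose, mean)),
    se = as.numeric(tapply(lsf, data$dose, function(x) {
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
    })),
    n_rep = as.numeric(tapply(lsf, data$dose, length)))
  w <- rep(1, nrow(agg))
  if (weighted && all(agg$n_rep >= weight_min_replicates) &&
      all(is.finite(agg$se)) && all(agg$se > 0)) {
    w <- 1 / agg$se^2
  }
  # linear-model start values (clipped into the feasible region)
  X <- cbind(-agg$dose, -agg$dose^2)
  start_ab <- tryCatch(stats::coef(stats::lm.fit(X, agg$lsf)),
                       error = function(e) c(0.5, 0.05))
  start <- list(a = max(start_ab[1], 1e-3), b = max(start_ab[2], 1e-4))
  fit <- tryCatch(
    minpack.lm::nlsLM(lsf ~ -(a * dose + b * dose^2), data = agg,
                      start = start, lower = c(0, 0), weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("LQ fit did not converge: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) c(a = NA_real_, b = NA_real_))
  alpha <- unname(cf["a"]); beta <- unname(cf["b"])
  structure(list(
    alpha = alpha, beta = beta,
    alpha_se = unname(ses["a"]), beta_se = unname(ses["b"]),
    d50_Gy = lq_d50(alpha, beta),
    beta_near_zero = beta < beta_zero_tol,
    points = agg, fit = fit),
    class = "lq_fit")
}

#' @export
print.lq_fit <- function(x, ...) {
  bshow <- if (x$beta_near_zero) "~0" else sprintf("%.3g", x$beta)
  cat(sprintf("LQ fit: alpha = %.3g +/- %.2g /Gy, beta = %s +/- %.2g /Gy^2\n",
              x$alpha, x$alpha_se, bshow, x$beta_se))
  cat(sprintf("  D50 = %.4g Gy (%d dose points)\n", x$d50_Gy, nrow(x$points)))
  invisible(x)
}

#' Iso-survival dose of a linear-quadratic curve
#'
#' Solves `alpha*D + beta*D^2 = -ln(sf_level)` for the dose at which the
#' surviving fraction equals `sf_level` (default 0.5, giving D50): the
#' positive quadratic root, or `-ln(sf_level)/alpha` when `beta = 0`.
#'
#' @param alpha,beta LQ parameters (vectorised); at least one must be
#'   positive.
#' @param sf_level Surviving-fraction level in (0, 1).
#' @return Dose in Gy.
#' @examples
#' lq_d50(log(2), 0)      # 1 Gy
#' lq_d50(0.47, 0.05)     # ~1.30 Gy
#' @export
lq_d50 <- function(alpha, beta = 0, sf_level = 0.5) {
  stopifnot(sf_level > 0, sf_level < 1)
  n <- max(length(alpha), length(beta))
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  if (any(alpha < 0) || any(beta < 0) || any(alpha == 0 & beta == 0)) {
    stop("need alpha >= 0, beta >= 0 and not both zero")
  }
  target <- -log(sf_level)
  lin <- beta == 0
  out <- numeric(n)
  out[lin] <- target / alpha[lin]
  if (any(!lin)) {
    a <- alpha[!lin]; b <- beta[!lin]
    out[!lin] <- (-a + sqrt(a^2 + 4 * b * target)) / (2 * b)
  }
  out
}

#' @rdname lq_d50
#' @param fit An `lq_fit`.
#' @export
d50 <- function(fit, sf_level = 0.5) {
  stopifnot(inherits(fit, "lq_fit"))
  lq_d50(fit$alpha, fit$beta, sf_level)
}

#' Relative biological effectiveness at an iso-survival level
#'
#' `RBE = D50(reference) / D50(test)`: the ratio of the doses at which the
#' reference (low-LET, X-ray) and test curves reach the same surviving
#' fraction (default 50%). Values above 1 mean the test radiation needs
#' less dose for the same effect.
#'
#' @param reference,test `lq_fit` objects, or bare lists with `alpha` and
#'   `beta` elements.
#' @param sf_level Iso-survival level (default 0.5).
#' @return Object of class `rbe_result` with elements `rbe`, `d50_reference_Gy`,
#'   `d50_test_Gy`, `sf_level`.
#' @examples
#' rbe(list(alpha = 0.47, beta = 0.05), list(alpha = 4.01, beta = 1.15))$rbe
#' @export
rbe <- function(reference, test, sf_level = 0.5) {
  dref <- lq_d50(reference$alpha, reference$beta %||% 0, sf_level)
  dtest <- lq_d50(test$alpha, test$beta %||% 0, sf_level)
  structure(list(rbe = dref / dtest, d50_reference_Gy = dref,
                 d50_test_Gy = dtest, sf_level = sf_level),
            class = "rbe_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rbe_result <- function(x, ...) {
  cat(sprintf("RBE at SF = %.0f%%: %.3g (D_ref %.3g Gy / D_test %.3g Gy)\n",
              100 * x$sf_level, x$rbe, x$d50_reference_Gy, x$d50_test_Gy))
  invisible(x)
}
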