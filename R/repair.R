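# DNA double-strand-break repair kinetics: exponential decay of the mean
# 53BP1 focus count per cell to a residual plateau,
# N(t) = (N0 - Plateau) * exp(-k*t) + Plateau.

#' Fit exponential-plateau repair kinetics to a foci time course
#'
#' Fits `N(t) = (N0 - Plateau) * exp(-k*t) + Plateau` to background-
#' corrected mean foci counts by bounded nonlinear least squares
#' (`N0 > 0`, `Plateau >= 0`, `k > 0`; Levenberg-Marquardt). The baseline
#' focus count of unirradiated controls is subtracted before fitting. The
#' repair half-life is reported as `t_half = half_life_constant / k`; the
#' default constant 0.69 follows the convention of published repair
#' tables (set `half_life_constant = log(2)` for the exact value). The
#' residual-damage fraction is `Plateau / N0`, the unrepaired share at
#' late times.
#'
#' @param times_h Time points after irradiation, hours (>= 4 points; the
#'   unirradiated `t = 0` state is represented by the baseline, not by a
#'   data point).
#' @param mean_foci Mean foci per cell at each time point.
#' @param baseline Baseline foci per cell of unirradiated controls,
#'   subtracted before fitting (default 0 for pre-corrected data).
#' @param se Optional standard errors of the mean foci counts (one per
#'   time point, e.g. from [foci_means()]). When supplied, points are
#'   weighted by `1/se^2` and the parameter covariance is taken from the
#'   weighted Jacobian with the error variances treated as known, instead
#'   of being rescaled by the residual variance of the (few) fitted
#'   points.
#' @param half_life_constant Numerator of the half-life conversion
#'   (default 0.69).
#' @return Object of class `repair_fit`: `n0`, `plateau`, `k_per_h`, their
#'   standard errors, `t_half_h`, `residual_fraction`,
#'   `plateau_at_bound`, and the corrected data.
#' @examples
#' t <- c(1, 2, 4, 8, 24)
#' fit <- fit_repair(t, (20 - 4) * exp(-0.3 * t) + 4)
#' c(fit$n0, fit$plateau, fit$k_per_h)
#' @export
fit_repair <- function(times_h, mean_foci, baseline = 0, se = NULL,
                       half_life_constant = 0.69) {
  stopifnot(length(times_h) == length(mean_foci))
  if (length(times_h) < 4) stop("need >= 4 time points")
  if (any(times_h <= 0)) stop("time points must be positive")
  d <- data.frame(t = times_h, n = mean_foci - baseline)
  if (all(d$n <= 0)) stop("all corrected counts are non-positive")
  w <- NULL
  if (!is.null(se)) {
    stopifnot(length(se) == length(times_h))
    if (any(!is.finite(se)) || any(se <= 0)) {
      stop("standard errors must be positive and finite")
    }
    w <- 1 / se^2
  }
  start <- list(n0 = max(d$n), plateau = max(min(d$n), 1e-3),
                k = 0.3)
  fit <- tryCatch(
    if (is.null(w)) {
      minpack.lm::nlsLM(n ~ (n0 - plateau) * exp(-k * t) + plateau, data = d,
                        start = start,
                        lower = c(n0 = 1e-9, plateau = 0, k = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(n ~ (n0 - plateau) * exp(-k * t) + plateau, data = d,
                        start = start, weights = w,
                        lower = c(n0 = 1e-9, plateau = 0, k = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    },
    error = function(e) stop("repair fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  ses <- if (is.null(w)) {
    tryCatch(summary(fit)$coefficients[, "Std. Error"],
             error = function(e) stats::setNames(rep(NA_real_, 3),
                                                 names(cf)))
  } else {
    # known-variance covariance: (J' W J)^-1 with W = diag(1/se^2);
    # nls model gradients already carry the sqrt-weights
    J <- fit$m$gradient()
    cv <- tryCatch(solve(crossprod(J)),
                   error = function(e) matrix(NA_real_, 3, 3))
    stats::setNames(sqrt(diag(cv)), names(cf))
  }
  n0 <- unname(cf["n0"]); plateau <- unname(cf["plateau"])
  k <- unname(cf["k"])
  if (plateau > n0) {
    warning("fitted plateau exceeds N0; time course is not decaying")
  }
  structure(list(
    n0 = n0, plateau = plateau, k_per_h = k,
    n0_se = unname(ses["n0"]), plateau_se = unname(ses["plateau"]),
    k_se = unname(ses["k"]),
    t_half_h = half_life_constant / k,
    half_life_constant = half_life_constant,
    residual_fraction = plateau / n0,
    plateau_at_bound = plateau < 1e-6,
    data = d, fit = fit),
    class = "repair_fit")
}

#' @export
print.repair_fit <- function(x, ...) {
  cat(sprintf("DSB repair fit: N0 = %.3g, plateau = %.3g foci/cell, k = %.3g /h\n",
              x$n0, x$plateau, x$k_per_h))
  cat(sprintf("  t1/2 = %.3g h (%.2f/k), residual fraction = %.2g%s\n",
              x$t_half_h, x$half_life_constant, x$residual_fraction,
              if (x$plateau_at_bound) " [plateau at bound]" else ""))
  invisible(x)
}

#' Predicted mean foci count of a repair fit
#' @param object A `repair_fit`.
#' @param newdata Optional data frame with column `t` (hours); defaults to
#'   the fitted time points.
#' @param ... Unused.
#' @return Numeric vector of baseline-corrected mean foci.
#' @export
predict.repair_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t else newdata$t
  (object$n0 - object$plateau) * exp(-object$k_per_h * t) + object$plateau
}

#' Repair half-life from a rate constant
#'
#' @param k_per_h Repair rate constant, 1/h.
#' @param half_life_constant Numerator (default the conventional 0.69; use
#'   `log(2)` for the exact conversion).
#' @return Half-life in hours.
#' @examples
#' repair_half_life(0.36)  # 1.92 h (to 2 decimals)
#' @export
repair_half_life <- function(k_per_h, half_life_constant = 0.69) {
  if (any(k_per_h <= 0)) stop("k must be positive")
  half_life_constant / k_per_h
}
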