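# Ra-223 decay-chain bookkeeping: the four-alpha cascade emission spectrum
# and the physical decay law used to integrate decays over an exposure.

#' The Ra-223 four-alpha cascade emission spectrum
#'
#' One Ra-223 disintegration, with its short-lived progeny in secular
#' equilibrium, emits four alpha particles ("one cascade decay"). Positions
#' 1-3 are monoenergetic; position 4 branches between two energies. The
#' default spectrum is 5.87, 6.82 and 7.38 MeV at probability 1, and
#' 6.62 MeV (99.7%) / 7.45 MeV (0.3%) at position 4, giving a mean energy
#' per emitted alpha of 6.67 MeV.
#'
#' @param emissions Data frame with columns `position` (integer 1..n),
#'   `energy_MeV` and `probability`; probabilities must sum to 1 within each
#'   position. Defaults to the Ra-223 chain.
#' @return An object of class `alpha_cascade`.
#' @examples
#' cas <- ra223_cascade()
#' cascade_mean_energy(cas)   # 6.67 MeV per alpha
#' cascade_total_energy(cas)  # 26.69 MeV per cascade decay
#' @export
ra223_cascade <- function(emissions = NULL) {
  if (is.null(emissions)) {
    emissions <- data.frame(
      position = c(1L, 2L, 3L, 4L, 4L),
      energy_MeV = c(5.87, 6.82, 7.38, 6.62, 7.45),
      probability = c(1, 1, 1, 0.997, 0.003))
  }
  stopifnot(is.data.frame(emissions),
            all(c("position", "energy_MeV", "probability") %in% names(emissions)))
  if (any(emissions$energy_MeV <= 0) || any(emissions$probability < 0)) {
    stop("energies must be positive and probabilities non-negative")
  }
  psum <- tapply(emissions$probability, emissions$position, sum)
  if (any(abs(psum - 1) > 1e-9)) {
    stop("emission probabilities must sum to 1 at every chain position")
  }
  structure(list(emissions = emissions,
                 n_positions = length(unique(emissions$position))),
            class = "alpha_cascade")
}

#' @export
print.alpha_cascade <- function(x, ...) {
  cat(sprintf("Alpha decay cascade: %d chain positions, mean %.2f MeV/alpha, %.2f MeV/decay\n",
              x$n_positions, cascade_mean_energy(x), cascade_total_energy(x)))
  print(x$emissions, row.names = FALSE)
  invisible(x)
}

#' Mean energy per emitted alpha of a cascade
#' @param cascade An [ra223_cascade()].
#' @return MeV per alpha particle (probability-weighted).
#' @export
cascade_mean_energy <- function(cascade = ra223_cascade()) {
  cascade_total_energy(cascade) / cascade$n_positions
}

#' Total probability-weighted energy of one cascade decay
#' @inheritParams cascade_mean_energy
#' @return MeV per cascade decay.
#' @export
cascade_total_energy <- function(cascade = ra223_cascade()) {
  with(cascade$emissions, sum(energy_MeV * probability))
}

#' Sample alpha energies for full cascade decays
#'
#' Draws the four alpha energies of `n` cascade decays: fixed energies at
#' the monoenergetic chain positions and a Bernoulli branch wherever a
#' position carries more than one line (position 4 of the Ra-223 chain,
#' branch probability 0.003). Uses the current R random number stream;
#' call [set.seed()] for reproducibility.
#'
#' @param n Number of cascade decays.
#' @inheritParams cascade_mean_energy
#' @return A numeric `n x n_positions` matrix of energies in MeV, one row
#'   per cascade decay.
#' @export
sample_cascade <- function(n = 1L, cascade = ra223_cascade()) {
  stopifnot(n >= 1)
  em <- cascade$emissions
  positions <- sort(unique(em$position))
  out <- matrix(0, nrow = n, ncol = length(positions))
  for (j in seq_along(positions)) {
    lines <- em[em$position == positions[j], , drop = FALSE]
    if (nrow(lines) == 1L) {
      out[, j] <- lines$energy_MeV
    } else {
      idx <- sample.int(nrow(lines), n, replace = TRUE, prob = lines$probability)
      out[, j] <- lines$energy_MeV[idx]
    }
  }
  out
}

#' Physical decay law
#'
#' @param half_life_days Physical half-life in days (Ra-223: 11.4 d).
#' @return Object of class `decay_law` with the half-life and the decay
#'   constant `lambda_per_s = ln(2) / half-life`.
#' @export
decay_law <- function(half_life_days = 11.4) {
  stopifnot(half_life_days > 0)
  structure(list(half_life_days = half_life_days,
                 lambda_per_s = log(2) / (half_life_days * 86400)),
            class = "decay_law")
}

#' @export
print.decay_law <- function(x, ...) {
  cat(sprintf("Decay law: half-life %.3g d, lambda %.4g /s\n",
              x$half_life_days, x$lambda_per_s))
  invisible(x)
}

#' Number of decays per ml over an exposure interval
#'
#' Integrates the exponential decay of an initial activity concentration
#' `A0` over an exposure of duration `T`:
#' `N = A0 * (1 - exp(-lambda * T)) / lambda`. Tends to `A0 * T` for short
#' exposures and to `A0 / lambda` for exposures long against the half-life.
#'
#' @param A0_Bq_per_ml Initial activity concentration in Bq/ml (1 Bq = 1
#'   cascade decay per second for Ra-223 with progeny in equilibrium).
#' @param duration_s Exposure duration in seconds.
#' @param law A [decay_law()].
#' @return Decays per ml over the interval (vectorised).
#' @export
decays_in_interval <- function(A0_Bq_per_ml, duration_s, law = decay_law()) {
  stopifnot(inherits(law, "decay_law"))
  if (any(A0_Bq_per_ml < 0) || any(duration_s < 0)) {
    stop("activity and duration must be non-negative")
  }
  A0_Bq_per_ml * (-expm1(-law$lambda_per_s * duration_s)) / law$lambda_per_s
}
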