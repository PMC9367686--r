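# Synthetic-data generators emulating the three assays consumed by the
# fitting stages: Poisson colony counts under LQ survival, Poisson per-cell
# foci counts decaying exponentially to a plateau over a background, and
# nucleus-area cohorts with planted giant/aberrant subpopulations. All
# generators draw from the current R random number stream; set.seed()
# makes them deterministic.

#' Generate a synthetic clonogenic survival experiment
#'
#' Colony counts are Poisson with mean
#' `n_seeded * PE * exp(-(alpha*D + beta*D^2))` per replicate, including
#' unirradiated (dose 0) controls. When `n_seeded` is `NULL`, the number
#' of cells seeded per dose is chosen so the expected colony count is
#' about `target_colonies` (the usual bench practice of seeding more cells
#' at higher doses), capped at 1e5.
#'
#' @param alpha,beta True LQ parameters (1/Gy, 1/Gy^2).
#' @param doses_Gy Dose levels, including 0.
#' @param n_replicates Replicates per dose (default 3).
#' @param pe Plating efficiency of unirradiated cells.
#' @param n_seeded Cells seeded per dose (scalar or one per dose);
#'   `NULL` to derive from `target_colonies`.
#' @param target_colonies Expected colonies per well when deriving
#'   `n_seeded`.
#' @return Data frame with columns `dose`, `colonies`, `seeded`, `pe`,
#'   `replicate`.
#' @examples
#' set.seed(1)
#' d <- gen_clonogenic(0.47, 0.05, doses_Gy = c(0, 1, 2, 4, 6, 8))
#' fit_lq(d)
#' @export
gen_clonogenic <- function(alpha, beta = 0,
                           doses_Gy = c(0, 0.5, 1, 2, 4, 6, 8),
                           n_replicates = 3, pe = 0.5, n_seeded = NULL,
                           target_colonies = 100) {
  stopifnot(alpha >= 0, beta >= 0, any(doses_Gy == 0))
  sf <- sf_lq(doses_Gy, alpha, beta)
  if (is.null(n_seeded)) {
    n_seeded <- pmin(ceiling(target_colonies / (pe * sf)), 1e5)
  }
  n_seeded <- rep_len(n_seeded, length(doses_Gy))
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    data.frame(dose = doses_Gy,
               colonies = stats::rpois(length(doses_Gy), n_seeded * pe * sf),
               seeded = n_seeded, pe = pe, replicate = r)
  }))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic per-cell 53BP1 foci time course
#'
#' Per-cell focus counts are Poisson with mean
#' `background + (N_induced - Plateau) * exp(-k*t) + Plateau`, where the
#' induced yield is `n0_per_Gy * dose * modality_scale` and the plateau is
#' `plateau_fraction` of the induced yield. The default modality scaling
#' reflects the observed ordering of focus induction: X-rays highest,
#' Ra-223 about 25% fewer, external alpha particles about 40% fewer.
#'
#' @param dose_Gy Delivered dose, Gy.
#' @param n0_per_Gy Induced foci per cell per Gy for the X-ray reference
#'   (default 20).
#' @param plateau_fraction Residual (unrepaired) fraction of the induced
#'   yield, in [0, 1].
#' @param k Repair rate constant, 1/h.
#' @param background Baseline foci per cell of unirradiated controls.
#' @param times_h Sampling times after irradiation, hours.
#' @param n_cells Cells scored per time point (default 50).
#' @param modality One of `"xray"`, `"ra223"`, `"alpha"`; sets the
#'   induction scale unless `modality_scale` is given.
#' @param modality_scale Optional explicit induction scale factor.
#' @return Data frame with columns `time_h`, `cell_id`, `foci`,
#'   `condition`.
#' @export
gen_foci_timecourse <- function(dose_Gy = 1, n0_per_Gy = 20,
                                plateau_fraction = 0.12, k = 0.36,
                                background = 3.1,
                                times_h = c(1, 2, 4, 8, 24), n_cells = 50,
                                modality = c("xray", "ra223", "alpha"),
                                modality_scale = NULL) {
  modality <- match.arg(modality)
  stopifnot(plateau_fraction >= 0, plateau_fraction <= 1, k > 0,
            background >= 0, all(times_h > 0), n_cells >= 1)
  if (is.null(modality_scale)) {
    modality_scale <- c(xray = 1.0, ra223 = 0.75, alpha = 0.60)[[modality]]
  }
  induced <- n0_per_Gy * dose_Gy * modality_scale
  plateau <- plateau_fraction * induced
  out <- do.call(rbind, lapply(times_h, function(t) {
    mu <- background + (induced - plateau) * exp(-k * t) + plateau
    data.frame(time_h = t, cell_id = seq_len(n_cells),
               foci = stats::rpois(n_cells, mu), condition = modality)
  }))
  rownames(out) <- NULL
  out
}

#' Mean foci per cell by time point
#'
#' Convenience aggregation of a per-cell foci table into the mean time
#' course that [fit_repair()] consumes.
#'
#' @param foci_table Data frame with columns `time_h` and `foci`.
#' @return Data frame with columns `time_h`, `mean_foci`, `se`, `n_cells`.
#' @export
foci_means <- function(foci_table) {
  stopifnot(all(c("time_h", "foci") %in% names(foci_table)))
  sp <- split(foci_table$foci, foci_table$time_h)
  data.frame(time_h = as.numeric(names(sp)),
             mean_foci = vapply(sp, mean, 0),
             se = vapply(sp, function(x) stats::sd(x) / sqrt(length(x)), 0),
             n_cells = vapply(sp, length, 0L),
             row.names = NULL)
}

#' Generate a synthetic nucleus-morphology cohort
#'
#' Control nucleus areas are lognormal; a planted `giant_fraction` of
#' cells gets areas strictly above `area_ratio` times the control mean
#' area (lognormal-tailed above the threshold), and a planted
#' `aberrant_fraction` gets two or more lobes. Membership is multinomial,
#' so the planted fractions are the per-cell probabilities. With the
#' default area spread (`sdlog = 0.25`) the lognormal tail above 2.5x the
#' mean carries < 0.01% mass, so essentially all non-planted cells
#' classify as normal.
#'
#' @param n Number of cells (default 200, the usual cohort size).
#' @param giant_fraction,aberrant_fraction Planted per-cell probabilities.
#' @param area_meanlog,area_sdlog Lognormal parameters of the control
#'   area distribution (um^2 scale; defaults give mean ~124 um^2).
#' @param dose,time_h,condition Annotation columns for grouping.
#' @param area_ratio Giant threshold multiple (default 2.5).
#' @return Data frame with columns `area_um2`, `lobes`, `dose`, `time_h`,
#'   `condition`.
#' @export
gen_nuclei <- function(n = 200, giant_fraction = 0, aberrant_fraction = 0,
                       area_meanlog = log(120), area_sdlog = 0.25,
                       dose = 0, time_h = 24, condition = "control",
                       area_ratio = 2.5) {
  stopifnot(n >= 1, giant_fraction >= 0, aberrant_fraction >= 0,
            giant_fraction + aberrant_fraction <= 1)
  control_mean <- exp(area_meanlog + area_sdlog^2 / 2)
  cls <- sample.int(3, n, replace = TRUE,
                    prob = c(1 - giant_fraction - aberrant_fraction,
                             giant_fraction, aberrant_fraction))
  area <- stats::rlnorm(n, area_meanlog, area_sdlog)
  lobes <- rep(1L, n)
  giant <- cls == 2L
  area[giant] <- control_mean * area_ratio *
    exp(stats::rexp(sum(giant), rate = 4))
  ab <- cls == 3L
  lobes[ab] <- 2L + stats::rpois(sum(ab), 1)
  area[ab] <- area[ab] * 1.5  # enlarged but multi-lobed morphology
  data.frame(area_um2 = area, lobes = lobes, dose = dose, time_h = time_h,
             condition = condition)
}

#' Generate a full synthetic study at the reference truth values
#'
#' Produces the three datasets of a complete in vitro study for one cell
#' line at the published reference truths: clonogenic survival under all
#' three radiation qualities, foci time courses, and morphology cohorts.
#' Used for end-to-end recovery checks of the fitting pipeline.
#'
#' @param cell_line One of the reference cell lines (default `"PC-3"`).
#' @param seed Integer seed.
#' @return List with elements `survival` (with a `modality` column),
#'   `foci`, `nuclei`.
#' @export
synthetic_study <- function(cell_line = "PC-3", seed = 1L) {
  set.seed(seed)
  lq <- reference_lq_params()
  lq <- lq[lq$cell_line == cell_line, ]
  if (!nrow(lq)) stop("unknown cell line: ", cell_line)
  rp <- reference_repair_params()
  rp <- rp[rp$cell_line == cell_line, ]
  bg <- reference_baseline_foci()
  bg <- bg$baseline[bg$cell_line == cell_line]

  doses <- list(xray = c(0, 0.5, 1, 2, 4, 6, 8),
                alpha = c(0, 0.25, 0.5, 1, 2),
                ra223 = c(0, 0.05, 0.1, 0.25, 0.5))
  survival <- do.call(rbind, lapply(seq_len(nrow(lq)), function(i) {
    mod <- lq$modality[i]
    d <- gen_clonogenic(lq$alpha[i], lq$beta[i], doses_Gy = doses[[mod]])
    d$modality <- mod
    d
  }))

  foci <- if (nrow(rp)) do.call(rbind, lapply(seq_len(nrow(rp)), function(i) {
    gen_foci_timecourse(dose_Gy = 1,
                        plateau_fraction = rp$residual_fraction[i],
                        k = rp$k[i], background = bg,
                        modality = rp$modality[i])
  })) else NULL

  nuclei <- rbind(
    gen_nuclei(200, 0, 0, dose = 0, condition = "control"),
    gen_nuclei(200, 0.15, 0.02, dose = 1, condition = "ra223"),
    gen_nuclei(200, 0.25, 0.05, dose = 2, condition = "ra223"))

  list(survival = survival, foci = foci, nuclei = nuclei)
}
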