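# CSV schemas, run manifests and the reference-table reproduction report.
# CSV dialect: comma-separated, '.' decimal, UTF-8, mandatory header row,
# canonical column order on write (so write -> read -> write round-trips
# byte-identically).

SURVIVAL_COLS <- c("dose", "colonies", "seeded", "pe", "replicate")
FOCI_COLS <- c("time_h", "cell_id", "foci", "condition")
NUCLEI_COLS <- c("area_um2", "lobes", "dose", "time_h", "condition")

read_schema_csv <- function(path, cols, what) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(d))
  if (length(missing)) {
    stop(sprintf("%s file %s lacks column(s): %s", what, path,
                 paste(missing, collapse = ", ")))
  }
  d[cols]
}

write_schema_csv <- function(d, path, cols) {
  missing <- setdiff(cols, names(d))
  if (length(missing)) {
    stop("data lacks column(s): ", paste(missing, collapse = ", "))
  }
  utils::write.csv(d[cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write the assay CSV schemas
#'
#' Readers validate the presence of the schema columns and return them in
#' canonical order; writers emit the canonical order so round trips are
#' byte-identical. Schemas: survival `dose, colonies, seeded, pe,
#' replicate`; foci `time_h, cell_id, foci, condition`; nuclei
#' `area_um2, lobes, dose, time_h, condition`.
#'
#' @param path CSV file path.
#' @param data Data frame to write.
#' @return Readers return a data frame; writers return `path` invisibly.
#' @name assay_csv
NULL

#' @rdname assay_csv
#' @export
read_survival_csv <- function(path) read_schema_csv(path, SURVIVAL_COLS, "survival")

#' @rdname assay_csv
#' @export
write_survival_csv <- function(data, path) write_schema_csv(data, path, SURVIVAL_COLS)

#' @rdname assay_csv
#' @export
read_foci_csv <- function(path) read_schema_csv(path, FOCI_COLS, "foci")

#' @rdname assay_csv
#' @export
write_foci_csv <- function(data, path) write_schema_csv(data, path, FOCI_COLS)

#' @rdname assay_csv
#' @export
read_nuclei_csv <- function(path) read_schema_csv(path, NUCLEI_COLS, "nuclei")

#' @rdname assay_csv
#' @export
write_nuclei_csv <- function(data, path) write_schema_csv(data, path, NUCLEI_COLS)

#' Read a run configuration file
#'
#' YAML configuration for the simulation and fitting entry points
#' (geometry dimensions, cascade spectrum, run sizes, seed, ...). Returns
#' the parsed list; unknown keys are preserved for the caller.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  cfg
}

#' Write a run manifest
#'
#' Every run writes a manifest next to its results: the echoed
#' configuration, the package version and the seed, serialised as JSON at
#' full double precision.
#'
#' @param path Output file path.
#' @param config Named list describing the run.
#' @param seed Integer seed used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed) {
  jsonlite::write_json(
    list(package = "ra223sim",
         version = as.character(utils::packageVersion("ra223sim")),
         seed = seed, config = config),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Regenerate the planning grid and derived-quantity reference reports
#'
#' Writes, under `output_dir`: the regenerated activity planning grid with
#' per-cell match flags against the printed reference grid
#' (`activity_grid.csv`); the D50/RBE values recomputed from the published
#' LQ parameters with containment flags against the published RBE and its
#' uncertainty (`rbe_check.csv`); repair half-lives from the published
#' rate constants via the 0.69/k convention (`repair_half_lives.csv`); the
#' stopping-power model evaluated at the two LET anchors
#' (`stopping_anchors.csv`); and a JSON summary (`summary.json`). A dose
#' factor may be supplied (e.g. a fresh [run_dosimetry()] estimate);
#' the default is the published reference value.
#'
#' @param output_dir Directory (created if needed).
#' @param dose_factor Dose factor for the activity grid.
#' @param physics A [stopping_power_model()] for the LET anchors.
#' @return Invisibly, a list with the data frames, the summary list, and
#'   `ok` (all checks passed).
#' @export
reproduce_reference_tables <- function(output_dir,
                                       dose_factor = ra223_reference_dose_factor,
                                       physics = stopping_power_model()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  computed <- activity_table(dose_factor = dose_factor)
  printed <- reference_activity_table()
  grid <- data.frame(
    duration_h = rep(computed$duration_h, each = ncol(computed) - 1L),
    dose_Gy = rep(as.numeric(sub("Gy_", "", names(computed)[-1])),
                  times = nrow(computed)),
    computed_kBq_ml = as.numeric(t(as.matrix(computed[-1]))),
    printed_kBq_ml = as.numeric(t(as.matrix(printed[-1]))))
  grid$match <- abs(grid$computed_kBq_ml - grid$printed_kBq_ml) < 1e-9
  utils::write.csv(grid, file.path(output_dir, "activity_grid.csv"),
                   row.names = FALSE, quote = FALSE)

  lq <- reference_lq_params()
  xr <- lq[lq$modality == "xray", c("cell_line", "alpha", "beta")]
  names(xr)[2:3] <- c("alpha_ref", "beta_ref")
  hi <- lq[lq$modality != "xray", ]
  rbe_tab <- merge(hi, xr, by = "cell_line", sort = FALSE)
  rbe_tab$d50_ref_Gy <- lq_d50(rbe_tab$alpha_ref, rbe_tab$beta_ref)
  rbe_tab$d50_test_Gy <- lq_d50(rbe_tab$alpha, rbe_tab$beta)
  rbe_tab$rbe_computed <- rbe_tab$d50_ref_Gy / rbe_tab$d50_test_Gy
  rbe_tab$contained <- abs(rbe_tab$rbe_computed - rbe_tab$rbe50) <=
    rbe_tab$rbe50_unc
  rbe_out <- rbe_tab[c("cell_line", "modality", "d50_ref_Gy", "d50_test_Gy",
                       "rbe_computed", "rbe50", "rbe50_unc", "contained")]
  utils::write.csv(rbe_out, file.path(output_dir, "rbe_check.csv"),
                   row.names = FALSE, quote = FALSE)

  rp <- reference_repair_params()
  rp$t_half_from_k <- repair_half_life(rp$k)
  utils::write.csv(rp[c("cell_line", "modality", "k", "t_half_printed",
                        "t_half_from_k")],
                   file.path(output_dir, "repair_half_lives.csv"),
                   row.names = FALSE, quote = FALSE)

  anchors <- data.frame(
    energy_MeV = c(6.67, 2.88),
    quoted_let_keV_um = c(72, 129.3),
    model_let_keV_um = stopping_power(c(6.67, 2.88), physics))
  anchors$rel_dev <- anchors$model_let_keV_um / anchors$quoted_let_keV_um - 1
  utils::write.csv(anchors, file.path(output_dir, "stopping_anchors.csv"),
                   row.names = FALSE, quote = FALSE)

  summary <- list(
    dose_factor_Gy_per_decay_ml = dose_factor,
    grid_cells_matching = sum(grid$match),
    grid_cells_total = nrow(grid),
    rbe_values_contained = sum(rbe_out$contained),
    rbe_values_total = nrow(rbe_out),
    let_anchor_max_rel_dev = max(abs(anchors$rel_dev)))
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ok <- summary$grid_cells_matching >= 10 &&
    summary$rbe_values_contained == summary$rbe_values_total &&
    summary$let_anchor_max_rel_dev <= 0.10
  if (!ok) {
    failing <- c(
      if (summary$grid_cells_matching < 10)
        paste("activity grid cells:",
              paste(which(!grid$match), collapse = ",")),
      if (summary$rbe_values_contained < summary$rbe_values_total)
        paste("RBE rows:", paste(which(!rbe_out$contained), collapse = ",")),
      if (summary$let_anchor_max_rel_dev > 0.10) "LET anchors")
    warning("reference checks failed: ", paste(failing, collapse = "; "))
  }
  invisible(list(activity_grid = grid, rbe = rbe_out, repair = rp,
                 anchors = anchors, summary = summary, ok = ok))
}
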