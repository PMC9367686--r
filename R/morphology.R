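# Rule-based nuclear-morphology classification: giant nuclei (G2/M arrest)
# and aberrant multi-lobed nuclei (mitotic catastrophe).

#' Classify nuclei by area and lobe count
#'
#' A nucleus with two or more distinct lobes is scored `aberrant`
#' (positive for mitotic catastrophe); otherwise a nucleus with area
#' greater than `area_ratio` (default 2.5) times the mean area of control
#' samples is scored `giant` (positive for G2/M arrest); the rest are
#' `normal`. The lobe rule takes precedence when both criteria hold. The
#' rule is scale-invariant: rescaling all areas and the control mean by a
#' common factor leaves labels unchanged.
#'
#' @param area Nucleus area (any consistent unit, e.g. um^2; vectorised).
#' @param control_mean_area Mean nucleus area of unirradiated controls
#'   (> 0).
#' @param lobe_count Number of distinct lobes (integer >= 1; vectorised).
#' @param area_ratio Giant-nucleus threshold as a multiple of the control
#'   mean area.
#' @return Factor with levels `normal`, `giant`, `aberrant`.
#' @examples
#' classify_nucleus(c(100, 270, 120), 100, c(1, 1, 3))
#' @export
classify_nucleus <- function(area, control_mean_area, lobe_count,
                             area_ratio = 2.5) {
  if (control_mean_area <= 0) stop("control mean area must be positive")
  if (any(lobe_count < 1)) stop("lobe count must be >= 1")
  if (any(area <= 0)) stop("areas must be positive")
  n <- max(length(area), length(lobe_count))
  area <- rep_len(area, n); lobe_count <- rep_len(lobe_count, n)
  lab <- rep("normal", n)
  lab[area > area_ratio * control_mean_area] <- "giant"
  lab[lobe_count >= 2] <- "aberrant"
  factor(lab, levels = c("normal", "giant", "aberrant"))
}

#' Giant and aberrant nucleus rates by treatment group
#'
#' Classifies each record with [classify_nucleus()] and reports, per
#' group, the percentage of giant and aberrant nuclei with binomial
#' standard errors (`100 * sqrt(p*(1-p)/n)`).
#'
#' @param records Data frame with columns `area_um2`, `lobes`, and the
#'   grouping columns in `by` (default `dose` and `time_h`).
#' @param control_mean_area Mean control nucleus area used by the
#'   classifier. If `NULL`, taken as the mean area of records with
#'   `dose == 0`.
#' @param by Character vector of grouping column names.
#' @param area_ratio Giant threshold multiple (default 2.5).
#' @return Data frame with the grouping columns, `n`, `pct_giant`,
#'   `pct_giant_se`, `pct_aberrant`, `pct_aberrant_se`.
#' @export
morphology_rates <- function(records, control_mean_area = NULL,
                             by = c("dose", "time_h"), area_ratio = 2.5) {
  stopifnot(is.data.frame(records),
            all(c("area_um2", "lobes") %in% names(records)),
            all(by %in% names(records)))
  if (is.null(control_mean_area)) {
    if (!"dose" %in% names(records) || !any(records$dose == 0)) {
      stop("no dose-0 controls to estimate the control mean area from")
    }
    control_mean_area <- mean(records$area_um2[records$dose == 0])
  }
  records$label <- classify_nucleus(records$area_um2, control_mean_area,
                                    records$lobes, area_ratio)
  groups <- split(records, records[by], drop = TRUE)
  if (!length(groups)) {
    warning("no non-empty groups")
    return(data.frame())
  }
  rows <- lapply(groups, function(g) {
    n <- nrow(g)
    pg <- mean(g$label == "giant")
    pa <- mean(g$label == "aberrant")
    cbind(g[1, by, drop = FALSE],
          data.frame(n = n,
                     pct_giant = 100 * pg,
                     pct_giant_se = 100 * sqrt(pg * (1 - pg) / n),
                     pct_aberrant = 100 * pa,
                     pct_aberrant_se = 100 * sqrt(pa * (1 - pa) / n)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}
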