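# The growth-faltering index: adj-FPC2 = child's FPC2 score minus the FPC2
# score of the WHO reference curve bounding the child's FPC1 stratum.

#' Compute per-child adj-FPC2 faltering scores
#'
#' Each child is assigned an FPC1 stratum (and its upper-limit reference
#' percentile) from `s1`, then
#' `adj_fpc2 = s2 - r2(reference percentile)`. Under the sign convention a
#' positive adj-FPC2 means the trajectory bends downward relative to the WHO
#' reference curve of the child's stratum; larger values mean more severe
#' faltering.
#'
#' @param scores An `fpca_scores` object (from a sign-conventioned model).
#' @param ref A `reference_system` built from the same model.
#' @return An object of class `faltering_result`: data frame with
#'   `child_id`, `sex`, `stratum`, `reference_percentile`, `s1`, `s2`,
#'   `adj_fpc2`, plus the fitted-curve matrix carried through as attribute
#'   `fitted`.
#' @export
compute_adj_fpc2 <- function(scores, ref) {
  df <- scores$scores
  ok <- is.finite(df$s1) & is.finite(df$s2)
  if (any(!ok)) {
    warning("excluded ", sum(!ok), " child(ren) with non-finite scores",
            call. = FALSE)
    df <- df[ok, , drop = FALSE]
  }
  assign <- assign_stratum(df$s1, ref)
  r2 <- ref$ref_scores$r2[match(assign$reference_percentile,
                                ref$ref_scores$percentile)]
  out <- data.frame(
    child_id = df$child_id,
    sex = df$sex,
    stratum = assign$stratum,
    reference_percentile = assign$reference_percentile,
    s1 = df$s1,
    s2 = df$s2,
    adj_fpc2 = df$s2 - r2,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "fitted") <- scores$fitted[ok, , drop = FALSE]
  attr(out, "grid") <- NULL
  class(out) <- c("faltering_result", "data.frame")
  out
}

#' Diagnostic correlations of FPC scores with HAZ levels and changes
#'
#' Pearson correlations of the overall-growth score `s1` and the faltering
#' index `adj_fpc2` against (i) fitted HAZ at a set of probe ages, (ii) the
#' change in HAZ percentile from birth to 24 months, and (iii) the change
#' from 6 to 18 months. Fitted-curve values are used because children are
#' not observed exactly at the probe ages. The expected pattern: `s1`
#' strongly negative with HAZ levels but weakly with percentile changes;
#' `adj_fpc2` strongly negative with percentile changes (a declining
#' percentile means faltering) but weakly with single-age HAZ.
#'
#' @param results A `faltering_result`.
#' @param model The `fpca_model` the scores came from (for the grid).
#' @param ages Probe ages in months (default 0, 6, 12, 18, 24).
#' @return Data frame with one row per probe quantity and columns
#'   `quantity`, `corr_s1`, `corr_adj_fpc2`.
#' @export
diagnostic_correlations <- function(results, model,
                                    ages = c(0, 6, 12, 18, 24)) {
  fitted <- attr(results, "fitted")
  if (nrow(results) < 3L) {
    stop("need at least 3 children for correlation diagnostics", call. = FALSE)
  }
  haz_at <- vapply(ages, function(a) {
    fitted[, which.min(abs(model$grid - a))]
  }, numeric(nrow(results)))
  pct <- haz_to_percentile(haz_at)
  dim(pct) <- dim(haz_at)
  probe <- cbind(haz_at,
                 pct[, which(ages == 24)] - pct[, which(ages == 0)],
                 pct[, which(ages == 18)] - pct[, which(ages == 6)])
  labels <- c(sprintf("haz_at_%g_months", ages),
              "pct_change_0_to_24", "pct_change_6_to_18")
  data.frame(
    quantity = labels,
    corr_s1 = apply(probe, 2, stats::cor, y = results$s1),
    corr_adj_fpc2 = apply(probe, 2, stats::cor, y = results$adj_fpc2),
    row.names = NULL
  )
}

#' Write a faltering-result table to CSV
#' @param results A `faltering_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_faltering <- function(results, path) {
  out <- as.data.frame(results)
  for (col in c("s1", "s2", "adj_fpc2")) out[[col]] <- format_full(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratum occupancy and mean faltering summary
#'
#' One row per stratum: the WHO upper-limit percentile band, number and
#' share of children, and mean/SD of adj-FPC2 — the table a cohort report
#' prints next to the stratum definitions.
#'
#' @param results A `faltering_result`.
#' @return Data frame with `stratum`, `n`, `share`, `mean_adj_fpc2`,
#'   `sd_adj_fpc2`.
#' @export
summarize_strata <- function(results) {
  agg <- lapply(sort(unique(results$stratum)), function(s) {
    x <- results$adj_fpc2[results$stratum == s]
    data.frame(stratum = s, n = length(x), share = length(x) / nrow(results),
               mean_adj_fpc2 = mean(x),
               sd_adj_fpc2 = stats::sd(x))
  })
  do.call(rbind, agg)
}
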