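# WHO-percentile reference system in HAZ space: constant-z pseudo-child
# curves, reference FPC scores, and FPC1 stratum boundaries.

#' Convert a WHO percentile to its constant HAZ value
#'
#' A child tracking the p-th percentile of the reference population has a
#' constant height-for-age z-score equal to the standard-normal quantile of
#' `p/100` (HAZ is 0 exactly at the median).
#'
#' @param p Percentile in (0, 100); vectorized.
#' @return Standard-normal quantile(s).
#' @export
percentile_to_z <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 100)) {
    stop("percentile must lie strictly inside (0, 100)", call. = FALSE)
  }
  stats::qnorm(p / 100)
}

#' Percentile of a HAZ value
#'
#' Inverse of [percentile_to_z()]: `100 * pnorm(haz)`.
#'
#' @param haz Height-for-age z-score(s); finite.
#' @return Percentile(s) in (0, 100).
#' @export
haz_to_percentile <- function(haz) {
  if (any(!is.finite(haz))) stop("haz must be finite", call. = FALSE)
  100 * stats::pnorm(haz)
}

#' Reference FPC scores of WHO-percentile pseudo-children
#'
#' For each percentile p, regresses the deviation of the constant reference
#' curve from the estimated mean curve, `d_p(t) = z_p - mu(t)`, on the two
#' eigenfunctions evaluated at `n_times` equally spaced ages spanning birth
#' to 24 months, by ordinary least squares without intercept. The ages are
#' interval midpoints (`(j - 1/2) * 24 / n_times`): with equal OLS weights
#' this makes the implicit quadrature midpoint-rule accurate, so the
#' regression coefficients agree closely with the continuous projection of
#' `d_p` onto the eigenfunctions (endpoint-inclusive spacing double-weights
#' the boundaries and biases the coefficients noticeably). The coefficients
#' `(r1_p, r2_p)` are the FPC scores a child growing exactly along that
#' percentile would have.
#'
#' @param model A sign-conventioned `fpca_model` with two components.
#' @param percentiles Percentile set (default the standard chart lines
#'   2, 5, 10, 25, 50, 75, 90, 95, 98).
#' @param n_times Number of equally spaced evaluation ages (default 18).
#' @return Data frame with columns `percentile`, `ref_z`, `r1`, `r2`.
#' @export
compute_reference_scores <- function(model,
                                     percentiles = c(2, 5, 10, 25, 50, 75, 90, 95, 98),
                                     n_times = 18L) {
  stopifnot(ncol(model$eigenfunctions) >= 2L, n_times >= 2L)
  lo <- model$grid[1]
  hi <- model$grid[length(model$grid)]
  times <- lo + (seq_len(n_times) - 0.5) * (hi - lo) / n_times
  X <- cbind(interp_grid(model$grid, model$eigenfunctions[, 1], times),
             interp_grid(model$grid, model$eigenfunctions[, 2], times))
  if (qr(X)$rank < 2L) {
    stop("eigenfunctions are collinear on the evaluation ages", call. = FALSE)
  }
  mu_t <- interp_grid(model$grid, model$mean, times)
  percentiles <- sort(percentiles)
  ref_z <- percentile_to_z(percentiles)
  coefs <- t(vapply(ref_z, function(z) {
    stats::lsfit(X, z - mu_t, intercept = FALSE)$coefficients
  }, numeric(2)))
  data.frame(percentile = percentiles, ref_z = ref_z,
             r1 = coefs[, 1], r2 = coefs[, 2], row.names = NULL)
}

#' Build FPC1 strata from reference scores
#'
#' Children are classified into 5 strata by comparing their FPC1 score with
#' the reference FPC1 scores of consecutive WHO percentiles. Under the sign
#' convention, `r1` decreases as the percentile increases, so larger `s1`
#' means worse overall growth. Stratum 1 collects children whose overall
#' growth is below the 2nd-percentile pseudo-child; strata 2-4 sit between
#' the 2/5, 5/10 and 10/25 percentile boundaries; stratum 5 merges everything
#' above the 25th percentile, but keeps per-child sub-stratum reference
#' percentiles (50, 75, 90, 95, 98) for adj-FPC2 computation. Intervals are
#' half-open with the boundary belonging to the better-percentile stratum,
#' and tile the whole real line.
#'
#' @param ref_scores Data frame from [compute_reference_scores()].
#' @param stratum_percentiles Boundary percentiles of strata 1-4
#'   (default 2, 5, 10, 25).
#' @param merged_top Percentiles merged into stratum 5
#'   (default 50, 75, 90, 95, 98).
#' @return Data frame (one row per classification interval) with columns
#'   `stratum`, `reference_percentile`, `lower_r1`, `upper_r1`; intervals are
#'   `lower_r1 <= s1 < upper_r1`.
#' @export
build_strata <- function(ref_scores, stratum_percentiles = c(2, 5, 10, 25),
                         merged_top = c(50, 75, 90, 95, 98)) {
  all_p <- c(stratum_percentiles, merged_top)
  missing_p <- setdiff(all_p, ref_scores$percentile)
  if (length(missing_p) > 0) {
    stop("reference scores lack percentile(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  r1 <- ref_scores$r1[match(all_p, ref_scores$percentile)]
  if (any(diff(r1) >= 0)) {
    stop("reference FPC1 scores are not strictly decreasing in percentile; ",
         "check the sign convention of the fitted model", call. = FALSE)
  }
  k <- length(all_p)
  # interval for percentile p_j: r1_{p_j} <= s1 < r1_{p_(j-1)}; the worst
  # interval (stratum 1) is unbounded above; children better than the last
  # percentile fold into its interval, so it is unbounded below.
  data.frame(
    stratum = pmin(seq_len(k), 5L),
    reference_percentile = all_p,
    lower_r1 = c(r1[-k], -Inf),
    upper_r1 = c(Inf, r1[-k]),
    row.names = NULL
  )
}

#' Build the complete reference system for a fitted model
#'
#' @param model A sign-conventioned `fpca_model`.
#' @param percentiles Percentile set.
#' @param n_times Number of regression ages (default 18).
#' @param stratum_percentiles,merged_top See [build_strata()].
#' @return An object of class `reference_system`: list with `ref_scores`,
#'   `strata`, `n_times`, `sex`.
#' @export
build_reference_system <- function(model,
                                   percentiles = c(2, 5, 10, 25, 50, 75, 90, 95, 98),
                                   n_times = 18L,
                                   stratum_percentiles = c(2, 5, 10, 25),
                                   merged_top = c(50, 75, 90, 95, 98)) {
  ref_scores <- compute_reference_scores(model, percentiles, n_times)
  strata <- build_strata(ref_scores, stratum_percentiles, merged_top)
  structure(list(ref_scores = ref_scores, strata = strata,
                 n_times = n_times, sex = model$sex),
            class = "reference_system")
}

#' @export
print.reference_system <- function(x, ...) {
  cat("<reference_system> ", nrow(x$ref_scores), " percentiles, ",
      max(x$strata$stratum), " strata (", x$n_times,
      " regression ages)\n", sep = "")
  print(x$ref_scores, digits = 4)
  invisible(x)
}

#' Assign FPC1 strata
#'
#' Intervals are half-open (`lower <= s1 < upper`), with a small relative
#' tolerance on the lower boundary: a score within 1% (of the boundary
#' magnitude) below a boundary is treated as sitting on it and assigned the
#' better-percentile stratum. This keeps the classification stable for
#' subjects lying numerically on a boundary — in particular the WHO
#' pseudo-children themselves, whose estimated scores define the boundaries
#' up to quadrature error.
#'
#' @param s1 Numeric vector of FPC1 scores.
#' @param ref A `reference_system`.
#' @return Data frame with `stratum` (1-5) and `reference_percentile` (the
#'   upper-limit percentile of the child's classification interval,
#'   sub-stratum resolution inside stratum 5).
#' @export
assign_stratum <- function(s1, ref) {
  st <- ref$strata
  tol <- ifelse(is.finite(st$lower_r1),
                0.01 * pmax(abs(st$lower_r1), 1), 0)
  idx <- vapply(s1, function(v) {
    which(v >= st$lower_r1 - tol & v < st$upper_r1)[1]
  }, integer(1))
  data.frame(stratum = st$stratum[idx],
             reference_percentile = st$reference_percentile[idx])
}

#' Serialize a reference system to structured text (JSON)
#' @param ref A `reference_system`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_system <- function(ref, path) {
  jsonlite::write_json(list(ref_scores = ref$ref_scores, strata = ref$strata,
                            n_times = ref$n_times, sex = ref$sex),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Reload a serialized reference system
#' @param path Path written by [write_reference_system()].
#' @return A `reference_system`.
#' @export
read_reference_system <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$strata$lower_r1[is.na(p$strata$lower_r1)] <- -Inf
  p$strata$upper_r1[is.na(p$strata$upper_r1)] <- Inf
  structure(list(ref_scores = as.data.frame(p$ref_scores),
                 strata = as.data.frame(p$strata),
                 n_times = as.integer(p$n_times), sex = p$sex),
            class = "reference_system")
}
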