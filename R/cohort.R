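# Core data container: a longitudinal HAZ cohort in long format.

#' Construct a longitudinal HAZ cohort
#'
#' Bundles long-format height-for-age z-score (HAZ) observations with an
#' optional per-child covariate table. Observations are validated, sorted by
#' child and age, and duplicate (child, age) rows are averaged (field practice
#' records the mean of repeated measurements taken at one visit).
#'
#' @param observations Data frame with columns `child_id`, `sex`
#'   (`"male"`/`"female"`), `age` (months, in \[0, 24\]) and `haz`.
#' @param covariates Optional data frame with one row per child, keyed by
#'   `child_id` (see [simulate_covariates()] for the expected fields).
#' @return An object of class `haz_cohort`: a list with elements
#'   `observations` and `covariates`.
#' @export
haz_cohort <- function(observations, covariates = NULL) {
  required <- c("child_id", "sex", "age", "haz")
  missing_cols <- setdiff(required, names(observations))
  if (length(missing_cols) > 0) {
    stop("observations lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  obs <- as.data.frame(observations)[required]
  obs$child_id <- as.character(obs$child_id)
  obs$sex <- as.character(obs$sex)
  obs$age <- as.numeric(obs$age)
  obs$haz <- as.numeric(obs$haz)

  bad_sex <- !obs$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop("unknown sex label(s): ",
         paste(unique(obs$sex[bad_sex]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(obs$age)) || any(!is.finite(obs$haz))) {
    stop("non-finite age or haz in observations; filter before construction",
         call. = FALSE)
  }
  if (any(obs$age < 0 | obs$age > 24)) {
    stop("ages must lie in [0, 24] months", call. = FALSE)
  }
  sex_per_child <- tapply(obs$sex, obs$child_id, function(s) length(unique(s)))
  if (any(sex_per_child > 1)) {
    stop("sex label must be constant within a child", call. = FALSE)
  }

  obs <- obs[order(obs$child_id, obs$age), , drop = FALSE]
  dup <- duplicated(obs[c("child_id", "age")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (child, age) row(s); keeping the mean HAZ",
            call. = FALSE)
    key <- interaction(obs$child_id, obs$age, drop = TRUE)
    agg <- stats::aggregate(haz ~ child_id + sex + age, data = obs, FUN = mean)
    obs <- agg[order(agg$child_id, agg$age), c("child_id", "sex", "age", "haz")]
  }
  rownames(obs) <- NULL

  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (!"child_id" %in% names(covariates)) {
      stop("covariate table lacks a child_id column", call. = FALSE)
    }
    covariates$child_id <- as.character(covariates$child_id)
  }

  structure(list(observations = obs, covariates = covariates),
            class = "haz_cohort")
}

#' @export
print.haz_cohort <- function(x, ...) {
  ids <- unique(x$observations$child_id)
  cat("<haz_cohort> ", length(ids), " children, ",
      nrow(x$observations), " observations\n", sep = "")
  if (length(ids) > 0) {
    nv <- table(x$observations$child_id)
    cat("  visits/child: ", min(nv), "-", max(nv),
        " (median ", stats::median(nv), ")\n", sep = "")
  }
  if (!is.null(x$covariates)) {
    cat("  covariates: ", nrow(x$covariates), " children x ",
        ncol(x$covariates) - 1L, " fields\n", sep = "")
  }
  invisible(x)
}

#' Number of children in a cohort
#' @param cohort A `haz_cohort`.
#' @return Integer count of distinct children.
#' @export
n_children <- function(cohort) {
  length(unique(cohort$observations$child_id))
}

#' Read a long-format HAZ cohort from CSV
#'
#' Expects a header row; one row per observation. Rows with non-finite age or
#' HAZ are dropped with a warning; rows with age outside \[0, 24\] months are
#' handled per `age_action`.
#'
#' @param path Path to the observation CSV.
#' @param schema Named character vector mapping the canonical column names
#'   (`child_id`, `sex`, `age`, `haz`) to the columns in the file.
#' @param covariate_path Optional path to a per-child covariate CSV.
#' @param age_action One of `"drop"` (drop-and-warn, default) or `"error"` for
#'   ages outside \[0, 24\].
#' @return A [haz_cohort()].
#' @export
read_cohort <- function(path,
                        schema = c(child_id = "child_id", sex = "sex",
                                   age = "age_months", haz = "haz"),
                        covariate_path = NULL,
                        age_action = c("drop", "error")) {
  age_action <- match.arg(age_action)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- unname(schema[c("child_id", "sex", "age", "haz")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  obs <- data.frame(
    child_id = as.character(raw[[schema[["child_id"]]]]),
    sex = as.character(raw[[schema[["sex"]]]]),
    age = suppressWarnings(as.numeric(raw[[schema[["age"]]]])),
    haz = suppressWarnings(as.numeric(raw[[schema[["haz"]]]])),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(obs$age) | !is.finite(obs$haz)
  if (any(bad)) {
    warning("dropped ", sum(bad), " row(s) with non-finite age or haz",
            call. = FALSE)
    obs <- obs[!bad, , drop = FALSE]
  }
  out_of_range <- obs$age < 0 | obs$age > 24
  if (any(out_of_range)) {
    if (age_action == "error") {
      stop(sum(out_of_range), " row(s) with age outside [0, 24] months",
           call. = FALSE)
    }
    warning("dropped ", sum(out_of_range),
            " row(s) with age outside [0, 24] months", call. = FALSE)
    obs <- obs[!out_of_range, , drop = FALSE]
  }
  covariates <- NULL
  if (!is.null(covariate_path)) {
    covariates <- utils::read.csv(covariate_path, stringsAsFactors = FALSE)
  }
  haz_cohort(obs, covariates)
}

#' Write a cohort's observations (and covariates) to CSV
#'
#' Numeric fields are written at full double precision so that
#' `read_cohort(write_cohort(x))` reproduces `x` exactly.
#'
#' @param cohort A `haz_cohort`.
#' @param path Output path for the observation CSV.
#' @param covariate_path Optional output path for the covariate CSV.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, covariate_path = NULL) {
  obs <- cohort$observations
  out <- data.frame(
    child_id = obs$child_id,
    sex = obs$sex,
    age_months = format_full(obs$age),
    haz = format_full(obs$haz),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(covariate_path)) {
    if (is.null(cohort$covariates)) {
      stop("cohort has no covariate table to write", call. = FALSE)
    }
    cov <- cohort$covariates
    cov_out <- cov
    num_cols <- vapply(cov, is.numeric, logical(1))
    cov_out[num_cols] <- lapply(cov[num_cols], format_full)
    utils::write.csv(cov_out, covariate_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Keep only children with a minimum number of observations
#'
#' Growth-curve estimation for a child is unreliable below a handful of
#' visits; the pipeline default retains children with at least 5
#' anthropometric measurements (roughly the first year of quarterly visits).
#'
#' @param cohort A `haz_cohort`.
#' @param min_n Minimum number of observations per child (default 5).
#' @return A `haz_cohort` restricted to qualifying children; the covariate
#'   table is subset to the survivors.
#' @export
filter_min_observations <- function(cohort, min_n = 5L) {
  stopifnot(min_n >= 1L)
  counts <- table(cohort$observations$child_id)
  keep <- names(counts)[counts >= min_n]
  obs <- cohort$observations[cohort$observations$child_id %in% keep, ,
                             drop = FALSE]
  cov <- cohort$covariates
  if (!is.null(cov)) cov <- cov[cov$child_id %in% keep, , drop = FALSE]
  rownames(obs) <- NULL
  structure(list(observations = obs, covariates = cov), class = "haz_cohort")
}

#' Partition a cohort by sex
#'
#' Growth references and FPCA are sex-specific, so the pipeline fits boys and
#' girls separately.
#'
#' @param cohort A `haz_cohort`; every child must carry a sex label.
#' @return A named list with `male` and `female` cohorts forming a disjoint,
#'   exhaustive partition of the input.
#' @export
split_by_sex <- function(cohort) {
  obs <- cohort$observations
  parts <- lapply(c(male = "male", female = "female"), function(s) {
    ids <- unique(obs$child_id[obs$sex == s])
    sub <- obs[obs$child_id %in% ids, , drop = FALSE]
    rownames(sub) <- NULL
    cov <- cohort$covariates
    if (!is.null(cov)) cov <- cov[cov$child_id %in% ids, , drop = FALSE]
    structure(list(observations = sub, covariates = cov),
              class = "haz_cohort")
  })
  parts
}
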