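# Risk-factor regression: OLS of adj-FPC2 on centered risk factors plus
# FPC1-stratum indicators, with Benjamini-Hochberg FDR adjustment.

#' Center continuous covariates at their sample mean
#'
#' Each named field is replaced by its deviation from the sample mean (for
#' interpretability of regression intercepts); the means are recorded.
#' Binary fields should not be listed and are passed through unchanged.
#'
#' @param covariates Covariate data frame.
#' @param which Character vector of fields to center.
#' @return The data frame with centered fields; recorded means in attribute
#'   `"centers"`.
#' @export
center_continuous <- function(covariates,
                              which = c("haz_at_birth", "maternal_height",
                                        "maternal_weight", "income",
                                        "ebf_le6", "ebf_gt6")) {
  which <- intersect(which, names(covariates))
  centers <- stats::setNames(numeric(length(which)), which)
  for (f in which) {
    m <- mean(covariates[[f]], na.rm = TRUE)
    if (isTRUE(stats::sd(covariates[[f]], na.rm = TRUE) == 0)) {
      warning("field '", f, "' has zero variance; centered anyway",
              call. = FALSE)
    }
    covariates[[f]] <- covariates[[f]] - m
    centers[f] <- m
  }
  attr(covariates, "centers") <- centers
  covariates
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, take
#' `q_(i) = min over j >= i of min(1, p_(j) * m / j)`, and return in the
#' original order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p)
  stepup <- pmin(1, p[o] * m / seq_len(m))
  q <- rev(cummin(rev(stepup)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Build the regression design from a covariate table: hinge-coded exclusive
# breastfeeding (slope up to 6 months, extra slope beyond) and the raw
# continuous/binary fields.
risk_design <- function(covariates) {
  x <- covariates
  need <- c("haz_at_birth", "maternal_height", "maternal_weight", "income",
            "mother_educated", "family_size_ge5", "preterm",
            "municipal_water", "food_coverage", "animal_in_house",
            "septic_toilet", "ebf_duration", "diarrhea_ge2")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("covariate table lacks field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data.frame(
    child_id = x$child_id,
    haz_at_birth = x$haz_at_birth,
    maternal_height = x$maternal_height,
    maternal_weight = x$maternal_weight,
    income = x$income,
    mother_educated = x$mother_educated,
    family_size_ge5 = x$family_size_ge5,
    preterm = x$preterm,
    municipal_water = x$municipal_water,
    food_coverage = x$food_coverage,
    animal_in_house = x$animal_in_house,
    septic_toilet = x$septic_toilet,
    ebf_le6 = pmin(x$ebf_duration, 6),
    ebf_gt6 = pmax(x$ebf_duration - 6, 0),
    diarrhea_ge2 = x$diarrhea_ge2,
    stringsAsFactors = FALSE
  )
}

#' Regress the faltering index on risk factors and FPC1 strata
#'
#' Ordinary least squares of adj-FPC2 on an intercept, mean-centered
#' continuous risk factors, binary risk factors, hinge-coded exclusive
#' breastfeeding (a slope up to 6 months and an additional slope beyond),
#' and stratum indicators with Stratum 1 (the most faltered) as reference.
#' Complete-case: children missing from the covariate table, or with missing
#' fields, are dropped. Per-term two-sided t-test p-values receive
#' Benjamini-Hochberg adjustment across all non-intercept terms. When
#' `covariates` is `NULL` the model degrades to strata-only.
#'
#' @param results A `faltering_result` (one sex).
#' @param covariates Per-child covariate table, or `NULL`.
#' @param sex Optional filter (`"male"`/`"female"`); defaults to using all
#'   rows of `results` (fit sexes separately upstream).
#' @return An object of class `risk_regression`: list with `table` (term,
#'   estimate, std_error, p_value, p_adjusted), `r_squared`, `n_used`,
#'   `reference_stratum`, `centers`, `fit` (the underlying `lm`).
#' @export
fit_risk_model <- function(results, covariates, sex = NULL) {
  df <- as.data.frame(results)
  if (!is.null(sex)) df <- df[df$sex == sex, , drop = FALSE]

  if (!is.null(covariates)) {
    design <- risk_design(covariates)
    design <- center_continuous(design)
    centers <- attr(design, "centers")
    dat <- merge(df[c("child_id", "stratum", "adj_fpc2")], design,
                 by = "child_id")
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    terms <- setdiff(names(design), c("child_id", "ebf_duration"))
  } else {
    dat <- df[c("child_id", "stratum", "adj_fpc2")]
    centers <- numeric(0)
    terms <- character(0)
  }
  # constant predictors carry no information and would make lm() rank
  # deficient (common for rare binaries in small cohorts): drop with warning
  if (length(terms) > 0) {
    constant <- vapply(terms, function(f) stats::var(dat[[f]]) == 0,
                       logical(1))
    if (any(constant)) {
      warning("dropping zero-variance predictor(s): ",
              paste(terms[constant], collapse = ", "), call. = FALSE)
      terms <- terms[!constant]
    }
  }
  dat$stratum <- factor(dat$stratum, levels = 1:5)
  n_pred <- length(terms) + nlevels(droplevels(dat$stratum)) - 1L
  if (nrow(dat) < n_pred + 10L) {
    stop("too few complete cases (", nrow(dat), ") for ", n_pred,
         " predictors", call. = FALSE)
  }
  rhs <- paste(c(terms, "stratum"), collapse = " + ")
  fml <- stats::as.formula(paste("adj_fpc2 ~", rhs))
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design; offending term(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  tab <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "Estimate"],
    std_error = sm$coefficients[, "Std. Error"],
    p_value = sm$coefficients[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab$p_adjusted <- NA_real_
  non_int <- tab$term != "(Intercept)"
  tab$p_adjusted[non_int] <- bh_adjust(tab$p_value[non_int])
  structure(list(table = tab,
                 r_squared = sm$r.squared,
                 n_used = nrow(dat),
                 reference_stratum = 1L,
                 centers = centers,
                 fit = fit),
            class = "risk_regression")
}

#' @export
print.risk_regression <- function(x, ...) {
  cat("<risk_regression> n = ", x$n_used,
      ", R^2 = ", round(x$r_squared, 3),
      " (reference: stratum ", x$reference_stratum, ")\n", sep = "")
  tab <- x$table
  tab$estimate <- signif(tab$estimate, 3)
  tab$std_error <- signif(tab$std_error, 3)
  tab$p_value <- signif(tab$p_value, 3)
  tab$p_adjusted <- signif(tab$p_adjusted, 3)
  print(tab)
  invisible(x)
}

#' Write a regression table to CSV
#'
#' Lays the result out as a report table: term, coefficient, p-value,
#' FDR-adjusted p-value, with an R^2 / n footer row.
#'
#' @param result A `risk_regression`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regression <- function(result, path) {
  tab <- result$table
  out <- data.frame(term = tab$term,
                    coefficient = format_full(tab$estimate),
                    std_error = format_full(tab$std_error),
                    p_value = format_full(tab$p_value),
                    adj_p_value = format_full(tab$p_adjusted),
                    stringsAsFactors = FALSE)
  footer <- data.frame(term = c("R_squared", "n_used"),
                       coefficient = format_full(c(result$r_squared,
                                                   result$n_used)),
                       std_error = "", p_value = "", adj_p_value = "",
                       stringsAsFactors = FALSE)
  utils::write.csv(rbind(out, footer), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
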