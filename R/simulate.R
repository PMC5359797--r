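# Seeded synthetic-cohort generator: sparse, noisy HAZ trajectories from a
# known rank-2 Karhunen-Loeve model plus covariates with known effects.

#' Default low-rank generative model for HAZ trajectories
#'
#' Builds the generative model used throughout the package's simulations:
#' a mean HAZ curve starting near -0.94 at birth and declining to about -2
#' by 24 months, two orthonormal eigenfunctions (an overall-growth component,
#' strictly negative over age, and a trajectory-change component crossing zero
#' once, near 12 months for boys and 14 months for girls), eigenvalues set so
#' the two components carry 93%/6% (boys) or 96%/3% (girls) of curve
#' variance, plus independent measurement noise.
#'
#' @param sex `"male"` or `"female"`.
#' @param n_children Number of children to enrol per simulated run. Defaults
#'   to 330 boys / 296 girls, the enrolment sizes the generator emulates.
#' @param noise_sd Measurement-error SD in z-score units (default 0.3).
#' @param grid Evaluation grid (ages in months).
#' @param covariate_effects Named numeric vector of true effects on the
#'   trajectory-change score (see [default_covariate_effects()]); `NULL`
#'   for no covariate structure.
#' @return An object of class `haz_gen_model`.
#' @export
default_generative_model <- function(sex = c("male", "female"),
                                     n_children = NULL,
                                     noise_sd = 0.3,
                                     grid = default_grid(),
                                     covariate_effects = default_covariate_effects()) {
  sex <- match.arg(sex)
  if (is.null(n_children)) n_children <- if (sex == "male") 330L else 296L
  dt <- grid_step(grid)

  # Mean curve: -0.94 at birth, saturating decline to -2.0 by 24 months.
  mu <- -0.94 - 1.06 * (1 - exp(-grid / 7)) / (1 - exp(-24 / 7))

  # phi1: strictly negative, magnitude growing with age (overall growth).
  g1 <- -(0.5 + grid / 24)
  phi1 <- g1 / sqrt(quad_inner(g1, g1, grid))

  # phi2: positive at young ages, one interior zero crossing (trajectory
  # change); crossing at 12 months for boys, 14 for girls. The cosine shape
  # parameter is pre-calibrated so the crossing lands on target after
  # Gram-Schmidt orthogonalization against phi1 under the grid quadrature.
  t0 <- if (sex == "male") 9.822634 else 13.17635
  g2 <- cos(pi * grid / (2 * t0))
  g2 <- g2 - quad_inner(g2, phi1, grid) * phi1
  phi2 <- g2 / sqrt(quad_inner(g2, g2, grid))
  if (phi2[1] < 0) phi2 <- -phi2

  shares <- if (sex == "male") c(93, 6) / 99 else c(96, 3) / 99
  total_var <- 31                      # integrated curve variance scale
  lambda <- total_var * shares

  model <- structure(list(
    sex = sex,
    grid = grid,
    mean_curve = mu,
    eigenfunctions = cbind(phi1, phi2),
    eigenvalues = lambda,
    noise_sd = noise_sd,
    visit_schedule = list(nominal = seq(0, 24, by = 3),
                          jitter_sd = 0.3,
                          continuation = 0.95),
    n_children = as.integer(n_children),
    covariate_effects = covariate_effects
  ), class = "haz_gen_model")
  validate_generative_model(model)
  model
}

#' Validate a generative model's invariants
#'
#' Checks eigenfunction orthonormality under the grid quadrature (tolerance
#' 1e-6), eigenvalue ordering and positivity, and a non-negative noise SD.
#'
#' @param model A `haz_gen_model`.
#' @return `model`, invisibly; errors on violation.
#' @export
validate_generative_model <- function(model) {
  phi <- model$eigenfunctions
  dt <- grid_step(model$grid)
  gram <- t(phi) %*% phi * dt
  if (max(abs(gram - diag(ncol(phi)))) > 1e-6) {
    stop("generative eigenfunctions are not orthonormal under the grid quadrature",
         call. = FALSE)
  }
  lam <- model$eigenvalues
  if (any(lam < 0) || is.unsorted(rev(lam))) {
    stop("eigenvalues must satisfy lambda1 >= lambda2 >= 0", call. = FALSE)
  }
  if (model$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  sched <- model$visit_schedule
  if (sched$continuation <= 0 || sched$continuation > 1) {
    stop("visit continuation probability must lie in (0, 1]", call. = FALSE)
  }
  invisible(model)
}

#' Default true covariate effects on the trajectory-change score
#'
#' Named effects (per unit of each covariate, on the FPC2-score scale) used by
#' the default generator so that the risk-factor regression stage has known
#' signal to recover. Unnamed covariates have zero effect. `ebf_gt6` acts on
#' the hinge `max(ebf_duration - 6, 0)`.
#'
#' @return Named numeric vector.
#' @export
default_covariate_effects <- function() {
  c(haz_at_birth = 0.4,
    maternal_weight = -0.008,
    income = -0.047,
    family_size_ge5 = 0.27,
    municipal_water = -0.33,
    animal_in_house = -0.35,
    ebf_gt6 = 0.056)
}

# Table of marginal distributions for the covariate generator: continuous
# fields as mean/sd, binary fields as proportions.
covariate_marginals <- function() {
  list(
    continuous = data.frame(
      field = c("haz_at_birth", "maternal_height", "maternal_weight",
                "income", "ebf_duration"),
      mean = c(-0.94, 149.71, 48.03, 6.96, 4.08),
      sd = c(1.14, 5.48, 8.43, 3.55, 2.25),
      stringsAsFactors = FALSE
    ),
    binary = data.frame(
      field = c("mother_educated", "family_size_ge5", "preterm",
                "municipal_water", "food_coverage", "animal_in_house",
                "septic_toilet", "diarrhea_ge2"),
      prob = c(0.634, 0.604, 0.040, 0.964, 0.960, 0.061, 0.354, 0.505),
      stringsAsFactors = FALSE
    )
  )
}

#' Simulate a per-child covariate table
#'
#' Continuous covariates are Gaussian and binary covariates Bernoulli, with
#' marginal moments matching the urban-slum cohort the generator emulates
#' (e.g. HAZ at birth -0.94 +/- 1.14, maternal weight 48.03 +/- 8.43 kg,
#' monthly income 6.96 +/- 3.55 thousand taka, exclusive breastfeeding
#' 4.08 +/- 2.25 months). `ebf_duration` is truncated to \[0, 24\] months and
#' `ebf_gt6` is derived from it, so `ebf_gt6 == 1` always implies
#' `ebf_duration > 6`.
#'
#' @param n Number of children.
#' @param seed Integer seed.
#' @param effects Named true-effect vector (see
#'   [default_covariate_effects()]); entries act on the trajectory-change
#'   score. `NULL` means all zero.
#' @param id_prefix Prefix for generated child ids.
#' @return A list with `covariates` (data frame, one row per child) and
#'   `beta` (the full named true-effect vector actually used, zeros included).
#' @export
simulate_covariates <- function(n, seed, effects = default_covariate_effects(),
                                id_prefix = "c") {
  stopifnot(n >= 0)
  marg <- covariate_marginals()
  with_seed(seed, {
    cov <- data.frame(child_id = sprintf("%s%04d", id_prefix, seq_len(n)),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(marg$continuous))) {
      f <- marg$continuous$field[i]
      cov[[f]] <- stats::rnorm(n, marg$continuous$mean[i], marg$continuous$sd[i])
    }
    cov$ebf_duration <- pmin(pmax(cov$ebf_duration, 0), 24)
    for (i in seq_len(nrow(marg$binary))) {
      f <- marg$binary$field[i]
      cov[[f]] <- stats::rbinom(n, 1L, marg$binary$prob[i])
    }
    cov$ebf_gt6 <- as.integer(cov$ebf_duration > 6)
    beta <- covariate_effect_vector(effects)
    list(covariates = cov, beta = beta)
  })
}

# Expand a (possibly partial) named effect vector over all effect-bearing
# covariate terms, filling zeros.
covariate_effect_vector <- function(effects) {
  terms <- c("haz_at_birth", "maternal_height", "maternal_weight", "income",
             "mother_educated", "family_size_ge5", "preterm",
             "municipal_water", "food_coverage", "animal_in_house",
             "septic_toilet", "ebf_le6", "ebf_gt6", "diarrhea_ge2")
  beta <- stats::setNames(numeric(length(terms)), terms)
  if (!is.null(effects)) {
    unknown <- setdiff(names(effects), terms)
    if (length(unknown) > 0) {
      stop("unknown covariate effect name(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    beta[names(effects)] <- effects
  }
  beta
}

# Covariate-driven displacement of the trajectory-change score for each child.
# ebf enters through the hinge basis min(d, 6) and max(d - 6, 0).
covariate_shift <- function(covariates, beta) {
  x <- covariates
  design <- cbind(
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
    diarrhea_ge2 = x$diarrhea_ge2
  )
  drop(design %*% beta[colnames(design)])
}

#' Simulate a sparse longitudinal HAZ cohort
#'
#' Each child receives true scores `s1 ~ N(0, lambda1)` and
#' `s2 ~ N(0, lambda2)` (the latter shifted by covariate effects when the
#' model carries them), a visit schedule of nominal quarterly ages with
#' Gaussian jitter truncated by geometric per-visit dropout, and observations
#' `X_i(t) + N(0, noise_sd^2)` where
#' `X_i(t) = mu(t) + s1 phi1(t) + s2 phi2(t)`.
#'
#' @param model A `haz_gen_model`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `cohort` (a [haz_cohort()], covariates attached when
#'   the model has covariate effects), `truth` (data frame: `child_id`,
#'   `sex`, `s1_true`, `s2_true`, `n_visits`, `dropout_age`) and `beta`
#'   (true covariate effect vector, or `NULL`).
#' @export
simulate_cohort <- function(model, seed) {
  validate_generative_model(model)
  n <- model$n_children
  sched <- model$visit_schedule
  grid <- model$grid
  prefix <- if (model$sex == "male") "b" else "g"

  covs <- NULL
  beta <- NULL
  shift <- numeric(n)
  if (!is.null(model$covariate_effects)) {
    sim_cov <- simulate_covariates(n, seed = seed + 1L,
                                   effects = model$covariate_effects,
                                   id_prefix = prefix)
    covs <- sim_cov$covariates
    beta <- sim_cov$beta
    if (n > 0) shift <- covariate_shift(covs, beta)
  }

  with_seed(seed, {
    ids <- sprintf("%s%04d", prefix, seq_len(n))
    s1 <- stats::rnorm(n, 0, sqrt(model$eigenvalues[1]))
    s2 <- stats::rnorm(n, 0, sqrt(model$eigenvalues[2])) + shift

    obs_list <- vector("list", n)
    n_visits <- integer(n)
    dropout_age <- numeric(n)
    nominal <- sched$nominal
    for (i in seq_len(n)) {
      k <- if (sched$continuation >= 1) {
        length(nominal)
      } else {
        min(length(nominal), 1L + stats::rgeom(1L, 1 - sched$continuation))
      }
      ages <- nominal[seq_len(k)]
      if (k > 1) {
        ages[-1] <- ages[-1] + stats::rnorm(k - 1L, 0, sched$jitter_sd)
      }
      ages <- pmin(pmax(ages, 0), 24)
      ages <- sort(ages)
      # jitter cannot realistically reorder quarterly visits; guard anyway
      ages <- ages[!duplicated(ages)]
      k <- length(ages)
      x <- interp_grid(grid, model$mean_curve, ages) +
        s1[i] * interp_grid(grid, model$eigenfunctions[, 1], ages) +
        s2[i] * interp_grid(grid, model$eigenfunctions[, 2], ages)
      y <- x + stats::rnorm(k, 0, model$noise_sd)
      obs_list[[i]] <- data.frame(child_id = ids[i], sex = model$sex,
                                  age = ages, haz = y,
                                  stringsAsFactors = FALSE)
      n_visits[i] <- k
      dropout_age[i] <- ages[k]
    }
    obs <- do.call(rbind, obs_list)
    if (is.null(obs)) {
      obs <- data.frame(child_id = character(), sex = character(),
                        age = numeric(), haz = numeric(),
                        stringsAsFactors = FALSE)
    }
    truth <- data.frame(child_id = ids, sex = rep(model$sex, n),
                        s1_true = s1, s2_true = s2,
                        n_visits = n_visits, dropout_age = dropout_age,
                        stringsAsFactors = FALSE)
    list(cohort = haz_cohort(obs, covariates = covs), truth = truth,
         beta = beta)
  })
}

#' Pseudo-child tracking a fixed WHO percentile
#'
#' A hypothetical subject growing exactly along the p-th WHO percentile has a
#' constant HAZ equal to the standard-normal quantile of `p/100` at every age.
#'
#' @param percentile Percentile in (0, 100).
#' @param ages Ages (months) at which to emit observations.
#' @param sex Sex label to attach (`"male"` by default).
#' @param child_id Identifier for the emitted rows.
#' @return Data frame of observations (`child_id`, `sex`, `age`, `haz`).
#' @export
simulate_pseudo_child <- function(percentile, ages, sex = "male",
                                  child_id = sprintf("pseudo_p%g", percentile)) {
  z <- percentile_to_z(percentile)
  data.frame(child_id = child_id, sex = sex, age = as.numeric(ages),
             haz = rep(z, length(ages)), stringsAsFactors = FALSE)
}

#' Write a truth table to CSV
#' @param truth Truth data frame from [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  num_cols <- vapply(out, is.numeric, logical(1))
  out[num_cols] <- lapply(out[num_cols], format_full)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
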