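# Fixtures built in code: tiny cohorts, dense noiseless cohorts from known
# low-rank structure, and a cached default fit shared across test files.

# A minimal hand-written cohort: 2 boys, 1 girl.
tiny_cohort <- function() {
  haz_cohort(data.frame(
    child_id = c("a", "a", "a", "b", "b", "c"),
    sex = c("male", "male", "male", "male", "male", "female"),
    age = c(0, 3, 6, 0, 12, 6),
    haz = c(-1, -1.2, -1.5, -0.5, -2, 0.3)
  ))
}

# Dense balanced cohort sampled exactly from mu + s1 phi1 + s2 phi2 at every
# grid point (optionally with iid noise): the oracle-friendly regime.
dense_cohort <- function(model, n = 60, seed = 1, noise_sd = 0,
                         ages = model$grid) {
  stats <- new.env()
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s1 <- rnorm(n, 0, sqrt(model$eigenvalues[1]))
  s2 <- rnorm(n, 0, sqrt(model$eigenvalues[2]))
  phi1 <- approx(model$grid, model$eigenfunctions[, 1], ages, rule = 2)$y
  phi2 <- approx(model$grid, model$eigenfunctions[, 2], ages, rule = 2)$y
  mu <- approx(model$grid, model$mean_curve, ages, rule = 2)$y
  obs <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(child_id = sprintf("d%03d", i), sex = model$sex, age = ages,
               haz = mu + s1[i] * phi1 + s2[i] * phi2 +
                 rnorm(length(ages), 0, noise_sd))
  }))
  list(cohort = haz_cohort(obs), s1 = s1, s2 = s2)
}

# One default-condition simulated fit per sex, computed once per test run.
.fit_cache <- new.env(parent = emptyenv())
cached_default_fit <- function(sex = "male", seed = 7) {
  key <- paste(sex, seed, sep = "_")
  if (is.null(.fit_cache[[key]])) {
    m <- default_generative_model(sex)
    sim <- simulate_cohort(m, seed = seed)
    coh <- filter_min_observations(sim$cohort, 5)
    fit <- fit_fpca(coh)
    .fit_cache[[key]] <- list(model_gen = m, sim = sim, cohort = coh,
                              fit = fit)
  }
  .fit_cache[[key]]
}

# Truth rows aligned to a score table.
aligned_truth <- function(sim, scores) {
  sim$truth[match(scores$scores$child_id, sim$truth$child_id), ]
}
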