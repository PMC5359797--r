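# Synthetic-cohort generator: model invariants, determinism, moments.

test_that("default generative models satisfy their structural invariants", {
  for (sx in c("male", "female")) {
    m <- default_generative_model(sx)
    dt <- m$grid[2] - m$grid[1]
    phi <- m$eigenfunctions
    # orthonormality under the grid quadrature
    expect_lt(max(abs(t(phi) %*% phi * dt - diag(2))), 1e-6)
    # phi1 strictly negative beyond birth
    expect_true(all(phi[-1, 1] < 0))
    # phi2 positive at birth with exactly one sign change, near the
    # sex-specific crossing age
    expect_gt(phi[1, 2], 0)
    changes <- which(diff(sign(phi[, 2])) != 0)
    expect_length(changes, 1L)
    target <- if (sx == "male") 12 else 14
    expect_lt(abs(m$grid[changes] - target), 0.5)
    # mean curve: starts at -0.94, declines to about -2
    expect_equal(m$mean_curve[1], -0.94)
    expect_lt(m$mean_curve[length(m$grid)], -1.9)
    expect_true(all(diff(m$mean_curve) < 0))
    # eigenvalue shares mirror the configured variance split
    shares <- m$eigenvalues / sum(m$eigenvalues)
    expected <- if (sx == "male") c(93, 6) / 99 else c(96, 3) / 99
    expect_equal(shares, expected, tolerance = 1e-12)
  }
  bad <- default_generative_model("male")
  bad$noise_sd <- -1
  expect_error(validate_generative_model(bad), "noise_sd")
})

test_that("degenerate model reproduces the mean curve exactly", {
  m <- default_generative_model("male", n_children = 20L, noise_sd = 0,
                                covariate_effects = NULL)
  m$eigenvalues <- c(0, 0)
  sim <- simulate_cohort(m, seed = 4)
  obs <- sim$cohort$observations
  mu_at <- approx(m$grid, m$mean_curve, obs$age, rule = 2)$y
  expect_equal(obs$haz, mu_at, tolerance = 1e-12)
})

test_that("simulation is deterministic in the seed", {
  m <- default_generative_model("female", n_children = 50L)
  a <- simulate_cohort(m, seed = 99)
  b <- simulate_cohort(m, seed = 99)
  expect_identical(a, b)
  c <- simulate_cohort(m, seed = 100)
  expect_false(identical(a$cohort$observations, c$cohort$observations))
})

test_that("true score moments match the generative eigenvalues", {
  m <- default_generative_model("male", n_children = 2000L,
                                covariate_effects = NULL)
  sim <- simulate_cohort(m, seed = 21)
  expect_lt(abs(var(sim$truth$s1_true) / m$eigenvalues[1] - 1), 0.1)
  expect_lt(abs(var(sim$truth$s2_true) / m$eigenvalues[2] - 1), 0.1)
  # empirical score covariance is diagonal within Monte-Carlo error
  expect_lt(abs(cor(sim$truth$s1_true, sim$truth$s2_true)), 0.05)
})

test_that("noiseless dense observations lie exactly on the rank-2 curve", {
  m <- default_generative_model("male", n_children = 10L, noise_sd = 0,
                                covariate_effects = NULL)
  m$visit_schedule$jitter_sd <- 0
  m$visit_schedule$continuation <- 1
  sim <- simulate_cohort(m, seed = 2)
  obs <- sim$cohort$observations
  tr <- sim$truth[match(obs$child_id, sim$truth$child_id), ]
  expected <- approx(m$grid, m$mean_curve, obs$age, rule = 2)$y +
    tr$s1_true * approx(m$grid, m$eigenfunctions[, 1], obs$age, rule = 2)$y +
    tr$s2_true * approx(m$grid, m$eigenfunctions[, 2], obs$age, rule = 2)$y
  expect_equal(obs$haz, expected, tolerance = 1e-12)
})

test_that("visit schedule gives quarterly jittered visits with dropout", {
  m <- default_generative_model("male", n_children = 500L)
  sim <- simulate_cohort(m, seed = 31)
  expect_true(all(sim$truth$n_visits >= 1 & sim$truth$n_visits <= 9))
  # with 0.95 continuation about 81% of children reach 5 visits
  frac5 <- mean(sim$truth$n_visits >= 5)
  expect_gt(frac5, 0.72)
  expect_lt(frac5, 0.9)
  # first visit at birth, all ages within range and increasing
  first <- tapply(sim$cohort$observations$age,
                  sim$cohort$observations$child_id, min)
  expect_true(all(first == 0))
  expect_true(all(tapply(sim$cohort$observations$age,
                         sim$cohort$observations$child_id,
                         function(a) all(diff(a) > 0))))
})

test_that("covariate marginals and internal consistency hold", {
  sc <- simulate_covariates(10000, seed = 8)
  cov <- sc$covariates
  expect_lt(abs(mean(cov$maternal_weight) - 48.03), 0.5)
  expect_lt(abs(mean(cov$haz_at_birth) + 0.94), 0.05)
  expect_lt(abs(mean(cov$mother_educated) - 0.634), 0.02)
  # ebf_gt6 == 1 always implies duration > 6
  expect_true(all(cov$ebf_duration[cov$ebf_gt6 == 1] > 6))
  expect_true(all(cov$ebf_duration[cov$ebf_gt6 == 0] <= 6))
  expect_true(all(cov$ebf_duration >= 0 & cov$ebf_duration <= 24))
  binaries <- c("mother_educated", "family_size_ge5", "preterm",
                "municipal_water", "food_coverage", "animal_in_house",
                "septic_toilet", "diarrhea_ge2", "ebf_gt6")
  for (b in binaries) expect_true(all(cov[[b]] %in% c(0, 1)))

  # returned beta covers every term, zeros where unspecified
  expect_equal(sum(sc$beta != 0), length(default_covariate_effects()))
  zero <- simulate_covariates(10, seed = 1, effects = NULL)
  expect_true(all(zero$beta == 0))
  expect_error(simulate_covariates(5, 1, effects = c(nonsense = 1)),
               "unknown")
})

test_that("covariate effects displace the trajectory-change score", {
  eff <- c(haz_at_birth = 0.5)
  m <- default_generative_model("male", n_children = 3000L,
                                covariate_effects = eff)
  sim <- simulate_cohort(m, seed = 13)
  merged <- merge(sim$truth, sim$cohort$covariates, by = "child_id")
  b <- coef(lm(s2_true ~ haz_at_birth, data = merged))["haz_at_birth"]
  expect_lt(abs(b - 0.5), 0.05)
  # and s1 stays independent of the covariates
  expect_lt(abs(cor(merged$s1_true, merged$haz_at_birth)), 0.05)
})

test_that("pseudo-children track their percentile exactly", {
  pc <- simulate_pseudo_child(50, ages = c(0, 6, 12))
  expect_equal(pc$haz, rep(0, 3))
  pc2 <- simulate_pseudo_child(2, ages = 0:24)
  expect_equal(unique(pc2$haz), qnorm(0.02), tolerance = 1e-12)
  # antisymmetry around the median
  for (p in c(2, 10, 25, 40)) {
    expect_equal(simulate_pseudo_child(p, 0)$haz,
                 -simulate_pseudo_child(100 - p, 0)$haz, tolerance = 1e-12)
  }
  expect_error(simulate_pseudo_child(0, 0), "\\(0, 100\\)")
  expect_error(simulate_pseudo_child(100, 0), "\\(0, 100\\)")
})
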