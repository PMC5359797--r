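# Sparse FPCA: smoothers, eigendecomposition, sign convention, BLUP scores.

test_that("mean smoother reproduces constants and linear targets", {
  # constant HAZ on an irregular design
  obs <- data.frame(child_id = rep(sprintf("c%d", 1:20), each = 4),
                    sex = "male",
                    age = rep(c(0, 7, 13.5, 22), 20),
                    haz = -1.3)
  mu <- estimate_mean(haz_cohort(obs), bandwidth = 3)
  expect_equal(mu$mean, rep(-1.3, 101), tolerance = 1e-10)

  # dense noiseless linear target: local-linear smooth is exact up to
  # binning/boundary error
  grid <- default_grid()
  obs2 <- do.call(rbind, lapply(1:8, function(i)
    data.frame(child_id = paste0("l", i), sex = "male",
               age = grid, haz = -1 - 0.05 * grid)))
  mu2 <- estimate_mean(haz_cohort(obs2), bandwidth = 2)
  expect_lt(max(abs(mu2$mean - (-1 - 0.05 * grid))), 0.02)

  # invariant to child relabeling (pooling is order-free)
  obs3 <- obs
  obs3$child_id <- rep(sprintf("z%d", 20:1), each = 4)
  mu3 <- estimate_mean(haz_cohort(obs3), bandwidth = 3)
  expect_identical(mu$mean, mu3$mean)

  expect_error(estimate_mean(haz_cohort(
    data.frame(child_id = c("a", "b"), sex = "male", age = 5,
               haz = c(0, 1)))), "distinct")
})

test_that("covariance smoother recovers a rank-1 surface and its noise", {
  grid <- default_grid()
  dt <- grid[2]
  g <- sin(pi * grid / 24)
  phi <- g / sqrt(sum(g * g) * dt)
  lambda <- 1
  sparse_ages <- seq(0, 24, by = 3)

  make_obs <- function(noise_sd, n, seed) {
    set.seed(seed)
    s <- rnorm(n, 0, sqrt(lambda))
    do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(child_id = sprintf("r%04d", i), sex = "male",
                 age = sparse_ages,
                 haz = s[i] * approx(grid, phi, sparse_ages)$y +
                   rnorm(length(sparse_ages), 0, noise_sd))))
  }

  # noiseless: surface ~ lambda phi phi', sigma2 ~ 0
  coh0 <- haz_cohort(make_obs(0, 400, 11))
  cv0 <- estimate_covariance(coh0, grid, mean = rep(0, 101), bandwidth = 2)
  expect_lt(abs(cv0$noise_var), 0.01)
  target <- lambda * outer(phi, phi)
  expect_lt(norm(cv0$surface - target, "F") / norm(target, "F"), 0.2)
  # leading eigenpair of the smoothed surface recovers (lambda, phi)
  eg0 <- eigendecompose(cv0$surface, grid, n_components = 1)
  expect_lt(abs(eg0$eigenvalues[1] - lambda) / lambda, 0.15)
  a <- eg0$eigenfunctions[, 1] * sign(sum(eg0$eigenfunctions[, 1] * phi))
  expect_lt(max(abs(a - phi)), 0.1)
  expect_identical(cv0$surface, t(cv0$surface))

  # N(0, 0.25) noise: diagonal-excess estimator lands near 0.25 at n = 500
  coh1 <- haz_cohort(make_obs(0.5, 500, 12))
  cv1 <- estimate_covariance(coh1, grid, mean = rep(0, 101), bandwidth = 2)
  expect_gt(cv1$noise_var, 0.15)
  expect_lt(cv1$noise_var, 0.35)

  expect_error(estimate_covariance(haz_cohort(
    data.frame(child_id = c("a", "b"), sex = "male", age = c(1, 2),
               haz = c(0, 1))), grid, mean = rep(0, 101), bandwidth = 2),
    ">= 2 observations")
})

test_that("eigendecomposition matches analytic shares and a brute-force oracle", {
  grid <- default_grid()
  dt <- grid[2]
  # three orthonormal shapes via QR
  raw <- cbind(rep(1, 101), grid, grid^2)
  q <- qr.Q(qr(raw)) / sqrt(dt)
  surf <- 93 * outer(q[, 1], q[, 1]) + 6 * outer(q[, 2], q[, 2]) +
    1 * outer(q[, 3], q[, 3])
  eg <- eigendecompose(surf, grid, n_components = 3)
  expect_equal(eg$eigenvalues, c(93, 6, 1), tolerance = 1e-8)
  expect_equal(eg$fve, c(0.93, 0.99, 1.00), tolerance = 1e-10)
  # two components reach > 98% dominance
  expect_gt(eg$fve[2], 0.98)
  # eigenfunctions recover the constructed basis up to sign
  for (k in 1:3) {
    expect_lt(min(max(abs(eg$eigenfunctions[, k] - q[, k])),
                  max(abs(eg$eigenfunctions[, k] + q[, k]))), 1e-6)
  }
  # quadrature orthonormality of the output
  gram <- t(eg$eigenfunctions) %*% eg$eigenfunctions * dt
  expect_lt(max(abs(gram - diag(3))), 1e-6)

  # rank-1 surface: single positive eigenvalue, eigenfunction up to sign
  s1 <- 5 * outer(q[, 1], q[, 1])
  expect_warning(eg1 <- eigendecompose(s1, grid, n_components = 2),
                 "positive")
  expect_equal(eg1$eigenvalues, 5, tolerance = 1e-8)

  # independent brute-force oracle: eigen() of the plain matrix, scaled
  ev_oracle <- eigen(surf, symmetric = TRUE)$values[1:3] * dt
  expect_lt(max(abs(eg$eigenvalues - ev_oracle)), 1e-8)

  expect_error(eigendecompose(surf + 1e-3 * upper.tri(surf), grid),
               "symmetric")
})

test_that("sign convention is idempotent and leaves reconstructions unchanged", {
  fx <- cached_default_fit("male")
  model <- fx$fit$model
  # flipped model returns to convention, twice = once
  flipped <- model
  flipped$eigenfunctions <- -flipped$eigenfunctions
  sc <- estimate_scores(fx$cohort, flipped)
  fixed <- apply_sign_convention(flipped, sc)
  expect_equal(fixed$model$eigenfunctions, model$eigenfunctions)
  again <- apply_sign_convention(fixed$model, fixed$scores)
  expect_identical(again$model$eigenfunctions, fixed$model$eigenfunctions)
  expect_identical(again$scores$scores, fixed$scores$scores)
  # phi1 non-positive on average; phi2 positive at birth
  expect_lte(mean(fixed$model$eigenfunctions[, 1]), 0)
  expect_gt(fixed$model$eigenfunctions[1, 2], 0)
  # reconstruction invariant under the joint flip
  expect_equal(fixed$scores$fitted, sc$fitted, tolerance = 1e-12)
})

test_that("conditional-expectation scores behave like a BLUP", {
  fx <- cached_default_fit("male")
  model <- fx$fit$model
  grid <- model$grid

  # child observed exactly on the mean curve has zero scores
  on_mean <- haz_cohort(data.frame(
    child_id = "m0", sex = "male", age = grid[seq(1, 101, by = 10)],
    haz = model$mean[seq(1, 101, by = 10)]))
  sc0 <- estimate_scores(on_mean, model)
  expect_equal(unname(unlist(sc0$scores[, c("s1", "s2")])), c(0, 0),
               tolerance = 1e-10)

  # dense noiseless child at mu + 2 phi1 with sigma2 -> 0: s1 -> 2, s2 -> 0
  m0 <- model
  m0$noise_var <- 0
  dense <- haz_cohort(data.frame(
    child_id = "d2", sex = "male", age = grid,
    haz = model$mean + 2 * model$eigenfunctions[, 1]))
  sc2 <- suppressWarnings(estimate_scores(dense, m0))
  expect_equal(sc2$scores$s1, 2, tolerance = 1e-3)
  expect_equal(sc2$scores$s2, 0, tolerance = 1e-3)
  # fitted curve is exactly mu + s1 phi1 + s2 phi2
  expect_equal(as.vector(sc2$fitted),
               model$mean + sc2$scores$s1 * model$eigenfunctions[, 1] +
                 sc2$scores$s2 * model$eigenfunctions[, 2],
               tolerance = 1e-12)

  # shrinkage: inflating sigma2 pulls both scores strictly toward zero
  m_noisy <- model
  m_noisy$noise_var <- 5
  sc_noisy <- estimate_scores(dense, m_noisy)
  expect_lt(abs(sc_noisy$scores$s1), abs(sc2$scores$s1))
  expect_gt(abs(sc_noisy$scores$s1), 0)
})

test_that("dense balanced noiseless fits match classical PCA (oracle equivalence)", {
  m <- default_generative_model("male", covariate_effects = NULL)
  dc <- dense_cohort(m, n = 80, seed = 17)
  grid <- m$grid
  dt <- grid[2]
  # data matrix children x grid, centred at the sample mean
  Y <- t(vapply(split(dc$cohort$observations$haz,
                      dc$cohort$observations$child_id),
                identity, numeric(length(grid))))
  C <- stats::cov(Y)
  eg <- eigendecompose((C + t(C)) / 2, grid, n_components = 2)
  oracle <- eigen(C, symmetric = TRUE)
  expect_lt(max(abs(eg$eigenvalues - oracle$values[1:2] * dt)), 1e-6)
  for (k in 1:2) {
    v <- oracle$vectors[, k] / sqrt(dt)
    expect_lt(min(max(abs(eg$eigenfunctions[, k] - v)),
                  max(abs(eg$eigenfunctions[, k] + v))), 1e-6)
  }
})

test_that("fitted models satisfy structural invariants and recover truth", {
  for (sx in c("male", "female")) {
    fx <- cached_default_fit(sx)
    model <- fx$fit$model
    dt <- model$grid[2]
    gram <- t(model$eigenfunctions) %*% model$eigenfunctions * dt
    expect_lt(max(abs(gram - diag(2))), 1e-6)
    expect_true(all(diff(model$eigenvalues) <= 0))
    expect_true(all(diff(model$fve) >= 0) && model$fve[2] <= 1)
    expect_gte(model$noise_var, 0)
    # rank-2 generator: two components dominate
    expect_gt(model$fve[2], 0.95)
    # scores recover the generating truth, positively signed after the
    # sign convention
    tr <- aligned_truth(fx$sim, fx$fit$scores)
    expect_gt(cor(fx$fit$scores$scores$s1, tr$s1_true), 0.95)
    expect_gt(cor(fx$fit$scores$scores$s2, tr$s2_true), 0.7)
  }
})

test_that("refitting the same cohort is bit-identical and serializes exactly", {
  fx <- cached_default_fit("male")
  fit2 <- fit_fpca(fx$cohort)
  expect_identical(fx$fit$model$eigenvalues, fit2$model$eigenvalues)
  expect_identical(fx$fit$scores$scores, fit2$scores$scores)

  dir <- withr::local_tempdir()
  f <- file.path(dir, "model.json")
  write_fpca_model(fx$fit$model, f)
  back <- read_fpca_model(f)
  expect_equal(back$mean, fx$fit$model$mean, tolerance = 1e-12)
  expect_equal(back$eigenvalues, fx$fit$model$eigenvalues, tolerance = 1e-12)
  expect_equal(back$eigenfunctions,
               unname(fx$fit$model$eigenfunctions), tolerance = 1e-12)
  # reloaded model scores the cohort identically to tight tolerance
  sc <- estimate_scores(fx$cohort, back)
  expect_equal(sc$scores$s1, fx$fit$scores$scores$s1, tolerance = 1e-12)
})
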