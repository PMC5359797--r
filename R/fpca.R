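# Sparse FPCA for irregular, noisy longitudinal data: smoothed mean,
# smoothed covariance surface with measurement-error variance, quadrature
# eigendecomposition, and conditional-expectation (BLUP) scores.

#' FPCA fitting settings
#'
#' @param grid Evaluation grid (default 101 equally spaced ages on
#'   \[0, 24\] months).
#' @param bandwidth_mean Bandwidth in months for the mean smoother, or
#'   `"auto"` for generalized cross-validation over a geometric ladder of 8
#'   candidates.
#' @param bandwidth_cov Bandwidth for the covariance-surface smoother, or
#'   `"auto"`.
#' @param n_components Number of components retained (2: an overall-growth
#'   and a trajectory-change component).
#' @return A list of settings.
#' @export
fpca_settings <- function(grid = default_grid(),
                          bandwidth_mean = "auto",
                          bandwidth_cov = "auto",
                          n_components = 2L) {
  list(grid = grid, bandwidth_mean = bandwidth_mean,
       bandwidth_cov = bandwidth_cov, n_components = as.integer(n_components))
}

#' Estimate the mean HAZ curve
#'
#' Local-linear Gaussian-kernel smooth of the pooled (age, HAZ) scatter,
#' evaluated on the grid. Observations are pre-binned to the grid (weighted
#' by counts). With `bandwidth = "auto"` the bandwidth minimizes generalized
#' cross-validation over a geometric ladder of 8 candidates.
#'
#' @param cohort A [haz_cohort()].
#' @param grid Evaluation grid.
#' @param bandwidth Months, or `"auto"`.
#' @return A list with `grid`, `mean` (values on the grid) and `bandwidth`.
#' @export
estimate_mean <- function(cohort, grid = default_grid(), bandwidth = "auto") {
  obs <- cohort$observations
  if (length(unique(obs$age)) < 2L) {
    stop("mean estimation needs observations at >= 2 distinct ages",
         call. = FALSE)
  }
  b <- bin_1d(obs$age, obs$haz, grid)
  if (identical(bandwidth, "auto")) {
    bandwidth <- select_bandwidth_1d(b$x, b$y, b$w, grid)
  }
  mu <- lls_1d(b$x, b$y, b$w, grid, bandwidth)
  list(grid = grid, mean = mu, bandwidth = bandwidth)
}

#' Estimate the covariance surface and measurement-error variance
#'
#' Raw covariances `(Y_ij - mu(t_ij)) (Y_il - mu(t_il))` for distinct visit
#' pairs (j != l) of each child are smoothed over the plane with a
#' local-plane Gaussian product-kernel smoother; same-visit pairs are
#' excluded, so the smoothed surface estimates the error-free covariance
#' `G(s, t)`. The measurement-error variance is the average excess of the
#' smoothed diagonal-inclusive variance over the surface diagonal, taken over
#' the central 80% of the grid and floored at zero. The surface is
#' symmetrized.
#'
#' @param cohort A [haz_cohort()].
#' @param grid Evaluation grid.
#' @param mean Mean curve on the grid (from [estimate_mean()]).
#' @param bandwidth Months, or `"auto"` (GCV over a ladder of 8 candidates).
#' @return A list with `surface` (grid x grid matrix), `noise_var`
#'   (sigma^2 >= 0) and `bandwidth`.
#' @export
estimate_covariance <- function(cohort, grid = default_grid(), mean,
                                bandwidth = "auto") {
  obs <- cohort$observations
  resid <- obs$haz - interp_grid(grid, mean, obs$age)
  split_idx <- split(seq_len(nrow(obs)), obs$child_id)
  multi <- split_idx[vapply(split_idx, length, integer(1)) >= 2L]
  if (length(multi) == 0L) {
    stop("covariance estimation needs at least one child with >= 2 observations",
         call. = FALSE)
  }
  pairs <- lapply(multi, function(ii) {
    k <- length(ii)
    pj <- rep(ii, each = k)
    pl <- rep(ii, times = k)
    keep <- pj != pl
    cbind(pj[keep], pl[keep])
  })
  pairs <- do.call(rbind, pairs)
  s <- obs$age[pairs[, 1]]
  t <- obs$age[pairs[, 2]]
  cc <- resid[pairs[, 1]] * resid[pairs[, 2]]

  bins <- bin_2d(s, t, cc, grid)
  if (identical(bandwidth, "auto")) {
    bandwidth <- select_bandwidth_2d(bins, grid)
  }
  surf <- lls_2d(bins, grid, bandwidth)$fit
  surf <- (surf + t(surf)) / 2

  # diagonal-inclusive variance: smooth of squared residuals against age
  vb <- bin_1d(obs$age, resid * resid, grid)
  vdiag <- lls_1d(vb$x, vb$y, vb$w, grid, bandwidth)
  inner <- grid >= grid[1] + 0.1 * diff(range(grid)) &
    grid <= grid[length(grid)] - 0.1 * diff(range(grid))
  noise_var <- max(0, mean(vdiag[inner] - diag(surf)[inner]))

  list(surface = surf, noise_var = noise_var, bandwidth = bandwidth)
}

#' Eigendecompose a covariance surface
#'
#' Quadrature-weighted (uniform grid step) eigendecomposition of a symmetric
#' surface. Negative eigenvalues are truncated to zero and excluded from the
#' fraction-of-variance-explained denominator; eigenfunctions are normalized
#' to unit quadrature norm.
#'
#' @param surface Symmetric grid x grid matrix.
#' @param grid Evaluation grid.
#' @param n_components Number of components to return.
#' @return A list with `eigenfunctions` (grid x K matrix), `eigenvalues`
#'   (length K), `fve` (cumulative fraction of variance explained, length K)
#'   and `all_positive` (full positive spectrum, for surface reconstruction).
#' @export
eigendecompose <- function(surface, grid, n_components = 2L) {
  if (max(abs(surface - t(surface))) > 1e-8 * max(1, max(abs(surface)))) {
    stop("surface must be symmetric", call. = FALSE)
  }
  dt <- grid_step(grid)
  eg <- eigen(surface * dt, symmetric = TRUE)
  pos <- eg$values > .Machine$double.eps * max(abs(eg$values), 1)
  lam_pos <- eg$values[pos]
  vec_pos <- eg$vectors[, pos, drop = FALSE] / sqrt(dt)
  n_pos <- length(lam_pos)
  if (n_components > n_pos) {
    warning("only ", n_pos, " positive component(s) available; returning all",
            call. = FALSE)
    n_components <- n_pos
  }
  k <- seq_len(n_components)
  fve <- cumsum(lam_pos)[k] / sum(lam_pos)
  list(eigenfunctions = vec_pos[, k, drop = FALSE],
       eigenvalues = lam_pos[k],
       fve = fve,
       all_positive = list(values = lam_pos, vectors = vec_pos))
}

#' Apply the growth-trajectory sign convention
#'
#' Eigenfunctions are defined up to sign. The convention fixed here makes
#' scores interpretable: the first component is non-positive on average over
#' age (larger score = overall worse growth), and the second component is
#' positive at the earliest age (larger score = later downward deviation,
#' i.e. faltering). Stored scores, if present, are flipped consistently, so
#' reconstructions are unchanged. Idempotent.
#'
#' @param model A `fpca_model`.
#' @param scores Optional score table from [estimate_scores()] to flip in
#'   step with the model.
#' @return The model (or, when `scores` is given, a list with `model` and
#'   `scores`).
#' @export
apply_sign_convention <- function(model, scores = NULL) {
  flip <- c(1, 1)
  if (mean(model$eigenfunctions[, 1]) > 0) flip[1] <- -1
  if (ncol(model$eigenfunctions) >= 2L && model$eigenfunctions[1, 2] < 0) {
    flip[2] <- -1
  }
  k <- seq_len(min(2L, ncol(model$eigenfunctions)))
  model$eigenfunctions[, k] <- sweep(model$eigenfunctions[, k, drop = FALSE],
                                     2, flip[k], "*")
  model$sign_flips <- flip[k]
  if (is.null(scores)) return(model)
  scores$scores[, c("s1", "s2")[k]] <-
    sweep(as.matrix(scores$scores[, c("s1", "s2")[k], drop = FALSE]),
          2, flip[k], "*")
  scores$fitted <- fitted_curves(model, scores$scores)
  list(model = model, scores = scores)
}

# Reconstruct fitted curves mu + s1 phi1 + s2 phi2 (rows = children).
fitted_curves <- function(model, score_df) {
  s <- as.matrix(score_df[, c("s1", "s2"), drop = FALSE])
  f <- matrix(model$mean, nrow = nrow(s), ncol = length(model$grid),
              byrow = TRUE) + s %*% t(model$eigenfunctions[, 1:2])
  rownames(f) <- score_df$child_id
  f
}

#' Estimate FPC scores by conditional expectation
#'
#' For child i with observation ages `t_i`, the score on component k is the
#' best linear predictor
#' `s_ik = lambda_k phi_k(t_i)' Sigma_i^{-1} (Y_i - mu(t_i))` with
#' `Sigma_i = G(t_i, t_i) + sigma^2 I`, where `G` is the positive-semidefinite
#' projection of the smoothed surface. This shrinks scores of sparsely or
#' noisily observed children toward zero, which is what makes 5-visit
#' children scorable at all. Curve values at observation ages are
#' interpolated from the grid.
#'
#' @param cohort A [haz_cohort()].
#' @param model A `fpca_model` (see [fit_fpca()]).
#' @return An object of class `fpca_scores`: list with `scores` (data frame
#'   `child_id`, `sex`, `s1`, `s2`) and `fitted` (children x grid matrix of
#'   reconstructed curves).
#' @export
estimate_scores <- function(cohort, model) {
  obs <- cohort$observations
  grid <- model$grid
  ap <- model$spectrum
  if (is.null(ap)) {
    ap <- list(values = model$eigenvalues, vectors = model$eigenfunctions)
  }
  # PSD surface from the positive spectrum
  G <- ap$vectors %*% (ap$values * t(ap$vectors))
  sigma2 <- model$noise_var
  phi <- model$eigenfunctions[, 1:2, drop = FALSE]
  lam <- model$eigenvalues[1:2]

  idx <- split(seq_len(nrow(obs)), obs$child_id)
  ids <- names(idx)
  out <- matrix(NA_real_, length(ids), 2L,
                dimnames = list(ids, c("s1", "s2")))
  sexes <- character(length(ids))
  ridge_warned <- FALSE
  for (i in seq_along(idx)) {
    ii <- idx[[i]]
    ti <- obs$age[ii]
    yi <- obs$haz[ii] - interp_grid(grid, model$mean, ti)
    m <- length(ti)
    Gi <- matrix(interp_surface(grid, G,
                                rep(ti, times = m), rep(ti, each = m)), m, m)
    Gi <- (Gi + t(Gi)) / 2
    Sig <- Gi + diag(sigma2, m)
    sol <- tryCatch(solve(Sig, yi), error = function(e) NULL)
    if (is.null(sol) || rcond(Sig) < 1e-12) {
      if (!ridge_warned) {
        warning("near-singular within-child covariance; ridge-stabilizing",
                call. = FALSE)
        ridge_warned <- TRUE
      }
      Sig <- Sig + diag(1e-8, m)
      sol <- solve(Sig, yi)
    }
    phit <- cbind(interp_grid(grid, phi[, 1], ti),
                  interp_grid(grid, phi[, 2], ti))
    out[i, ] <- lam * drop(t(phit) %*% sol)
    sexes[i] <- obs$sex[ii[1]]
  }
  score_df <- data.frame(child_id = ids, sex = sexes,
                         s1 = out[, 1], s2 = out[, 2],
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(scores = score_df,
                 fitted = fitted_curves(model, score_df)),
            class = "fpca_scores")
}

#' Fit sparse FPCA end to end
#'
#' Composes mean smoothing, covariance smoothing with measurement-error
#' estimation, quadrature eigendecomposition (two components by default),
#' the sign convention, and conditional-expectation scoring. A warning is
#' emitted when the two retained components explain less than 90% of the
#' error-free curve variance.
#'
#' @param cohort A [haz_cohort()] (single sex; use [split_by_sex()] first).
#' @param settings See [fpca_settings()].
#' @return A list with `model` (class `fpca_model`: `grid`, `mean`,
#'   `eigenfunctions`, `eigenvalues`, `noise_var`, `fve`, `n_subjects`,
#'   `bandwidths`, `spectrum`) and `scores` (class `fpca_scores`).
#' @export
fit_fpca <- function(cohort, settings = fpca_settings()) {
  grid <- settings$grid
  mu <- estimate_mean(cohort, grid, settings$bandwidth_mean)
  cv <- estimate_covariance(cohort, grid, mu$mean, settings$bandwidth_cov)
  eg <- eigendecompose(cv$surface, grid, settings$n_components)
  model <- structure(list(
    grid = grid,
    mean = mu$mean,
    eigenfunctions = eg$eigenfunctions,
    eigenvalues = eg$eigenvalues,
    noise_var = cv$noise_var,
    fve = eg$fve,
    n_subjects = n_children(cohort),
    bandwidths = c(mean = mu$bandwidth, cov = cv$bandwidth),
    spectrum = eg$all_positive,
    sex = cohort$observations$sex[1]
  ), class = "fpca_model")
  model <- apply_sign_convention(model)
  if (length(model$fve) >= 2L && model$fve[2] < 0.9) {
    warning("two components explain only ",
            round(100 * model$fve[2], 1),
            "% of curve variance", call. = FALSE)
  }
  scores <- estimate_scores(cohort, model)
  list(model = model, scores = scores)
}

#' @export
print.fpca_model <- function(x, ...) {
  cat("<fpca_model> ", x$n_subjects, " subjects, grid of ",
      length(x$grid), " ages on [", x$grid[1], ", ",
      x$grid[length(x$grid)], "] months\n", sep = "")
  cat("  eigenvalues: ", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n  FVE: ", paste(signif(x$fve, 4), collapse = ", "),
      "\n  noise variance: ", signif(x$noise_var, 4), "\n", sep = "")
  invisible(x)
}

#' Serialize a fitted FPCA model to structured text (JSON)
#'
#' Stores everything needed for exact reload: grid, mean, eigenfunctions,
#' eigenvalues, noise variance, FVE, bandwidths and the full positive
#' spectrum. Values are written at full double precision.
#'
#' @param model A `fpca_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fpca_model <- function(model, path) {
  payload <- list(
    sex = model$sex,
    grid = model$grid,
    mean = model$mean,
    eigenfunctions = model$eigenfunctions,
    eigenvalues = model$eigenvalues,
    noise_var = model$noise_var,
    fve = model$fve,
    n_subjects = model$n_subjects,
    bandwidths = as.list(model$bandwidths),
    sign_flips = model$sign_flips,
    spectrum = list(values = model$spectrum$values,
                    vectors = model$spectrum$vectors)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Reload a serialized FPCA model
#' @param path Path written by [write_fpca_model()].
#' @return A `fpca_model`.
#' @export
read_fpca_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    grid = as.numeric(p$grid),
    mean = as.numeric(p$mean),
    eigenfunctions = as.matrix(p$eigenfunctions),
    eigenvalues = as.numeric(p$eigenvalues),
    noise_var = as.numeric(p$noise_var),
    fve = as.numeric(p$fve),
    n_subjects = as.integer(p$n_subjects),
    bandwidths = unlist(p$bandwidths),
    spectrum = list(values = as.numeric(p$spectrum$values),
                    vectors = as.matrix(p$spectrum$vectors)),
    sign_flips = as.numeric(p$sign_flips),
    sex = p$sex
  ), class = "fpca_model")
}

#' Write a score table to CSV
#' @param scores An `fpca_scores` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- scores$scores
  out$s1 <- format_full(out$s1)
  out$s2 <- format_full(out$s2)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
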