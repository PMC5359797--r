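# Local-linear kernel smoothers used by the FPCA stage. Raw data are first
# binned to the evaluation grid (weighted by counts), which keeps the 2-D
# covariance smoother tractable for cohorts of hundreds of children while
# changing estimates only at the sub-grid-step scale.

gauss_kernel <- function(u, h) exp(-(u * u) / (2 * h * h))

# Bin (x, y) pairs to the nearest grid point; returns per-bin weighted means
# and counts for nonempty bins.
bin_1d <- function(x, y, grid) {
  h <- grid_step(grid)
  idx <- pmin(pmax(round((x - grid[1]) / h) + 1, 1), length(grid))
  cnt <- tapply(rep(1, length(x)), idx, sum)
  ybar <- tapply(y, idx, mean)
  i <- as.integer(names(cnt))
  list(x = grid[i], y = as.numeric(ybar), w = as.numeric(cnt))
}

# Weighted local-linear fit of binned data, evaluated at `xout`. Returns
# fitted values; when `hat = TRUE` also the hat diagonal at the bin centers
# (for GCV), in which case xout must equal the bin centers.
lls_1d <- function(xb, yb, wb, xout, h, hat = FALSE) {
  K <- gauss_kernel(outer(xout, xb, "-"), h)        # m x B
  W <- sweep(K, 2, wb, "*")
  D <- outer(xout, xb, "-")
  S0 <- rowSums(W)
  S1 <- rowSums(W * D)
  S2 <- rowSums(W * D * D)
  T0 <- rowSums(W * rep(yb, each = length(xout)))
  T1 <- rowSums(W * D * rep(yb, each = length(xout)))
  det <- S0 * S2 - S1 * S1
  # fall back to local constant where the local design is degenerate
  fit <- ifelse(abs(det) > 1e-12 * pmax(S0 * S2, 1e-300),
                (S2 * T0 - S1 * T1) / det,
                T0 / pmax(S0, 1e-300))
  if (!hat) return(fit)
  # hat diagonal: weight the bin's own (binned) response receives at its
  # center; per raw observation the leverage is hat_b / count_b.
  k0 <- gauss_kernel(0, h)
  hat_diag <- ifelse(abs(det) > 1e-12 * pmax(S0 * S2, 1e-300),
                     wb * k0 * S2 / det,
                     wb * k0 / pmax(S0, 1e-300))
  list(fit = fit, hat = hat_diag)
}

# Geometric bandwidth ladder spanning sparse-visit to oversmoothed scales.
bandwidth_ladder <- function(grid, n_candidates = 8L,
                             lo = 1.0, hi = 0.5 * diff(range(grid))) {
  exp(seq(log(lo), log(hi), length.out = n_candidates))
}

# GCV over a bandwidth ladder for the 1-D smoother on binned data.
select_bandwidth_1d <- function(xb, yb, wb, grid, ladder = bandwidth_ladder(grid)) {
  n <- sum(wb)
  scores <- vapply(ladder, function(h) {
    f <- lls_1d(xb, yb, wb, xb, h, hat = TRUE)
    tr <- sum(f$hat)
    if (!is.finite(tr) || tr >= 0.95 * n) return(Inf)
    rss <- sum(wb * (yb - f$fit)^2)
    n * rss / (n - tr)^2
  }, numeric(1))
  if (all(!is.finite(scores))) return(ladder[length(ladder)])
  ladder[which.min(scores)]
}

# --- 2-D smoother on the grid x grid plane ---------------------------------

# Bin (s, t, y) triples to grid-cell centers.
bin_2d <- function(s, t, y, grid) {
  h <- grid_step(grid)
  n <- length(grid)
  is_ <- pmin(pmax(round((s - grid[1]) / h) + 1, 1), n)
  it_ <- pmin(pmax(round((t - grid[1]) / h) + 1, 1), n)
  key <- (is_ - 1L) * n + it_
  cnt <- tapply(rep(1, length(y)), key, sum)
  ybar <- tapply(y, key, mean)
  k <- as.integer(names(cnt))
  iu <- (k - 1L) %/% n + 1L
  iv <- (k - 1L) %% n + 1L
  list(u = grid[iu], v = grid[iv], iu = iu, iv = iv,
       y = as.numeric(ybar), w = as.numeric(cnt))
}

# Weighted local-plane (degree-1) fit of binned surface data, evaluated on
# the full grid x grid. Exploits the product kernel: bins sit on grid cells,
# so 1-D kernel matrices over the grid suffice. Returns the fitted surface;
# with `hat = TRUE` also the hat diagonal at the nonempty bins.
lls_2d <- function(bins, grid, h, hat = FALSE) {
  n <- length(grid)
  Kg <- gauss_kernel(outer(grid, grid, "-"), h)     # n x n 1-D kernel
  u <- bins$u; v <- bins$v; w <- bins$w; y <- bins$y
  B <- length(y)
  Kv <- Kg[, bins$iv, drop = FALSE]                 # n x B: k(t_j - v_b)
  Ku <- Kg[, bins$iu, drop = FALSE]                 # n x B: k(s_i - u_b)
  fit <- matrix(NA_real_, n, n)
  hat_diag <- if (hat) numeric(B) else NULL
  ones <- rep(1, B)
  k0 <- gauss_kernel(0, h)

  for (i in seq_len(n)) {
    a <- Ku[i, ] * w                                # bin weights for row i
    du <- u - grid[i]
    # moment columns: [1, du, v, du^2, du*v, v^2, y, y*du, y*v]
    M <- cbind(ones, du, v, du * du, du * v, v * v, y, y * du, y * v) * a
    S <- Kv %*% M                                   # n x 9 row sums per t_j
    S00 <- S[, 1]; S10 <- S[, 2]
    S01 <- S[, 3] - grid * S00
    S20 <- S[, 4]
    S11 <- S[, 5] - grid * S10
    S02 <- S[, 6] - 2 * grid * S[, 3] + grid^2 * S00
    T00 <- S[, 7]; T10 <- S[, 8]
    T01 <- S[, 9] - grid * S[, 7]
    # solve 3x3 normal equations [S00 S10 S01; S10 S20 S11; S01 S11 S02]
    # for the local intercept via Cramer's rule (vectorized over t_j)
    A11 <- S20 * S02 - S11 * S11
    A12 <- S10 * S02 - S11 * S01
    A13 <- S10 * S11 - S20 * S01
    det3 <- S00 * A11 - S10 * A12 + S01 * A13
    b0 <- (T00 * A11 - T10 * A12 + T01 * A13) / det3
    # local-constant fallback where the plane fit is degenerate
    bad <- !is.finite(b0) | abs(det3) < 1e-10 * pmax(abs(S00 * A11), 1e-300)
    if (any(bad)) b0[bad] <- (T00 / pmax(S00, 1e-300))[bad]
    fit[i, ] <- b0
    if (hat) {
      sel <- which(bins$iu == i)
      if (length(sel) > 0) {
        j <- bins$iv[sel]
        inv11 <- A11 / det3
        lv <- ifelse(bad, 1 / pmax(S00, 1e-300), inv11)
        hat_diag[sel] <- w[sel] * k0 * k0 * lv[j]
      }
    }
  }
  if (hat) list(fit = fit, hat = hat_diag) else list(fit = fit)
}

# The covariance ladder starts near the nominal visit spacing: raw
# covariances only exist at visit-pair ages, so narrower kernels cannot
# pool between age clusters and GCV degenerates toward fitting pair noise.
select_bandwidth_2d <- function(bins, grid,
                                ladder = bandwidth_ladder(grid, lo = 2.0)) {
  n_raw <- sum(bins$w)
  scores <- vapply(ladder, function(h) {
    f <- lls_2d(bins, grid, h, hat = TRUE)
    tr <- sum(f$hat)
    if (!is.finite(tr) || tr >= 0.95 * n_raw) return(Inf)
    fitted_at_bins <- f$fit[cbind(bins$iu, bins$iv)]
    rss <- sum(bins$w * (bins$y - fitted_at_bins)^2)
    n_raw * rss / (n_raw - tr)^2
  }, numeric(1))
  if (all(!is.finite(scores))) return(ladder[length(ladder)])
  ladder[which.min(scores)]
}
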