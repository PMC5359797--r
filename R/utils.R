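# Internal helpers shared across the package.

#' Default evaluation grid
#'
#' Equally spaced ages (months) on \[0, 24\] used for all functional objects.
#'
#' @param n_points Number of grid points.
#' @return Numeric vector of ages in months.
#' @export
default_grid <- function(n_points = 101L) {
  seq(0, 24, length.out = n_points)
}

# Uniform quadrature weight (Riemann sum step) for a regular grid.
grid_step <- function(grid) {
  stopifnot(length(grid) >= 2L)
  diff(grid[1:2])
}

# Quadrature inner product <f, g> = sum f g dt on a regular grid.
quad_inner <- function(f, g, grid) {
  sum(f * g) * grid_step(grid)
}

# Evaluate randomness with a local, restorable RNG state so that simulation
# functions are deterministic in `seed` without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Linear interpolation of a grid function at arbitrary ages (no extrapolation
# beyond the grid range; `rule = 2` clamps to the boundary values).
interp_grid <- function(grid, values, at) {
  stats::approx(grid, values, xout = at, rule = 2)$y
}

# Bilinear interpolation of a grid x grid surface at arbitrary (s, t) pairs.
interp_surface <- function(grid, surface, s, t) {
  n <- length(grid)
  clamp <- function(x) pmin(pmax(x, grid[1]), grid[n])
  s <- clamp(s); t <- clamp(t)
  h <- grid_step(grid)
  is_ <- pmin(pmax(floor((s - grid[1]) / h) + 1, 1), n - 1)
  it_ <- pmin(pmax(floor((t - grid[1]) / h) + 1, 1), n - 1)
  ws <- (s - grid[is_]) / h
  wt <- (t - grid[it_]) / h
  v00 <- surface[cbind(is_, it_)]
  v10 <- surface[cbind(is_ + 1, it_)]
  v01 <- surface[cbind(is_, it_ + 1)]
  v11 <- surface[cbind(is_ + 1, it_ + 1)]
  (1 - ws) * (1 - wt) * v00 + ws * (1 - wt) * v10 +
    (1 - ws) * wt * v01 + ws * wt * v11
}

# Format numbers for CSV output at full double precision so that a
# write/read roundtrip is lossless.
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    sprintf("%.17g", v)
  }, character(1))
  out
}
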