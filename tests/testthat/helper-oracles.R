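# Independent oracles used across tests. These deliberately re-derive the
# quantities from first principles (hand-coded quantiles, naive loops, grid
# search, enumeration) rather than calling the package's own code paths.

# Hand-coded linear-interpolation (type 7) sample quantile.
quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Naive two-loop SEM caller: per-probe fences from hand-coded quantiles,
# then a per-cell comparison.
naive_sem_mask <- function(m) {
  mask <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ok <- !is.na(x)
    q1 <- quantile7(x[ok], 0.25)
    q3 <- quantile7(x[ok], 0.75)
    iqr <- q3 - q1
    lo <- q1 - 3 * iqr
    hi <- q3 + 3 * iqr
    for (i in seq_len(nrow(m))) {
      mask[i, j] <- !is.na(m[i, j]) && (m[i, j] < lo || m[i, j] > hi)
    }
  }
  mask
}

# REML profile log-likelihood, vectorized over a tau2 grid.
reml_ll_grid <- function(t2_grid, b, v) {
  vmat <- outer(t2_grid, v, "+")
  w <- 1 / vmat
  s <- rowSums(w)
  bh <- as.vector(w %*% b) / s
  dev <- sweep(matrix(b, length(t2_grid), length(b), byrow = TRUE), 1, bh)
  -0.5 * (rowSums(log(vmat)) + log(s) + rowSums(w * dev^2))
}

# Iteratively refined grid search for the REML tau2 (three passes of 10,001
# points, zooming on the bracketing interval; final resolution far below
# 1e-6) and the corresponding pooled mean.
grid_reml_oracle <- function(b, v, tau2_max = 10 * max(v) * length(b),
                             stages = 3, points = 10001) {
  lo <- 0
  hi <- tau2_max
  t2 <- 0
  for (s in seq_len(stages)) {
    grid <- seq(lo, hi, length.out = points)
    vals <- reml_ll_grid(grid, b, v)
    i <- which.max(vals)
    step <- grid[2] - grid[1]
    t2 <- grid[i]
    lo <- max(0, t2 - step)
    hi <- min(tau2_max, t2 + step)
  }
  w <- 1 / (v + t2)
  list(tau2 = t2, beta = sum(w * b) / sum(w))
}

# Ordinary least squares by explicit normal equations.
normal_equations_ols <- function(X, y) {
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(solve(xtx)) * sigma2)
  list(beta = drop(beta), se = se)
}

# Exact tail probability of the overlap count when drawing n_loci probes
# uniformly without replacement from a universe with `k_in` probes inside
# the region set (hypergeometric enumeration).
exact_overlap_tail <- function(observed, n_universe, k_in, n_loci) {
  counts <- 0:n_loci
  probs <- stats::dhyper(counts, k_in, n_universe - k_in, n_loci)
  sum(probs[counts >= observed])
}

# Small synthetic-study config used by several suites: quick to simulate,
# all five factors present in every cohort.
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(n_cohorts = 2, n_per_cohort = 120, n_clock_cpgs = 30,
                   n_sem_cpgs = 80, n_wbc_cpgs = 20, n_inert_cpgs = 10,
                   seed = 42)
  do.call(simulation_config, utils::modifyList(defaults, args))
}
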