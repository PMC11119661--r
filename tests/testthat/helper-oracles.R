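# Shared fixtures and independent oracles for the test suite.

# Worked bistable example used throughout: strong steep positive feedback,
# weak basal rate, gates at their long-time value.
p_star <- model_parameters(a = 2, b = 0, c = 0.05, d = 1, K = 1, k = 4)

# Draw n random in-bounds parameter sets, reproducibly.
random_parameter_sets <- function(n, seed = 1) {
  set.seed(seed)
  m <- genecircuit:::sample_log_uniform(default_bounds(), n)
  lapply(seq_len(n), function(i) as_parameters(m[i, ]))
}

# Brute-force fixed-point oracle: dense sign scan of the steady-state
# function on a log grid, roots refined with uniroot (Brent), stability from
# the local sign pattern. Deliberately independent of find_fixed_points.
oracle_fixed_points <- function(p, x_lo = 1e-4, x_hi = NULL, n_grid = 1e5) {
  if (is.null(x_hi)) {
    x_hi <- max(10, 2 * (p[["a"]] + p[["c"]]) / max(p[["d"]], 1e-12))
    while (steady_state_function(x_hi, p) > 0) x_hi <- x_hi * 2
  }
  grid <- exp(seq(log(x_lo), log(x_hi), length.out = n_grid))
  gv <- steady_state_function(grid, p)
  idx <- which(gv[-n_grid] * gv[-1] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(function(x) steady_state_function(x, p),
                   c(grid[i], grid[i + 1]), tol = 1e-13)$root
  }, 0)
  stable <- gv[idx] > 0  # descending crossing => stable
  data.frame(x_star = roots, stable = stable)
}

# Exact solution of the feedback-free linear circuit dx/dt = c - d x.
linear_solution <- function(x0, c0, d0, t) {
  if (d0 == 0) return(x0 + c0 * t)
  c0 / d0 + (x0 - c0 / d0) * exp(-d0 * t)
}
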