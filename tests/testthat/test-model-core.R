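test_that("Hill terms evaluate their algebraic corners and stay in [0, 1]", {
  expect_equal(hill_term(1, 1, 1), 0.5)
  expect_equal(hill_term(0.5, 4, 0), 1)
  expect_equal(hill_term(0.5, 4, 1), 0.0625 / 1.0625)
  expect_equal(hill_term(0.3, 0, 3), 1 / 4)  # h = 0 gives 1 / (1 + H)
  expect_error(hill_term(0, 2, 0), "degenerate")

  expect_equal(time_factor(0, 2, 1), 0)
  expect_equal(time_factor(1, 2, 1), 0.5)
  expect_equal(time_factor(Inf, 2, 1), 1)
  expect_equal(time_factor(Inf, 0, 3), 1 / 4)

  for (p in random_parameter_sets(25, seed = 4)) {
    x <- exp(seq(log(1e-4), log(10), length.out = 30))
    h1 <- hill_term(x, p[["k"]], p[["K"]])
    h2 <- time_factor(c(0, 0.3, 1, 5, Inf), p[["m"]], p[["M"]])
    expect_true(all(h1 >= 0 & h1 <= 1))
    expect_true(all(h2 >= 0 & h2 <= 1))
    expect_true(all(diff(h1) >= -1e-12))  # monotone in x
  }
})

test_that("model right-hand side matches direct arithmetic and its bounds", {
  p <- model_parameters(c = 0.3, d = 1)
  expect_equal(model_rhs(0.5, 0.7, p), -0.2)

  p2 <- model_parameters(a = 2, k = 1, K = 1, m = 2, M = 1, d = 0)
  expect_equal(model_rhs(1, 1, p2), 0.5)

  # independent scripted evaluation of the full expression
  p3 <- model_parameters(a = 1.5, b = 0.8, c = 0.05, d = 1, K = 0.7, L = 2,
                         M = 0.1, N = 0.3, k = 2, l = 1, m = 2, n = 4)
  x <- 1.2; t <- 0.4
  expected <- 1.5 * (x^2 / (x^2 + 0.7)) * (t^2 / (t^2 + 0.1)) -
    0.8 * (x / (x + 2)) * (t^4 / (t^4 + 0.3)) + 0.05 - 1 * x
  expect_equal(model_rhs(x, t, p3), expected)

  # F bounded above by a + c and below by -(b + d x) + c
  for (p in random_parameter_sets(25, seed = 5)) {
    x <- exp(seq(log(1e-4), log(10), length.out = 20))
    f <- model_rhs(x, 0.5, p)
    expect_true(all(f <= p[["a"]] + p[["c"]] + 1e-12))
    expect_true(all(f >= -(p[["b"]] + p[["d"]] * x) + p[["c"]] - 1e-12))
  }
})

test_that("integration is exact on closed-form cases and clamps its output", {
  p <- model_parameters(d = 1)
  tr <- integrate_trajectory(p, 1, c(0, 0.5, 1))
  expect_equal(tr$x, exp(-c(0, 0.5, 1)), tolerance = 1e-6)

  # pure constant production from the clamp floor
  tr2 <- integrate_trajectory(model_parameters(c = 1, d = 1e-12), 1e-4,
                              c(0, 0.5, 1))
  expect_equal(tr2$x[3], 1.0001, tolerance = 1e-6)

  # clamp: strong decay cannot emit values below the floor
  tr3 <- integrate_trajectory(model_parameters(d = 20), 0.5,
                              seq(0, 2, length.out = 30))
  expect_true(all(tr3$x >= EXPR_CLAMP))

  # determinism
  p4 <- random_parameter_sets(1, seed = 8)[[1]]
  a1 <- integrate_trajectory(p4, 0.5, seq(0, 1, length.out = 40))
  a2 <- integrate_trajectory(p4, 0.5, seq(0, 1, length.out = 40))
  expect_identical(a1, a2)
})

test_that("bistable integration converges to the attractors of the steady state", {
  fp <- find_fixed_points(p_star)
  st <- fp$x_star[fp$stable]
  lo_attr <- min(st); hi_attr <- max(st)
  # long-time runs with the gates saturated (M, N tiny)
  p <- p_star
  p[["M"]] <- 1e-8; p[["N"]] <- 1e-8
  t_long <- seq(0, 40, length.out = 50)
  low <- integrate_trajectory(p, 0.5, t_long)
  high <- integrate_trajectory(p, 1.2, t_long)
  expect_equal(tail(low$x, 1), lo_attr, tolerance = 1e-4)
  expect_equal(tail(high$x, 1), hi_attr, tolerance = 1e-4)
})
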