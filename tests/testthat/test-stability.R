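test_that("steady-state function matches algebra at its closed-form points", {
  expect_equal(steady_state_function(1, model_parameters(c = 1, d = 1)), 0)
  # a x/(x+K) = d x has the interior solution x* = a/d - K
  p <- model_parameters(a = 2, d = 1, K = 0.5, k = 1)
  expect_equal(steady_state_function(1.5, p), 0, tolerance = 1e-12)
  # direct arithmetic at the worked bistable example
  expect_equal(steady_state_function(0.5, p_star),
               2 * 0.5^4 / (0.5^4 + 1) + 0.05 - 0.5)
})

test_that("fixed points of the worked bistable example match the oracle", {
  fp <- find_fixed_points(p_star)
  expect_equal(nrow(fp), 3)
  expect_equal(fp$stable, c(TRUE, FALSE, TRUE))
  expect_false(any(fp$boundary))
  expect_equal(fp$x_star[1], 0.050, tolerance = 1e-2)
  expect_gt(fp$x_star[2], 0.9); expect_lt(fp$x_star[2], 1.0)
  expect_gt(fp$x_star[3], 1.9); expect_lt(fp$x_star[3], 2.0)
  orc <- oracle_fixed_points(p_star)
  expect_equal(fp$x_star, orc$x_star, tolerance = 1e-8)
  expect_equal(fp$stable, orc$stable)
})

test_that("simple circuits yield the expected fixed-point structure", {
  fp1 <- find_fixed_points(model_parameters(c = 1, d = 1))
  expect_equal(sum(!fp1$boundary), 1)
  expect_equal(fp1$x_star[!fp1$boundary], 1, tolerance = 1e-8)
  expect_true(fp1$stable[!fp1$boundary])

  # pure decay: only the clamp boundary attractor
  fp2 <- find_fixed_points(model_parameters(d = 1))
  expect_equal(nrow(fp2), 1)
  expect_true(fp2$boundary[1])
  expect_true(fp2$stable[1])
  expect_equal(fp2$x_star[1], EXPR_CLAMP)
})

test_that("root finder agrees with the brute-force sign-scan oracle", {
  sets <- random_parameter_sets(60, seed = 21)
  for (p in sets) {
    fp <- find_fixed_points(p)
    interior <- fp[!fp$boundary, ]
    orc <- oracle_fixed_points(p)
    expect_equal(nrow(interior), nrow(orc))
    if (nrow(orc) > 0) {
      expect_equal(interior$x_star, orc$x_star, tolerance = 1e-4)
      expect_equal(interior$stable, orc$stable)
      # alternation of stability for a 1-D gradient flow
      expect_true(all(diff(fp$stable) != 0))
    }
  }
})

test_that("long-time integration only lands on points flagged stable", {
  sets <- random_parameter_sets(8, seed = 22)
  for (p in sets) {
    pp <- p
    pp[["M"]] <- 1e-10; pp[["N"]] <- 1e-10  # saturate the gates
    fp <- find_fixed_points(pp)
    st <- fp$x_star[fp$stable]
    # relaxation time scales with 1/d; integrate long enough to converge
    t_end <- 400 / min(1, max(pp[["d"]], 1e-2))
    set.seed(1)
    for (x0 in exp(runif(6, log(1e-3), log(5)))) {
      xe <- tail(integrate_trajectory(pp, x0,
                                      seq(0, t_end, length.out = 60))$x, 1)
      expect_lt(min(abs(xe - st)), 1e-3 + 1e-3 * min(st[which.min(abs(xe - st))]))
    }
  }
})

test_that("closed-form steady state a/d - K holds for k = 1, b = c = 0", {
  set.seed(33)
  found <- 0
  while (found < 50) {
    a <- exp(runif(1, log(0.1), log(20)))
    d <- exp(runif(1, log(0.05), log(5)))
    K <- exp(runif(1, log(1e-3), log(10)))
    if (a / d - K <= 1e-3) next
    found <- found + 1
    p <- model_parameters(a = a, d = d, K = K, k = 1)
    fp <- find_fixed_points(p)
    interior <- fp$x_star[!fp$boundary]
    expect_equal(interior[length(interior)], a / d - K, tolerance = 1e-8)
  }
})

test_that("genes are classified by error threshold and stable-state count", {
  expect_equal(classify_gene(p_star, fitting_error = 0.5)$klass, "unfit")
  prof <- classify_gene(p_star, fitting_error = 0.01)
  expect_equal(prof$klass, "multistable")
  expect_equal(prof$n_stable, 2L)
  expect_equal(classify_gene(model_parameters(c = 0.5, d = 1),
                             fitting_error = 0.01)$klass, "monostable")
  # table-level screen
  fits <- dplyr::bind_rows(
    tibble::tibble(gene_id = "bi", t(as.numeric(p_star)) |>
                     as.data.frame() |> setNames(names(p_star)),
                   fitting_error = 0.01),
    tibble::tibble(gene_id = "bad", t(as.numeric(p_star)) |>
                     as.data.frame() |> setNames(names(p_star)),
                   fitting_error = 0.2))
  cls <- classify_genes(fits)
  expect_equal(cls$klass, c("multistable", "unfit"))
  expect_match(cls$fixed_points[1], "stable;.*unstable;.*stable")
})

test_that("bifurcation scans find the saddle-node asymmetry in K but not L", {
  # K inert when a = 0
  bd0 <- bifurcation_scan(model_parameters(c = 1, d = 1), "K", n_points = 40)
  expect_true(all(abs(bd0$x_star[!bd0$boundary] - 1) < 1e-6))
  expect_equal(nrow(saddle_nodes(bd0)), 0)

  bdK <- bifurcation_scan(p_star, "K", n_points = 120)
  expect_s3_class(bdK, "bifurcation_diagram")
  expect_equal(attr(bdK, "base_value"), 1)
  sn <- saddle_nodes(bdK)
  # scanning K upward destroys the upper stable branch at a finite value
  drop <- sn[sn$n_stable_lo == 2 & sn$n_stable_hi == 1, ]
  expect_gte(nrow(drop), 1)
  expect_gt(min(drop$value_lo), 1)
  expect_true(is.finite(min(drop$value_hi)))
  # beyond the saddle-node only the low state remains
  top <- dplyr::filter(bdK, value == max(value))
  expect_equal(sum(top$stable), 1)
  expect_lt(top$x_star[top$stable], 0.1)

  # L is decoupled when b = 0: identical diagram across the whole grid
  bdL <- bifurcation_scan(p_star, "L", n_points = 40)
  per_value <- bdL |>
    dplyr::group_by(value) |>
    dplyr::summarise(sig = paste(signif(x_star, 8), collapse = ";"),
                     .groups = "drop")
  expect_equal(length(unique(per_value$sig)), 1)

  # branch continuity on the stable-count-preserving segments
  counts <- bdK |> dplyr::group_by(value) |>
    dplyr::summarise(n = sum(stable), .groups = "drop")
  expect_true(all(abs(diff(counts$n)) <= 1))
})

test_that("perturbation snapshots commit to attractors of the fitted circuit", {
  p <- p_star
  p[["M"]] <- 1e-6; p[["m"]] <- 2
  traj <- integrate_trajectory(p, 1.2, seq(0, 1, length.out = 30))
  snaps <- perturbation_snapshots(p, traj, folds = c(0.6, 1.0, 1.4),
                                  t_max = 40)
  expect_setequal(unique(snaps$fold), c(0.6, 1.0, 1.4))
  fp <- find_fixed_points(p)
  st <- fp$x_star[fp$stable]
  ends <- snaps |> dplyr::group_by(fold) |>
    dplyr::summarise(xe = tail(x, 1), .groups = "drop")
  for (xe in ends$xe) expect_lt(min(abs(xe - st)), 1e-3)
  # identity fold reproduces the fitted trajectory on the data span
  id <- dplyr::filter(snaps, fold == 1, t <= 1)
  expect_equal(id$x[seq_along(traj$t)], traj$x, tolerance = 1e-6)
})
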