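test_that("smoothing spline reproduces flat and linear curves with correct derivatives", {
  tg <- seq(0, 1, length.out = 30)
  flat <- smooth_and_differentiate(tibble::tibble(t = tg, x = rep(0.7, 30)))
  expect_lt(max(abs(flat$dx)), 1e-8)
  expect_equal(flat$x_smooth, rep(0.7, 30), tolerance = 1e-10)

  lin <- smooth_and_differentiate(tibble::tibble(t = tg, x = tg + 0.2))
  expect_equal(lin$dx, rep(1, 30), tolerance = 1e-6)

  set.seed(14)
  tg2 <- seq(0, 1, length.out = 60)
  noisy <- tibble::tibble(t = tg2, x = exp(-tg2) + rnorm(60, 0, 0.01))
  sm <- smooth_and_differentiate(noisy)
  d_mid <- sm$dx[which.min(abs(tg2 - 0.5))]
  expect_lt(abs(d_mid - (-exp(-0.5))), 0.05)

  expect_error(smooth_and_differentiate(tibble::tibble(t = 1:5 / 5, x = 1:5)),
               "fewer than 8")
})

test_that("match loss is zero at a perfect match and locally minimal at truth", {
  tg <- seq(0, 1, length.out = 20)
  p <- model_parameters(c = 1, d = 1)
  x <- rep(1, 20)
  expect_equal(match_loss(p, tg, x, dx = rep(0, 20), lambda = 0), 0)
  p0 <- model_parameters(d = 1e-3)
  p0[["d"]] <- 0
  expect_equal(match_loss(p0, tg, x, dx = rep(0, 20), lambda = 5), 0)

  # noise-free gradient data: the generating parameters beat perturbations
  p1 <- model_parameters(a = 1.5, b = 0.3, c = 0.05, d = 1, K = 0.7, L = 2,
                         M = 0.1, N = 0.3, k = 2, l = 1, m = 2, n = 4)
  xs <- seq(0.1, 2, length.out = 40)
  dx <- model_rhs(xs, 0.5, p1)
  l_true <- match_loss(p1, rep(0.5, 40), xs, dx, lambda = 0)
  set.seed(2)
  for (i in 1:10) {
    pp <- p1 * exp(rnorm(12, 0, 0.05))
    pp <- as_parameters(setNames(as.numeric(pp), names(p1)))
    expect_gte(match_loss(pp, rep(0.5, 40), xs, dx, lambda = 0), l_true)
  }
})

test_that("trajectory RMSE is exact for closed-form fits and penalizes perturbation", {
  tg <- seq(0, 1, length.out = 25)
  p <- model_parameters(d = 1.3)
  traj <- tibble::tibble(t = tg, x = exp(-1.3 * tg))
  expect_lt(fitting_error(p, traj), 1e-6)

  pb <- p_star
  pb[["M"]] <- 1e-6
  traj_b <- integrate_trajectory(pb, 1.2, tg)
  e_true <- fitting_error(pb, traj_b)
  pp <- pb; pp[["a"]] <- pb[["a"]] * 1.1
  expect_gt(fitting_error(pp, traj_b), e_true)
})

test_that("flat genes get minimal-norm fits with tiny error", {
  set.seed(5)
  tg <- seq(0, 1, length.out = 40)
  traj <- tibble::tibble(t = tg, x = clamp_expr(0.7 + rnorm(40, 0, 0.003)))
  cfg <- fit_config(n_starts = 15, seed = 9)
  fit <- fit_gene(traj, cfg)
  expect_lt(fit$fitting_error, 0.01)
  # l2 selection: the returned regulation norm is <= any pool member's
  expect_gte(fit$n_candidates, 1)
  norm <- sqrt(sum(fit$parameters[c("a", "b", "c", "d")]^2))
  expect_lt(norm, 2)  # a flat gene needs almost no regulation energy

  # penalty monotonicity: stronger lambda never increases the returned norm
  norms <- vapply(c(0, 1e-3, 1e-1), function(lam) {
    f <- fit_gene(traj, fit_config(n_starts = 10, seed = 9,
                                   lambda_penalty = lam))
    sqrt(sum(f$parameters[c("a", "b", "c", "d")]^2))
  }, 0)
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("fits are deterministic and improve (never worsen) with more starts", {
  set.seed(77)
  tg <- seq(0, 1, length.out = 30)
  p <- model_parameters(a = 1.2, c = 0.05, d = 1, K = 0.5, k = 3, M = 0.01,
                        m = 2)
  traj <- integrate_trajectory(p, 0.3, tg)
  traj$x <- clamp_expr(traj$x + rnorm(30, 0, 0.01))

  f1 <- fit_gene(traj, fit_config(n_starts = 12, seed = 4))
  f2 <- fit_gene(traj, fit_config(n_starts = 12, seed = 4))
  expect_identical(glance(f1), glance(f2))
  expect_identical(as.numeric(f1$parameters), as.numeric(f2$parameters))

  # the best near-optimal-pool RMSE never worsens as starts accumulate
  errs <- vapply(c(4, 8, 16), function(ns) {
    fit_gene(traj, fit_config(n_starts = ns, seed = 4))$best_rmse
  }, 0)
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("noise-free synthetic genes are fitted to near-zero trajectory RMSE", {
  spec <- synthetic_spec(n_genes = 50, noise_sd = 0, seed = 19)
  dat <- generate_dataset(spec)
  fits <- fit_genes(dat$trajectories, fit_config(n_starts = 40, seed = 19))
  expect_gte(mean(fits$fitting_error < 0.02), 0.95)
})

test_that("tidy and glance expose the fit in broom shape", {
  tg <- seq(0, 1, length.out = 20)
  traj <- tibble::tibble(t = tg, x = exp(-tg))
  fit <- fit_gene(traj, fit_config(n_starts = 4, seed = 2), gene_id = "g1",
                  branch = "C1")
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b", "c", "d", "K", "L", "M", "N",
                          "k", "l", "m", "n"))
  gl <- glance(fit)
  expect_equal(gl$gene_id, "g1")
  expect_equal(gl$branch, "C1")
  expect_true(gl$fitting_error >= 0)
})
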