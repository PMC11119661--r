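#' Estimation settings for gradient-matching fits
#'
#' Bundles every knob of the smooth-and-match estimator: the number of
#' multi-start initial guesses, the RNG seed, box bounds, the weight of the
#' l2 penalty on the regulation magnitudes `(a, b, c, d)` (interpreted as the
#' energetic cost of activating/inhibiting expression), the relative
#' trajectory-RMSE band defining the near-optimal candidate pool, and the
#' fit/unfit error cutoff.
#'
#' @param n_starts Independent log-uniform initial guesses per gene
#'   (default 40).
#' @param seed RNG seed; per-gene substreams are derived from it.
#' @param bounds Per-parameter `c(lower, upper)` list, see [default_bounds()].
#' @param lambda_penalty Weight of the l2 penalty on `(a, b, c, d)` inside
#'   the match loss (default 1e-3).
#' @param near_opt_tolerance Relative trajectory-RMSE band defining the
#'   candidate pool from which the minimal-norm solution is picked
#'   (default 0.05).
#' @param error_threshold Fitting-error cutoff separating fit from unfit
#'   genes (default 0.1 on the normalized-expression RMSE scale).
#' @param max_eval Cap on objective evaluations per start.
#' @param spline_df Optional degrees of freedom for the smoothing spline;
#'   `NULL` selects smoothness by generalized cross-validation.
#' @param polish Refine the leading solutions by trajectory-space least
#'   squares when the best RMSE exceeds the smoothing noise floor (default
#'   `TRUE`). Disable for large median-level scans where per-gene polish
#'   does not affect the statistic.
#' @return A list of class `fit_config`.
#' @examples
#' cfg <- fit_config(n_starts = 10, seed = 7)
#' @export
fit_config <- function(n_starts = 40, seed = 1, bounds = default_bounds(),
                       lambda_penalty = 1e-3, near_opt_tolerance = 0.05,
                       error_threshold = 0.1, max_eval = 2000,
                       spline_df = NULL, polish = TRUE) {
  stopifnot(n_starts >= 1, lambda_penalty >= 0, near_opt_tolerance >= 0,
            error_threshold >= 0, max_eval >= 10)
  validate_bounds(bounds)
  structure(
    list(n_starts = as.integer(n_starts), seed = as.integer(seed),
         bounds = bounds, lambda_penalty = lambda_penalty,
         near_opt_tolerance = near_opt_tolerance,
         error_threshold = error_threshold, max_eval = as.integer(max_eval),
         spline_df = spline_df, polish = isTRUE(polish)),
    class = "fit_config"
  )
}

#' Smooth a trajectory and estimate its pseudotime derivative
#'
#' Fits a cubic smoothing spline (smoothness selected by generalized
#' cross-validation unless `spline_df` is given) and returns the spline value
#' and its analytic first derivative at each observed pseudotime — the
#' "smooth" half of smooth-and-match estimation. Smoothed values are clamped
#' at [EXPR_CLAMP].
#'
#' @param traj A data frame with columns `t` (strictly increasing) and `x`;
#'   at least 8 points (shorter branches carry too little pseudotime signal
#'   and should be skipped).
#' @param cfg A [fit_config()].
#' @return A tibble with columns `t`, `x_smooth`, `dx`.
#' @examples
#' tr <- tibble::tibble(t = seq(0, 1, length.out = 30),
#'                      x = exp(-seq(0, 1, length.out = 30)))
#' sd <- smooth_and_differentiate(tr, fit_config())
#' @export
smooth_and_differentiate <- function(traj, cfg = fit_config()) {
  stopifnot(all(c("t", "x") %in% names(traj)))
  t <- traj$t; x <- traj$x
  if (length(t) < 8) {
    stop("trajectory has fewer than 8 pseudotime points; skip this branch",
         call. = FALSE)
  }
  if (any(diff(t) <= 0)) stop("pseudotime must be strictly increasing",
                              call. = FALSE)
  fit <- if (is.null(cfg$spline_df)) {
    stats::smooth.spline(t, x, cv = FALSE)
  } else {
    stats::smooth.spline(t, x, df = cfg$spline_df)
  }
  tibble::tibble(
    t = t,
    x_smooth = clamp_expr(predict(fit, t)$y),
    dx = predict(fit, t, deriv = 1)$y
  )
}

#' Gradient-matching loss
#'
#' The "match" half of smooth-and-match: the squared mismatch between the
#' spline derivative and the circuit right-hand side along the smoothed
#' curve, plus the l2 penalty on the regulation magnitudes:
#' `sum_j (dx_j - F(x_j, t_j))^2 + lambda (a^2 + b^2 + c^2 + d^2)`.
#'
#' @param params Model parameters.
#' @param t,x,dx Equal-length vectors: pseudotimes, smoothed values,
#'   derivative estimates.
#' @param lambda Penalty weight.
#' @return Non-negative loss value.
#' @examples
#' p <- model_parameters(c = 1, d = 1)
#' match_loss(p, t = c(0, 1), x = c(1, 1), dx = c(0, 0), lambda = 0)  # 0
#' @export
match_loss <- function(params, t, x, dx, lambda = 0) {
  p <- as_parameters(params)
  stopifnot(length(t) == length(x), length(x) == length(dx))
  r <- dx - model_rhs(x, t, p)
  sum(r^2) + lambda * sum(p[c("a", "b", "c", "d")]^2)
}

# Refine a parameter set by Levenberg-Marquardt on the integrated
# trajectory; returns NULL when the refinement fails or does not improve.
polish_trajectory_fit <- function(par, lo, hi, x0, ref_traj, sqrt_lambda) {
  resid_fn <- function(p) {
    xm <- integrate_raw(setNames(p, param_names()), x0, ref_traj$t,
                        rtol = 1e-7, atol = 1e-9)
    if (anyNA(xm)) return(rep(1e3, nrow(ref_traj) + 4))
    c(clamp_expr(xm) - ref_traj$x, sqrt_lambda * p[1:4])
  }
  res <- try(suppressWarnings(minpack.lm::nls.lm(
    par = par, lower = lo, upper = hi, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 60, maxfev = 900,
                                         ftol = 1e-10, ptol = 1e-8)
  )), silent = TRUE)
  if (inherits(res, "try-error")) return(NULL)
  p2 <- setNames(pmin(pmax(res$par, lo), hi), param_names())
  rmse <- fitting_error(p2, ref_traj, x0 = x0)
  if (!is.finite(rmse)) return(NULL)
  list(par = p2, rmse = rmse)
}

# Residual vector for least squares: model mismatch rows then penalty rows.
match_residuals <- function(par, t, x, dx, sqrt_lambda) {
  a <- par[1]; b <- par[2]; cc <- par[3]; d <- par[4]
  K <- par[5]; L <- par[6]; M <- par[7]; N <- par[8]
  k <- par[9]; l <- par[10]; m <- par[11]; n <- par[12]
  xk <- x^k; xl <- x^l; tm <- t^m; tn <- t^n
  FF <- a * xk / (xk + K) * tm / (tm + M) -
    b * xl / (xl + L) * tn / (tn + N) + cc - d * x
  c(dx - FF, sqrt_lambda * par[1:4])
}

# Analytic Jacobian of match_residuals wrt the 12 parameters.
match_jacobian <- function(par, t, x, dx, sqrt_lambda) {
  a <- par[1]; b <- par[2]
  K <- par[5]; L <- par[6]; M <- par[7]; N <- par[8]
  k <- par[9]; l <- par[10]; m <- par[11]; n <- par[12]
  xk <- x^k; xl <- x^l; tm <- t^m; tn <- t^n
  P <- xk / (xk + K); Q <- tm / (tm + M)
  R <- xl / (xl + L); S <- tn / (tn + N)
  dP_dK <- -xk / (xk + K)^2
  dR_dL <- -xl / (xl + L)^2
  dQ_dM <- -tm / (tm + M)^2
  dS_dN <- -tn / (tn + N)^2
  lx <- log(x)
  lt <- ifelse(t > 0, log(t), 0)  # t = 0 contributes 0 via tm = 0
  dP_dk <- K * xk * lx / (xk + K)^2
  dR_dl <- L * xl * lx / (xl + L)^2
  dQ_dm <- M * tm * lt / (tm + M)^2
  dS_dn <- N * tn * lt / (tn + N)^2
  nr <- length(x)
  # residual r = dx - F, so dr/dtheta = -dF/dtheta
  J <- cbind(
    a = -P * Q, b = R * S, c = rep(-1, nr), d = x,
    K = -a * Q * dP_dK, L = b * S * dR_dL,
    M = -a * P * dQ_dM, N = b * R * dS_dN,
    k = -a * Q * dP_dk, l = b * S * dR_dl,
    m = -a * P * dQ_dm, n = b * R * dS_dn
  )
  pen <- matrix(0, nrow = 4, ncol = 12)
  pen[cbind(1:4, 1:4)] <- sqrt_lambda
  rbind(J, pen)
}

#' Trajectory RMSE of a parameter set against a gene's data
#'
#' Integrates the circuit from the first data point `(t_1, x_1)` and returns
#' the root-mean-square deviation from the data on the normalized-expression
#' scale — the fitting-error metric behind the fit/unfit cutoff of 0.1.
#' A failed integration yields `Inf` (the gene becomes "unfit").
#'
#' @param params Model parameters.
#' @param traj A data frame with columns `t` and `x` (the observed
#'   trajectory).
#' @param x0 Initial value for the integration; defaults to the first data
#'   point. [fit_gene()] passes the first smoothed value.
#' @return Non-negative RMSE, or `Inf` on integrator failure.
#' @examples
#' p <- model_parameters(d = 1)
#' tr <- tibble::tibble(t = seq(0, 1, 0.1), x = exp(-seq(0, 1, 0.1)))
#' fitting_error(p, tr)  # ~0
#' @export
fitting_error <- function(params, traj, x0 = traj$x[1]) {
  p <- as_parameters(params)
  xm <- integrate_raw(p, x0, traj$t)
  if (anyNA(xm)) return(Inf)
  sqrt(mean((clamp_expr(xm) - traj$x)^2))
}

#' Fit the gene circuit to one pseudotime trajectory
#'
#' Smooth-and-match estimation with multiple starts: draws `n_starts`
#' log-uniform initial guesses within the bounds (seeded), minimizes the
#' penalized gradient-matching loss from each with bound-constrained
#' Levenberg-Marquardt least squares (analytic Jacobian), scores every
#' converged solution by its integrated-trajectory RMSE, forms the candidate
#' pool of solutions within `near_opt_tolerance` (relative) of the best RMSE,
#' and returns the pool member with the smallest l2 norm of `(a, b, c, d)` —
#' the minimal-regulation-energy representative among near-optimal fits.
#'
#' @param traj A data frame with columns `t`, `x` for one gene (>= 8 points).
#' @param cfg A [fit_config()].
#' @param gene_id,branch Labels carried into the result.
#' @param stream Integer substream index (used by [fit_genes()] to give each
#'   gene its own reproducible RNG stream; 0 uses `cfg$seed` directly).
#' @return An object of class `gene_fit`: a list with `gene_id`, `branch`,
#'   `parameters`, `fitting_error`, `best_rmse` (the pool's best trajectory
#'   RMSE), `gradient_loss`, `start_index`,
#'   `n_candidates`, `seed`, `n_starts`, `smoothed`. Use [tidy()] for the
#'   parameter table and [glance()] for the fit summary. If no start
#'   converges the result carries `fitting_error = Inf` and `NA` parameters.
#' @examples
#' \donttest{
#' p <- model_parameters(a = 2, c = 0.05, d = 1, K = 1, k = 4, m = 2, M = 0.1)
#' traj <- integrate_trajectory(p, 0.3, seq(0, 1, length.out = 60))
#' fit <- fit_gene(traj, fit_config(n_starts = 10, seed = 1))
#' glance(fit)
#' }
#' @export
fit_gene <- function(traj, cfg = fit_config(), gene_id = "gene",
                     branch = NA_character_, stream = 0L) {
  sm <- smooth_and_differentiate(traj, cfg)
  t <- sm$t; x <- sm$x_smooth; dx <- sm$dx
  lo <- bounds_lower(cfg$bounds)
  hi <- bounds_upper(cfg$bounds)
  sqrt_lambda <- sqrt(cfg$lambda_penalty)
  seed_used <- if (stream > 0) substream_seed(cfg$seed, stream, 1L) else cfg$seed
  set.seed(seed_used)
  starts <- sample_log_uniform(cfg$bounds, cfg$n_starts)
  # candidates are scored by trajectory RMSE against the observed data,
  # integrating from the first smoothed value; the noise floor keeps the
  # relative near-optimal band meaningful
  ref_traj <- tibble::tibble(t = traj$t, x = traj$x)

  sols <- vector("list", cfg$n_starts)
  for (i in seq_len(cfg$n_starts)) {
    res <- try(suppressWarnings(minpack.lm::nls.lm(
      par = starts[i, ], lower = lo, upper = hi,
      fn = match_residuals, jac = match_jacobian,
      t = t, x = x, dx = dx, sqrt_lambda = sqrt_lambda,
      control = minpack.lm::nls.lm.control(
        maxiter = 100, maxfev = cfg$max_eval, ftol = 1e-10, ptol = 1e-10)
    )), silent = TRUE)
    if (inherits(res, "try-error")) next
    par <- setNames(pmin(pmax(res$par, lo), hi), param_names())
    rmse <- fitting_error(par, ref_traj, x0 = x[1])
    if (!is.finite(rmse)) next
    sols[[i]] <- list(par = par, rmse = rmse, start = i)
  }
  sols <- sols[!vapply(sols, is.null, TRUE)]
  # Trajectory-space polish: gradient matching is fast but inherits the
  # spline's bias at sharp switch corners, which integration amplifies. When
  # the best trajectory RMSE stays above the smoothing noise floor, refine
  # the leading solutions by bounded least squares on the integrated
  # trajectory itself (warm-started at the gradient-matching optima).
  if (length(sols) > 0 && cfg$polish) {
    sigma_hat <- stats::sd(traj$x - x)
    floor_rmse <- max(0.01, 1.5 * sigma_hat)
    if (min(vapply(sols, `[[`, 0, "rmse")) > floor_rmse) {
      ord <- order(vapply(sols, `[[`, 0, "rmse"))
      for (j in head(ord, 5)) {
        pol <- polish_trajectory_fit(sols[[j]]$par, lo, hi, x[1], ref_traj,
                                     sqrt_lambda)
        if (!is.null(pol)) {
          sols[[length(sols) + 1]] <- list(par = pol$par, rmse = pol$rmse,
                                           start = sols[[j]]$start)
        }
      }
    }
  }
  if (length(sols) == 0) {
    out <- list(gene_id = gene_id, branch = branch,
                parameters = setNames(rep(NA_real_, 12), param_names()),
                fitting_error = Inf, best_rmse = Inf, gradient_loss = Inf,
                start_index = NA_integer_, n_candidates = 0L,
                seed = seed_used, n_starts = cfg$n_starts, smoothed = sm)
    class(out) <- "gene_fit"
    return(out)
  }
  rmses <- vapply(sols, `[[`, 0, "rmse")
  best <- min(rmses)
  pool <- sols[rmses <= best * (1 + cfg$near_opt_tolerance)]
  norms <- vapply(pool, function(s) sqrt(sum(s$par[1:4]^2)), 0)
  chosen <- pool[[which.min(norms)]]
  out <- list(
    gene_id = gene_id, branch = branch,
    parameters = structure(chosen$par, class = "model_parameters"),
    fitting_error = chosen$rmse, best_rmse = best,
    gradient_loss = match_loss(chosen$par, t, x, dx, cfg$lambda_penalty),
    start_index = chosen$start, n_candidates = length(pool),
    seed = seed_used, n_starts = cfg$n_starts, smoothed = sm
  )
  class(out) <- "gene_fit"
  out
}

#' @export
print.gene_fit <- function(x, ...) {
  cat("<gene_fit> ", x$gene_id,
      if (!is.na(x$branch)) paste0(" (", x$branch, ")"),
      "\n  fitting error (RMSE): ", signif(x$fitting_error, 4),
      "  [", x$n_candidates, " near-optimal candidate(s) of ", x$n_starts,
      " starts]\n", sep = "")
  print(setNames(as.numeric(x$parameters), names(x$parameters)))
  invisible(x)
}

#' Fit every gene in a trajectory table
#'
#' Applies [fit_gene()] to each `(gene_id, branch)` trajectory in a long
#' table. Each gene gets its own RNG substream derived from `cfg$seed` and
#' the gene's position, so results do not depend on execution order.
#'
#' @param trajectories A long data frame with columns `gene_id`, `t`, `x`
#'   (and optionally `branch`).
#' @param cfg A [fit_config()].
#' @param verbose Emit a progress message every 25 genes.
#' @return A tibble with one row per gene: `gene_id`, `branch`, the 12
#'   parameters, `fitting_error`, `gradient_loss`, `start_index`,
#'   `n_candidates`, `seed`.
#' @examples
#' \donttest{
#' dat <- generate_dataset(synthetic_spec(n_genes = 3, seed = 2))
#' fits <- fit_genes(dat$trajectories, fit_config(n_starts = 5, seed = 2))
#' }
#' @export
fit_genes <- function(trajectories, cfg = fit_config(), verbose = FALSE) {
  stopifnot(all(c("gene_id", "t", "x") %in% names(trajectories)))
  if (!"branch" %in% names(trajectories)) trajectories$branch <- NA_character_
  keys <- dplyr::distinct(trajectories, .data$gene_id, .data$branch)
  purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    tr <- dplyr::filter(trajectories,
                        .data$gene_id == keys$gene_id[i],
                        (is.na(keys$branch[i]) & is.na(.data$branch)) |
                          (!is.na(keys$branch[i]) & .data$branch == keys$branch[i]))
    fit <- fit_gene(dplyr::arrange(tr, .data$t), cfg,
                    gene_id = keys$gene_id[i], branch = keys$branch[i],
                    stream = i)
    if (verbose && i %% 25 == 0) {
      message("fitted ", i, "/", nrow(keys), " genes")
    }
    dplyr::bind_cols(glance(fit)[, c("gene_id", "branch")], tidy_params(fit),
                     glance(fit)[, c("fitting_error", "best_rmse",
                                     "gradient_loss", "start_index",
                                     "n_candidates", "seed")])
  })
}

tidy_params <- function(fit) {
  tibble::as_tibble(as.list(setNames(as.numeric(fit$parameters),
                                     param_names())))
}

#' @rdname fit_gene
#' @param x A `gene_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gene_fit <- function(x, ...) {
  tibble::tibble(term = param_names(),
                 estimate = as.numeric(x$parameters[param_names()]))
}

#' @rdname fit_gene
#' @exportS3Method generics::glance
glance.gene_fit <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_id, branch = x$branch,
    fitting_error = x$fitting_error, best_rmse = x$best_rmse,
    gradient_loss = x$gradient_loss,
    start_index = x$start_index, n_candidates = x$n_candidates,
    seed = x$seed, n_starts = x$n_starts
  )
}
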