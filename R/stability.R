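#' Steady-state function of the circuit at the long-time limit
#'
#' As pseudotime grows, both Hill gates saturate (to 1 for positive Hill
#' coefficients), leaving the autonomous balance
#' `g(x) = a h(x; k, K) - b h(x; l, L) + c - d x`. Fixed points of the
#' long-time dynamics are the roots of `g`; a root is stable when `g' < 0`.
#'
#' @param x Expression value(s). Vectorized.
#' @param params Model parameters.
#' @return Numeric vector `g(x)`.
#' @examples
#' p <- model_parameters(c = 1, d = 1)
#' steady_state_function(1, p)  # 0
#' @export
steady_state_function <- function(x, params) {
  model_rhs(x, Inf, params)
}

#' Find fixed points of the long-time dynamics
#'
#' Scans `g(x)` ([steady_state_function()]) for sign changes on a dense
#' log-spaced grid over `[x_lo, x_hi]`, refines each bracket by bisection to
#' an interval below `1e-10 * max(1, x)`, merges roots closer than `1e-6`
#' relative, and classifies stability by the sign of a central-difference
#' derivative with step `1e-6 * x`. When the flow at the clamp floor points
#' downward (`g(x_lo) < 0`) the clamp creates an absorbing low-expression
#' state, reported as a stable fixed point flagged `boundary = TRUE`; it
#' counts toward multistability but can be filtered out via the flag.
#'
#' The default upper limit is extended automatically until `g(x_hi) < 0`,
#' which is guaranteed for large `x` since `g(x) <= a + c - d x`.
#'
#' @param params Model parameters.
#' @param x_lo Lower search limit (default the expression clamp).
#' @param x_hi Upper search limit; `NULL` picks
#'   `max(10, 2 (a + c) / d)` and extends if needed.
#' @param n_grid Number of log-spaced scan points.
#' @return A tibble with columns `x_star`, `stable`, `boundary`, `g_prime`,
#'   ordered by `x_star`.
#' @examples
#' p <- model_parameters(a = 2, c = 0.05, d = 1, K = 1, k = 4)
#' find_fixed_points(p)  # bistable: clamp state, unstable threshold, high state
#' @export
find_fixed_points <- function(params, x_lo = EXPR_CLAMP, x_hi = NULL,
                              n_grid = 2000) {
  p <- as_parameters(params)
  stopifnot(x_lo >= EXPR_CLAMP / 10, is.null(x_hi) || x_hi > x_lo)
  d <- max(p[["d"]], 1e-12)
  if (is.null(x_hi)) x_hi <- max(10, 2 * (p[["a"]] + p[["c"]]) / d)
  g <- function(x) steady_state_function(x, p)
  # ensure the scan window captures the decay regime at large x
  tries <- 0
  while (g(x_hi) > 0 && tries < 60) {
    x_hi <- x_hi * 2
    tries <- tries + 1
  }
  grid <- exp(seq(log(x_lo), log(x_hi), length.out = n_grid))
  gv <- g(grid)
  roots <- numeric(0)
  hit <- which(gv[-n_grid] * gv[-1] < 0)
  for (i in hit) {
    lo <- grid[i]; hi <- grid[i + 1]
    flo <- gv[i]
    while (hi - lo > 1e-10 * max(1, lo)) {
      mid <- (lo + hi) / 2
      fm <- g(mid)
      if (fm == 0) { lo <- mid; hi <- mid; break }
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots <- c(roots, grid[which(gv == 0)])
  roots <- sort(unique(roots))
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) / pmax(roots[-length(roots)], EXPR_CLAMP) > 1e-6)
    roots <- roots[keep]
  }
  gp <- vapply(roots, function(r) {
    st <- 1e-6 * max(r, EXPR_CLAMP)
    (g(r + st) - g(r - st)) / (2 * st)
  }, 0)
  out <- tibble::tibble(
    x_star = roots, stable = gp < 0, boundary = FALSE, g_prime = gp
  )
  if (g(x_lo) < 0 && (length(roots) == 0 ||
                      (roots[1] - x_lo) / x_lo > 1e-6)) {
    st <- 1e-6 * x_lo
    out <- dplyr::bind_rows(
      tibble::tibble(x_star = x_lo, stable = TRUE, boundary = TRUE,
                     g_prime = (g(x_lo + st) - g(max(x_lo - st, x_lo / 2))) /
                       (x_lo + st - max(x_lo - st, x_lo / 2))),
      out
    )
  }
  dplyr::arrange(out, .data$x_star)
}

#' Classify a fitted gene by its long-time stability structure
#'
#' A gene whose fitting error exceeds `error_threshold` is `unfit` (excluded
#' from the stability screen, mirroring the fit/unfit cutoff of 0.1 on the
#' normalized-expression RMSE). Otherwise the gene is `multistable` when the
#' long-time dynamics admit two or more stable fixed points (the absorbing
#' clamp state counts) and `monostable` otherwise.
#'
#' @param params Model parameters (ignored for `unfit` calls with
#'   non-finite parameters).
#' @param fitting_error Trajectory RMSE of the fit.
#' @param error_threshold Fit/unfit cutoff (default 0.1).
#' @param x_lo,x_hi Search range forwarded to [find_fixed_points()].
#' @param gene_id,branch Labels carried into the output.
#' @return A list of class `steady_state_profile`: `gene_id`, `branch`,
#'   `fixed_points` (tibble), `n_stable`, `klass` in
#'   `c("monostable", "multistable", "unfit")`.
#' @examples
#' p <- model_parameters(a = 2, c = 0.05, d = 1, K = 1, k = 4)
#' classify_gene(p, fitting_error = 0.02)$klass  # multistable
#' @export
classify_gene <- function(params, fitting_error, error_threshold = 0.1,
                          x_lo = EXPR_CLAMP, x_hi = NULL,
                          gene_id = "gene", branch = NA_character_) {
  if (!is.finite(fitting_error) || fitting_error > error_threshold) {
    out <- list(gene_id = gene_id, branch = branch,
                fixed_points = tibble::tibble(
                  x_star = numeric(0), stable = logical(0),
                  boundary = logical(0), g_prime = numeric(0)),
                n_stable = NA_integer_, klass = "unfit")
    class(out) <- "steady_state_profile"
    return(out)
  }
  fp <- find_fixed_points(params, x_lo = x_lo, x_hi = x_hi)
  n_stable <- sum(fp$stable)
  out <- list(gene_id = gene_id, branch = branch, fixed_points = fp,
              n_stable = n_stable,
              klass = if (n_stable >= 2) "multistable" else "monostable")
  class(out) <- "steady_state_profile"
  out
}

#' @export
print.steady_state_profile <- function(x, ...) {
  cat("<steady_state_profile> ", x$gene_id,
      if (!is.na(x$branch)) paste0(" (", x$branch, ")"), "\n",
      "  class: ", x$klass, ", stable states: ", x$n_stable, "\n", sep = "")
  print(x$fixed_points)
  invisible(x)
}

#' Screen a table of fitted genes for multistability
#'
#' Applies [classify_gene()] to every row of a fits table (the output of
#' [fit_genes()]) and serializes the fixed points.
#'
#' @param fits A data frame with columns `gene_id`, the 12 parameters and
#'   `fitting_error` (a `branch` column is carried through if present).
#' @param error_threshold Fit/unfit RMSE cutoff.
#' @param x_hi Upper search limit; `NULL` uses the automatic range.
#' @return A tibble with `gene_id`, `branch`, `klass`, `n_stable` and
#'   `fixed_points` serialized as `"x:stable;..."`.
#' @examples
#' \donttest{
#' spec <- synthetic_spec(n_genes = 4, seed = 1)
#' dat <- generate_dataset(spec)
#' fits <- fit_genes(dat$trajectories, fit_config(n_starts = 4, seed = 1))
#' classify_genes(fits)
#' }
#' @export
classify_genes <- function(fits, error_threshold = 0.1, x_hi = NULL) {
  stopifnot(is.data.frame(fits), "gene_id" %in% names(fits))
  branch <- if ("branch" %in% names(fits)) fits$branch else
    rep(NA_character_, nrow(fits))
  purrr::map_dfr(seq_len(nrow(fits)), function(i) {
    row <- fits[i, ]
    prof <- classify_gene(
      if (all(is.finite(unlist(row[param_names()])))) as_parameters(row) else
        model_parameters(),
      fitting_error = row$fitting_error,
      error_threshold = error_threshold, x_hi = x_hi,
      gene_id = row$gene_id, branch = branch[i]
    )
    tibble::tibble(
      gene_id = prof$gene_id, branch = prof$branch, klass = prof$klass,
      n_stable = prof$n_stable,
      fixed_points = paste(
        sprintf("%.6g:%s", prof$fixed_points$x_star,
                ifelse(prof$fixed_points$stable, "stable", "unstable")),
        collapse = ";")
    )
  })
}

#' One-parameter bifurcation scan over K or L
#'
#' Sweeps the chosen inhibitory half-saturation constant (`K` inhibits the
#' positive feedback, `L` the negative feedback) over a log-spaced grid,
#' recomputing the long-time fixed points at each value. Intervals where the
#' stable-point count changes by one locate saddle-node bifurcations, where a
#' stable/unstable pair is created or annihilated.
#'
#' @param params Model parameters (the base point; its `K` or `L` is marked
#'   as `base_value`).
#' @param scanned `"K"` or `"L"`.
#' @param decades Half-width of the scan in decades around the base value
#'   (default 3, i.e. base x 10^-3 ... base x 10^3). If the base value is 0
#'   an absolute range `1e-4 ... 1e2` is used.
#' @param n_points Grid resolution.
#' @param x_hi Upper fixed-point search limit (`NULL` = automatic).
#' @return A tibble of class `bifurcation_diagram` with columns `gene_id`,
#'   `scanned`, `value`, `x_star`, `stable`, `boundary`; attributes
#'   `base_value` and `scanned`.
#' @examples
#' p <- model_parameters(a = 2, c = 0.05, d = 1, K = 1, k = 4)
#' bd <- bifurcation_scan(p, "K", n_points = 60)
#' saddle_nodes(bd)
#' @export
bifurcation_scan <- function(params, scanned = c("K", "L"), decades = 3,
                             n_points = 200, x_hi = NULL, gene_id = "gene") {
  p <- as_parameters(params)
  scanned <- match.arg(scanned)
  base <- p[[scanned]]
  grid <- if (base > 0) {
    base * 10^seq(-decades, decades, length.out = n_points)
  } else {
    10^seq(log10(EXPR_CLAMP), 2, length.out = n_points)
  }
  out <- purrr::map_dfr(grid, function(v) {
    pv <- p
    pv[[scanned]] <- v
    fp <- find_fixed_points(pv, x_hi = x_hi)
    tibble::tibble(value = v, x_star = fp$x_star, stable = fp$stable,
                   boundary = fp$boundary)
  })
  out <- dplyr::mutate(out, gene_id = gene_id, scanned = scanned, .before = 1)
  attr(out, "base_value") <- base
  attr(out, "scanned") <- scanned
  class(out) <- c("bifurcation_diagram", class(out))
  out
}

#' Locate saddle-node intervals in a bifurcation diagram
#'
#' Reports grid intervals where the count of stable fixed points changes,
#' bracketing parameter values at which a stable/unstable pair appears or
#' disappears.
#'
#' @param diagram Output of [bifurcation_scan()].
#' @return A tibble with `value_lo`, `value_hi`, `n_stable_lo`, `n_stable_hi`.
#' @export
saddle_nodes <- function(diagram) {
  counts <- diagram |>
    dplyr::group_by(.data$value) |>
    dplyr::summarise(n_stable = sum(.data$stable), .groups = "drop") |>
    dplyr::arrange(.data$value)
  ch <- which(diff(counts$n_stable) != 0)
  tibble::tibble(
    value_lo = counts$value[ch], value_hi = counts$value[ch + 1],
    n_stable_lo = counts$n_stable[ch], n_stable_hi = counts$n_stable[ch + 1]
  )
}

#' Trajectories from perturbed initial conditions
#'
#' Integrates the fitted circuit from initial values scaled by each fold
#' change (e.g. 0.6-, 0.8-, 1.2-, 1.4-fold of the first observed value) over
#' the data's pseudotime span plus a long-time extension, showing which
#' attractor each perturbation commits to.
#'
#' @param params Model parameters.
#' @param traj A data frame with columns `t`, `x` (one gene's trajectory).
#' @param folds Positive fold-change multipliers applied to `traj$x[1]`.
#' @param t_max End of the long-time extension (default 5; the time gates are
#'   near-saturated well before this for typical fits).
#' @param n_extra Points added on the extension.
#' @return A tibble with columns `fold`, `t`, `x`.
#' @examples
#' p <- model_parameters(a = 2, c = 0.05, d = 1, K = 1, k = 4, m = 2, M = 0.1)
#' traj <- integrate_trajectory(p, 0.9, seq(0, 1, length.out = 30))
#' snaps <- perturbation_snapshots(p, traj, folds = c(0.6, 1.4))
#' @export
perturbation_snapshots <- function(params, traj, folds = c(0.6, 0.8, 1.2, 1.4),
                                   t_max = 5, n_extra = 40) {
  p <- as_parameters(params)
  stopifnot(all(folds > 0), all(c("t", "x") %in% names(traj)))
  t_grid <- c(traj$t, seq(max(traj$t) + 1e-6, t_max, length.out = n_extra))
  purrr::map_dfr(folds, function(f) {
    x0 <- clamp_expr(f * traj$x[1])
    tr <- try(integrate_trajectory(p, x0, t_grid), silent = TRUE)
    if (inherits(tr, "try-error")) {
      warning("integration failed for fold ", f, call. = FALSE)
      return(tibble::tibble(fold = f, t = numeric(0), x = numeric(0)))
    }
    dplyr::mutate(tr, fold = f, .before = 1)
  })
}
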