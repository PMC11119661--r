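#' Specification of a synthetic trajectory dataset
#'
#' Describes a benchmark dataset of per-gene pseudotime trajectories with
#' known ground truth, emulating smoothed pseudotime-pipeline output:
#' per-gene curves over `n_pc` representative pseudotime points in \[0, 1\],
#' values clamped at [EXPR_CLAMP], generated from known circuit parameters
#' plus additive Gaussian noise.
#'
#' @param n_genes Number of genes.
#' @param class_mix Named fractions of `monostable`, `bistable` and `flat`
#'   ground-truth genes (must sum to 1).
#' @param n_pc Representative pseudotime points per gene (default 60).
#' @param noise_sd SD of additive Gaussian noise on the normalized-expression
#'   scale (default 0.02; smoothed curves carry little residual noise).
#' @param t_span Pseudotime span (default \[0, 1\]).
#' @param seed RNG seed; all randomness derives from it via per-gene
#'   substreams.
#' @param bounds Parameter sampling ranges (default: the estimation bounds).
#' @param x0_range Range for log-uniform sampling of initial expression.
#' @return A list of class `synthetic_spec`.
#' @examples
#' spec <- synthetic_spec(n_genes = 10, seed = 1)
#' @export
synthetic_spec <- function(n_genes = 50,
                           class_mix = c(monostable = 0.5, bistable = 0.5,
                                         flat = 0),
                           n_pc = 60, noise_sd = 0.02, t_span = c(0, 1),
                           seed = 1, bounds = default_bounds(),
                           x0_range = c(0.05, 3)) {
  stopifnot(n_genes >= 1, n_pc >= 8, noise_sd >= 0,
            length(t_span) == 2, t_span[1] < t_span[2])
  mix <- class_mix[c("monostable", "bistable", "flat")]
  mix[is.na(mix)] <- 0
  names(mix) <- c("monostable", "bistable", "flat")
  if (abs(sum(mix) - 1) > 1e-8) stop("class_mix fractions must sum to 1",
                                     call. = FALSE)
  validate_bounds(bounds)
  structure(
    list(n_genes = as.integer(n_genes), class_mix = mix,
         n_pc = as.integer(n_pc), noise_sd = noise_sd, t_span = t_span,
         seed = as.integer(seed), bounds = bounds, x0_range = x0_range),
    class = "synthetic_spec"
  )
}

#' Sample ground-truth circuit parameters of a requested stability class
#'
#' Every returned set carries a class label verified by the long-time
#' fixed-point analysis ([find_fixed_points()]), and stable states are
#' required to lie on the scale of normalized expression data (below 5).
#'
#' `monostable` sets are rejection-sampled log-uniformly within the bounds
#' until exactly one stable state is found. `flat` genes are the
#' feedback-free family `a = b = c = 0` (pure decay to the clamp floor).
#' `bistable` sets emulate expressed on/off switch genes — the multistable
#' exemplars of pseudotime screens: the induced state `x_hi`, the
#' threshold-to-state ratio, the Hill steepness `k` and the degradation `d`
#' are drawn on data-like scales and the two fixed-point conditions are
#' solved for `a` and `K`, giving a weak-basal positive-autoregulation switch
#' with an off state at/near the clamp; the remaining parameters are drawn
#' log-uniformly and the class is then verified (construct-then-verify
#' rather than blind rejection, which almost never lands on identifiable
#' switches).
#'
#' @param class_label One of `"monostable"`, `"bistable"`, `"flat"`.
#' @param bounds Sampling bounds (see [default_bounds()]).
#' @param max_tries Rejection cap (default 1e4) before erroring.
#' @return A `model_parameters` vector with attribute `class_label`.
#' @examples
#' set.seed(1)
#' p <- sample_parameters("bistable")
#' sum(find_fixed_points(p)$stable) >= 2
#' @export
sample_parameters <- function(class_label = c("monostable", "bistable", "flat"),
                              bounds = default_bounds(), max_tries = 10000) {
  class_label <- match.arg(class_label)
  if (class_label == "flat") {
    p <- as_parameters(sample_log_uniform(bounds, 1)[1, ])
    p[c("a", "b", "c")] <- 0
    p[["d"]] <- max(p[["d"]], 0.5)  # visible decay within the window
    attr(p, "class_label") <- "flat"
    return(p)
  }
  for (i in seq_len(max_tries)) {
    if (class_label == "monostable") {
      p <- as_parameters(sample_log_uniform(bounds, 1)[1, ])
      fp <- tryCatch(find_fixed_points(p), error = function(e) NULL)
      if (is.null(fp)) next
      stable <- fp$x_star[fp$stable]
      if (length(stable) == 1 && max(stable) <= 5) {
        attr(p, "class_label") <- "monostable"
        return(p)
      }
    } else {
      p <- construct_switch(bounds)
      if (is.null(p)) next
      fp <- tryCatch(find_fixed_points(p), error = function(e) NULL)
      if (is.null(fp)) next
      stable <- fp$x_star[fp$stable]
      if (length(stable) >= 2 && min(stable) <= 0.05 && max(stable) <= 5 &&
          max(stable) >= 0.2 && min(diff(sort(stable))) >= 0.2) {
        attr(p, "class_label") <- "bistable"
        return(p)
      }
    }
  }
  stop("could not sample a ", class_label,
       " parameter set within ", max_tries, " tries; bounds too tight",
       call. = FALSE)
}

# Draw an on/off switch candidate: place the unstable threshold x_u and the
# induced state x_hi, then solve a K (x_u^k + K)^-1 x_u^k = d x_u and the
# analogous equation at x_hi for (a, K). Returns NULL when the solution
# leaves the box bounds.
construct_switch <- function(bounds) {
  x_hi <- exp(runif(1, log(0.6), log(3)))
  x_u <- x_hi * runif(1, 0.15, 0.5)
  k <- runif(1, 2, 8)
  d <- exp(runif(1, log(0.5), log(6)))
  K <- x_u^(k - 1) * x_hi^(k - 1) * (x_u - x_hi) /
    (x_u^(k - 1) - x_hi^(k - 1))
  a <- d * (x_u^k + K) / x_u^(k - 1)
  if (K < bounds$K[1] || K > bounds$K[2] || a > bounds$a[2]) return(NULL)
  model_parameters(
    a = a,
    b = exp(runif(1, log(1e-4), log(0.05))),    # weak negative feedback
    c = exp(runif(1, log(1e-4), log(5e-3))),    # weak basal rate: off state
    d = d, K = K,
    L = exp(runif(1, log(1e-4), log(100))),
    M = exp(runif(1, log(1e-6), log(1e-2))),    # gate opens in-window
    N = exp(runif(1, log(1e-6), log(100))),
    k = k, l = runif(1, 0.5, 8), m = runif(1, 0.5, 8), n = runif(1, 0.5, 8)
  )
}

#' Generate one synthetic gene trajectory
#'
#' Integrates the circuit from a sampled (or supplied) initial value over
#' `n_pc` evenly spaced pseudotimes, adds `N(0, noise_sd^2)` noise and clamps
#' at [EXPR_CLAMP].
#'
#' @param params Ground-truth model parameters.
#' @param spec A [synthetic_spec()] (controls `n_pc`, `noise_sd`, `t_span`,
#'   `x0_range`).
#' @param gene_id Label for the output rows.
#' @param x0 Optional initial value; `NULL` samples log-uniformly from
#'   `spec$x0_range`. On integration failure (or a rejected `accept`
#'   predicate) `x0` is resampled up to `max_tries` times before erroring.
#' @param accept Optional predicate `function(t_grid, x_noisefree)` returning
#'   `TRUE` for acceptable noise-free trajectories; used by
#'   [generate_dataset()] to require data-like (expressed, committed) curves.
#' @param max_tries Resampling cap for `x0`.
#' @return A list with `trajectory` (tibble `gene_id`, `t`, `x`) and
#'   `truth` (one-row tibble: `gene_id`, `x0`, the 12 parameters).
#' @examples
#' spec <- synthetic_spec(n_genes = 1, noise_sd = 0)
#' set.seed(1)
#' g <- generate_gene(model_parameters(c = 0.5, d = 1), spec)
#' @export
generate_gene <- function(params, spec, gene_id = "gene", x0 = NULL,
                          accept = NULL, max_tries = 10) {
  p <- as_parameters(params)
  t_grid <- seq(spec$t_span[1], spec$t_span[2], length.out = spec$n_pc)
  for (try in seq_len(max_tries)) {
    x0_i <- if (is.null(x0)) {
      exp(runif(1, log(spec$x0_range[1]), log(spec$x0_range[2])))
    } else x0
    xm <- integrate_raw(p, x0_i, t_grid)
    if (!anyNA(xm) && (is.null(accept) || isTRUE(accept(t_grid, xm)))) {
      x <- clamp_expr(xm + rnorm(spec$n_pc, 0, spec$noise_sd))
      return(list(
        trajectory = tibble::tibble(gene_id = gene_id, t = t_grid, x = x),
        truth = dplyr::bind_cols(
          tibble::tibble(gene_id = gene_id, x0 = x0_i),
          tibble::as_tibble(as.list(setNames(as.numeric(p), param_names()))))
      ))
    }
    if (!is.null(x0)) break
  }
  stop("no acceptable trajectory for synthetic gene ", gene_id, call. = FALSE)
}

#' Generate a full synthetic dataset with verified class labels
#'
#' Draws ground-truth parameter sets per class according to `class_mix`
#' (counts by largest remainder), simulates each gene with its own RNG
#' substream derived from `spec$seed`, and returns trajectory and
#' ground-truth tables. Class labels are verified against the fixed-point
#' analysis of the exact parameters. Monostable and bistable trajectories
#' must be expressed (mean above 0.1, i.e. they would pass the
#' low-expression filter of a real pipeline); bistable trajectories must
#' additionally commit to the induced state by the end of the window, as an
#' observed switch gene does. Parameters and initial values are resampled
#' until these hold.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `trajectories` (long tibble `gene_id`, `branch`, `t`,
#'   `x`) and `truth` (tibble `gene_id`, `class`, `x0`, 12 parameters).
#' @examples
#' \donttest{
#' dat <- generate_dataset(synthetic_spec(n_genes = 6, seed = 3))
#' table(dat$truth$class)
#' }
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  counts <- floor(spec$class_mix * spec$n_genes)
  rem <- spec$n_genes - sum(counts)
  if (rem > 0) {
    frac <- spec$class_mix * spec$n_genes - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  labels <- rep(names(counts), counts)
  width <- max(3, nchar(spec$n_genes))
  trajs <- vector("list", spec$n_genes)
  truths <- vector("list", spec$n_genes)
  for (i in seq_along(labels)) {
    set.seed(substream_seed(spec$seed, i, 1L))
    gene_id <- sprintf("g%0*d", width, i)
    g <- NULL
    for (attempt in 1:50) {
      p <- sample_parameters(labels[i], spec$bounds)
      accept <- dataset_accept(labels[i], p)
      g <- tryCatch(
        generate_gene(p, spec, gene_id = gene_id, accept = accept,
                      max_tries = 20),
        error = function(e) NULL
      )
      if (!is.null(g)) break
    }
    if (is.null(g)) {
      stop("could not generate an acceptable ", labels[i], " gene (", gene_id,
           ")", call. = FALSE)
    }
    g$trajectory$branch <- "sim"
    trajs[[i]] <- g$trajectory[, c("gene_id", "branch", "t", "x")]
    truths[[i]] <- dplyr::bind_cols(
      tibble::tibble(gene_id = g$truth$gene_id, class = labels[i]),
      g$truth[, c("x0", param_names())]
    )
  }
  list(trajectories = dplyr::bind_rows(trajs),
       truth = dplyr::bind_rows(truths))
}

#' Generate per-cell observations for smoothing-resolution studies
#'
#' Emulates the unsmoothed single-cell layer beneath the representative
#' pseudotime curves: for each gene of a dataset specification, `n_cells`
#' pseudotimes are drawn uniformly in the span, the noise-free circuit
#' solution is evaluated there, and per-cell Gaussian noise is added. The
#' result feeds [resmooth_at_npc()] / [robustness_scan()], which rebuild
#' representative curves at different resolutions from the same cells.
#'
#' @param spec A [synthetic_spec()]; `spec$noise_sd` is the per-cell noise SD
#'   (typically larger than the smoothed-curve noise; default here scales it
#'   by `cell_noise_factor`).
#' @param n_cells Cells per gene (default 200).
#' @param cell_noise_factor Multiplier on `spec$noise_sd` for per-cell noise
#'   (default 5: single cells are far noisier than smoothed curves).
#' @return A list with `cells` (long tibble `gene_id`, `t`, `x`) and `truth`
#'   (as in [generate_dataset()]).
#' @examples
#' \donttest{
#' cd <- generate_cell_data(synthetic_spec(n_genes = 2, seed = 4), n_cells = 50)
#' }
#' @export
generate_cell_data <- function(spec, n_cells = 200, cell_noise_factor = 5) {
  stopifnot(inherits(spec, "synthetic_spec"), n_cells >= 20)
  dat <- generate_dataset(spec)
  sd_cell <- spec$noise_sd * cell_noise_factor
  cells <- purrr::map_dfr(seq_len(nrow(dat$truth)), function(i) {
    row <- dat$truth[i, ]
    p <- as_parameters(row)
    set.seed(substream_seed(spec$seed, i, 2L))
    t_cells <- sort(runif(n_cells, spec$t_span[1], spec$t_span[2]))
    # solve once on a fine grid, interpolate at cell pseudotimes
    t_fine <- seq(spec$t_span[1], spec$t_span[2], length.out = 301)
    xm <- integrate_raw(p, row$x0, t_fine)
    if (anyNA(xm)) stop("integration failed for ", row$gene_id, call. = FALSE)
    x_cells <- stats::approx(t_fine, xm, xout = t_cells)$y +
      rnorm(n_cells, 0, sd_cell)
    tibble::tibble(gene_id = row$gene_id, t = t_cells, x = clamp_expr(x_cells))
  })
  list(cells = cells, truth = dat$truth)
}

# Class-specific acceptance of the noise-free curve: expressed for mono and
# bistable; bistable additionally committed to the induced (upper) state.
dataset_accept <- function(class_label, params) {
  if (class_label == "flat") return(NULL)
  if (class_label == "monostable") {
    return(function(t_grid, xm) mean(xm) >= 0.1)
  }
  fp <- find_fixed_points(params)
  x_top <- max(fp$x_star[fp$stable])
  function(t_grid, xm) {
    mean(xm) >= 0.1 &&
      abs(xm[length(xm)] - x_top) / x_top <= 0.1
  }
}
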