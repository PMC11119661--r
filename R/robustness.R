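#' Rebuild representative pseudotime curves at a chosen resolution
#'
#' Smooths per-cell observations of each gene with a cubic smoothing spline
#' (generalized cross-validation) and evaluates the fit at `npc` evenly
#' spaced representative pseudotime points — the smoothing step whose
#' resolution parameter the robustness scan varies.
#'
#' @param cells Long data frame with columns `gene_id`, `t`, `x`
#'   (per-cell observations).
#' @param npc Number of representative points (>= 8).
#' @param t_span Pseudotime span of the representative grid.
#' @return A long tibble `gene_id`, `branch`, `t`, `x` with `npc` rows per
#'   gene, values clamped at [EXPR_CLAMP].
#' @examples
#' \donttest{
#' cd <- generate_cell_data(synthetic_spec(n_genes = 2, seed = 4), n_cells = 60)
#' tr <- resmooth_at_npc(cd$cells, npc = 20)
#' }
#' @export
resmooth_at_npc <- function(cells, npc, t_span = c(0, 1)) {
  stopifnot(all(c("gene_id", "t", "x") %in% names(cells)), npc >= 8)
  t_rep <- seq(t_span[1], t_span[2], length.out = npc)
  cells |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 8) stop("gene ", key$gene_id, " has fewer than 8 cells",
                            call. = FALSE)
      fit <- stats::smooth.spline(d$t, d$x, cv = FALSE)
      tibble::tibble(branch = "sim", t = t_rep,
                     x = clamp_expr(predict(fit, t_rep)$y))
    }) |>
    dplyr::ungroup()
}

#' Kruskal-Wallis test of parameter estimates across resolution groups
#'
#' For each of the 12 circuit parameters, tests whether the per-gene
#' estimates differ in distribution between groups (one group per smoothing
#' resolution `npc`), using the nonparametric one-way Kruskal-Wallis test.
#' All-constant parameters (ties only) are reported with p = 1.
#'
#' @param fits_by_group Data frame containing the 12 parameter columns and a
#'   grouping column.
#' @param group Name of the grouping column (default `"npc"`).
#' @return A tibble with columns `parameter`, `statistic`, `p_value`.
#' @examples
#' df <- data.frame(npc = rep(c(55, 60), each = 5),
#'                  matrix(runif(120), 10, 12,
#'                         dimnames = list(NULL, c("a","b","c","d","K","L",
#'                                                 "M","N","k","l","m","n"))))
#' kw_parameter_test(df)
#' @export
kw_parameter_test <- function(fits_by_group, group = "npc") {
  stopifnot(group %in% names(fits_by_group),
            all(param_names() %in% names(fits_by_group)))
  grp <- factor(fits_by_group[[group]])
  stopifnot(nlevels(grp) >= 2)
  purrr::map_dfr(param_names(), function(pn) {
    v <- fits_by_group[[pn]]
    ok <- is.finite(v)
    if (stats::var(v[ok]) == 0) {
      return(tibble::tibble(parameter = pn, statistic = 0, p_value = 1))
    }
    kw <- kruskal.test(v[ok], grp[ok])
    tibble::tibble(parameter = pn, statistic = unname(kw$statistic),
                   p_value = kw$p.value)
  })
}

#' Robustness of parameter estimates to the smoothing resolution
#'
#' Re-smooths per-cell data at each requested number of representative
#' pseudotime points, refits every gene at each resolution, and tests each
#' of the 12 parameters for distributional differences across resolutions
#' with the Kruskal-Wallis test. In the robust regime no parameter should
#' differ (all p-values above the significance threshold of 1e-4).
#'
#' @param cells Long data frame `gene_id`, `t`, `x` of per-cell observations
#'   (e.g. from [generate_cell_data()]).
#' @param npc_values Two or more resolutions to compare (e.g. `55:60`).
#' @param cfg A [fit_config()]; each resolution reuses the same seed stream
#'   so gene substreams align across groups. Median-level scans typically
#'   use modest `n_starts` and `polish = FALSE`.
#' @param verbose Progress messages per resolution.
#' @return A list of class `robustness_scan`: `p_values` (tibble
#'   `parameter`, `statistic`, `p_value`), `medians` (per-npc per-parameter
#'   gene-wide medians), `fits` (all per-resolution fit tables).
#' @examples
#' \donttest{
#' cd <- generate_cell_data(synthetic_spec(n_genes = 3, seed = 5))
#' rs <- robustness_scan(cd$cells, npc_values = c(12, 16),
#'                       cfg = fit_config(n_starts = 4))
#' rs$p_values
#' }
#' @export
robustness_scan <- function(cells, npc_values, cfg = fit_config(),
                            verbose = FALSE) {
  stopifnot(length(npc_values) >= 2, all(npc_values >= 8))
  fits <- purrr::map_dfr(npc_values, function(npc) {
    trajs <- resmooth_at_npc(cells, npc)
    if (verbose) message("fitting at npc = ", npc)
    dplyr::mutate(fit_genes(trajs, cfg), npc = npc, .before = 1)
  })
  p_values <- kw_parameter_test(fits, group = "npc")
  medians <- fits |>
    dplyr::group_by(.data$npc) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(param_names()),
                                   ~ median(.x, na.rm = TRUE)),
                     .groups = "drop")
  structure(list(p_values = p_values, medians = medians, fits = fits),
            class = "robustness_scan")
}

#' @export
print.robustness_scan <- function(x, ...) {
  cat("<robustness_scan> npc groups:",
      paste(sort(unique(x$fits$npc)), collapse = ", "), "\n")
  print(x$p_values)
  invisible(x)
}
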