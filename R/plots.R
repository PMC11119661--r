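#' Plot a potential landscape
#'
#' Heatmap of `U(x, t)` over the expression-by-pseudotime grid; valleys
#' (low `U`, dark) are attracting expression states.
#'
#' @param object A [potential_landscape()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.potential_landscape <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$x,
                                       fill = .data$U)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "pseudotime", y = "normalized expression",
                  fill = "U(x, t)",
                  title = unique(object$gene_id)[1],
                  subtitle = "valleys (dark) are attractors") +
    ggplot2::theme_minimal()
}

#' Plot a bifurcation diagram
#'
#' Stable branches in red, unstable in blue, against the scanned inhibitory
#' half-saturation constant on a log axis; the dashed line marks the fitted
#' base value.
#'
#' @param object A [bifurcation_scan()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bifurcation_diagram <- function(object, ...) {
  base <- attr(object, "base_value")
  pl <- ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$x_star,
                                             colour = .data$stable)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "blue"),
                                 labels = c(`TRUE` = "stable",
                                            `FALSE` = "unstable")) +
    ggplot2::labs(x = attr(object, "scanned"), y = "steady-state expression",
                  colour = NULL, title = unique(object$gene_id)[1]) +
    ggplot2::theme_minimal()
  if (!is.null(base) && base > 0) {
    pl <- pl + ggplot2::geom_vline(xintercept = base, linetype = "dashed")
  }
  pl
}

#' Plot a fitted gene against its data
#'
#' Overlays the observed trajectory, the smoothing spline, and the
#' integrated fitted circuit.
#'
#' @param fit A [fit_gene()] result.
#' @param traj The trajectory the gene was fitted to (columns `t`, `x`).
#' @return A ggplot object.
#' @export
plot_gene_fit <- function(fit, traj) {
  stopifnot(inherits(fit, "gene_fit"))
  model <- integrate_trajectory(fit$parameters, fit$smoothed$x_smooth[1],
                                traj$t)
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::tibble(t = traj$t, x = traj$x), what = "data"),
    dplyr::mutate(tibble::tibble(t = fit$smoothed$t,
                                 x = fit$smoothed$x_smooth), what = "spline"),
    dplyr::mutate(model, what = "model")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$x,
                                   colour = .data$what)) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$what == "data"),
                        size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$what != "data")) +
    ggplot2::labs(x = "pseudotime", y = "normalized expression",
                  colour = NULL, title = fit$gene_id,
                  subtitle = sprintf("fitting error (RMSE) = %.3g",
                                     fit$fitting_error)) +
    ggplot2::theme_minimal()
}

#' Plot perturbation snapshots over the landscape attractors
#'
#' Trajectories from fold-changed initial conditions, with horizontal lines
#' at the long-time stable states.
#'
#' @param snapshots Output of [perturbation_snapshots()].
#' @param params The parameters used (for attractor lines); optional.
#' @return A ggplot object.
#' @export
plot_snapshots <- function(snapshots, params = NULL) {
  pl <- ggplot2::ggplot(snapshots,
                        ggplot2::aes(x = .data$t, y = .data$x,
                                     colour = factor(.data$fold))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pseudotime", y = "normalized expression",
                  colour = "fold change") +
    ggplot2::theme_minimal()
  if (!is.null(params)) {
    fp <- find_fixed_points(params)
    pl <- pl + ggplot2::geom_hline(yintercept = fp$x_star[fp$stable],
                                   linetype = "dotted")
  }
  pl
}
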