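#' Saturating Hill term
#'
#' Evaluates `x^h / (x^h + H)`, the building block of the circuit right-hand
#' side. The value always lies in \[0, 1\] and is nondecreasing in `x` for
#' positive `h` and `H`.
#'
#' Degenerate corners follow the algebraic limits: `h = 0` gives the constant
#' `1 / (1 + H)`; `H = 0` with `x > 0` gives 1 (full saturation). The corner
#' `x = 0, H = 0, h > 0` is a genuine 0/0 and raises an error.
#'
#' @param x Expression level(s), >= 0. Vectorized.
#' @param h Hill coefficient, >= 0 (scalar).
#' @param H Half-saturation constant, >= 0 (scalar).
#' @return Numeric vector of values in \[0, 1\].
#' @examples
#' hill_term(1, 1, 1)      # 0.5
#' hill_term(0.5, 4, 0)    # 1: zero half-saturation saturates
#' @export
hill_term <- function(x, h, H) {
  stopifnot(h >= 0, H >= 0, all(x >= 0))
  if (h == 0) return(rep(1 / (1 + H), length(x)))
  if (H == 0) {
    if (any(x == 0)) {
      stop("hill_term is undefined at x = 0 with H = 0 and h > 0 ",
           "(degenerate parameters)", call. = FALSE)
    }
    return(rep(1, length(x)))
  }
  xh <- x^h
  xh / (xh + H)
}

#' Pseudotime Hill gate
#'
#' The nonautonomous gate `t^h / (t^h + H)` that switches feedback regulation
#' on as pseudotime progresses. Identical in form to [hill_term()] but takes
#' pseudotime, and additionally accepts `t = Inf` to represent the long-time
#' limit used by the steady-state analysis: the gate saturates to 1 when
#' `h > 0` (and to the algebraic constant `1/(1+H)` when `h = 0`).
#'
#' @param t Pseudotime(s), >= 0; `Inf` is the long-time limit. Vectorized.
#' @param h Hill coefficient (scalar).
#' @param H Half-saturation constant (scalar).
#' @return Numeric vector of values in \[0, 1\].
#' @examples
#' time_factor(0, 2, 1)    # 0: gate closed at the trajectory start
#' time_factor(Inf, 2, 1)  # 1: long-time limit
#' @export
time_factor <- function(t, h, H) {
  stopifnot(h >= 0, H >= 0, all(t >= 0))
  out <- numeric(length(t))
  inf <- is.infinite(t)
  if (any(inf)) out[inf] <- if (h > 0) 1 else 1 / (1 + H)
  if (any(!inf)) out[!inf] <- hill_term(t[!inf], h, H)
  out
}

#' Right-hand side of the gene-circuit ODE
#'
#' The rate of change of normalized expression `x` at pseudotime `t`:
#' positive feedback gated by pseudotime, minus negative feedback gated by
#' pseudotime, plus basal transcription, minus first-order degradation:
#'
#' `F(x, t) = a h(x; k, K) g(t; m, M) - b h(x; l, L) g(t; n, N) + c - d x`
#'
#' where `h` is [hill_term()] and `g` is [time_factor()]. Passing `t = Inf`
#' evaluates the steady-state (long-time limit) form.
#'
#' @param x Expression level(s). Vectorized.
#' @param t Pseudotime, scalar or same length as `x`; `Inf` for the long-time
#'   limit.
#' @param params A [model_parameters()] vector (or anything [as_parameters()]
#'   accepts).
#' @return Numeric vector of rates (expression per unit pseudotime).
#' @examples
#' p <- model_parameters(c = 0.3, d = 1)
#' model_rhs(0.5, 0.2, p)  # -0.2
#' @export
model_rhs <- function(x, t, params) {
  p <- as_parameters(params)
  p[["a"]] * hill_term(x, p[["k"]], p[["K"]]) * time_factor(t, p[["m"]], p[["M"]]) -
    p[["b"]] * hill_term(x, p[["l"]], p[["L"]]) * time_factor(t, p[["n"]], p[["N"]]) +
    p[["c"]] - p[["d"]] * x
}

#' Integrate a gene trajectory from the circuit model
#'
#' Solves `dx/dt = F(x, t)` with a stiff-capable solver (`deSolve::lsoda`,
#' rtol 1e-8, atol 1e-10) from `x0` at `t_grid[1]`. High Hill coefficients
#' make the right-hand side stiff near thresholds, hence the implicit-capable
#' method. Output values are clamped from below at [EXPR_CLAMP]; the solver
#' state itself is not clamped, keeping the solution smooth.
#'
#' @param params Model parameters.
#' @param x0 Initial expression at `t_grid[1]` (>= [EXPR_CLAMP]).
#' @param t_grid Increasing pseudotime grid; may extend beyond \[0, 1\] for
#'   long-time runs.
#' @param rtol,atol Solver tolerances.
#' @return A tibble with columns `t` and `x`.
#' @examples
#' p <- model_parameters(d = 1)
#' integrate_trajectory(p, 1, c(0, 0.5, 1))  # exp(-t)
#' @export
integrate_trajectory <- function(params, x0, t_grid, rtol = 1e-8, atol = 1e-10) {
  p <- as_parameters(params)
  stopifnot(x0 >= 0, length(t_grid) >= 2, all(diff(t_grid) > 0))
  x <- integrate_raw(p, x0, t_grid, rtol, atol)
  if (anyNA(x)) {
    stop("trajectory integration failed (step-size collapse) for parameters: ",
         paste(sprintf("%s=%.4g", names(p), p), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(t = t_grid, x = clamp_expr(x))
}

# Bare integration: numeric vector of x at t_grid, NA on solver failure.
integrate_raw <- function(p, x0, t_grid, rtol = 1e-8, atol = 1e-10) {
  a <- p[["a"]]; b <- p[["b"]]; cc <- p[["c"]]; d <- p[["d"]]
  K <- p[["K"]]; L <- p[["L"]]; M <- p[["M"]]; N <- p[["N"]]
  k <- p[["k"]]; l <- p[["l"]]; m <- p[["m"]]; n <- p[["n"]]
  rhs <- function(t, y, parms) {
    x <- max(y[1], 0)
    xk <- x^k; xl <- x^l; tm <- t^m; tn <- t^n
    list(a * xk / (xk + K) * tm / (tm + M) -
           b * xl / (xl + L) * tn / (tn + N) + cc - d * x)
  }
  sol <- try(suppressWarnings(
    deSolve::lsoda(y = x0, times = t_grid, func = rhs, parms = NULL,
                   rtol = rtol, atol = atol)
  ), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(t_grid)) {
    return(rep(NA_real_, length(t_grid)))
  }
  sol[, 2]
}
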