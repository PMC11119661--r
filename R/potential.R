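# Gauss hypergeometric 2F1(1, b; b+1; z) for real z <= 0, b > 1.
#
# This is the only hypergeometric case the landscape needs: it is the
# closed-form antiderivative factor of a Hill term. Three regimes keep the
# evaluation well conditioned over the whole negative axis:
#   z in (-0.5, 0]   : defining series  b * sum z^n / (b + n)
#   z in (-2, -0.5]  : Pfaff transform, series in w = z/(z-1) in (1/3, 2/3]
#   z <= -2          : connection formula at 1/z (series in |1/z| <= 1/2)
# The connection formula degenerates when eps = b - 1 is a positive integer
# (k = 1 or k = 1/2); those cases have exact elementary log forms used for
# any z. Near-integer eps is handled by the connection formula itself, which
# stays accurate to ~1e-8 within 1e-10 of the poles.
hyp2f1_1b <- function(b, z, tol = 1e-15, nmax = 2000L) {
  stopifnot(length(b) == 1, b > 1, all(z <= 0))
  vapply(z, function(zz) hyp2f1_1b_scalar(b, zz, tol, nmax), 0)
}

hyp2f1_1b_scalar <- function(b, z, tol, nmax) {
  if (z == 0) return(1)
  eps <- b - 1
  p <- round(eps)
  if (p >= 1 && abs(eps - p) < 1e-12) {
    # b = p + 1 integer: b * sum_n z^n/(b+n) = -(b/z^b) (log(1-z) + sum_{m<b} z^m/m)
    ms <- seq_len(p)
    return(-(b / z^b) * (log1p(-z) + sum(z^ms / ms)))
  }
  if (z > -0.5) {
    n <- 0; term <- 1; s <- 0
    repeat {
      s <- s + b / (b + n) * term
      term <- term * z
      n <- n + 1
      if (abs(term) < tol * abs(s) || n > nmax) break
    }
    return(s)
  }
  if (z > -2) {
    # Pfaff: (1-z)^-1 * 2F1(1, 1; b+1; z/(z-1)); terms n!/(b+1)_n w^n
    w <- z / (z - 1)
    term <- 1; s <- 0; n <- 0
    repeat {
      s <- s + term
      n <- n + 1
      term <- term * n / (b + n) * w
      if (abs(term) < tol * abs(s) || n > nmax) break
    }
    return(s / (1 - z))
  }
  # z <= -2: 2F1(1,b;b+1;z) = (b/eps) (-z)^-1 2F1(1,-eps;1-eps;1/z)
  #                           + Gamma(2+eps) Gamma(-eps) (-z)^-(1+eps)
  u <- 1 / z
  term <- 1; s <- 0; n <- 0
  repeat {
    s <- s + (-eps) / (n - eps) * term
    term <- term * u
    n <- n + 1
    if (abs(term) < tol * max(abs(s), 1) || n > nmax) break
  }
  (b / eps) / (-z) * s + gamma(2 + eps) * gamma(-eps) * (-z)^(-(1 + eps))
}

# Antiderivative of the Hill term: int_0^x s^h/(s^h + H) ds, in the
# hypergeometric closed form x^(h+1)/(H(h+1)) 2F1(1, 1+1/h; 2+1/h; -x^h/H).
hill_antiderivative <- function(x, h, H) {
  stopifnot(h >= 0, H >= 0)
  if (h == 0) return(x / (1 + H))
  if (H == 0) return(x)
  b <- 1 + 1 / h
  x^(h + 1) / (H * (h + 1)) * hyp2f1_1b(b, -x^h / H)
}

#' Potential landscape value of the gene circuit
#'
#' Evaluates the closed-form potential `U(x, t)` whose negative x-gradient is
#' the circuit right-hand side: `dx/dt = -dU/dx = F(x, t)`. Valleys of `U`
#' are therefore attractors, matching the Waddington picture of marbles
#' rolling downhill into stable expression states. The feedback terms
#' integrate to Gauss hypergeometric expressions,
#' `x^(k+1)/(K(k+1)) * 2F1(1, 1+1/k; 2+1/k; -x^k/K)` and its `l`/`L`
#' counterpart, each gated by the pseudotime factor; the basal and
#' degradation terms give `c x - (d/2) x^2`, all taken with an overall minus
#' sign so that the gradient-flow convention above holds.
#'
#' The value is defined up to an additive constant per `(t, params)`;
#' [potential_by_quadrature()] provides an independent numerical route for
#' cross-checks.
#'
#' @param x Expression value(s), >= [EXPR_CLAMP]. Vectorized.
#' @param t Pseudotime (scalar; `Inf` for the long-time limit).
#' @param params Model parameters.
#' @return Numeric vector of landscape values (sign convention:
#'   `dx/dt = -dU/dx`).
#' @examples
#' p <- model_parameters(c = 1, d = 1)
#' # feedback-free circuit: U(x) = -(c x - d x^2 / 2)
#' potential(c(0.5, 1, 2), t = 0.5, p)
#' @export
potential <- function(x, t, params) {
  p <- as_parameters(params)
  stopifnot(length(t) == 1, all(x >= 0))
  pos <- p[["a"]] * hill_antiderivative(x, p[["k"]], p[["K"]]) *
    time_factor(t, p[["m"]], p[["M"]])
  neg <- p[["b"]] * hill_antiderivative(x, p[["l"]], p[["L"]]) *
    time_factor(t, p[["n"]], p[["N"]])
  -(pos - neg + p[["c"]] * x - p[["d"]] / 2 * x^2)
}

#' Potential by adaptive quadrature
#'
#' Computes `U(x, t) - U(x_ref, t)` as `-integral from x_ref to x of F(s, t) ds`
#' by adaptive quadrature — a route independent of the hypergeometric closed
#' form, used to validate it. Agrees with [potential()] up to an additive
#' constant in `x`.
#'
#' @param x Expression value(s). Vectorized.
#' @param t Pseudotime (scalar; `Inf` allowed).
#' @param params Model parameters.
#' @param x_ref Reference expression where the potential is taken as 0.
#' @return Numeric vector of landscape values relative to `x_ref`.
#' @examples
#' p <- model_parameters(d = 2)
#' potential_by_quadrature(1, t = 0, p, x_ref = 1e-4)  # ~1: integral of 2s
#' @export
potential_by_quadrature <- function(x, t, params, x_ref = EXPR_CLAMP) {
  p <- as_parameters(params)
  stopifnot(length(t) == 1, x_ref > 0, all(x > 0))
  vapply(x, function(xx) {
    if (abs(xx - x_ref) <= 1e-12 * max(1, abs(x_ref))) return(0)
    # tolerance ladder: extremely tight absolute tolerances can trip the
    # extrapolation-table roundoff guard on near-linear integrands
    for (tols in list(c(1e-10, 1e-12), c(1e-10, 1e-10), c(1e-9, 1e-9))) {
      q <- tryCatch(
        integrate(function(s) model_rhs(s, t, p), lower = x_ref, upper = xx,
                  rel.tol = tols[1], abs.tol = tols[2], subdivisions = 200L),
        error = function(e) NULL)
      if (!is.null(q) && q$message == "OK") return(-q$value)
    }
    stop("quadrature failed to converge", call. = FALSE)
  }, 0)
}

#' Potential landscape over an expression-by-pseudotime grid
#'
#' Tabulates [potential()] on `x_grid` x `t_grid`, the object plotted as a
#' Waddington-style landscape and exported as long-format CSV.
#'
#' @param params Model parameters.
#' @param x_grid Increasing expression grid (>= [EXPR_CLAMP]).
#' @param t_grid Pseudotime grid in \[0, 1\] (values beyond 1 allowed for
#'   long-time views).
#' @param gene_id Label carried into the output.
#' @return A tibble of class `potential_landscape` with columns
#'   `gene_id`, `t`, `x`, `U`; attribute `convention` records the sign
#'   convention (`dx/dt = -dU/dx`).
#' @examples
#' p <- model_parameters(a = 2, c = 0.05, d = 1, K = 1, k = 4)
#' ls <- potential_landscape(p, x_grid = seq(0.01, 3, length.out = 40))
#' head(ls)
#' @export
potential_landscape <- function(params, x_grid = seq(EXPR_CLAMP, 3, length.out = 100),
                                t_grid = seq(0, 1, length.out = 21),
                                gene_id = "gene") {
  p <- as_parameters(params)
  stopifnot(all(diff(x_grid) > 0), all(x_grid >= EXPR_CLAMP))
  out <- tidyr::expand_grid(t = t_grid, x = x_grid) |>
    dplyr::group_by(.data$t) |>
    dplyr::mutate(U = potential(.data$x, .data$t[1], p)) |>
    dplyr::ungroup() |>
    dplyr::mutate(gene_id = gene_id, .before = 1)
  attr(out, "convention") <- "dx/dt = -dU/dx (valleys are attractors)"
  class(out) <- c("potential_landscape", class(out))
  out
}
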