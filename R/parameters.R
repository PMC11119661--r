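#' Model parameters of the autoregulatory gene circuit
#'
#' The circuit for a single gene has twelve non-negative parameters: the
#' magnitudes of positive and negative feedback (`a`, `b`), the basal
#' transcription rate `c`, the degradation rate `d`, half-saturation constants
#' of the expression-dependent Hill terms (`K`, `L`) and of the
#' pseudotime-dependent Hill gates (`M`, `N`), and four Hill coefficients
#' (`k`, `l` for expression, `m`, `n` for pseudotime).
#'
#' Rates (`a`, `b`, `c`) are in normalized-expression units per unit
#' pseudotime, `d` in 1/pseudotime; `K`, `L` live on the expression^k scale,
#' `M`, `N` on the pseudotime^m scale; Hill coefficients are dimensionless.
#'
#' @param a,b Magnitudes of positive / negative feedback regulation (>= 0).
#' @param c Basal transcription rate (>= 0).
#' @param d Degradation rate (>= 0).
#' @param K,L Half-saturation constants of the expression Hill terms.
#' @param M,N Half-saturation constants of the pseudotime Hill gates.
#' @param k,l,m,n Hill coefficients.
#' @return A named numeric vector of class `model_parameters`.
#' @examples
#' p <- model_parameters(a = 2, c = 0.05, d = 1, K = 1, k = 4)
#' model_rhs(0.5, t = Inf, p)
#' @export
model_parameters <- function(a = 0, b = 0, c = 0, d = 1,
                             K = 1, L = 1, M = 1, N = 1,
                             k = 2, l = 2, m = 2, n = 2) {
  p <- c(a = a, b = b, c = c, d = d, K = K, L = L, M = M, N = N,
         k = k, l = l, m = m, n = n)
  validate_parameters(p)
  structure(p, class = "model_parameters")
}

param_names <- function() c("a", "b", "c", "d", "K", "L", "M", "N",
                            "k", "l", "m", "n")

validate_parameters <- function(p) {
  stopifnot(is.numeric(p), length(p) == 12)
  if (!all(param_names() %in% names(p))) {
    stop("parameters must be named a, b, c, d, K, L, M, N, k, l, m, n",
         call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("all 12 circuit parameters must be finite and non-negative",
         call. = FALSE)
  }
  invisible(p)
}

#' Coerce a named vector, list or one-row data frame to model parameters
#'
#' Convenience for pulling a parameter set out of a fits table row.
#'
#' @param x A named numeric vector, list, or one-row data frame containing
#'   columns/elements `a` through `n`.
#' @return A `model_parameters` vector.
#' @examples
#' fits_row <- tibble::tibble(gene_id = "g1", a = 1, b = 0, c = 0.1, d = 1,
#'   K = 1, L = 1, M = 1, N = 1, k = 2, l = 2, m = 2, n = 2)
#' as_parameters(fits_row)
#' @export
as_parameters <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- unlist(x[param_names()])
  }
  p <- setNames(as.numeric(x[param_names()]), param_names())
  validate_parameters(p)
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Default box bounds for parameter estimation and sampling
#'
#' Covers the scales seen in log-normalized single-cell expression data while
#' excluding degenerate Hill gates: rates up to 20, basal rate up to 5,
#' degradation bounded away from 0, half-saturation constants spanning several
#' decades, and Hill coefficients in \[0.5, 8\].
#'
#' @return A named list; each element is `c(lower, upper)` for one parameter.
#' @examples
#' default_bounds()$K
#' @export
default_bounds <- function() {
  list(
    a = c(0, 20), b = c(0, 20), c = c(0, 5), d = c(1e-3, 20),
    K = c(1e-4, 1e2), L = c(1e-4, 1e2), M = c(1e-6, 1e2), N = c(1e-6, 1e2),
    k = c(0.5, 8), l = c(0.5, 8), m = c(0.5, 8), n = c(0.5, 8)
  )
}

validate_bounds <- function(bounds) {
  stopifnot(is.list(bounds), all(param_names() %in% names(bounds)))
  for (nm in param_names()) {
    b <- bounds[[nm]]
    if (length(b) != 2 || any(!is.finite(b)) || b[1] > b[2] || b[1] < 0) {
      stop("bounds for ", nm, " must be c(lower, upper) with 0 <= lower <= upper",
           call. = FALSE)
    }
  }
  invisible(bounds)
}

bounds_lower <- function(bounds) vapply(bounds[param_names()], `[`, 0, 1)
bounds_upper <- function(bounds) vapply(bounds[param_names()], `[`, 0, 2)

# Log-uniform draw within bounds; zero lower bounds are lifted to a small
# positive floor so the log scale is usable. Draws are row-wise so that for a
# fixed RNG state the first k rows do not depend on n (start-count prefix
# property of the multi-start scheme).
sample_log_uniform <- function(bounds, n = 1) {
  lo <- bounds_lower(bounds)
  hi <- bounds_upper(bounds)
  lo_eff <- pmax(lo, 1e-4)
  log_lo <- log(lo_eff)
  log_hi <- log(pmax(hi, lo_eff))
  u <- matrix(runif(n * 12), nrow = n, ncol = 12, byrow = TRUE)
  out <- exp(sweep(sweep(u, 2, log_hi - log_lo, `*`), 2, log_lo, `+`))
  colnames(out) <- param_names()
  out
}
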