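---
title: "Modeling pseudotime expression trajectories with autoregulatory gene circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling pseudotime expression trajectories with autoregulatory gene circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genecircuit)
library(dplyr)
```

## The model

Each gene is modeled independently as a one-variable autoregulatory circuit.
The normalized expression $x(t)$ of a gene along pseudotime $t \in [0, 1]$
obeys the nonautonomous ODE

$$
\frac{dx}{dt} = F(x, t) =
a\,\frac{x^{k}}{x^{k}+K}\,\frac{t^{m}}{t^{m}+M}
- b\,\frac{x^{l}}{x^{l}+L}\,\frac{t^{n}}{t^{n}+N}
+ c - d\,x .
$$

The first term is positive feedback of expression on its own production, the
second negative feedback, $c$ a basal transcription rate, and $d$ first-order
degradation. The pseudotime gates $t^m/(t^m+M)$ and $t^n/(t^n+N)$ encode that
the effective strength of feedback regulation changes as the cell population
progresses (signaling context, chromatin state, drug exposure): regulation
switches on as the gates saturate. All twelve parameters are non-negative.
Expression is clamped from below at $10^{-4}$ (`EXPR_CLAMP`) everywhere:
in the data, in emitted trajectories, and in the fixed-point search.

Interpretation and units: $a, b, c$ are rates on the normalized-expression
scale per unit pseudotime; $d$ has units 1/pseudotime; $K, L$ live on the
$x^k$ (resp. $x^l$) scale and $M, N$ on the $t^m$ (resp. $t^n$) scale; the
Hill coefficients $k, l, m, n$ are dimensionless steepnesses.

### Long-time stability

At the long-time limit the gates saturate to 1 (the package represents this
limit by `t = Inf` rather than a large number; a zero Hill coefficient
saturates to the algebraic value $1/(1+H)$), leaving the autonomous steady
state function

$$ g(x) = a\,\frac{x^{k}}{x^{k}+K} - b\,\frac{x^{l}}{x^{l}+L} + c - d\,x . $$

Fixed points are roots of $g$; a root is stable iff $g'(x^\*) < 0$. Because
$g(x) \le a + c - dx$, $g$ is eventually negative, so the search window
$[10^{-4}, \max(10,\ 2(a+c)/d)]$ (extended automatically until $g < 0$ at
the top) contains all roots. `find_fixed_points()` scans a 2000-point
log-spaced grid for sign changes, refines each bracket by bisection to an
interval below $10^{-10}\max(1, x)$, merges roots closer than $10^{-6}$
relative, and takes stability from a central difference with step
$10^{-6}x$. These tolerances sit well below the resolution of normalized
expression data and well above double-precision noise.

The clamp floor creates one modeling choice with real consequences: when
$g(10^{-4}) < 0$ the floor is an absorbing "off" state. We count it as a
stable fixed point, flagged `boundary = TRUE`, and it does count toward
multistability — biologically it is the silenced expression state of an
on/off switch — but the flag lets users exclude it.

A gene is classified `multistable` when it has at least two stable states,
`monostable` otherwise, and `unfit` when its fitting error exceeds the
cutoff (0.1 RMSE on the normalized-expression scale), in which case the
fixed-point structure is not interpreted.

### The potential landscape

Because the system is one-dimensional, $F$ always has a potential:
$dx/dt = -\partial U/\partial x$ with

$$
U(x,t) = -\Bigl[
a\,A_{k,K}(x)\,\tfrac{t^{m}}{t^{m}+M}
- b\,A_{l,L}(x)\,\tfrac{t^{n}}{t^{n}+N}
+ c\,x - \tfrac{d}{2}x^{2}\Bigr],
\qquad
A_{h,H}(x) = \int_0^x \frac{s^{h}}{s^{h}+H}\,ds
= \frac{x^{h+1}}{H(h+1)}\,
{}_2F_1\!\Bigl(1,\,1+\tfrac1h;\,2+\tfrac1h;\,-\tfrac{x^{h}}{K}\Bigr).
$$

Two sign conventions circulate for such landscapes (defining $U$ so that its
derivative *is* $F$, or so that its *negative* derivative is $F$); they are
mutually inconsistent and only the second preserves the Waddington picture
in which valleys are attractors and trajectories roll downhill. We store the
gradient-flow convention $dx/dt = -\partial U / \partial x$ and record it in
the `convention` attribute of every landscape object.

Evaluating ${}_2F_1(1, \beta; \beta+1; z)$ on the whole negative real axis
is the only numerically delicate step. The package uses three regimes: the
defining series for $z \in (-0.5, 0]$; the Pfaff transformation (series in
$z/(z-1)$) for $z \in (-2, -0.5]$; and a connection formula in $1/z$ for
$z \le -2$, which stays well conditioned down to $z \sim -10^{12}$ (so no
quadrature fallback is needed even for very steep Hill terms with tiny
half-saturation constants). When $1/k$ is a positive integer ($k = 1$ or
$k = 1/2$) the connection formula degenerates and exact elementary
logarithmic antiderivatives are used instead; within $\sim 10^{-10}$ of
those points the connection formula itself remains accurate to better than
$10^{-7}$. `potential_by_quadrature()` computes $-\int F\,dx$ by adaptive
quadrature as a fully independent route; the two agree to an additive
constant within $10^{-6}$ across random parameter sets, and the analytic
$x$-gradient of $-U$ reproduces $F$ to $10^{-5}$ relative — both checks run
in the test suite.

### Integration

`deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`: high Hill coefficients
make the right-hand side stiff near thresholds, so a stiff-capable method is
required. The clamp is applied to *outputs* only, not inside the solver
state, keeping the solution smooth; whether the original pipeline clamps
during integration or only in normalization is not decidable from its
description, and output-clamping is the less intrusive reading.

## Parameter estimation

Estimation is smooth-and-match gradient matching with multi-start local
optimization:

1. **Smooth.** A cubic smoothing spline with smoothness chosen by
   generalized cross-validation (the standard smooth-and-match practice; a
   fixed `spline_df` can be supplied instead) gives $\hat x(t_j)$ and the
   analytic derivative $\widehat{dx}(t_j)$ at the observed pseudotimes.
   Branches with fewer than 8 representative points are rejected — too
   little pseudotime span to constrain a dynamical model.
2. **Match.** The penalized loss
   $\sum_j \bigl(\widehat{dx}_j - F(\hat x_j, t_j)\bigr)^2
   + \lambda (a^2+b^2+c^2+d^2)$
   is minimized by bound-constrained Levenberg–Marquardt least squares
   (`minpack.lm::nls.lm`) with an analytic Jacobian, from `n_starts = 40`
   log-uniform initial guesses inside the box bounds. The penalty
   ($\lambda = 10^{-3}$ by default) encodes that the magnitudes of
   activation and inhibition are energetically costly; it acts as a soft
   preference inside the optimization.
3. **Score and select.** Every converged solution is scored by its
   *trajectory RMSE*: the model is integrated from the first smoothed value
   and compared to the observed trajectory. Solutions within
   `near_opt_tolerance` (5% relative) of the best RMSE form the
   near-optimal candidate pool, and the pool member with the smallest
   $\ell_2$ norm of $(a, b, c, d)$ is returned — a hard minimal-energy
   tie-break complementing the soft penalty. Scoring against the *observed*
   (noisy) trajectory matters: the noise floors the RMSE, so the relative
   band genuinely contains statistically indistinguishable fits; scored
   against the smoothed curve the best RMSE approaches zero and the band
   collapses to winner-take-all, disabling the minimal-norm selection.
4. **Polish.** Gradient matching inherits the spline's bias at sharp switch
   corners, which integration amplifies. When the best trajectory RMSE
   exceeds the smoothing noise floor ($\max(0.01,\ 1.5\,\hat\sigma)$ with
   $\hat\sigma$ the data-minus-spline SD), the leading solutions are
   refined by bounded least squares on the integrated trajectory itself,
   warm-started at the gradient-matching optima. This engages rarely (hard,
   steep genes) and leaves easy fits untouched.

Box bounds: $a, b \in [0, 20]$, $c \in [0, 5]$, $d \in [10^{-3}, 20]$,
$K, L \in [10^{-4}, 10^{2}]$, $M, N \in [10^{-6}, 10^{2}]$, and Hill
coefficients in $[0.5, 8]$. They cover the scales of log-normalized
single-cell expression while excluding degenerate gates ($h = 0$); zero
lower bounds are lifted to $10^{-4}$ for the log-uniform start draws.
Convergence tolerances are $10^{-10}$ on the objective with at most 2000
evaluations per start. Every gene gets its own RNG substream derived from
the run seed and the gene index, so fits are reproducible and independent
of execution order; the same draw stream is a prefix of itself as
`n_starts` grows, which makes "more starts never hurt" a testable
invariant.

### Robustness to the smoothing resolution

Representative curves depend on how many support points (`npc`) the
smoothing uses. `robustness_scan()` rebuilds curves from per-cell
observations at each requested `npc`, refits all genes, and applies the
Kruskal–Wallis test per parameter across resolutions; in the robust regime
all 12 p-values exceed the $10^{-4}$ significance threshold, while a
ten-fold shift planted in one group drives at least one p-value below it.
Medians are reported per resolution over all fitted genes. These scans use
`n_starts = 10` and `polish = FALSE`: gene-wide medians and rank-based
tests are insensitive to the start count and to per-gene polish, and the
scan refits every gene six times.

## The synthetic benchmark

The generator emulates smoothed pseudotime-pipeline output: per-gene curves
over `n_pc = 60` representative points in $[0,1]$, clamped at $10^{-4}$,
with additive Gaussian noise (`noise_sd = 0.02`) — smoothed curves carry
only small, roughly symmetric residual noise, which is what an additive
model captures. Initial values are log-uniform on $[0.05, 3]$, spanning the
basins of typical switches without starting at the clamp. Ground-truth
classes are verified by the fixed-point analysis of the exact parameters.

Monostable genes are rejection-sampled log-uniformly within the estimation
bounds (accepting a single stable state at or below 5, the top of the
normalized-expression scale). Bistable genes are built as expressed on/off
switches, the biology that motivates multistability screens: the induced
state, the threshold-to-state ratio, the Hill steepness and the degradation
rate are drawn on data-like scales and the two fixed-point conditions are
solved for $a$ and $K$; basal rate and negative feedback are weak, and the
positive gate opens within the observation window. Blind rejection sampling
from the full box was tried first and almost never yields switches whose
trajectories actually express the switch — accepted sets had attractors far
outside the data range or dynamics too slow for the window. Trajectories
must pass the low-expression filter (mean $\ge 0.1$), and bistable
trajectories must commit to the induced state by the end of the window,
mirroring the fact that permanently silent genes are removed upstream by
the low-expression filter. A `flat` class ($a = b = c = 0$, pure decay)
exercises the penalty and the filter. For smoothing-resolution studies,
`generate_cell_data()` exposes the unsmoothed layer: 200 per-gene cells at
uniform pseudotimes with five-fold larger noise, from which curves are
re-smoothed at any `npc`.

What the generator does *not* emulate: dropout and count noise of raw
single-cell data, pseudotime estimation error, branch assignment error,
cell-density variation along pseudotime, and gene–gene dependence. Passing
benchmarks here therefore validates the estimator and screen under the
model's own assumptions, not the upstream pipeline.

## Known limitations

**The stability class of a fitted gene is not identifiable from a single
trajectory.** This is the central caveat for interpreting multistability
screens. A bistable switch trajectory — slow start, rapid rise, committed
plateau — can be reproduced essentially exactly (to $\sim 10^{-6}$ RMSE on
noise-free data) by monostable parameter sets that route the dynamics
through the pseudotime gates instead of the expression feedback, because
$x$ and $t$ increase together along a single trajectory and are therefore
confounded. The returned class is then decided by the near-optimal
tie-break rather than by the data. In benchmark runs with the default
generator, monostable ground truth is recovered for $\sim 95$% of genes but
bistable ground truth for only $\sim 50$%, and no defensible generator
regime we explored pushes class recovery near 100%. The fitting-error
criterion is unaffected (all benchmark fits land well under the 0.1
cutoff). Observing the same gene on multiple branches, or perturbation
data, would break the confound; with one trajectory per gene, multistable
calls should be read as "consistent with bistability under the
minimal-energy prior", not as demonstrated bistability.

Other limitations: one ODE per gene (no gene–gene coupling); no stochastic
(Langevin / chemical master equation) landscape; no uncertainty
quantification on parameters; one-parameter bifurcation scans only (the
$K$–$L$ interplay is read from the two separate diagrams); no continuation
methods — in one dimension a dense grid plus root finding is sufficient and
simpler.

## Problem sizes

The shipped tests and the acceptance script use: 100 random circuits
(50 grid points each) for the gradient-identity and landscape-route checks;
200 random circuits against a $10^5$-point brute-force sign scan for the
fixed-point oracle; a 50-gene benchmark (25 monostable / 25 bistable,
`n_pc = 60`, `noise_sd = 0.02`, `n_starts = 40`) for the end-to-end screen;
and a 200-gene per-cell dataset re-smoothed at `npc` 55–60 for the
robustness scan. A full benchmark run completes in minutes on one core.
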