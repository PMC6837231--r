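---
title: "Likelihoods and Fisher information around co-dimension 1 bifurcations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihoods and Fisher information around co-dimension 1 bifurcations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifinfer)
```

## The problem

A co-dimension 1 bifurcation is a qualitative change in a dynamical
system's long-run behaviour driven by a single parameter α: equilibria
appear or vanish (saddle-node), exchange stability (transcritical), or
split (pitchfork). `bifinfer` asks what this global structure does to a
*local* statistical question: given noisy time-series observations of the
state, how well can α and the initial condition IC be inferred?

The package works with the four scalar normal forms

- saddle-node: $\dot X = \alpha - X^2$,
- transcritical: $\dot X = \alpha X - X^2$,
- supercritical pitchfork: $\dot X = \alpha X - X^3$,
- subcritical pitchfork: $\dot X = \alpha X + X^3$,

whose fixed points and stability are known in closed form
(`fixed_points()`), and whose solutions are available analytically
(`closed_form_solution()`; the transcritical equation is logistic, both
pitchforks are Bernoulli equations in $u = X^{-2}$, and the saddle-node
solution follows from tanh/tan addition identities). These closed forms are
used as independent oracles for the numerical integrator, never as its
implementation.

On the fixed-point structure, two details deserve note. The stability of
the transcritical branch $X = \alpha$ for $\alpha < 0$ follows the
linearization $f'(X) = \alpha - 2X$, which gives $f'(\alpha) = -\alpha > 0$:
the branch is unstable, and the origin is stable, with the labels swapping
at $\alpha = 0$. And the saddle-node equilibria sit at $\pm\sqrt{\alpha}$,
the real roots of $\alpha - X^2$.

## Statistical model

Observations are $y_i = \mu_i(\theta_{true}) + \varepsilon_i$,
$\varepsilon_i \sim N(0, \sigma^2)$ i.i.d., with $\mu(\theta)$ the model
solution at $M$ evenly spaced times and $\theta = (\alpha, IC)$. Up to an
additive constant the Gaussian log-likelihood is

$$\ln L(\theta \mid D) = -\tfrac12 \sum_{i=1}^{M} (y_i - \mu_i(\theta))^2.$$

The constant is fixed to 0 and no $1/\sigma^2$ weight is applied: neither
affects the argmax, and it keeps the noiseless self-likelihood exactly 0 —
a convenient exactness anchor for tests. The observed Fisher information is
the negative Hessian of $\ln L$ at $\theta$, summarized by its trace

$$FI_{obs}(\theta) = -(H_{\alpha\alpha} + H_{IC\,IC}),$$

a scalar gauge of how sharply the likelihood is curved, hence how
certain an estimate at $\theta$ would be.

**Divergence convention.** All four normal forms blow up in finite time
once a trajectory leaves every basin of attraction. Such $\theta$ have no
usable likelihood: `log_likelihood()` returns $-\infty$ (a status, not an
error), and Fisher map cells whose trajectory — or any of whose nine
finite-difference stencil evaluations — diverges are set to 0 with status
`divergent_set_zero`. A finite penalty instead of $-\infty$ would invent
an ordering among non-inferable points; the explicit $-\infty$ keeps grid
argmaxes well defined and makes the excluded region visible in exports.
The stencil rule means a margin of at most one FD step (default $10^{-3}$)
around each basin boundary is conservatively zeroed.

**Whole-plane maps use noiseless self-generated data.** A Fisher map
evaluates $FI_{obs}$ at every grid point $\theta$. The information is a
property of the likelihood around *its* maximum, so each $\theta$ is
scored against the noiseless observation generated at $\theta$ itself,
making it the exact MLE of its own data. This is what makes a plane-wide
map well defined, and it reproduces the characteristic geometry: ridges of
high information along bifurcation points and unstable equilibria (where
nearby parameters produce qualitatively different trajectories), low
information deep in stable regimes (where trajectories all collapse onto
the same attractor), zeros over divergent regions.

## Numerical choices

- **Integrator.** Classic fixed-step RK4 (compiled), each observation
  interval subdivided evenly so observation times are hit exactly; the
  requested step (default $10^{-3}$) is an upper bound on the actual step.
  Fourth-order convergence is property-tested (step-halving error ratios
  in $[8, 32]$), and accuracy against the closed forms is $\sim 10^{-14}$
  at the default step — far below every noise level studied.
- **Time window.** $t \in [0, 10]$ with $M \in \{1000, 500, 10\}$
  observations. Over the parameter ranges scanned
  ($|\alpha|, |IC| \le 2$) converging trajectories reach their fixed point
  well within the window, and diverging ones blow up inside it, so the
  ok/diverged classification is sharp.
- **Divergence threshold.** $|X| > 10^6$ declares blow-up, checked on
  every internal step so that blow-up between sparse observations
  ($M = 10$) is caught. Because blow-up is finite-time, the classification
  is insensitive to this constant (property-tested at $10^4$ vs $10^8$);
  the detected divergence time tracks the analytic blow-up time to a few
  internal steps.
- **Finite differences.** Central 3-point stencils for the diagonal
  Hessian entries, the 4-point cross stencil for the mixed entry, steps
  $10^{-3}$ in both directions. At an exact MLE the stencil differences
  are small numbers computed from a baseline of 0, so cancellation is
  benign; agreement with a Richardson-extrapolated oracle (steps
  $10^{-2}$, $5\times10^{-3}$) is within $10^{-3}$ relative. Raw traces
  are stored — they can dip below zero at FD-error level — and a
  clamped-at-zero view (`fisher_map_values()`) is used for export.
- **"Marginal" Fisher information at fixed IC.** `fisher_slice()` reports
  the fixed-IC row of the full trace map by default; treating the IC as
  known (only the $-H_{\alpha\alpha}$ curvature) is a defensible
  alternative reading and is available via `component = "alpha"`, with the
  choice recorded in output metadata.
- **MLE search.** A 41×41 coarse grid over the bounds locates the best
  cell, then Nelder–Mead refinement polishes it. The refinement is
  derivative-free on purpose — the likelihood is non-smooth at divergence
  boundaries — and out-of-bounds or divergent proposals are rejected
  through a finite penalty so the simplex contracts back. Ties on grids
  break toward smallest α, then smallest IC, for determinism.
- **Map grids.** Whole-plane scans default to $\alpha, IC \in [-2, 2]$;
  the pipeline default is 101×101 cells, and the test suite uses 41×41
  (the structure being checked — peak locations, symmetry, basin
  boundaries, quadrant signs — is fully resolved at that resolution).

## The synthetic-data generator

`generate_observation()` emulates the study conditions: exact RK4
solutions observed at $M \in \{1000, 500, 10\}$ evenly spaced times, with
i.i.d. zero-mean Gaussian noise of $\sigma \in \{0, 0.1, 1.0\}$ (named
`low`, `moderate`, `heavy`) added per time point *after* solving. A single
integer seed drives one dedicated, restorable RNG stream per observation,
so observations are bit-reproducible and the caller's RNG is untouched. A
diverging $\theta_{true}$ yields a flagged, value-less observation so
parameter scans can traverse divergent regions.

What this emulates — and what it does not: additive, homoscedastic,
independent Gaussian measurement error on a deterministic ODE. Real
biological time series feature intrinsic (process) stochasticity,
multiplicative or log-normal error, irregular sampling and missingness;
none of these are generated, so passing tests demonstrate correctness of
the inference machinery under the stated error model, not robustness to
misspecified noise. Log-normal noise is a natural extension point of
`noise_spec()` but is deliberately not implemented.

## Calibrated accuracy checks

Two kinds of quantitative checks back the test suite. First, exactness
anchors with closed-form expected values (noiseless self-likelihood 0; a
constant-residual case with $M = 10$ giving exactly $-5$; FD Hessian of an
analytic quadratic giving $(-1, 0, -1)$). Second, a stochastic recovery
check at $\sigma = 0.1$, $M = 1000$, saddle-node
$\theta_{true} = (1, 1.5)$: its thresholds (median error over 20 seeds
below 0.01 in α and 0.035 in IC) were frozen from an independent
calibration run — a zooming brute-force grid search over the *closed-form*
likelihood, sharing no code with the RK4/simplex path — which achieved
median errors of 0.0050 (α) and 0.0175 (IC); the thresholds are twice
those values to absorb seed-set variation.

The printed ranges of map maxima depend on every numerical setting (grid,
window, FD steps), so cross-bifurcation comparisons are asserted as
orderings under matched defaults (e.g. the supercritical pitchfork map's
maximum exceeds the transcritical one's) rather than as absolute values.

## Limitations

- Scalar state only; the normal forms are the one-dimensional canonical
  cases, and the machinery does not handle oscillatory (Hopf) or
  higher-co-dimension bifurcations.
- $FI_{obs}$ is a local, point-wise summary: it says nothing about
  multi-modality of the likelihood far from the evaluation point.
- Whole-plane maps score each $\theta$ against its own noiseless data;
  they characterize the geometry of inferability, not the sampling
  distribution of any single experiment's estimate.
- Near basin boundaries the FD stencil zeroes a one-step margin, so
  extremely thin high-information ridges may be clipped at coarse grid
  resolutions.
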