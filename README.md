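# bifinfer

Parameter inferability around co-dimension 1 bifurcations.

Many biological dynamical systems — cell-fate switches, epidemic thresholds,
ecological tipping points — sit near a *bifurcation*: a point in parameter
space where a small change in one parameter qualitatively reorganizes the
dynamics (equilibria appear, disappear, or exchange stability). When such a
system is fit to time-series data, that global structure leaves a strong
imprint on *how well* the kinetic parameter and the initial condition can be
inferred. `bifinfer` quantifies this for the four canonical scalar
co-dimension 1 normal forms

| bifurcation | ODE |
|---|---|
| saddle-node | dX/dt = α − X² |
| transcritical | dX/dt = αX − X² |
| supercritical pitchfork | dX/dt = αX − X³ |
| subcritical pitchfork | dX/dt = αX + X³ |

by mapping, over the whole (α, IC) plane:

- the **log-likelihood** of θ = (α, IC) given observations
  D = (y₁, …, y_M) under i.i.d. Gaussian measurement noise,
  ln L(θ | D) = −½ Σᵢ (yᵢ − μᵢ(θ))² up to a constant, with μ(θ) the RK4
  solution of the model at the observation times;
- the **maximum-likelihood estimate** (grid search plus derivative-free
  simplex refinement);
- the **observed Fisher information**, the negative trace of the
  finite-difference Hessian of the log-likelihood,
  FI_obs(θ) = −tr H(ln L) = −(H_αα + H_ICIC), a scalar measure of how
  sharply the likelihood is curved — i.e. how reliably θ can be inferred.

Parameter combinations whose trajectories blow up in finite time have no
defined likelihood; they get ln L = −∞ and FI_obs = 0 (flagged
`divergent_set_zero`), so divergent regions are mapped rather than crashed
into. The package is aimed at anyone studying practical identifiability of
ODE models near qualitative regime changes.

## Worked example

```r
library(bifinfer)

fixed_points("saddle_node", 1)
#> Fixed points of saddle_node at alpha = 1:
#>  location stability
#>        -1  unstable
#>         1    stable

# synthetic data: alpha = 1, IC = 1.5, M = 1000 points on [0, 10],
# moderate Gaussian noise (sigma = 0.1)
g   <- time_grid(1000)
obs <- generate_observation("saddle_node", theta(1, 1.5), g,
                            noise_spec(level = "moderate"), seed = 1)

find_mle(obs = obs, alpha_bounds = c(-2, 2), ic_bounds = c(-2, 2))
#> MLE: alpha_hat = 0.995444, ic_hat = 1.52285, loglik = -5.34412 (1760 evaluations)

# observed Fisher information at three points of the (alpha, IC) plane
fisher_trace("saddle_node", theta(0.05, 1.5), g)
#> observed FI trace: 2326.02 (ok)
fisher_trace("saddle_node", theta(1.5, 1.5), g)
#> observed FI trace: 173.482 (ok)
fisher_trace("saddle_node", theta(-0.5, 1.5), g)
#> observed FI trace: 0 (divergent_set_zero)
```

Reading the numbers: with moderate noise the MLE lands within ~0.02 of the
truth. The Fisher information is largest just above the bifurcation point
α = 0 (2326: tiny decreases of α flip the system into the divergent regime,
so the likelihood is sharply curved there), an order of magnitude smaller
deep in the stable regime at α = 1.5 (173: trajectories change slowly with
θ, so inference is less certain), and zeroed at α = −0.5 where no fixed
point exists and every trajectory diverges.

Whole-plane maps and fixed-IC slices come from `fisher_map()` and
`fisher_slice()`; likelihood surfaces from `likelihood_surface()`. Each has
a CSV + JSON exporter (`write_fisher_map()`, `write_surface()`, …), and
`run_command()` (or the `inst/cli/bifrun.R` script) drives the same stages
from a flat YAML config.

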