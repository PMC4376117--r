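---
title: "Fitting Wiener diffusion models to response-time data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting Wiener diffusion models to response-time data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wienerfit)
```

## The model

wienerfit fits the Wiener diffusion model of fast binary decisions. Evidence
accumulates from a starting point $z = z_r a$ toward one of two absorbing
thresholds at $0$ and $a$, with constant mean drift $v$ and Gaussian noise of
standard deviation $s$ (the diffusion constant, fixed at $s = 1$; estimates
from other scales convert by multiplying $v$, $a$ and $s_v$ with the ratio of
diffusion constants, see `rescale_parameters()`). The response is determined by
the threshold hit first; the response time is the first-passage time plus a
non-decision time covering encoding and motor processes. The full model has
eight parameters:

| parameter | meaning | unit / range |
|---|---|---|
| `v`   | drift rate (speed of information uptake)   | evidence/s, typically $-4$ to $4$ |
| `a`   | threshold separation (response caution)    | evidence units, $> 0$, typically 0.6–2 |
| `zr`  | relative starting point (decision bias)    | $(0,1)$; 0.5 = unbiased |
| `t0`  | mean non-decision time                     | s, $\ge 0$ |
| `d`   | non-decision time difference between the responses | s; upper gets $t_0 - d/2$, lower $t_0 + d/2$ |
| `sv`  | inter-trial SD of drift (normal)           | $\ge 0$ |
| `szr` | inter-trial range of `zr` (uniform)        | $\ge 0$; the distribution must stay inside $(0,1)$ |
| `st0` | inter-trial range of `t0` (uniform)        | s, $\ge 0$ |

`validate_parameters()` additionally requires the smallest realizable
non-decision time, $t_0 - s_{t0}/2 - |d|/2$, to be non-negative — the model
must not predict negative response times. This joint constraint is our
addition; it is exactly the condition under which every simulated trial has a
well-defined response time.

## Predicted distributions: two engines

**Densities** (used by the maximum-likelihood criterion) come from the two
classical series representations of the Wiener first-passage-time density, one
converging quickly for small scaled times $t/a^2$ and one for large. For each
evaluation the representation whose published truncation bound needs fewer
terms is used, with the bound set to $\epsilon = \min(10^{-6},
10^{-\mathrm{precision}})$: never looser than $10^{-6}$, tighter when a higher
precision is requested. Drift variability is integrated analytically (the
drift enters the series only through $\exp[(a-z)v - v^2 t/2]$, whose normal
mixture is a Gaussian integral); starting-point and non-decision variability
are integrated with a midpoint rule of $\max(4, \lceil 0.8 \cdot
10^{\mathrm{precision}/2}\rceil)$ steps per dimension. The constant 0.8 was
calibrated against a $10^4$-step reference so that the refinement error is
about $10^{-\mathrm{precision}}$. The density at $t \le 0$ is defined as 0,
avoiding the $t^{-3/2}$ singularity of the small-time series.

**CDFs** (used by the Kolmogorov–Smirnov and chi-square criteria and all
export/simulation tools) come from a finite-difference solution of the
backward PDE $\partial_t F = \tfrac12 \partial_{zz} F + v\,\partial_z F$ with
boundary values $F(t,0)=0$, $F(t,a)=1$: one solve yields the upper-threshold
CDF for *every* starting point, which makes the uniform starting-point
integration essentially free — this is why the PDE route is preferred over the
explicit CDF series when inter-trial variabilities are present. The scheme is
Crank–Nicolson in time with centered second-order space differences
(unconditionally stable, so the drift term imposes no step-size constraint)
and two half-step fully implicit startup steps to damp the oscillations the
discontinuous initial condition would otherwise excite. Drift variability is
averaged over $\max(4, 2\,\mathrm{precision})$ Gauss–Hermite nodes (the
analytic trick above holds for densities, not for the PDE solution);
non-decision variability by the same midpoint rule as the density engine.

Grid sizes follow the single `precision` knob (target error
$\approx 10^{-\mathrm{precision}}$, default 3): $n_z = \lceil 60\,a\cdot
10^{(\mathrm{precision}-3)/2} \rceil$ spatial steps (floored at 20 and at
$2|v|a$ so the cell Péclet number stays small) and a time step of at most
$\min(h/(2\max(1,|v|)),\ 0.005\cdot 10^{-(\mathrm{precision}-3)/2})$ s. The
constants were calibrated so that, at the default precision, the time
derivative of the PDE solution matches the series density to better than
$10^{-3}$ and the long-time limit matches the closed-form absorption
probability to the same tolerance; the package's tests re-verify both
couplings, as well as the agreement of the two series representations to
$10^{-6}$. The time horizon starts at the analytic decay estimate of the
slowest mode and doubles until the unabsorbed mass falls below
$10^{-\mathrm{precision}}$ (seven doublings at most). Two numerical
safeguards are applied to the grid solution: clamping to $[0,1]$ and
monotonicity enforcement along the time axis; both act at the order of the
scheme's rounding ripples, far below its discretization error.

## Fit criteria

* **ML**: $\mathrm{LL} = \sum_i \ln g(RT_i, k_i)$ over trials, with each
  density floored at $10^{-6}$ for robustness against fast outliers; the
  search minimizes $-\mathrm{LL}$. `bic()` implements
  $\mathrm{BIC} = -2\,\mathrm{LL} + P\ln M$.
* **CS**: both response distributions are split into 6 bins at their
  empirical 0.1/0.3/0.5/0.7/0.9 quantiles (type-7, i.e. linear interpolation
  between order statistics), giving up to 12 bins per condition;
  $\mathrm{CS} = \sum (o_i - p_i)^2/p_i$ is summed over conditions. Predicted
  counts are *joint* masses — total condition trials times the probability of
  the response *and* the bin — so response frequencies are part of the fit. A
  response observed fewer than 12 times in a condition contributes no bins
  (its quantile edges would be too unreliable). With $K$ conditions, $N$ bins
  and $P$ free parameters the statistic is asymptotically $\chi^2$ with
  $K(N-1) - P$ degrees of freedom, which the test suite verifies by
  simulation at the data-generating parameters ($P = 0$).
* **KS**: both response distributions are merged into one *combined*
  distribution over signed time by negating lower-threshold response times;
  $D$ is the maximum vertical distance between the empirical step function
  (evaluated on both sides of each jump) and the predicted combined CDF, and
  is mapped to a p-value with the asymptotic Kolmogorov series at
  $\lambda = (\sqrt n + 0.12 + 0.11/\sqrt n)D$. Across conditions the product
  of p-values is maximized; internally the optimizer minimizes
  $-\sum \ln p$ for numerical stability.

Trial minimums are enforced before any search: ML and KS need at least 10
trials per condition; CS needs, per condition, at least one response given in
12 or more trials.

## The search

Free parameters (any of the eight not fixed by `fixed`/`set`, expanded per
condition by `depends`) are searched with a Nelder–Mead simplex under a
*lexicographic penalty*: theoretically impossible parameter constellations are
never scored by the criterion; they are ranked strictly worse than every valid
vertex and, among themselves, by the summed magnitude of their constraint
violations, which gives the simplex a slope back into the valid region. The
start is the closed-form EZ estimate of $(v, a, t_0)$ from accuracy, RT mean
and RT variance (computed per condition cell; shared parameters use the
cell average), with $z_r = 0.5$ and all variabilities 0. Edge accuracies are
nudged by half a trial before the logit; an exactly symmetric cell is nudged
upward by the same amount, since the EZ closed forms degenerate there; the EZ
$t_0$ is clamped into $[0, \min(RT) - 0.05]$ so the start is always valid.
Initial simplex steps are 0.1 for `a`, `v`, `sv`, `st0`, 0.05 for `zr`,
`szr`, and 0.02 s for `t0`, `d`. The search runs three times — restarting
from the incumbent with a re-inflated simplex — under consecutively stricter
stopping criteria (objective spread below $10^{-2}, 10^{-3}, 10^{-4}$;
iteration caps 400, 600, 800), and all three fit values are reported. The
whole pipeline is deterministic given the data, so identical inputs give
bit-identical results.

## Simulation tools

`sample_dataset()` draws each trial's drift, starting point and non-decision
time from their inter-trial distributions and then inverts the basic-model
combined CDF (computed by the PDE engine on its grid, inverted by linear
interpolation) at a uniform draw; the small unabsorbed residual mass beyond
the grid horizon (about $10^{-\mathrm{precision}}$) is folded back
proportionally. When only the starting point varies, a single PDE solve
serves all trials via its $z$-grid; per-trial drifts require one solve each.
`deterministic_dataset()` places $n$ noise-free trials at the full-model
combined-CDF quantiles of $(i - 0.5)/n$ — the plotting-position convention;
the sign of the quantile fixes the response. `simulate_paths()` is a direct
Euler–Maruyama simulation of the accumulation process, deliberately
independent of both distribution engines; the test suite uses it as the
reference oracle (at step sizes of $10^{-4}$ s, where its boundary-crossing
bias is well below the sampling error of the test sample sizes).

`montecarlo_fit_threshold()` implements fit-assessment calibration: parameter
vectors are drawn from the multivariate normal defined by the mean and
covariance of per-participant estimates (rejecting invalid draws; a
rank-deficient covariance is ridge-regularized with a warning), one data set
is simulated per draw — each condition cell separately, then combined — and
refitted with the same specification. The critical value is the 5% bad-fit
quantile of the resulting fit indices: the lower 5% for KS (small p bad), the
upper 95% for CS and ML (large values bad).

## What the generator does and does not emulate

The synthetic-data tools draw from exactly the model being fitted: stationary
drift, constant thresholds, independent trials, and the three standard
inter-trial distributions. Real data additionally contain contaminants
(guesses, lapses, fast outliers), drifts that may vary within a trial, and
sequential dependencies. Passing recovery and calibration tests therefore
demonstrates the correctness of the implementation under the model's own
assumptions — not that the model is adequate for any particular experiment.
The ML criterion in particular is known to be fragile under fast outliers
(one floored density changes LL by $\ln 10^{-6}$), which is why the KS
criterion is the default.

## Problem sizes used in the test suite

The stochastic suites run at sizes chosen to give stable verdicts on one CPU:
series/PDE/closed-form agreement on a fixed parameter lattice; simulation
self-consistency as 100 KS tests at $n = 1000$ trials (pass rate $\ge 95\%$
at $\alpha = 0.01$); ML recovery as 50 replicates of $n = 500$ trials from
$(a, v, t_0, z_r) = (1, 1.5, 0.3, 0.5)$ with tolerance bands $\pm 0.3$,
$\pm 0.15$ and $\pm 0.03$ (pass rate $\ge 90\%$); chi-square calibration as
200 replicates of $n = 1000$ trials against $\chi^2(11)$. Euler–Maruyama
cross-checks use $4000$ paths at $dt = 10^{-4}$ s.

## Known limitations

* The PDE engine's accuracy is lowest in the first ~0.2 s of decision time
  for steep-drift/small-threshold settings, where the solution has a sharp
  boundary layer; at the default precision the error there can approach
  $2 \cdot 10^{-3}$ before settling below $10^{-3}$.
* Per-trial drift variability makes `sample_dataset()` solve one PDE per
  trial; for large simulations with `sv > 0` prefer `simulate_paths()`.
* No standard errors or posterior uncertainty are computed for the
  estimates; the Monte-Carlo threshold machinery addresses model fit, not
  parameter uncertainty.
* Time-varying drift, collapsing thresholds and multi-alternative choices
  are outside the model family.

## A complete example

```{r, eval = FALSE}
set.seed(1)
truth <- dm_params(v = 1.5, a = 1, zr = 0.5, t0 = 0.3)
trials <- sample_dataset(truth, n = 500)
fit <- dm_fit(trials, method = "ml",
              fixed = list(zr = 0.5, d = 0, sv = 0, szr = 0, st0 = 0))
tidy(fit)
glance(fit)
autoplot(fit, trials)
```
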