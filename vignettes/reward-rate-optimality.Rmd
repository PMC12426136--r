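---
title: "Reward-rate optimal thresholds in the diffusion model: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-rate optimal thresholds in the diffusion model: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrddm)
```

# The scientific question

In speeded two-alternative forced-choice tasks, a decision-maker controls a
speed-accuracy trade-off. Under the diffusion model, noisy evidence
accumulates at drift rate $v$ between two absorbing boundaries separated by
$a$; the threshold separation $a$ is the caution parameter. The reward rate

$$\mathrm{RR} = \frac{PC}{MRT + ITI + FDT + (1 - PC)\,ET}$$

(correct responses per second of task time, with $PC$ the accuracy, $MRT$ the
summary response time, and $ITI$, $FDT$, $ET$ the task's inter-trial,
feedback, and additional error-timeout dead times) defines an *optimal*
threshold $b$: the value of $a$ that maximises RR given the decision-maker's
other parameters and the task timing. `rrddm` provides the machinery to ask
whether groups of decision-makers set thresholds at, above (overly cautious),
or below (overly urgent) this optimum, and whether some groups sit closer to
it than others — in particular under *fixed-time* block designs (a fixed
time budget per block, trial count varies) versus *fixed-trial* designs
(fixed trial count, duration varies).

Two hierarchical model families implement the two kinds of assessment:

* **Qualitative** (`block_threshold_model()`, `run_qualitative()`): the
  threshold is free to vary per block; the block-by-block group-level
  threshold posteriors are displayed against the group's optimal-threshold
  distribution, obtained by pushing every group-level posterior draw of
  $(v, t_{er})$ through the optimal-threshold search.
* **Quantitative** (`difference_model()`, `run_quantitative()`): each
  participant's threshold is parameterised as $a_i = b_i + c_i$, where $b_i$
  is the reward-rate-optimal threshold implied by their other parameters and
  $c_i$ their distance from optimality. For two groups, the group-level $c$
  means are $m \mp \Delta_c / 2$, and $\Delta_c$ carries one of three priors
  (unrestricted normal; positive truncation; negative truncation), giving an
  effect-vs-null Bayes factor and two directional ones via the Savage-Dickey
  density ratio.

# The full diffusion model and its likelihood

The full model adds between-trial variability: drift drawn
$\mathrm{Normal}(v, s_v)$, relative start point Uniform over
$z \pm s_z/2$, non-decision time Uniform over $t_{er} \pm s_{ter}/2$ (the
standard full-diffusion convention; the variability families are a package
choice, as is the relative start-point parameterisation $z = z_{abs}/a$,
which keeps the start unbiased when thresholds vary across blocks). The
within-trial diffusion coefficient is the scaling constant and is fixed at
$s = 1$ throughout; the common alternative 0.1 convention merely rescales
$v$, $a$ and $s_v$ by 10.

The first-passage-time density uses the small-time and large-time series
representations with the usual accuracy-based switch; the number of terms is
chosen from the standard error bounds at tolerance $10^{-7}$. The full-model
likelihood integrates the density analytically over the Gaussian drift
distribution and by fixed-order Gauss-Legendre quadrature over the two
uniform distributions (7 nodes for the start point, 9 for non-decision time,
both exposed as arguments). With all variabilities at zero the likelihood
reduces exactly to the Wiener density, which the test suite verifies, along
with normalisation of the full density to $1 \pm 10^{-3}$ on a fixture grid.

# Simulation: Euler-Maruyama with bridge crossing detection

`simulate_trials()` discretises the accumulation at step `dt` (default 10 ms,
the setting used for the optimal-threshold search; oracle comparisons use
1 ms) and censors decisions at 10 s. Naive endpoint checking misses
within-step boundary crossings and biases first-passage times upward by
$O(\sqrt{dt})$ — large enough to fail a 3-Monte-Carlo-SE comparison with the
closed-form mean decision time even at 1 ms. Each step therefore also draws
Brownian-bridge crossing probabilities
$\exp\{-2 (a - x_t)(a - x_{t+dt})/(s^2 dt)\}$ (and the mirror image at 0) and
absorbs accordingly, which removes the $\sqrt{dt}$ term; the residual $O(dt)$
bias is about 1 ms at `dt = 0.001`. Timed-out trials are counted as errors
with decision time equal to the censoring bound when computing reward rates
(configurable via `timeout_as_error`).

Every trial owns an RNG substream derived from the seed and the trial index.
This makes output bit-reproducible and, more importantly, implements *common
random numbers* for the threshold grid search: trial $j$ experiences the
same noise path at every candidate threshold, so the simulated RR curve is a
smooth function of $a$ and the argmax does not jump between adjacent grid
values because of fresh noise.

# The optimal-threshold search

`optimal_threshold()` scans $a$ over 0.01–4 in steps of 0.01 (the published
search range), either by simulation (2000 trials per grid value at 10 ms) or
through the closed-form simple-model expressions

$$PC(a) = \frac{1 - e^{-2 v a z / s^2}}{1 - e^{-2 v a / s^2}}, \qquad
  E[DT](a) = \frac{a}{v}\,\frac{1 - e^{-2 v a z/s^2}}{1 - e^{-2 v a/s^2}} - \frac{za}{v},$$

with the drift-free limits handled explicitly. Ties resolve to the smallest
threshold. The closed-form path is the oracle for the simulation path and is
also what the hierarchical difference model uses for $b_i$ in its
no-variability variant: $b_i$ is deterministic given $(v_i, t_{er,i})$, so it
is memoised on values quantised to 0.01 (two participants with identical
parameters share one computation; a near-zero `quantize` recovers full
recomputation, and the test suite checks the cached and uncached paths
agree). The full-variability variant uses the simulation path with a
0.05-step coarse scan plus 0.01 local refinement, reflecting the heavy cost
of simulating the RR curve inside MCMC.

**A caution about Monte-Carlo argmax noise.** The RR curve is extremely flat
near its maximum for drift rates typical of random-dot-motion tasks: for
$v = 1$, $t_{er} = 0.3$ and the default timing, the closed-form curve stays
within 0.1% of its peak over a span of about 0.16 in $a$:

```{r flatness}
grid <- seq(0.01, 4, by = 0.01)
rr <- rr_curve_closed_form(grid, v = 1, z_rel = 0.5, ter = 0.3, timing_config())
range(grid[rr > max(rr) * 0.999])
```

At 2000 trials per grid value the Monte-Carlo tilt of that plateau moves the
argmax by about $\pm 0.1$ (standard deviation) even with full common-random-
numbers coupling; agreement with the closed-form argmax to $\pm 0.05$ would
require roughly an order of magnitude more trials. The simulation settings
follow the published procedure, so this residual argmax noise is a property
of the method, not of the implementation; the test suite documents it by
asserting the empirically attainable $\pm 0.25$ band at 2000 trials, and the
acceptance checks report the measured maximum deviation. Downstream this
noise matters little: optimal-threshold *distributions* (one argmax per
posterior draw) average over it.

# Hierarchical estimation by DE-MCMC

Models are estimated hierarchically: individual parameters follow group-level
truncated-normal distributions (normal for $c$), with weakly informative
hyperpriors centred on values typical for random-dot-motion cohorts
(`hyperprior_config()`: group means for $v$, $t_{er}$, $a$ centred at 1.5,
0.3 s and 1.5 with generous SDs; half-normal priors on group SDs; $\Delta_c$
prior SD 0.5). These defaults are package choices standing in for the
original study's unpublished prior settings, and every one is an argument.

Sampling uses differential-evolution MCMC: $3k$ chains for $k$ free
per-individual parameters; each chain proposes
$\theta' = \theta_i + \gamma(\theta_m - \theta_n) + \mathrm{U}(-0.001, 0.001)$
from two other chains' states, with $\gamma = 2.38/\sqrt{2d}$ per block.
Updates are blocked per participant (ascending order, one cached likelihood
evaluation per update) and then for the group-level block; migration (cyclic
state exchange among a random chain subset) runs with probability 0.1 during
burn-in only. Defaults are 4000 iterations with 1000 burn-in. `diagnostics()`
reports split-$\hat R$ (warning above 1.1) and effective sample sizes.
Reference-scale fits in this package's tests use 2000 iterations on cohorts
of 20 participants with 400 analysed trials each, which keeps a three-
replicate recovery study within a practical single-CPU budget while leaving
clear convergence margins; the full 4000-iteration default matches the
published setting.

The sign convention for the two-group comparison: $\Delta_c > 0$ means group
A (the first group) is *closer* to optimality, i.e. group c-means are
$m - \Delta_c/2$ (A) and $m + \Delta_c/2$ (B). The positive-truncation model
is therefore the "A closer" directional hypothesis, matching the
A-vs-Null / B-vs-Null table layout. The three priors are fitted as three
separate models (as in the original analysis), not by reweighting one fit.

# Bayes factors

`savage_dickey_bf()` estimates $BF_{10} = p(\Delta_c = 0) / p(\Delta_c = 0
\mid \mathrm{data})$ with a Gaussian KDE (Silverman bandwidth) for the
posterior density, reflected at the boundary for truncated priors (whose
prior density at 0 is the half-normal value $2\phi(0; 0, \sigma)$). A
moment-based truncated-normal estimator is available as a cross-check
(`estimator = "normal"`). When the estimated posterior density at the point
falls below $10^{-6}$ of the prior density it is floored there with a
warning, capping the Bayes factor rather than returning infinity.
`adjusted_bf()` replaces the density at 0 by the maximum estimated density
within 0.25 prior SDs of 0 (half-width exposed as `neighborhood`), so
adjusted directional Bayes factors can only shrink — the behaviour visible
in published adjusted columns. The A-vs-B comparison is the exact quotient
of the two directional Bayes factors (`transitive_ratio()`), and
`interpret_bf()` applies the conventional 3 / 10 / 100 evidence bands.

# The synthetic-data generator

`generate_experiment()` emulates the structure of the blocked
random-dot-motion experiments: 20 blocks of either 60 s (fixed time) or 40
trials (fixed trial); per-participant parameters drawn from group-level
truncated normals; trial feedback timing from `timing_config()` (0.5 s
feedback, 0.5 s ITI, 1.0 s extra error timeout by default — set `et = 0`
for designs with equal correct/error feedback). Defaults
(`group_spec()`: mean $v = 1.1$, SD 0.25; $t_{er} = 0.35$ s, SD 0.05;
unbiased start; initial threshold 1.4) were chosen once to reproduce
published group descriptives (accuracy near 0.8, median RT near 0.8 s,
25–27 trials per minute) and are not tuned per test. Thresholds can decline
geometrically across blocks toward an asymptote — by default each
participant's own optimal threshold plus a group-level distance
`c_asymptote` — emulating cohorts that approach optimality over practice.
In fixed-time blocks the trial in progress when the budget expires is
completed (the cutoff behaviour is not documented for the original task;
the budget check applies to trial start times, so a block always contains
at least one trial). Anticipatory responses (faster than 250 ms) incur the
1.5-s "Too Fast" pause in the block's wall time; an optional contaminant
process can generate them, and is off by default.

What the generator does *not* emulate: dot-kinematogram stimulus properties,
learning or fatigue dynamics beyond the threshold trajectory, RT contaminant
mixtures beyond the optional anticipatory process, and any dependence of
drift on block. Passing recovery tests on this synthetic structure therefore
demonstrates that the estimation machinery is self-consistent — not that the
model is true of any empirical dataset.

# Preprocessing conventions

Responses faster than 250 ms or slower than 10 s are excluded, with the
boundary values retained (a strict reading of "faster/slower than").
Participants below 60% accuracy are excluded (exactly 60% is retained), as
are fixed-time participants with fewer than 200 total trials; accuracy is
assessed after RT filtering (the ordering is not documented in the original
procedure; filtering first is this package's documented default). Group
summaries report the median RT (the tabulated convention) and compute the
reward rate from the (median RT, accuracy) pair; the simulation-side reward
rate uses mean RT, the convention of the printed formula — both are exposed
via `mrt_type`.

# Numerical choices, in one place

* Series truncation for the Wiener density: error-bound criterion at
  $10^{-7}$.
* Quadrature: Gauss-Legendre, 7 (start point) and 9 (non-decision time)
  nodes; integrands are smooth on these ranges and the normalisation test
  holds to $10^{-3}$.
* Simulator: 10-ms default step, bridge crossing detection, per-trial RNG
  substreams, 10-s censoring; timed-out trials are errors for RR purposes.
* Optimal-threshold grid 0.01–4 by 0.01; ties to the smallest value;
  memoisation quantises $(v, t_{er})$ to 0.01.
* Quantiles everywhere are the linear-interpolation empirical definition
  (R type 7); optimality bands use the 10/20/40/60/80/90% set.
* Degenerate inputs: empty data, non-positive thresholds or SDs, and
  inconsistent non-decision parameters yield `-Inf` log posteriors or
  errors, never silent NaNs; the sampler refuses non-finite initial states
  and surfaces NaN posteriors with the offending state.

# Known limitations

* The Monte-Carlo argmax noise discussed above: at the published simulation
  size (2000 trials), simulated optimal thresholds carry irreducible noise
  of roughly $\pm 0.1$–0.2 where the RR curve is flat.
* The qualitative block-threshold model estimates one threshold per block
  per participant; with the full 20-block design this is a large parameter
  space, and reduced-scale fits (fewer blocks or iterations) are the
  practical default in tests.
* Bayes factors from KDE density ratios are unreliable when the posterior
  sits many SDs from the test point; the capped values (with warnings)
  should be read as "beyond the estimator's range", and the adjusted
  variants as the conservative report.
* The closed-form oracle covers only the no-variability model; full-model
  optimal thresholds rest on the simulation path alone.
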