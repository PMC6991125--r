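---
title: "Modelling batch-culture growth and decline with churchill"
author: "churchill package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling batch-culture growth and decline with churchill}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(churchill)
```

## The model

A batch culture inoculated at low density grows roughly exponentially,
saturates, and then declines as nutrients run out and waste accumulates.
`churchill` describes the natural-log cell density with the
Churchill–Usagi blending of two asymptotic exponentials,

$$\ln N(t) = \left(\frac{1}{K_1}e^{-\lambda_1 t}
  + \frac{1}{K_2}e^{\lambda_2 t}\right)^{-1},$$

a harmonic interpolation between the growth envelope $K_1 e^{\lambda_1 t}$
and the decline envelope $K_2 e^{-\lambda_2 t}$. Useful identities,
all exposed and unit-tested:

* at $t = 0$ the curve equals $K_1 K_2/(K_1+K_2)$, which ties $K_1$ to the
  inoculation density once $K_2$ is known;
* the curve is bounded above by the pointwise minimum of the two
  envelopes and is unimodal, peaking at
  $t^* = \ln(\lambda_1 K_2/\lambda_2 K_1)/(\lambda_1+\lambda_2)$
  (`peak_time()` returns this closed form unclamped — a negative value
  simply means the curve is monotone declining over the observed range);
* as $t \to \infty$ the ln density tends to $0^+$, i.e. the model never
  predicts extinction, only decay towards one cell per unit volume.

The model is phenomenological: $\lambda_1$ and $\lambda_2$ (h⁻¹) are
summary exponents of the log-growth and log-decline phases, not rates of a
mechanistic birth–death process. All four parameters are strictly
positive.

## Fitting

`churchill_fit()` minimises the sum of squared residuals **on the ln-count
scale**, $\sum_i (\ln N_i - \ln N(t_i))^2$, because the model predicts
$\ln N$ directly and counts are analysed ln-transformed throughout.
Numerical choices:

* **Positivity** is enforced by optimising $\log$-parameters, keeping the
  problem smooth and unconstrained rather than box-bounded.
* The solver is Levenberg–Marquardt (`minpack.lm::nls.lm`) with the
  analytic Jacobian derived from the curve gradient
  (`ln_abundance_grad()`), verified against central differences.
* The objective is non-convex, so the fit is **multi-started**: one
  deterministic start from `initial_guess()` plus `restarts - 1` starts
  whose parameters are jittered by factors uniform in $[0.5, 2]$ under a
  fixed seed (`fit_control()`). Fitting is therefore deterministic given
  its options, and never touches the caller's RNG state.
* Convergence uses tight tolerances (relative change of the residual SS
  $< 10^{-10}$, gradient criterion $10^{-8}$, at most 500 iterations);
  parameter estimates are reported to far fewer significant figures than
  this resolves.
* **Degenerate inputs**: rates at or below an identifiability floor of
  $10^{-4}\,\mathrm{h}^{-1}$ — indistinguishable from "no growth/decline"
  over a few-hundred-hour experiment — mark the fit as a boundary case and
  set `converged = FALSE`, so a flat series can never pass as a clean fit.
  Counts of zero or below are rejected outright (the ln transform is
  undefined and no pseudo-count rule is assumed); series shorter than
  `min_obs` (default 5, at least one point per parameter) raise an
  insufficient-data error.

### Starting values

The initial guess exploits the envelope structure rather than generic
heuristics. Over the points from the best 3-point window onward,
$\ln\ln N$ is nearly linear with intercept $\log K_2$ and slope
$-\lambda_2$, so a straight-line fit supplies both decline parameters at
once; this remains accurate when the decline envelope sits well above the
observed peak (large $\lambda_2$), where reading $K_2$ off the peak height
would be off by several-fold. When no decline is observed the rate falls
back to the floor and $K_2$ to the best window mean. $\lambda_1$ comes
from the earliest pre-peak secant of $\ln\ln N$ (least contaminated by the
decline term), and $K_1$ solves the $t=0$ identity. On noise-free series
in the realistic parameter range all four guesses land within a factor of
three of truth, close enough that the first start almost always reaches
the global optimum and the jittered restarts are insurance.

Per-replicate fits are canonical. A pooled all-points fit across
replicates (`churchill_fit_pooled()`) is available for display, but never
feeds inference. Replicates whose fits do not converge are flagged by
`fit_replicates()` with a warning and excluded listwise by the inference
layer — refitting by hand is a deliberate user action, not an automatic
fallback.

## Per-replicate responses

Three responses per replicate feed inference: the two fitted exponents and
`max_abundance()`, the maximal mean over windows of three *consecutive*
timepoints. The window statistic is computed on ln counts
(`type = "mean_ln"`), consistent with every other ln-scale analysis; the
alternative reading — ln of the mean of the raw counts — is exposed as
`type = "ln_mean"` for sensitivity analysis, since the two differ slightly
(by Jensen's inequality) and either is a defensible definition of an
"average peak". Maximum abundance and carrying capacity are treated as the
same quantity. The statistic shifts by exactly $\ln c$ when counts are
scaled by $c$, and appending timepoints below the best window cannot
change it.

## Factorial inference

Per host and per response the model is a **saturated cell-means model**
over inoculum × vitamin: one mean per design cell, a pooled residual
variance $\hat\sigma^2$ with $N - (\text{number of cells})$ degrees of
freedom. This is the simplest linear model that supports every reported
comparison — contrasts conditioned on a vitamin level and contrasts
conditioned on an inoculation state — and on a balanced design its
marginal means coincide with raw cell means, so no estimability questions
arise. The implementation uses the closed forms (cell means, pooled
variance, $t = \Delta/\mathrm{SE}$ with
$\mathrm{SE} = \hat\sigma\sqrt{1/n_A + 1/n_B}$, which also handles the
unbalanced cells left by excluded non-converged fits); the test suite
cross-checks estimates, SEs and adjusted p-values against `lm()` +
`emmeans` as an independent route.

**Multiplicity.** The family for inoculation comparisons is *all pairs
among the six inoculation states within one vitamin level*, adjusted by
the studentized-range (Tukey) correction via `stats::ptukey`; the
inoculum-vs-control table and the inoculum-vs-inoculum table are the two
complementary slices of that one family. A Dunnett-style
"five-vs-control" family would also have been defensible for the control
table; Tukey-within-level was chosen as the single default because one
coherent family covers both tables, and the family definition is exposed
(`adjust = "none"` disables it). Vitamin contrasts condition on an
inoculation state and compare two levels — a family of size one, never
adjusted. Significance defaults to adjusted $p < 0.05$ (`alpha`,
configurable).

**Percent impact.** Effects are reported as
$100\,(\bar x_{\text{eff}} - \bar x_{\text{def}})
/ \tfrac12(\bar x_{\text{eff}} + \bar x_{\text{def}})$ — the difference
relative to the *average* of the two conditions, which is symmetric,
scale-invariant, and bounded by ±200 % for positive responses (all three
responses are positive). Impacts are computed from raw condition means of
the per-replicate estimates, identical to model-adjusted means under
balance. The vitamin table is oriented replete − deficient; inoculation
tables are oriented effector − control. Direction semantics:
increased growth or maximum abundance is *beneficial* and decreased
*detrimental*, while for the decline exponent the signs flip.

## The synthetic generator

`simulate_experiment()` emulates the statistical structure the analysis
assumes, so the full pipeline can be exercised end to end:

* the factorial layout: 3 hosts × 6 inoculation states × 2 vitamin levels
  × 3 replicates (36 combinations, 108 bottles), sampling at 0 h, 24 h,
  then every 60 h to 624 h — a fixed representative grid within the
  "initial count, a count at about one day, then every 2–3 days for 3–4
  weeks" cadence (12 timepoints);
* default truth $K_1 = 1.82$, $K_2 = 14$, $\lambda_1 = 0.018$,
  $\lambda_2 = 0.002$: initial modeled density 5 cells µL⁻¹ (within the
  1–10 cells µL⁻¹ inoculation range), peak near 212 h (inside 200–400 h)
  at ≈ 3.8 × 10³ cells µL⁻¹ — fixture choices representative of diatom
  batch cultures, not estimates of any particular dataset;
* multiplicative mean-one lognormal noise on counts (CV 0.05 — positive
  counts with roughly constant CV, as flow-cytometric counting error
  behaves) and a mean-one lognormal jitter (CV 0.05) on each replicate's
  true parameters, standing in for bottle-to-bottle biological variation;
* treatment effects are *planted* as multiplicative factors on any
  parameter of any subset of cells (`scenario_spec(effects = ...)`), so
  recovery can be checked against closed forms: a $0.6\times$ factor on
  $\lambda_1$ should be reported as
  $100\,(0.6-1)/0.8 = -50\,\%$ growth impact;
* seeding: a single master seed, with each replicate's draws taken from a
  sub-stream derived by a stable hash of its labels — adding, removing or
  renaming one cell never perturbs another cell's data.

What the generator does **not** emulate: mechanistic diatom–bacteria
interactions, vitamin depletion dynamics, free-living bacterial
trajectories, irregular per-replicate sampling times, count censoring or
instrument dropout, and any correlation between replicates beyond shared
truth. Passing tests therefore demonstrate that the estimator and the
inference chain are correct *for data of the assumed form*; they cannot
certify robustness to real-data pathologies such as heteroscedastic
counting error at low densities.

## Problem sizes in the test suite

The suite verifies the closed-form peak time against bracketing plus
derivative bisection on 100 random parameter draws; noise-free
generator→fitter round trips on all 36 design cells (recovery to
$10^{-6}$ relative); median rate-recovery error under 5 % count noise over
200 simulated series (observed ≈ 1 %, asserted < 10 %); type-I error of
the vitamin contrast over 2,000 null simulations with 3 replicates per
cell (asserted within [0.03, 0.07]); and planted-effect recovery through
the full pipeline on a one-host design. These sizes give stable
Monte-Carlo verdicts while keeping the default test run fast.

## Known limitations

* The model cannot represent a lag phase, a shoulder, or secondary
  growth; replicates showing those will fit poorly and should be caught
  by inspecting `summary()` residuals or `plot()`.
* $\lambda_2$ is weakly identified when an experiment ends near the peak;
  the boundary flag marks the extreme case, but shallow declines still
  carry wide standard errors.
* The pooled-variance model assumes homoscedastic responses across cells
  within a host; gross violations (e.g. one treatment collapsing
  entirely) call for a different error model than this package provides.
* With three replicates per cell, the Tukey-adjusted contrasts have
  limited power; the percent-impact point estimates remain unbiased but
  should be read with their adjusted p-values.

```{r example}
spec <- default_design(seed = 1, noise = noise_model(0, 0), replicates = 1)
series <- count_table_series(simulate_experiment(spec))
fit <- churchill_fit(series[[1]])
coef(fit)
peak_time(fit$params)
```
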