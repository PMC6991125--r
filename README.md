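# churchill

Growth-and-decline trajectory analysis for batch cultures.

Batch cultures of microalgae (and of bacteria grown in broth) follow a
characteristic unimodal trajectory: near-exponential growth, a peak, and a
slow decline. Experiments that perturb such cultures — for example
inoculating xenic diatom cultures with individual bacterial strains under
vitamin-replete and vitamin-deficient media — need all three phases
summarised per replicate before treatments can be compared. `churchill`
provides that pipeline for people running factorial batch-culture
experiments with cell-count time series (e.g. flow-cytometric counts):

1. **Curve fitting.** Each replicate's ln-transformed counts are fit by
   nonlinear least squares to the Churchill–Usagi blended-asymptote
   equation

   ln *N*(*t*) = [ (1/*K*₁) e^(−λ₁ t) + (1/*K*₂) e^(λ₂ t) ]⁻¹

   where λ₁ (h⁻¹) is the growth exponent, λ₂ (h⁻¹) the decline exponent,
   and *K*₁, *K*₂ set the initial and peak ln densities. The curve peaks at
   *t*\* = ln(λ₁*K*₂ / λ₂*K*₁) / (λ₁ + λ₂).

2. **Per-replicate responses.** The growth exponent, the decline exponent,
   and the maximum abundance — defined as the best mean of three
   consecutive ln counts, a data statistic rather than a fit output.

3. **Factorial inference.** Per host and response, a saturated cell-means
   linear model (inoculum × vitamin), estimated marginal means,
   Tukey-adjusted pairwise contrasts within each vitamin level, unadjusted
   vitamin contrasts within each inoculation state, and the percent-impact
   metric 100 (x̄_eff − x̄_def) / [(x̄_eff + x̄_def)/2], classified as
   beneficial or detrimental (faster decline is harm, everything else
   follows the sign).

A seeded synthetic-experiment generator reproduces the 3-host × 6-inoculum
× 2-vitamin × 3-replicate design with multiplicative lognormal count noise,
so the whole pipeline is testable without any external data.

## Worked example

```r
library(churchill)

spec   <- default_design(seed = 2024)        # the factorial design
counts <- simulate_experiment(spec)           # tidy count table, 1296 rows
series <- count_table_series(counts)

fit <- churchill_fit(series[["Chaetoceros sp. KBDT32.control.replete.1"]])
summary(fit)
#> Churchill-Usagi growth-and-decline fit
#> Series: Chaetoceros sp. KBDT32 / control / replete / 1
#>
#>         Estimate Std. Error
#> K1        2.0714     0.0391
#> K2       14.6796     0.1871
#> lambda1   0.0166     0.0003
#> lambda2   0.0020     0.0000
#>
#> Residual SS 0.01841 (ln scale), residual SD 0.04797 on 8 df
#> Peak ln abundance at 218.6 h; ln abundance at t=0: 1.815
```

The replicate grew at 0.0166 h⁻¹, peaked around 219 h, and declined at
0.0020 h⁻¹; the ln density at inoculation (1.815, i.e. ~6 cells µL⁻¹) and
the residual SD of 0.048 on the ln scale say the curve tracks the counts to
within ~5%.

```r
params <- fit_replicates(series)              # 108 rows, one per replicate
tabs   <- build_impact_tables(params, alpha = 0.05)
tabs
#> Impact tables (alpha = 0.05)
#>
#> Inoculation vs control (within vitamin level): 0 significant of 90 comparisons
#> ...
```

This scenario plants no treatment effects, so inoculation-vs-control finds
nothing — only the chance-level scatter expected among the 180
inoculum-pair and 54 vitamin comparisons. Planting an effect (see
`scenario_spec(effects = ...)`) makes the corresponding row appear with its
percent impact and adjusted p-value. `plot(fit)` draws counts and curve;
`write_parameter_table()` / `write_report_tables()` serialise the results.

A shell entry point covering simulate → fit → compare → report is installed
at `system.file("scripts", "growthpipe", package = "churchill")`:

```sh
Rscript inst/scripts/growthpipe all --seed 31 --out-dir runs/demo
```

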