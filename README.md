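# shoretrends

Detection and attribution of biodiversity change in long-term, multi-
investigator rocky-shore surveys.

The package implements the analysis chain for a nine-decade intertidal
census of the kind run at Hopkins Marine Station (central California): a
1931–1933 baseline plus 17 recent site-years (1993–2023) of complete
invertebrate counts in the same 19 permanent quadrats, spanning five
investigator eras. It is written for ecologists analysing comparable
long-term monitoring data: tabular records in, tidy tibbles out, with the
pipe all the way through.

## What it computes

**Coverage-standardized Hill diversity.** Samples of unequal effort are
compared at equal *sample coverage* (the probability that the next
individual belongs to an already-seen taxon), estimated from singleton and
doubleton counts. Hill numbers ᵠD give diversity in effective taxa:
richness (q = 0), Hill-Shannon (q = 1, common taxa), Hill-Simpson (q = 2,
dominant taxa), plus evenness E = (¹D − 1)/(⁰D − 1). Rarefaction is exact
hypergeometric expectation; extrapolation uses the standard
singleton/doubleton asymptotics, capped at 2n for richness.

**Bayesian trend and attribution models.** Four Normal-likelihood models,
fit by built-in Gibbs/slice samplers (4 chains × 3,000 iterations by
default, rank-normalized split R̂ and effective-sample-size diagnostics):

1. *Trend + era*: y ~ N(α_era + β_year · year_decades, σ) — the total
   effect of year, with investigator era as an index effect.
2. *Linear attribution*: adds β_temp · SST_p90; year is included because it
   is a common cause (fork) of temperature and diversity. A *naive*
   temperature-only variant is kept as the confounded negative control.
3. *GP attribution*: replaces the linear year term with a squared-
   exponential Gaussian process over year, absorbing smooth autocorrelated
   confounds.
4. *Range contrast*: a measurement-error hierarchical model on per-taxon
   mean log response ratios, estimating Δ = α_southern − α_coastwide.

The temperature covariate is the 90th percentile of daily SST over the 365
days before each survey (`max_sst_p90()`).

**Evidence grading.** Posterior sign probabilities map to strong / moderate
/ weak / none at 95/90/80%; interval comparisons use disjoint 95% (strong)
and 80% (weak) credible intervals; change against the unreplicated 1930s
baseline is declared strong when no recent-year 95% predictive interval
envelopes the baseline.

**Population change.** Per-taxon log response ratios
ln[(n_year + 1)/(n_baseline + 1)] against the pooled baseline, an inclusion
filter (≥ 20 individuals, ≥ 5 plots), and geographic range classes split at
Cape Mendocino (40.44°N) and Point Conception (34.45°N).

**Synthetic data.** `generate_community()` produces raw survey databases
with the statistical structure the analysis assumes — lognormal abundances,
range-class trends, a dominance-mediated temperature effect, era- and
mobility-specific detection effort, negative-binomial counts, taxonomy
quirks — together with the full latent truth, so every stage is testable
without the archived dataset.

## Worked example

Generate a synthetic database, run the full pipeline, and read the results:

```r
library(shoretrends)

cfg <- sim_config(seed = 11)
sim <- generate_community(cfg)

res <- run_analysis(
  records = sim$records, crosswalk = sim$crosswalk,
  traits = sim$traits, temperature = sim$temperature,
  metrics = c("q0", "q1", "q2", "evenness"),
  models = c("trend", "temp_naive", "temp_linear", "lrr"),
  n_boot = 0, seed = 5,
  mcmc = mcmc_control(n_chains = 2, n_iter = 1000, n_warmup = 500, seed = 5)
)

res$evidence$trend
#> # A tibble: 4 × 6
#>   metric   direction p_sign slope_grade baseline_strong_change transition_year
#>   <chr>    <chr>      <dbl> <chr>       <lgl>                            <dbl>
#> 1 q0       negative   0.722 none        FALSE                               NA
#> 2 q1       negative   0.902 moderate    TRUE                              1993
#> 3 q2       negative   0.946 moderate    TRUE                              1993
#> 4 evenness negative   0.94  moderate    TRUE                              1993

tidy(res$fits$trend)[5, 1:5]
#> # A tibble: 1 × 5
#>   term      estimate std.error conf.low conf.high
#>   <chr>        <dbl>     <dbl>    <dbl>     <dbl>
#> 1 beta_year    -1.00     0.804    -2.61     0.536

res$evidence$temp_linear
#> # A tibble: 1 × 3
#>   subject               p_negative grade
#>   <chr>                      <dbl> <chr>
#> 1 temp_linear:beta_temp      0.961 strong
```

Read: in this synthetic world (southern taxa rising, coastwide falling, a
warming-linked dominance tilt, one low-effort era), richness shows no trend
and no departure from the 1930s baseline, while Hill-Shannon, Hill-Simpson
and evenness all decline moderately (90–95% posterior probability of a
negative decadal slope) and every recent year's 95% predictive interval
excludes the baseline — strong evidence of change, from 1993 onward. The
year-adjusted temperature model grades the warming effect on Hill-Shannon
as strong (96.1% probability of a negative slope). `res$evidence$temp_naive`
vs `res$evidence$temp_linear` contrasts the confounded and adjusted
estimates; `res$lrr` holds the per-taxon log response ratios;
`res$manifest$stages` logs record counts through every filter stage.

`autoplot(res$diversity)`, `autoplot(res$fits$trend)` and
`plot_lrr(res$lrr)` draw the standard figures; `tidy()` / `glance()` work
on every fitted model.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates a synthetic database from the stated study structure, runs the
complete pipeline at the full sampler protocol (all four models, including
the doubled-iteration GP fit), and writes the machine-readable result
summary to `--out`. The seed controls every stochastic stage, so reruns are
bit-reproducible.
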