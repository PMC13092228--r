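---
title: "Methods: detecting and attributing biodiversity change in a multi-investigator rocky-shore survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and attributing biodiversity change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A rocky intertidal transect at Hopkins Marine Station (central California)
has been censused since 1931–1933 across five investigator eras: a pooled
historical baseline, then 17 recent site-years (1993–2023) in four eras, each
pooling the same 19 permanent quadrats. Counting every macroscopic
invertebrate in fixed quadrats over nine decades gives an unusually direct
record of biodiversity change, but also three entangled inferential problems:

1. **Detection.** Has diversity changed over the recent three decades, and
   relative to the 1930s baseline, given that each investigator team counts
   with different effort and skill?
2. **Attribution.** Is the change caused by warming seawater, given that
   temperature and everything else trend with year?
3. **Composition.** Which taxa drive the change, and does a taxon's
   geographic range predict its trajectory?

`shoretrends` implements the full analysis chain for data of this shape:
tabular survey records in, tibbles of standardized diversity estimates,
posterior summaries, and evidence grades out.

## Data processing

Raw records (`load_survey_records()`) carry either an integer count or one of
the historical qualitative codes ("abundant", "common", "occasional",
"rare"), never both. Taxon names are harmonized to current usage through an
explicit crosswalk (`harmonize_taxonomy()`); the mapping is many-to-one and
deterministic, so synonym counts pool downstream. Four removal rules prepare
the counted dataset (`apply_quantitative_filters()`), in this order:
qualitative-only taxa, epibionts not assessed in the baseline, records above
genus level, and genus-level records where two or more congeneric species
were counted anywhere in the dataset (counting both a genus and its species
would inflate richness). The genus rule is evaluated dataset-wide rather than
per era: a name comfortable at species level in one era but genus level in
another is the same taxonomic concept throughout. Taxa first counted after
the baseline are reconciled against the baseline's full species list: absent
taxa become true zeros, present-but-unquantified taxa enter a presence-only
registry — they cannot enter count-based estimators, and treating them as
zeros would manufacture false increases.

The filter order follows the order the rules are stated in the survey's own
processing description; because the rules touch disjoint record sets
(qualitative, epibiont, above-genus, genus-with-congeners), the composition
is order-stable and idempotent, which the test suite checks directly.

Counts are pooled over the fixed quadrat set per site-year
(`pool_site_year_matrix()`); duplicate (year, quadrat, taxon) entries are a
hard error by default because silent summation hides double data entry.
Densities per square metre (`summarize_density_by_era()`) use a quadrat area
of 0.8361 m² — the original quadrats are square yards.

## Coverage-standardized Hill diversity

The number of individuals counted per site-year varies several-fold across
eras, so raw diversity indices confound community change with effort. All
estimates are therefore standardized to equal *sample coverage* — the
probability that the next individual drawn belongs to an already-observed
taxon — rather than equal counts. For a sample with `n` individuals, `f1`
singletons and `f2` doubletons,

    C = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2)).

Hill numbers `D(q)` express diversity in effective taxa at sensitivity order
`q`: richness (`q = 0`), Hill-Shannon (`q = 1`, common taxa), Hill-Simpson
(`q = 2`, dominant taxa). `estimate_at_coverage()` inverts the coverage
curve to the sample size `m*` that attains the target coverage,
interpolating by exact hypergeometric expectation below the reference sample
and extrapolating through the singleton/doubleton asymptotics above it.
Numerical choices, fixed here and covered by oracle tests:

* Rarefaction uses exact combinatorics in log space (`lchoose`), valid for
  real-valued `m`; for `n <= 12` it agrees with exhaustive subsample
  enumeration to 1e-9, and with 50,000-draw Monte Carlo subsampling within
  three Monte-Carlo standard errors for larger `n`.
* `q = 1` interpolation is the expected plug-in Shannon entropy of the
  subsample; `q = 1` extrapolation blends observed entropy with the
  asymptotic (Chao–Wang–Jost-type) entropy estimator in proportion `n/m` vs
  `m*/m`. `q = 2` has a single closed form valid on both sides of `n`.
* Richness extrapolation is capped at twice the reference sample size; the
  estimator is unreliable beyond, and a target needing more is an error, not
  a number. Orders 1 and 2 may extrapolate to their asymptote.
* When `f2 = 0` the coverage-extrapolation coefficient substitutes
  `(f1 - 1)` for `f1` (the standard fallback); the reference-sample coverage
  estimate itself keeps the primary formula, with the convention that a
  degenerate denominator (single singleton) yields coverage 0.
* The common target for a series is the minimum, across site-years, of the
  coverage attained at twice each year's sample size — the convention of the
  coverage-standardization literature; a fixed target can be supplied.
* Bootstrap CIs resample a coverage-adjusted community (observed relative
  abundances shrunk to estimated coverage, plus Chao-estimated unseen taxa
  sharing the deficit), 200 multinomial replicates by default, percentile
  intervals. Identical seeds give identical intervals.
* Undefined quantities (empty year, fewer than two taxa for evenness)
  propagate as `NA`, never as zero: a missing community is not a depauperate
  one.

Evenness separates relative-abundance structure from richness. The survey
literature it follows cites evenness without printing a formula, so the
definition is configurable: the default `formula_id = "hill_ratio"` is
`(D1 - 1)/(D0 - 1)`, zero for complete dominance and one for perfect
evenness; `"log_ratio"` (`ln D1 / ln D0`) is provided as the main published
alternative. Standardized evenness is assembled from the coverage-
standardized `D0` and `D1`.

## The temperature covariate

Attribution uses maximum, not mean, temperature: ecological damage on the
shore tracks extremes. `max_sst_p90()` reduces the daily SST series to the
empirical 90th percentile over the 365-day window ending the day before the
survey reference date, so the hypothesized cause strictly precedes the
effect. The quantile convention (linear interpolation, R type 7) and window
bounds are recorded in the output, making the covariate bit-reproducible;
the source series never states its own convention, so ours is explicit.
When the survey day within a year is unknown the window falls back to the
prior calendar year. Windows with fewer than 200 daily observations yield a
missing covariate with a warning — a percentile over a sparse, hand-collected
series is misleading — and such years are dropped from attribution fits with
a log note.

## The causal structure and the four models

The analysis follows a directed acyclic graph: year influences diversity
both directly (drift and unmeasured drivers) and through temperature;
investigator era affects only the *measurement* of diversity. Two
consequences structure the models:

* To estimate the **total effect of year**, temperature must be *excluded* —
  it is a mediator (pipe) on one of year's causal paths.
* To estimate the **effect of temperature**, year must be *included* — it is
  a common cause (fork) of temperature and diversity, i.e. a confound.

All models are Normal-likelihood Bayesian regressions.

**Model 1 (trend + era).** `y ~ N(alpha_era + beta_year * year_c, sigma)`
with year centered and scaled to decades. Era is an index variable — one
intercept per era, no reference level — because eras are ordered in time and
none is a natural control.

**Model 2 (linear attribution).** Adds centered temperature:
`mu = alpha_era + beta_temp * t_c + beta_year * year_c`. The *naive* variant
(temperature only) is retained deliberately as the negative control: its
coefficient is confounded by anything trending with year, and the synthetic
causal-signature test shows its intervals undercover zero while Model 2's
are near nominal.

**Model 3 (Gaussian-process attribution).**
`y_i ~ N(alpha + beta_temp * t_c + f(year_i), sigma)` with a squared-
exponential GP over year, `K_ij = eta^2 exp(-d_ij^2 / (2 ell^2))` plus
diagonal jitter. The GP absorbs smooth, autocorrelated confounds — the
non-linear generalization of conditioning on year. The latent `f` is
marginalized during sampling (the marginal likelihood is multivariate
normal) and drawn per retained iteration afterwards. Era intercepts are
excluded by default: the GP over year can absorb era-block shifts, and with
17 observations the extra intercepts mostly trade off against `f`. This is a
package design choice, exposed as `include_era`, and the implementation
claims no more than "non-linear and autocorrelated confounds with year" for
this model.

**Model 4 (measurement-error contrast).** Each taxon's mean log response
ratio is an error-prone observation of a latent true change:
`obs_i ~ N(theta_i, se_i)`, `theta_i ~ N(alpha_class, sigma_theta)`; the
estimand is `delta = alpha_southern - alpha_coastwide`. Observed standard
errors are floored at 1e-3 (configurable): a taxon observed identically in
every year has `se = 0`, which would make its latent state a delta function.

**Priors.** The survey protocol this package follows states only "weakly
informative normal priors", so the defaults are data-scaled and exposed in
full:
`alpha ~ N(mean(y), 2 sd(y))`, `beta_year ~ N(0, 2 sd(y))` per decade,
`beta_temp ~ N(0, 2 sd(y)/sd(t))`, `sigma ~ Exponential(1/sd(y))`,
`eta ~ half-N(0, sd(y))`, and a lognormal length-scale prior centered near 8
years with 2.5–97.5% mass roughly spanning 2–30 years.
`prior_predictive_trend()` implements the protocol's prior-predictive check.

**Sampling.** No Stan-family sampler is available in the supported
environment, and these four models are small and largely conjugate, so the
samplers are written in R: conjugate multivariate-normal Gibbs updates for
all regression coefficients and latent states, univariate slice sampling
(stepping-out) for scale and GP hyperparameters on the log scale. Defaults
mirror the survey protocol — 4 chains × 3,000 iterations, half warm-up
(6,000 retained), doubled for the GP model, 2,000 iterations for Model 4.
Convergence is judged by rank-normalized split-chain R-hat < 1.05 (strict)
and effective sample size > 1,000 (`mcmc_diagnostics()`); fits that fail are
flagged, never silently accepted. For deliberately scaled-down runs the
fit-time flag caps the ESS bar at a quarter of the retained draws so that it
detects poor mixing rather than small sample size; `mcmc_diagnostics()`
called directly always applies the full-protocol thresholds. Identical seeds
reproduce draws exactly. Calibration is tested three ways: simulation-based
calibration ranks for the fast models, parameter recovery
(bias and CI coverage) for all four, and the naive-vs-adjusted causal
signature for the attribution pair.

## The language of evidence

Results are graded, not thresholded at 0.05. For slopes, the posterior
probability of the estimated sign maps to strong (≥ 0.95), moderate
(≥ 0.90), weak (≥ 0.80), or none. For comparisons, disjoint 95% credible
intervals are strong evidence and disjoint 80% intervals weak evidence.
Change relative to the unreplicated 1930s baseline uses the predictive
envelope: strong change is declared when no recent-year 95% posterior-
predictive interval contains the baseline value; interval bounds count as
containment (closed intervals, conservative toward "no change"), and the
first year after which containment never recurs is reported.
`count_strong_changes()` tallies taxa whose LRR confidence interval excludes
zero; because published tables round bounds to one decimal, it always
reports both the strict convention and a rounding-aware one (a printed bound
of exactly 0.0 treated as rounded away from zero). The two conventions can
disagree — on the published 48-taxon table they give 41 and 44 strong
changes respectively — and the package reports both rather than adjudicating.

## Population change and geographic range

Per-taxon change is the log response ratio
`ln((n_year + 1)/(n_baseline + 1))` of pooled site-level totals against the
pooled 1931–1933 baseline, averaged over the 17 recent years. Taxa with
fewer than 20 individuals overall or present in fewer than five plots are
excluded (both bounds inclusive). The CI of the mean is the normal
approximation by default — the survey protocol states "95% confidence
interval" without a method — with a bootstrap alternative. Range classes use
two biogeographic breakpoints, Cape Mendocino (40.44°N) and Point Conception
(34.45°N): the classification rule names the capes, the coordinates are
fixed here and configurable. Northern limit south of Cape Mendocino → southern;
southern limit north of Point Conception → northern; extending beyond both →
coastwide; otherwise uncertain, and uncertain taxa are excluded from the
Model 4 contrast but retained, flagged, in every output.

## What the synthetic generator states, and what a green test means

`generate_community()` inverts the analysis assumptions into a generator so
every stage is testable without the archived data. Its defaults are a stated
world, chosen once:

* 19 quadrats; baseline year plus 17 recent site-years in the four recent
  eras (1993, 1994, 1996 for the first recent era, then the six documented
  resurvey years of 1999–2015, then annual).
* A lognormal abundance distribution (`meanlog = log 10`, `sdlog = 1.5`,
  120-taxon pool), giving a few thousand individuals per site-year with
  strong dominance — the shape, though not the absolute scale, of the real
  transect, kept at desk scale so the full pipeline runs in seconds.
* Range-class trends of ±0.15 log units per decade (southern up, coastwide
  down), which over nine decades produces log response ratios of the
  magnitude the published table prints.
* Temperature acts on *dominance*: each taxon's log abundance gains
  `beta_temp_true * z_i` per °C, `z_i` its standardized log baseline
  abundance. Warm years therefore tilt abundance toward dominants, lowering
  Hill-Shannon and evenness at fixed richness — matching an estimand in
  common-taxa units — and the induced diversity-scale effect is computable
  from the latent truth.
* A lognormal abundance offset of +2 log-units for sessile taxa, with 70%
  of the pool mobile: sessile taxa on this shore are few but enormously
  abundant (barnacle-style recruitment pulses) while mobile taxa form the
  speciose tail. Without this structure, mobility-specific effort tilts the
  dominance hierarchy and moves Hill-Simpson — the opposite of the observed
  artifact.
* Era effort has two observer-error components, both mobile-specific and
  both coupled through shared uniforms so that lowering effort can never
  raise a count: (i) binomial *count thinning* (detection 0.3 in 1999–2015,
  1 elsewhere), and (ii) whole-species *overlooking*, where a mobile
  species with thinned site total `N` is dropped entirely with probability
  `exp(-N/30)` in the low-effort era. The distinction matters: random
  thinning alone produces an effort artifact that coverage standardization
  corrects — as it is designed to — so a richness dip that survives
  standardization, as observed, requires the species-level overlooking that
  field observers actually commit. Neither component touches latent
  diversity.
* Daily SST: seasonal sinusoid (amplitude 1.5 °C around 12.5 °C) plus a
  0.01 °C/yr trend and 0.5 °C daily noise, so the annual 90th percentile
  warms ~0.3 °C over 30 years.
* Quadrat-level counts are negative binomial (`size = 1`), not Poisson:
  barnacle-style clumping is the norm on this shore.
* Taxonomy quirks — historical synonyms (10% of taxa), qualitative-only
  records (3%), genus-level records in 2020+ (3%) — are injected and
  labelled, so filter-report counts can be matched exactly against the
  injection bookkeeping.

The generator returns the full latent truth. Recovery estimands are defined
on that truth: the latent Hill-Shannon series (from expected abundances) and
its least-squares year and temperature coefficients, and the latent
southern-minus-coastwide mean LRR. `recovery_suite()` runs the entire
pipeline per replicate and reports bias, RMSE and CI coverage against these
estimands, excluding and counting replicates with failed diagnostics.

What a green suite does establish: the estimators match independent oracles;
the samplers are calibrated on data generated from their own models; the
naive/adjusted contrast shows the causal signature the DAG predicts; the
pipeline reproduces the qualitative era artifact; and the whole chain is
deterministic under a seed. What it does not establish: that the real
transect's numbers are reproduced (the archived data are not an input), that
the generator's SAD or effort values equal the real ones, or that the GP
model matches the original Model 3 beyond its stated role of absorbing
smooth year-confounds.

## Known limitations

* Hill-Shannon interpolation costs O(S · max count) per evaluation; with
  heavy bootstrapping on large communities this is the slow path.
* The evenness CI is derived from the standardized `D1` interval holding
  `D0` at its point estimate, ignoring their dependence; it is labelled as
  such and not used for any evidence grade.
* The baseline is a single pooled survey: baseline-relative statements lean
  on the predictive-envelope construction, not on replication.
* Era and year are partially collinear in Model 1 by design; the joint
  year+era posterior is the estimand, and single-coefficient summaries
  should be read accordingly.
* `posterior_predict()` covers the linear models; GP prediction off the
  observed year grid is out of scope.
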