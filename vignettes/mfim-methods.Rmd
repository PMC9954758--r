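---
title: "Multifactor interaction models of reading: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifactor interaction models of reading: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfim)
```

## The model

Developmental dyslexia is increasingly described by multifactor accounts:
no single cognitive deficit explains the disorder; instead, many functions
(phonological awareness, rapid naming, visual search, memory, general
intelligence, ...) each contribute a small share to the efficiency of
reading. `mfim` implements the *interactive* version of that idea as a
testable statistical pipeline.

The generative hypothesis is a threshold law. Let $f_1, \dots, f_k$ be a
child's z-scored cognitive functions and $w_i \ge 0$ their weights. The
aggregate efficiency index is

$$ M = \sum_i w_i f_i, $$

and latent reading ability is

$$ r = M + \gamma \, \min(0,\, M - \tau) + \varepsilon, $$

i.e. reading tracks aggregate efficiency while $M$ clears the threshold
$\tau$, but once the aggregate falls short, the shortfall is amplified by
the factor $1 + \gamma$. The hinge is the minimal functional form
expressing "difficulty proportional to the gap below threshold"; smooth
alternatives would add parameters the data cannot separate at clinical
sample sizes, so they are out of scope here.

The law's testable signature does not require observing $\tau$ or
$\gamma$. If the impact of one function depends on the collective state of
the others, then in the regression

$$ y = b_0 + b_1 x + b_2 \cdot \mathrm{OF} + b_3\,(x \cdot \mathrm{OF}) +
\varepsilon $$

the interaction coefficient $b_3$ must be **negative**: the lower the
"other factors" index OF, the steeper the effect of the singled-out
predictor $x$. All inference on $b_3$ is therefore one-tailed in the
negative direction by default (`direction = "negative"`, with an explicit
flag to flip it for other designs).

## Pipeline stages and their parameters

**Composites** (`composite_score`). Reading accuracy and speed are each
the arithmetic mean of three component z-scores (text, word, nonword
reading); memory averages forward and backward letter span. A composite is
missing whenever any component is missing — complete-case selection
happens once, at the model-fitting stage, not silently earlier.

**Screening** (`screen_predictors`). A candidate predictor enters the
analysis only if its Pearson correlation with *both* reading outcomes is
non-negative (all measures are oriented so higher z = better performance;
the package does not re-orient). Within a declared group of alternative
measures for one construct, the measure maximizing the summed correlation
is kept. Exact ties are reported unresolved rather than broken by an
arbitrary rule, because the choice affects every downstream index.

**Weights** (`of_weights`). The index weights are plain Pearson
correlations of each predictor with the targeted reading outcome, computed
on the *weighting sample* — deliberately a separate argument from the
analysis sample, because a retrospective database typically supports
correlation estimation on far more children (pairwise-complete, here) than
the complete-case subset the models are fitted on. Weights are not
renormalized to sum to one; the index is a weighted sum, and any common
rescaling would only rescale $b_2$ and $b_3$ without changing t statistics.
Separate weight vectors are computed per outcome.

**OF index** (`of_index`). For the singled-out predictor $x$,
$\mathrm{OF} = \sum_{j \ne x} w_j z_j$; with no predictor singled out the
same function returns the full multifactor index for descriptive use. The
index is missing for a child missing any contributor.

**Interaction fit** (`fit_interaction`). Ordinary least squares on the
complete cases over $\{y, x, \mathrm{OF}\}$, with standard errors from the
unbiased residual variance and the inverse cross-product matrix. Residual
degrees of freedom follow the $n - 4$ convention (intercept plus three
slopes); with $n = 55$ complete cases this gives the $t(51)$ reference
distribution. Variables are not mean-centered before forming the product:
the inputs are z-scores (or weighted sums of z-scores) already, and
interpretation at fixed moderator levels is delegated to `simple_slopes`,
which evaluates the OF-slope and intercept at the predictor's mean and
±1 SD. No multiple-comparison correction is applied anywhere, because the
negative interaction is predicted in *every* test rather than in at least
one; the report records this policy in its metadata.

**Bayes factors** (`adjust_se`, `bf_uniform`, `classify_evidence`). The
evidence for the directional alternative uses a normal likelihood centered
at the estimate, with the standard error first inflated by
$1 + 20/\mathrm{df}^2$ — the published small-sample correction for
approximating a t likelihood by a normal, equal to 1.008 at df = 51. H1
places a uniform prior on a negative interval $[\ell, 0]$; H0 is the point
null at zero. The Bayes factor has the exact closed form

$$ BF_{10} = \frac{\frac{1}{u-\ell}\left[\Phi\!\left(\tfrac{u-\hat b}{s}\right)
 - \Phi\!\left(\tfrac{\ell-\hat b}{s}\right)\right]}{\phi(\hat b;\,0,\,s)}, $$

verified in the test suite against adaptive quadrature of the defining
integral to a relative $10^{-8}$. Prior intervals are **required inputs**
per analysis row: they encode substantive expectations about plausible
effect sizes and the package does not derive them. Evidence categories
follow the conventional bands ($<1/3$ null, $[1/3,3]$ inconclusive,
$(3,10]$ moderate, $(10,30]$ strong), with a `very_strong` band above 30
added for completeness beyond the usual convention.

## The synthetic cohort generator

Because clinical child-level data of this kind are access-restricted,
every pipeline stage is validated against `simulate_cohort`, which
generates cohorts with the statistical structure the analysis assumes:

1. `sample_factors` — zero-mean multivariate normal cognitive z-scores
   with a configurable correlation matrix;
2. `reading_from_factors` — the threshold law above, observed through
   three noisy components per outcome dimension;
3. `apply_diagnosis_filter` — clinical ascertainment: a child is retained
   only if at least one reading component z-score is ≤ −2;
4. `inject_missingness` — a random subset of children keeps all
   predictors; the rest lose a random nonempty predictor subset
   (missing completely at random; reading columns are never deleted).

Defaults are chosen to be *illustrative of a referred clinical cohort*,
not estimates of any study population: 266 children sampled, 55 left
complete; exchangeable factor correlation 0.3 (all five measures correlate
positively with reading and with each other); generative weights 0.35
(phonological awareness), 0.30 (RAN speed), 0.25 (visual search speed),
0.20 (IQ), 0.20 (memory), mirroring the field's ranking of how often each
function appears as a "core deficit"; $\tau = 0.5$ and $\gamma = 1.5$, so
most referred children sit below the efficiency threshold and the
below-threshold shortfall is amplified 2.5-fold; latent noise SD 0.5 and
per-component measurement noise SD 0.3. At these values the ascertainment
step retains roughly 35–40% of sampled children, so a 266-child draw
comfortably supports the 55-complete-case structure. Setting $\gamma = 0$
recovers a purely additive model, which is the null configuration used for
calibration.

All randomness flows from one integer seed through named substreams
(factors, reading noise, component noise, missingness), so each stage is
individually reproducible and regenerating with the same configuration is
bit-identical.

What the generator does *not* emulate: test-battery-era missingness (the
real mechanism is systematic by assessment period, not MCAR — no data
exist to model it), non-normal score distributions, floor effects in
severely impaired readers, age structure, and comorbidity. Passing tests
therefore demonstrate that the pipeline recovers the structure it assumes,
not that real reading data satisfy those assumptions.

## Statistical guarantees checked by the test suite

- **Exactness of the fit.** Coefficients and standard errors match an
  explicit normal-equations solve to $10^{-10}$ on fixed tables, and
  noiseless interactive data are interpolated exactly.
- **Null calibration.** With $\gamma = 0$, weights estimated per cohort,
  and no ascertainment, the one-tailed interaction test's rejection rate
  over 1,000 simulated cohorts of n = 500 lies inside the binomial 99%
  band around 0.05, and the p values are near-uniform
  (Kolmogorov–Smirnov distance < 0.05). Under multivariate-normal factors
  the conditional mean of reading given $(x, \mathrm{OF})$ is exactly
  linear, so the null t statistic is exactly $t_{n-4}$ up to the
  (vanishing) effect of estimating the weights on the same cohort.
- **Sign recovery under amplification.** With $\gamma = 1.5$ at n = 500,
  the mean fitted interaction coefficient is negative over 200 replicates
  and the rejection rate clearly exceeds the null rate. Only the *sign*
  is asserted: ascertainment on poor reading distorts effect magnitudes
  relative to the population, so recovering $\gamma$ itself is not a
  supported claim. A large-sample (n = 50,000) population check confirms
  the negative interaction coefficient by brute-force regression.
- **Determinism.** Simulating and analysing with a fixed seed renders
  byte-identical report files across runs.

The problem sizes above (1,000 × 500 for calibration, 200 × 500 for
power, 50,000 for the population check) were chosen as the smallest scales
at which the binomial and Kolmogorov–Smirnov bounds are informative.

## Known limitations

- Weights are correlations estimated with error; the pipeline propagates
  no weight uncertainty into the interaction SEs (matching standard
  practice for composite indices, but a caveat for small weighting
  samples).
- The one printed-precision subtlety a user should know: feeding rounded
  estimates and SEs through `one_tailed_t` can land a p value on the
  wrong side of a 3-decimal rounding boundary relative to values computed
  from unrounded inputs.
- Uniform priors only; half-normal or default Bayes-factor machinery is
  deliberately out of scope.
- The hinge threshold law treats $\tau$ and $\gamma$ as fixed population
  constants, whereas the motivating theory describes a fluid,
  within-reader quantity; the simulator operationalizes the average.

## A minimal worked run

```{r}
coh <- simulate_cohort(cohort_config(seed = 7))
coh

cc <- na.omit(coh$table)
priors <- expand.grid(outcome = c("reading_accuracy", "reading_speed"),
                      predictor = coh$config$factor_names,
                      stringsAsFactors = FALSE)
priors$lower <- -0.8
priors$upper <- 0

res <- mfi_analysis(coh$table, cc,
                    predictors = coh$config$factor_names,
                    outcomes = c("reading_accuracy", "reading_speed"),
                    priors = priors)
res
```

Note the attenuation: the cohort was ascertained on poor reading, so
fitted interaction estimates are much smaller in magnitude than the
generative amplification would suggest — the expected behaviour, and the
reason magnitude recovery is not among the package's claims.
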