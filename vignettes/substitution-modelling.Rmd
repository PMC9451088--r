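---
title: "Modelling time-use reallocations and health: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling time-use reallocations and health: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timeswap)
```

## The problem

How a day is divided between sleep, screen time, physical activity, quiet
time, passive transport, school-related activities and domestic/self-care is
associated with children's body composition, psychosocial wellbeing and
academic performance. Because the seven durations always sum to 24 hours,
they cannot be analysed as free covariates: increasing one activity
necessarily decreases others, and the parts carry only relative
information. `timeswap` implements the compositional approach to this
problem: model the outcome on an unconstrained log-ratio representation of
the composition, then translate fitted models into the practically
interpretable question "if a person moved X minutes from activity A to
activity B, how would the expected outcome differ?" — an isotemporal
substitution estimate, with a 95% confidence interval, from any starting
composition the user chooses.

## The model

**Coordinates.** A strictly positive 7-part composition is mapped to six
isometric log-ratio (ilr) coordinates. For a sequential binary partition
whose row k splits a group into r parts (+1) and s parts (−1),

z_k = sqrt(rs / (r + s)) · ln( g(+group) / g(−group) ),

with g(·) the geometric mean. The default basis is the pivot-coordinate
partition in the fixed part order above. The choice of partition is
mathematically immaterial here: any two valid partitions are related by a
rotation of the coordinates, the second-order polynomial model span is
rotation-invariant, and therefore fitted values, F statistics and all
substitution estimates are identical across bases (this is property-tested
to 1e-9). The partition used at fit time is serialized inside every model
artifact so that predictions are always made in the fitting basis.

**Regression.** For each outcome, ordinary least squares on a 35-column
design: intercept; the six ilr coordinates; their six squares and fifteen
pairwise products (27 composition-derived columns capturing non-linearity
and interaction on the simplex); and seven covariate columns (female
indicator, age in years, socioeconomic z-score, and four pubertal-status
indicators against the pre-pubertal reference). Body fat percentage is
ln-transformed before fitting to normalize its right-skewed residuals;
the other outcomes are modelled on their natural scale. Complete cases
only; the residual degrees of freedom are n − 35. The joint contribution
of the 27 composition columns is assessed by the partial F test against
the covariate-only model, and the value of the second-order terms by AIC
(Gaussian convention, identical to `stats::AIC` on `lm`).

**Privacy-preserving artifacts.** A fitted model is serialized to JSON
containing only the coefficient vector, its full covariance matrix, the
residual degrees of freedom, the partition and coding metadata — never
unit-level records; the loader rejects files containing unknown fields.
Standard errors alone would not suffice: the variance of a contrast
(x₁ − x₀)ᵀβ̂ requires the full covariance, so the covariance matrix is the
stored object.

**Substitution estimates.** A reallocation is a vector of signed per-part
minute changes netting to zero, each bounded by a configurable cap
(default 60 min), and rejected if it would drive any part negative. For an
identity-scale outcome the difference between the new and initial
compositions is the linear contrast d = (x₁ − x₀)ᵀβ̂ with variance
(x₁ − x₀)ᵀV(x₁ − x₀) and a t-based CI on n − 35 degrees of freedom. For
the log-scale outcome the raw-scale difference exp(ŷ₁) − exp(ŷ₀) gets a
MOVER (method of variance estimates recovery, Zou's construction)
interval, combining the raw-scale limits of each prediction with the
correlation r = x₁ᵀVx₀ / (se₁·se₂) of the two link-scale predictions. All
differences are also reported as percentages of the prediction at the
initial composition (the per-user baseline, rather than the sample mean
outcome, since the estimate is conditional on the user's own starting
composition and covariates).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| closure total | 1440 min/day | the 24-h constraint; inputs not summing to it (±1 min at the CLI) are rejected, not renormalized |
| zero imputation | 3.25 min | 65% of the 5-minute recall sampling frame, used for user-supplied zero durations |
| reallocation cap | 60 min | maximum per-part change; configurable by the deploying analyst |
| alpha | 0.05 | two-sided error rate of all intervals |
| covariate defaults | ses_z = 0, mid-pubertal | used when a prediction profile supplies only sex and age (mid-pubertal is the sample mode) |
| weekday:weekend weight | 5:2 | weekly aggregation of multi-day recalls |

t rather than normal quantiles are used throughout; at the residual
degrees of freedom of the intended scale (≈1637) they are nearly
identical, but t keeps small-sample fits exact.

## Numerical choices

* **Fitting** uses the QR decomposition (`lm.fit`); a rank-deficient
  design raises an error rather than silently pseudo-inverting. This
  matters in practice: in small simulated samples the rare post-pubertal
  level (0.5%) can be entirely absent, leaving an all-zero indicator
  column. Simulation studies in the test suite therefore condition on
  designs in which all five pubertal levels are observed.
* **ilr inversion** subtracts the log-scale maximum before
  exponentiating, so extreme coordinates cannot overflow.
* **Dataset zero replacement** treats zeros as below-detection durations
  in the spirit of log-ratio EM: additive log-ratios against a zero-free
  reference part are imputed by iterated OLS conditional means, clamped to
  the observed log-ratio range, with affected rows re-closed
  multiplicatively after each sweep (convergence tolerance 1e-6, max 50
  sweeps). Working on log-ratios rather than raw log-durations makes each
  sweep invariant to the re-closure, which is required for convergence.
  With a single row, fewer than ten zero-free rows, or no zero-free part,
  it falls back to the fixed 3.25-min rule — with no cross-row
  information the two coincide conceptually.
* **Exact-zero contrasts.** When the initial and new compositions are
  identical the difference is exactly 0 with a zero-width interval. For
  the MOVER construction this is a special case: the general formula at
  correlation 1 does not collapse to zero width because the lognormal
  limits are asymmetric, so the identical-composition case is returned
  directly.
* **Ties and ordering.** Design columns have a fixed documented order
  (intercept, linear, squared, interactions lexicographic, covariates) so
  serialized artifacts are stable; JSON is written at full precision
  (round-trips are lossless).

## What the synthetic generator emulates — and what it does not

The restricted cohort underlying the intended deployment cannot be
redistributed, so the generator produces structurally faithful stand-ins
with known ground truth. Compositions are logistic-normal: ilr coordinates
drawn around the published compositional mean (sleep 709.7, screen 175.0,
physical activity 116.9, quiet 70.2, passive transport 35.8, school 129.1,
domestic/self-care 203.3 min/day) with coordinate SD 0.45, chosen so that
per-part dispersions are of the same order as the published arithmetic
SDs. Covariates follow the published sample margins (48.4% female, age
12.0 (0.4), SES z 0.20 (0.99), pubertal 9.6/25.8/51.0/13.1/0.5%).
Outcomes are generated from known 35-coefficient vectors with genuine
curvature; intercepts are calibrated so the expected outcome at the centre
matches the published descriptives (body fat median ≈ 19.9%, psychosocial
≈ 77 (≈ 11–14), writing ≈ 533 (≈ 65)), and effect sizes are set so the
three compositional F statistics land in the published significant range
(≈ 2.3–4.0 at n = 1685) and so AIC prefers the polynomial model — the
qualitative structure the engine is designed around. Writing scores are
trimmed at ±4 sample SDs (one pass), structural zeros are injected only
into the low-duration parts (quiet time, passive transport), and
multi-day tables draw two weekdays and one weekend day per participant
with ilr-scale day noise and multiplicative weekend shifts (e.g. school
time × 0.15 on weekends).

The generator is deliberately *not* a calibrated re-creation of the
cohort: the ilr covariance is diagonal (real activity behaviours
covary), covariates are independent of the composition (in reality
pubertal status and SES pattern time use), measurement error in the
recall instrument is not modelled, and outcomes are exactly Gaussian
given the design. Passing tests therefore demonstrate the statistical
machinery — coverage, size, unbiasedness, invariances — under a known
truth, not predictive validity on real children.

## Problem sizes used in validation

The test suite validates, among others: CI coverage of a fixed 60-min
screen→physical-activity reallocation for both the linear and MOVER
constructions over 2000 simulated datasets of n = 500 (both observed near
95%); the size of the 27-df partial F test under a compositionally null
generator over 2000 datasets (observed ≈ 0.047 at α = 0.05); and pooled
coefficient CI coverage of the full simulate → inject zeros → replace →
fit pipeline over 200 datasets of n = 1685. Contrast standard errors are
cross-checked against 100,000-draw Monte-Carlo oracles, and the MOVER
interval against a 200,000-draw percentile oracle in the independent
case. Coverage is pooled across coefficients for the pipeline check
because a per-coefficient band of 93–97% at 200 replicates would be
narrower than its own binomial noise.

## Known limitations

* Cross-sectional associations only; nothing here supports causal
  interpretation of a reallocation.
* One outcome per model; no joint modelling of the three outcomes, no
  survey weights, mixed effects or covariate×composition interactions.
* The lrEM-style zero replacement is a re-implementation of the idea, not
  of any specific package's algorithm; at 5-minute recall granularity
  substitution estimates are insensitive to this choice.
* Alternative log-ratio systems (alr/clr regression) and Bayesian zero
  imputation are out of scope.
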