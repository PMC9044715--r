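---
title: "Methods: MANOVA for circular responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MANOVA for circular responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circmanova)
```

## The model

An angle θ is represented by its unit vector (cos θ, sin θ). For a sample
θ₁, …, θₙ this gives an n × 2 response matrix Y, and any explanatory
structure — grouping factors, linear covariates, interactions — enters
through an ordinary multivariate linear model Y = XB + ε. The two
coordinates of a single angle are orthogonal functions of the same
measurement, which is what lets a *multivariate* test recover directional
information that each coordinate alone carries only partially.

Every term is tested with Pillai's trace. Writing H_t for the term's
hypothesis SSCP (sums of squares and cross-products) and E for the
residual SSCP,

$$V_t = \mathrm{tr}\!\left(H_t (H_t + E)^{-1}\right), \qquad
F \approx \frac{2n^* + s + 1}{2m + s + 1}\,\frac{V/s}{1 - V/s},$$

with s = min(2, q), m = (|2 − q| − 1)/2 and n\* = (d − 3)/2 for q
hypothesis and d residual degrees of freedom. For the intercept (q = 1)
this is algebraically the one-sample Hotelling T² of the hypothesis "mean
response = (0, 0)": the sample's mean vector sits at the center of the
unit circle exactly when the angles carry no preferred direction, so the
intercept row of the MANOVA table is a test of circular uniformity against
unimodal clustering. The package's test suite pins this equivalence to
1e-9 against an independently coded Hotelling T².

### Sequential partition and term order

Hypothesis SSCPs are **sequential (Type-I)**: term t is adjusted only for
the terms listed before it, computed by successive orthogonal projections
(a nested orthonormal basis built term block by term block). The intercept
is the first block — its H is the grand-mean SSCP n·m̄m̄ᵀ — which is the
sequential convention; with unbalanced data or correlated covariates,
reordering terms changes the partition, and users should list terms in
the order their hypotheses are meant to be adjusted. The partition is
verified on every fit by the conservation identity Σₜ Hₜ + E = YᵀY.

Factors use treatment contrasts with the first level in sorted order as
reference. This affects coefficient interpretation only, never the
whole-term Pillai tests, but is fixed so that fits are reproducible.

Covariates are **not centered**. The intercept hypothesis is therefore
"mean direction undefined at covariate value 0 and reference factor
levels"; the CLI prints a note when a covariate with nonzero mean enters a
model, since the intercept's meaning shifts accordingly. Centering
covariates before the fit restores the "overall non-uniformity" reading
of the intercept when that is wanted.

## Monte-Carlo calibration

The F approximation for Pillai's trace runs slightly anticonservative at
small n (empirically, type-I error ≈ 0.12 at n = 5, back at the nominal
0.05 by n ≈ 15). `mc_calibrated_manova()` corrects this by whole-procedure
simulation: B samples of n angles are drawn from Uniform[0, 2π), the model
is refit to each with the **design held fixed** (the null hypothesis is a
uniform response, not an exchangeability statement about the rows, so no
permutation scheme is involved), and each term's observed theory p is
ranked against that term's own B null p-values, lower tail:

$$p_{mc} = \frac{1 + \#\{p^{null} \le p^{obs}\}}{B + 1}.$$

The +1 convention makes the p-value valid (never below 1/(B+1)); ties
count toward rejection. Because the design is fixed, the per-replicate
refit reduces to projecting the new response onto the pre-computed basis,
so calibration costs O(B·n·k) and B = 9999 is cheap even inside loops.

## Reference tests

**Rayleigh.** Z = n·r̄² with r̄ the mean resultant length. The p-value uses
the standard exponential series with first- and second-order 1/n
corrections (the Greenwood–Durand form used across circular software),
clamped to [0, 1]. Powerful against unimodal alternatives, blind to
symmetric multimodal ones.

**Hermans–Rasson** (second variant). The pairwise statistic

$$T = \frac{1}{n}\sum_{i,j}\Big[\,\big||\theta_i-\theta_j|-\pi\big| -
\tfrac{\pi}{2} - 2.895\big(|\sin(\theta_i-\theta_j)| - \tfrac{2}{\pi}\big)\Big]$$

over all ordered pairs including i = j, with p-values by Monte Carlo
against uniform samples of the same size. The constant 2.895 is the
literature value of this variant; it is a named object (`hr_constant`)
rather than a buried literal so it can be corrected in one place should
the canonical form be revised. The implementation is pinned against a
literal double-loop oracle to 1e-9.

## The samplers and what the generator emulates

* **von Mises** draws use the Best–Fisher wrapped-Cauchy envelope
  rejection algorithm — exact for every κ, no tuning; κ = 0 falls back to
  the uniform sampler.
* **Wrapped skew normal** uses the delta representation of the skew
  normal on the line (δ = α/√(1+α²), z = δ|u₀| + √(1−δ²)u₁) followed by
  location–scale wrapping θ = (ξ + ωz) mod 2π. The (ξ, ω, α) convention
  matches the parameter triple quoted for the simulation scenarios
  (location 0, dispersion 2, skewness 30). Only distributional properties
  are asserted (first trigonometric moments, skewness sign), not
  stream-level equality with any other generator.
* **Mixtures** assign each draw to a component i.i.d. by weight
  (multinomial, not stratified), matching the i.i.d. sampling semantics
  of the study designs. Specs serialize to JSON for scenario configs.

The simulation defaults are the study conditions themselves: unimodal
suites at κ = 1 and (ω = 2, α = 30) over n ∈ {5, 10, 15, 25, 50, 100};
bimodal von Mises (modes 0°/180° and 0°/240°, κ = 1) over
n ∈ {10, …, 200}; trimodal (0°/120°/240° and 0°/120°/270°) over
n ∈ {15, …, 300}; 10° bins for the rounding-sensitivity scenario; and the
two-group × five-age design with a κ schedule linear in age,
κ(age) = κ₁ + (κ₅ − κ₁)(age − 1)/4 — the simplest reading of a
concentration that "increases each year" — equal cell allocation
n_total/10, and a constant directional offset between groups at all ages.

What the generator does **not** emulate: within-individual correlation
(repeated releases of the same animal), heteroscedastic or drifting
concentration within a cell, covariate measurement error, unbalanced or
missing cells. Passing simulation tests therefore demonstrate operating
characteristics for independent draws under clean designs; with repeated
measures the model's independence assumption is violated and a
random-effects extension (not provided here) would be needed.

## Numerical choices

* Angles are stored in radians on [0, 2π); inputs declare degrees or
  radians explicitly. The mean direction is reported as `NA` when
  r̄ < 1e-12 rather than returning an arbitrary atan2 of noise.
* Binning maps each angle to the nearest multiple of the width with
  half-open upper rounding at exact midpoints (a 5.0° observation in 10°
  bins goes to 10°), the behavior of field measurements rounded to the
  nearest mark; binned simulations do not jitter ties. Binning is
  idempotent.
* Rank handling: each term block is orthogonalized (twice, for numerical
  safety) against the preceding blocks; a block whose residual columns
  fall below 1e-8 relative tolerance is reported as aliased with the
  offending term's name rather than silently dropped.
* A singular residual SSCP (all angles identical) is an error
  ("degenerate response"); a term that fits the response perfectly
  (V/s = 1) reports p = 0 with an explicit degeneracy flag instead of an
  exception, since toy datasets hit it routinely.
* Monte-Carlo p-values ignore exact ties when a shared null sample is
  used inside the harness (the statistics are continuous); the per-sample
  functions count ties conservatively.

## The simulation harness

`run_uniformity_suite()` estimates rejection rates (p < α, the strict
inequality) over replicate draws. Two engineering choices keep large
studies tractable without changing any definition:

* The Rayleigh and intercept-Pillai p-values are computed by vectorized
  twins of the per-sample functions; unit tests assert equality to 1e-12,
  so harness rates are produced by the same method users call.
* Hermans–Rasson rejections use the Monte-Carlo critical value of the
  null statistic distribution at each n — the identical decision rule to
  the per-sample Monte-Carlo test at fixed α, at a fraction of the cost.
  The null reference is always the *continuous* uniform, also in binned
  scenarios: sensitivity of a continuous-calibrated test to rounded data
  is precisely what the binned suite measures.
* Inside power loops the calibrated MANOVA uses B = 999 nulls per
  replicate by default (the full 9999 × 9999 is quadratic); the flag
  `B_mc` restores any scale.

`run_hypothetical_suite()` fits ~ age + group (intercept, then the linear
covariate, then the factor) per replicate and reports per-term rates,
plus Rayleigh/Hermans–Rasson on the pooled angles for the uniformity
comparison. The package's own test suite runs these studies at reduced
replicate counts (1500–5000 per condition, 9999 where the computation is
vectorized), with tolerance bands derived from the binomial 99% margin at
the chosen count.

## Model selection

`select_model()` implements the two-stage screen used for observational
datasets with many candidate variables:

1. Fit the full model with every candidate and compute per-channel
   partial η² = SSₜ/(SSₜ + SS_res) from the sequential partition — this
   matches the per-response univariate ANOVA decomposition exactly. The
   full model is fitted with candidates in sorted order so the screen
   does not depend on the order the user happens to list variables.
   Candidates are ranked by the mean of the two channel η²s (the `max`
   aggregation is available as an option) and the top `top_n` survive.
2. All 2^top_n subsets (intercept always included) are fitted and ranked
   by the mean of the two channels' Gaussian AICs,
   AIC = n·log(2πRSS/n) + n + 2(k+1), i.e. the conventional full-likelihood
   AIC of each underlying `lm`. Ties break toward fewer terms, then
   lexicographically.

Interactions are never generated automatically — list them explicitly as
candidates. Axial explanatory directions should be doubled *before*
screening (the package transforms covariates first, then screens). The
enumeration is guarded at top_n ≤ 15.

## Known limitations

* Sequential (Type-I) tests only; no Type-II/III analogues, and only
  Pillai's trace (not Wilks or Roy) since the two-channel case makes the
  statistics nearly equivalent and Pillai is the most robust of them.
* Independence across observations is assumed throughout; no random
  effects or repeated-measures structure.
* The intercept test, like the Rayleigh test, has essentially no power
  against symmetric bimodal or any trimodal alternative — by design it
  measures the first trigonometric moment. Axial doubling rescues the
  symmetric bimodal case; otherwise the Hermans–Rasson test is the right
  omnibus tool.
* Calibration targets the uniform null; it does not robustify the factor
  or covariate tests against non-uniform but null-consistent responses.
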