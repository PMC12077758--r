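---
title: "Methods: latitudinal gradients of mitochondrial genetic diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latitudinal gradients of mitochondrial genetic diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models implemented in `latdiv`, the
assumptions behind them, the numerical choices made where several defensible
options existed, and what the synthetic-data generator does and does not
emulate.

## From alignments to band-level diversity

The unit of analysis is the (species, one-degree latitudinal band) cell.
Banding truncates latitude toward the equator and keeps the hemisphere in
the sign: `assign_band(-23.57) == -23`. We deliberately keep bands *signed*:
a study region spanning both hemispheres (here roughly 36°N–32°S) can
contain more distinct bands than absolute values alone would allow, and a
diversity peak *near the equator* is an interior feature only on a signed
axis — on |latitude| it degenerates into a boundary trend. An
`absolute = TRUE` switch provides the collapsed-hemispheres reading for
sensitivity analyses.

Inclusion filters mirror standard macrogenetic practice: at least 3
sequences per cell (diversity estimates from n < 3 are dominated by
sampling noise) and at least 4 distinct bands per species (fewer bands
cannot support even a linear within-species trend). Cells are dropped
first, then species; every exclusion is logged with a reason so the row
counts at each step are auditable.

Alignment columns containing a gap or any non-ACGT symbol in *any* sequence
of a species are removed for that species as a whole (complete deletion).
This makes the per-site denominator of nucleotide diversity unambiguous and
gives all of a species' band estimates a common site set, so they are
comparable along the gradient. Site filtering is grouped per species — not
per band — for exactly that comparability reason. Haplotype identity is
exact string equality on the retained columns; we do not attempt
ambiguity-code matching, which would make haplotype counts depend on an
arbitrary resolution order.

Diversity per cell uses Nei's unbiased estimators: the n/(n−1) factor
corrects for drawing the same sequence twice. Distances are raw per-site
difference proportions with no model correction (e.g. no Jukes–Cantor) —
the quantities being modeled are the classical raw-difference diversity
statistics, and within-species COI divergence is small enough that
multiple-hit corrections would be far below the sampling noise. A `biased`
flag exposes the uncorrected variants for cross-checks.

A sample-size quality-control regression (`sample_size_qc`) checks that the
number of sequences behind each estimate does not predict the estimate.
Outliers are removed iteratively by an externally studentized residual
threshold of 3 (configurable). The original procedure this stands in for is
visual inspection of residual plots; a fixed studentized-residual rule is
the closest *reproducible* analogue, and every exclusion is logged. The
regression is diversity-on-n (not n-on-band): that orientation yields one
p-value per diversity metric, which is the quantity of interest.

## The pooled latitude model

For bands hosting two or more species (the pooled, "total diversity"
analysis only — within-species analyses use all of a species' bands), the
model ladder is

y = β₀ + β₁ z + ... + β_q z^q + a_s + ε,  a_s ~ N(0, σ²_α),  ε ~ N(0, σ²_ε)

with q = 0…4, z the scaled (SD 1) and centered (mean 0) band latitude, and
a random intercept a_s per species. Scaling and centering before taking
powers keeps the polynomial terms on comparable scales and usable together;
we use *raw* powers of z rather than an orthogonal basis so the printed
coefficients retain their direct meaning (the quadratic term is the
curvature of the hump). An orthogonal mode exists behind a flag.

Estimation is full maximum likelihood, not REML: the ladder compares models
with different fixed effects, and only ML likelihoods are comparable across
such models. The reported variance components are therefore also the ML
ones.

**Numerics.** Both β and σ²_ε have closed forms given the variance ratio
λ = σ²_α/σ²_ε (generalized least squares, with per-group Woodbury
identities so no N×N matrix is ever formed). The only free parameter is
t = log λ, and Nelder–Mead minimizes the profiled deviance in t from three
starts (λ = 0.01, 1, 100) with relative tolerance 1e-10. The boundary
σ²_α = 0 is admitted by clamping t at −30 and probing it explicitly; such
singular fits are retained in model comparison but flagged. Standard errors
come from the GLS covariance at the optimum. The test suite verifies the
optimizer against a 200 × 200 brute-force grid over (σ²_α, σ²_ε), against
the dense-matrix GLS closed form, and against an independent ML
mixed-model implementation.

**Bookkeeping.** k counts the fixed effects plus two variance parameters,
so the ladder's orders 0…4 carry k = 3, 4, 5, 6, 7; OLS fits count one
variance parameter. AIC = −2ℓ + 2k; AICc adds 2k(k+1)/(N−k−1).

**Selection rule.** The lowest-AIC model is selected when it leads by
ΔAIC > 2; when several models sit within 2 units of the minimum, the least
complex member of that set is selected. Complexity ties break toward lower
AIC. This parsimony tie-break matters in practice: a quartic can edge out a
quadratic by a fraction of a unit, and the rule prevents that fraction from
buying two extra parameters.

Marginal and conditional R² use the variance-partition form: with σ²_f the
population variance (N denominator) of the fixed-effect predictions,
R²m = σ²_f / (σ²_f + σ²_α + σ²_ε) and R²c adds σ²_α to the numerator.

The parametric bootstrap resimulates **both** the species intercepts and
the residuals from the fitted variances (a full parametric bootstrap),
refits, and reports per-coefficient bias and SE; holding the random
effects fixed would understate the uncertainty that the species draw
contributes. Replicates that fail to converge are dropped and counted; a
summary with more than 20% failures is flagged unreliable. B = 1000 by
default, seed-deterministic.

## Environmental drivers

The six environmental layers are averaged per band, z-scored over the
analysis rows, and screened: pairwise Pearson |r| > 0.7 or VIF > 5 flags
collinearity. Candidate predictor sets are built by excluding one member of
each flagged pair in every combination — with the expected single SST–
dissolved-oxygen pair this produces exactly two five-variable sets (an
oxygen set and a temperature set); the construction generalizes to any
number of flagged pairs by Cartesian choice. One global mixed model per
set is compared by the same ΔAIC-2 rule; sets within 2 units are *all*
carried forward.

Within each retained set, every predictor subset (2^p models, including
the intercept-only null) is fitted with the species random intercept and
ranked by AICc. Akaike weights are computed over the full ranking, then
renormalized over the ΔAICc < 2 top set for averaging and importance; both
normalizations are reported, because importance-type weights are sometimes
quoted against the full ranking and sometimes against the top set.

Averaging is **full** (zero-substitution): a term absent from a model
contributes estimate 0 and SE 0 there. This is the only convention under
which a term's importance weight below 1 coexists coherently with a single
averaged estimate per term; conditional averaging is available behind a
flag. Unconditional variance follows Burnham–Anderson:
Σ w_m (se²_m + (β̂_m − β̄)²). Confidence intervals use the normal 95%
multiplier (≈1.96); with top sets of a handful of models there is no
defensible finer-grained df accounting. A term whose interval excludes
zero is flagged — interval position, not importance weight, is the
evidence of a driver.

## Within-species trends

Per species and metric, the same ladder runs as OLS with orders capped so
at least one residual degree of freedom remains (and no order can exceed
the number of distinct bands minus one). Adjusted R² is reported only for
non-null selections — an adjusted R² for an intercept-only model is not
meaningful. Species where nothing beyond the null model is estimable are
skipped with a log entry rather than failing the run.

## The synthetic-data generator

The generator provides ground truth at two levels.

**Response level** (`simulate_response_table`): draws y directly from the
mixed model above. Defaults: 23 species, 5–12 bands each inside 36°N–32°S,
3–15 sequences per cell, β = (0.66, 0, −0.05), σ²_α = 0.015, σ²_ε = 0.02.
These place the response on the scale of haplotype diversity (a bounded
quantity around 0.6–0.7), give a modest equatorial hump, and split the
non-fixed variance so that species identity explains substantially more
than latitude — the variance structure a mixed-model analysis of this kind
of data has to cope with. Because the generator is Gaussian, draws are not
strictly confined to [0, 1]; this is the model's own assumption, not a
bug, and is one reason passing tests here do not certify behaviour on
bounded real data.

**Sequence level** (`simulate_sequences`): a star genealogy. Per cell, the
number and frequencies of haplotype classes follow a Chinese-restaurant
(Ewens) scheme with concentration θ = θ_scale · μ · L, and each haplotype
carries Poisson(λ_scale · μ · L) private substitutions from a species-level
reference (collisions redrawn so distinct classes stay distinct whenever
possible). The per-cell target μ = exp(b₀ + b₁z + b₂z² + a_s) is injected
on the log scale to keep μ positive; defaults b₀ = log(0.006), b₂ = −0.5,
log-scale σ²_α = 0.09 put π in the few-per-mill range typical of
within-species COI variation, with an equatorial hump spanning roughly a
five-fold diversity ratio from equator to range edge. Both θ and λ are
monotone in μ, so realized π and Hd track the latent gradient; because the
analysis model fits the *identity* scale while the truth lives on the log
scale, sequence-level recovery tests compare signs, orders and rank
correlations rather than raw coefficients — exact-coefficient recovery is
tested on the response-level path.

What the generator does **not** emulate: coalescent genealogies with drift
and migration, recombination, selection, range-edge demography, uneven
GenBank sampling, alignment error, or ambiguity codes. Passing tests
demonstrate that the estimators and the inference chain recover the
structures they assume; they do not show that real decapod data satisfy
those assumptions.

**Environmental fields** (`simulate_env_fields`): SST decreases with
absolute latitude plus noise; dissolved oxygen is an inverse-linear
function of SST with small noise (realized r ≤ −0.7 enforced, fields
redrawn up to 100 times otherwise); salinity, current velocity and pH are
weakly structured noise; chlorophyll-a can carry an injected association
with the diversity target for driver-recovery experiments. The redraw
guard also enforces that *only* the SST–oxygen pair crosses the screening
threshold, so the two-candidate-set construction is a property of the
default conditions, not of a lucky seed.

## Problem sizes and determinism

Every stochastic function takes a seed and restores the caller's RNG state;
identical configuration and seed reproduce outputs bit for bit, and the
pipeline manifest records the configuration, seed and row counts after
every filter so any number in any report can be regenerated from the
manifest alone.

The test suite and the acceptance script run simulations at sizes chosen to
pin the operating characteristics without waste: 1000 random samples for
the diversity-estimator oracle, 50 datasets against the 200 × 200
likelihood grid, 200 response-level replicates for CI coverage and bias of
the quadratic coefficient, and 100 sequence-level replicates each for hump
detection and null behaviour (40 each in the faster acceptance script).
Scaled-down property tests inside the module suites use 15–25 replicates
with correspondingly tolerant pass thresholds.

## Limitations

- Band means of environmental layers discard within-band spatial variance;
  no distance-along-coast or spatial-autocorrelation correction is applied.
- The LMM assumes Gaussian residuals for responses that are bounded
  ([0, 1]) and, for π, strongly right-skewed near zero; this mirrors the
  standard practice the package implements, but residual checks on real
  data remain the user's job.
- Model-averaged coefficients across non-nested subsets inherit the usual
  interpretive caveats; the package reports both weight normalizations and
  flags CI-zero crossings rather than declaring "significance".
- The star-genealogy generator is a calibration device, not a demographic
  model; effect sizes estimated from it do not translate to real taxa.
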