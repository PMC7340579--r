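---
title: "Methods: composite quality scores, temporal percentiles, and imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite quality scores, temporal percentiles, and imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdbqual)
```

## Scope and data model

`pdbqual` assesses X-ray crystallographic models from the validation
metrics the archive attaches to each deposit: Clashscore, Ramachandran
outliers (%), Rotamer outliers (%), RSRZ outliers (%), and R-free (%),
with the R factor, resolution, and deposition year as supporting
variables. A deposit belongs to one of two scoring populations: the
protein group (protein-only deposits plus protein–nucleic-acid
complexes, for which all five metrics exist) or the nucleic group
(nucleic-acid-only deposits). Ramachandran and Rotamer outliers are
backbone/side-chain concepts with no meaning for nucleic acids; the
package treats those cells as structurally *inapplicable* — distinct
from *missing* — and excludes them from imputation, missingness
statistics, and scoring alike. R-free and R are carried in percent units
throughout, matching how archive-wide statistics are usually printed.

## Tie-averaged percentiles

All scoring rests on one primitive: deposits are ranked from worst to
best in quality orientation (every raw metric is a "badness" measure,
so lower raw value = better), tied values receive the average rank of
their tie group, and the percentile is `100·rank/N`. Under this
inclusive convention the worst deposit of a population scores `100/N`,
the best scores exactly 100, and the population mean is identically
`100(N+1)/(2N)` — a property the test suite asserts on every generated
population, since it pins down the convention uniquely. A midpoint
convention (`100·(rank−0.5)/N`), which centres the scale at 50 but never
awards exactly 100, is available via `convention = "midpoint"`; the
inclusive form is the default because a population of one should score
100 (this matters for the temporal measures, where the first deposit of
a stratum is ranked against itself alone).

## The geometry aggregate and the composite scores

For the protein group the three geometry metrics are collapsed into one
axis by PCA. Deposits with grossly pathological geometry (Rotamer
outliers > 50 %, Ramachandran outliers > 45 %, or Clashscore > 250) are
excluded *from the fit only*: they would otherwise dominate both the
standardization and the loadings. The remaining deposits are
standardized to zero mean and unit variance per metric, and the
decomposition is an ordinary covariance eigendecomposition
(`stats::prcomp`; the tests cross-check loadings and explained variance
against `eigen` on the covariance matrix to 1e-10). PC1 is oriented so
that all three loadings are non-negative, making "larger PC1 = worse
geometry" unambiguous; excluded outliers are then scored through the
fitted model like any other deposit. Zero variance in any geometry
metric is a hard error — a population in which, say, every Clashscore is
identical cannot support a standardized PCA, and silently dropping the
metric would change the score's meaning.

The composites average three component percentiles, computed within the
deposit's molecule group over the full (imputed) dataset:

* protein group: R-free, RSRZ outliers, geometry PC1;
* nucleic group: R-free, RSRZ outliers, Clashscore.

The averaging variant is the arithmetic mean; the minimum variant takes
the worst component. Both are always computed (`q1`, `q1_min`), the
final percentile `p_q1` ranks whichever `variant` selects. Because the
three PC1 loadings come out nearly equal on realistic data, a PCA-free
approximation that replaces the PC1 percentile with the plain mean of
the three geometry-metric percentiles tracks the exact score closely
(Spearman > 0.95 on generator output); it is exposed as `q1p_approx()`
for settings where fitting a PCA is unwanted. Note the approximation is
only faithful when the geometry metrics are genuinely correlated — on
data with independent geometry columns PC1 is an essentially arbitrary
rotation and the approximation degrades, which is why the package keeps
the exact construction as the default.

## Temporal percentiles

`P_Q1(t)` ranks each deposit's Q1 within the population of same-group
deposits entered *strictly before* it, plus the deposit itself;
`P_Q1(t,d)` additionally conditions on the deposit's resolution bin
(rounded half-up to 0.1 Å, capped at [1, 4] Å — half-up rather than
banker's rounding so that bin edges are deterministic and
documentation-friendly). Design decisions worth stating explicitly:

* **Q1 is computed once, globally.** Component percentiles are not
  re-derived inside each historical population; only the final
  percentile is re-ranked. Recomputing components per reference
  population would make every deposit's score an O(N) object and the
  whole sweep O(N²) without changing the ranking question being asked
  ("how does this deposit's overall quality compare to what preceded
  it?").
* **"Prior" means strictly earlier deposition date.** Same-date deposits
  are excluded from each other's reference populations — with
  year-precision legacy dates there is no defensible ordering within a
  date, and including contemporaries asymmetrically would break
  determinism. The deposit itself is always included, so the measure is
  well defined from the first deposit onward (it scores 100).
* **Complexity.** The sweep processes each (group[, bin]) stratum
  chronologically in equal-date batches over a Fenwick tree of
  compressed Q1 values: O(N log N) overall, and *causal* by
  construction — deposits dated later can never influence an earlier
  score. The tests assert exact equality with a per-deposit brute-force
  re-ranking up to N = 2000 and prefix-stability under truncation.

## Missing data

About one deposit in eight lacks at least one quality metric (RSRZ
dominates; the metric simply did not exist for early depositions).
Three imputation methods are provided: column mean, column median, and
chained equations. The chained-equations imputer initializes missing
cells at column means, then cycles over incomplete columns in descending
missingness order, regressing each column's observed entries on all
other metrics plus resolution and year, with a Bayesian ridge whose
regularization and noise precisions are estimated by evidence
maximization. Predictions are posterior means, so the imputer is
deterministic; the `seed` argument is recorded for provenance only.
Numerical choices: at most 10 cycles by default with early stop when no
imputed cell moves by more than 1e-4 (convergence is typically reached
in a handful of cycles); the ridge solve works in the eigenbasis of the
predictor Gram matrix with null-space projection, so perfectly collinear
or constant predictors are handled exactly rather than by jitter; a
column left with no varying predictors falls back to its mean with a
warning. All imputed values are clipped to legal ranges (Clashscore ≥ 0,
outlier percentages [0, 100], R factors (0, 100)); observed cells are
never altered, which the tests check bit-for-bit.

## Evaluating imputation

The harness hides observed cells of the complete-row subset at the
archive's per-metric rates, lets every method impute the *same* masked
table (a paired design), and scores MAD, MAE, and RMSE per metric
against the hidden truth; over repetitions the methods are compared with
a Friedman test (repetitions as blocks) and Nemenyi post hoc pairwise
tests through the studentized-range distribution. Two conventions
deserve a note:

* **MAD** here defaults to the *median absolute error*,
  `median(|truth − imputed|)`, so that MAD, MAE and RMSE share a scale
  and interpretation (three magnitude measures of increasing outlier
  sensitivity). The classical dispersion-about-the-median form is
  available as `mad_mode = "dispersion"`.
* **Correlated masking.** Independent per-metric Bernoulli masking at
  the archive's marginal rates *overestimates* the fraction of deposits
  with at least one missing cell (the product rule gives ~16 % where the
  archive shows ~12.7 %), because real missingness is correlated — RSRZ
  and R-free are co-missing in early depositions. `inject_missingness()`
  therefore supports a common-factor Gaussian-copula mode: a per-deposit
  shared latent plus per-metric idiosyncratic latents, thresholded so
  every marginal rate is preserved exactly while the factor loading —
  solved by 1-D root-finding on the closed-form expectation — hits a
  requested any-missing fraction. The default remains independent
  masking; the correlated mode reproduces the archive's joint pattern
  when both proportions matter.

## The synthetic archive

The generator draws deposits from a latent-quality Gaussian copula: a
latent quality that improves with deposition year (default 0.045 SD per
year), worsens with resolution (0.8 SD per Å), and carries per-journal
Gaussian offsets (SD 0.3) plus unit noise; a rank-based normal-scores
transform makes the copula latent exactly Gaussian so the configured
marginals are preserved. Right-skewed metrics (Clashscore and the three
outlier percentages) map through lognormal marginals matched to the
published archive-wide means and SDs; R-free and R are jointly Gaussian
at correlation 0.9. Deposition years follow an exponential growth curve,
resolutions a year-conditioned lognormal centred near 2.1 Å, journal
sizes a Zipf profile with 16 % of deposits unpublished ("To be
published"), 7 % nucleic-acid-only and 7 % complexes. Missingness is
applied per metric at the archive's rates, with RSRZ missingness decaying
exponentially from the earliest years (rescaled to keep the configured
average). The metric-to-quality copula strengths (0.5–0.65) are free
parameters with no published counterpart; they were fixed once at values
that give realistic inter-metric correlation and are overridable in
`synthetic_config()`.

What the generator does *not* emulate: per-journal historical volume
trajectories, the archive's actual growth curve, heavy-tailed outlier
clusters beyond the lognormal tails, structured (non-random) missingness
other than the RSRZ era effect, and any real journal identities.
Passing tests on this data therefore demonstrate the *pipeline's
statistical behaviour* (calibration, causality, parameter recovery),
not agreement with the real archive's headline numbers, which depend on
the true snapshot.

## Problem sizes and runtime

The test suite works at n = 200–10 000 deposits per case (50 000 for
marginal-calibration checks), brute-force oracles up to N = 2000, and
100-repetition paired evaluations on small matrices; the acceptance
script uses a 50 000-deposit synthetic archive and a 20-repetition
benchmark over a 4000-deposit complete subset. These sizes keep every
property estimable with comfortable statistical margins while the full
suite runs in well under a minute.

## Known limitations

* Journal-name unification ships as normalization (case folding,
  punctuation stripping) plus a user-supplied alias map; no curated
  alias table is bundled, so unique-journal counts on real data depend
  on the user's map.
* The chained-equations imputer produces a single completed dataset
  (posterior means), not multiple stacked imputations; downstream
  variance estimates do not account for imputation uncertainty. This is
  the right trade-off for ranking, where only the completed values are
  consumed.
* Impact correlations join deposits to indicator years by deposition
  year; publication year is not tracked, and journal-years with fewer
  than 5 deposits (configurable) contribute no point.
* Temporal percentiles for year-precision dates treat all same-year
  deposits as contemporaneous, which slightly enlarges the excluded set
  relative to archives with full dates.
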