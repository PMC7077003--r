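---
title: "Benchmarking variant effect predictions against deep mutational scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking variant effect predictions against deep mutational scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmsbench)
```

## The problem

Deep mutational scanning (DMS) experiments measure a functional score for
thousands of single amino-acid variants (SAVs) of one protein in a single
assay. Computational variant effect predictors (conservation baselines,
SIFT- or PolyPhen-style classifiers, supervised regressors) claim to
anticipate those effects from sequence alone. Comparing the two is harder
than it sounds: every assay reports on its own scale, in its own direction,
with its own noise floor, and every predictor has its own score range and
orientation. `dmsbench` implements a complete harmonization-and-evaluation
pipeline so that the comparison is well defined, reproducible, and testable
end to end on synthetic data with known structure.

## Score processing

**Anchoring and orientation.** For each measurement the wild-type score is
subtracted and the sign fixed so that 0 means wild-type-like, negative
means reduced fitness (deleterious) and positive means increased fitness
(beneficial). We keep this signed scale as the working intermediate: the
two effect sides must be analyzed separately, because assays are not
symmetric around wild type and a joint normalization would over- or
under-weight one side.

**Unit interpolation.** Within one dataset and one side, effect magnitudes
`|signed|` are divided by the side maximum, mapping scores onto [0, 1]
with 1 the strongest observed effect on that side. This is a strictly
monotone map, so Spearman correlations and AUCs computed downstream are
provably unchanged by it — a property the test suite asserts to 1e-12.

**Synonymous thresholding.** Synonymous nucleotide variants leave the
protein unchanged; their score spread estimates the experimental noise
around wild type. The interval covering the middle 90/95/99% of the
synonymous signed scores (schemes `syn90`/`syn95`/`syn99`) defines
"neutral"; SAVs outside it are "effect". Choices pinned here, with
reasons:

* thresholds are computed on the *signed* (pre-interpolation) scale,
  because synonymous scores straddle 0 and the interval must be two-sided;
* quantiles use linear interpolation between order statistics
  (`stats::quantile` type 7), the common scientific-software default;
* the interval is closed at both bounds — the synonymous variants defining
  the bounds must themselves count as neutral;
* datasets with fewer than `min_synonymous = 10` synonymous records are
  refused for classification (they still get normalized scores); ten is
  the smallest count at which a middle-95% interval is more than a range
  estimate.

## Predictor harmonization

Each method is described by data, not code: a registry entry with its
theoretical score range, orientation, default binary threshold, and (for
Envision-style methods) the unit interval its beneficial-side scores map
onto. Reversed methods (lower score = more effect, e.g. SIFT) are oriented
by `s' = max + min - s`; all scores are then mapped linearly from the
theoretical range onto [0, 1]. Binary calls use a strict `>` at the
oriented default threshold, uniformly — this matches treating a flipped
conservation score of exactly 0 as no call.

The **naive conservation** baseline reads effect straight off a PSI-BLAST
position-specific scoring matrix: the per-substitution log-odds with the
sign flipped, so rarer substitutions score as stronger effect. Integer
log-odds have no published theoretical bounds; we pin (-17, 17) in the
registry (spanning what PSI-BLAST emits in practice) and clamp with a
logged count. This is a convention of this package, recorded in the
registry so results are reproducible, not a value with independent
standing.

Two null baselines calibrate what a metric value is worth: shuffling a
predictor's scores across variants (identical marginal, no variant
information) and drawing scores from a normal distribution around the
experimental mean. A method whose MSE matches its own shuffled version is
mimicking the score distribution, not predicting variants.

## Evaluation

All comparisons run on the largest common subset of variant keys
(`protein|position|wt|mut`), per dataset, per side. Metrics are Spearman ρ
(primary; robust to the monotone rescalings both sides undergo), Pearson R
(reported for comparability, not interpreted — DMS scores are skewed with
outliers), and MSE on the unit scale. Confidence intervals are percentile
bootstrap: resample index pairs with replacement, recompute, take the
2.5th/97.5th percentiles; 1000 replicates by default, seeded. The same
bootstrap serves the AUC, for internal consistency. Undefined statistics
(constant vectors, single-class resamples) propagate as missing values,
never as 0, and a bootstrap fails if more than half its resamples are
undefined.

ROC curves sweep every distinct score threshold; tied scores collapse to
one point, which makes the trapezoidal AUC exactly equal to
P(effect variant outscores neutral variant) + 0.5 P(tie). The test suite
checks this equivalence against exhaustive pair enumeration, and against
an independent ROC implementation.

**Binned recall.** To see *which* effects a binary classifier finds, SAVs
are sorted by experimental effect strength and split into 20 equal-count
bins; per bin we report the fraction called "effect". Equal-count (not
equal-width) bins keep the per-bin estimates comparable; any remainder is
spread over the lowest bins, and ties at borders follow the deterministic
key order. The adjusted variant subtracts bin 1's recall, i.e. a method's
base calling rate on the weakest effects.

**Agreement.** For two experiments on one protein, `delta_rho` is the mean
prediction-experiment Spearman minus the experiment-experiment Spearman,
and `delta_mse` the experiment-experiment MSE minus the mean
prediction-experiment MSE, all on the common SAV subset. Negative values
mean the experiments agree better with each other than with the method —
the realistic ceiling for predictor performance. Pairs from the same
publication (shared provenance tag) are excluded; beneficial-side pairs
with fewer than 10 common SAVs are flagged `low_n`.

## The synthetic generator

`generate_dms()` emulates the statistical shape of a published scan, not
any particular study:

* up to `19 * N` SAVs, each assigned deleterious / beneficial /
  near-neutral with configurable fractions (defaults 0.6 / 0.2 / 0.2,
  a deleterious:beneficial ratio of 3 — inside the 1.5–22.5 range seen
  across published scans);
* per-side Gamma-distributed effect magnitudes (shape 2; scales 1.0
  deleterious vs 0.4 beneficial), heavy-tailed and strictly positive, with
  the deleterious tail dominant;
* synonymous records and near-neutral SAVs drawn Normal(0, 0.1) around
  wild type (the synonymous noise floor);
* defaults `N = 200`, 100 synonymous records — a mid-sized published scan;
  tests and the acceptance script state larger sizes where a property
  needs them.

Controlled correlations use a Gaussian copula: the target vector's normal
scores are mixed with independent noise at latent weight
`r = 2 sin(pi * rho / 6)`, the exact inverse of the bivariate-normal
Spearman relation, then transformed back (predictors: normal CDF onto
[0, 1]; replicates: quantile-mapped onto the original score marginal). We
use this closed form rather than a numeric search — it is the value any
such search would converge to. Realized correlations hit the target to
within sampling error (about 1/sqrt(n)); at 10,000 SAVs that is well
inside ±0.03.

Synthetic PSSMs assign integer log-odds proportional to minus the true
deleterious magnitude (plus optional noise, then rounding), the wild-type
residue a positive value, and round-trip exactly through the PSI-BLAST
ASCII writer/reader.

What the generator does **not** emulate: position-level effect
correlation (real mutational sensitivity clusters along the sequence),
assay-specific censoring and floor effects, sequencing-count noise models,
and multi-functional proteins scoring differently across assays. Passing
tests therefore demonstrate the pipeline's correctness and calibration on
idealized data, not predictor performance on any real proteome.

## Numerical and design notes

* Positive class is always "effect", score orientation "higher = effect"
  after harmonization.
* Deterministic ordering everywhere: paired vectors sort by position then
  substituted residue, so reruns are byte-identical.
* One global seed derives per-stage seeds through a 31-bit multiplicative
  hash of (stage, dataset, method); stages never share streams.
* Exact duplicate score rows are deduplicated silently; conflicting
  duplicates are errors naming the variant. Categorical score sets are
  rejected at parse time.
* Sequence mismatches: a dataset is accepted against a sequence when at
  most 5 positions disagree and implied identity is at least 98%
  (measurements on close homologs), with per-variant flags.

## Known limitations

The Gaussian copula used for rank-correlation targeting has unbounded
tails: however many variants are scored, there is always an effect-strength
bin where a strong-but-imperfect classifier's expected number of stray
calls is of order one, and a single stray call can invert one adjacent
pair of bin recalls. In consequence, per-bin recall against a Spearman-0.95
copy of the experiment is weakly increasing across all 20 bins in only
roughly 90% of simulations at large-protein scale (we measure 89/100 at
N = 1200), approaching but not reaching certainty as n grows. The mean
recall profile is monotone; the occasional inversion is a tail property of
the noise model, not of the binning code.

Pearson CIs share the percentile bootstrap of the other metrics; no
Fisher-z interval is offered. Cross-dataset score calibration is
deliberately out of scope: normalization is strictly per measurement.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
oracle equivalences on hundreds of small instances (n ≤ 50); threshold
coverage at 10,000 synonymous variants; bootstrap coverage over 500
simulations of n = 1000 pairs; calibration at 10,013 SAVs (N = 527);
agreement over 100 simulated proteins at N = 30; binned recall over 100
simulations at N = 1200; and the full benchmark at N = 500 with four
predictors and a 1000-replicate bootstrap, run twice to assert
byte-identical output.
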