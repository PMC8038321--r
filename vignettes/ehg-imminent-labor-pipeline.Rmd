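---
title: "Predicting imminent labor from the electrohysterogram: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting imminent labor from the electrohysterogram: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

Threatened preterm labor (TPL) is the most common cause of hospitalization in
the second half of pregnancy, yet most women admitted with TPL do not deliver
preterm. Cervical length and related obstetric markers have good negative but
poor positive predictive value, so clinical practice tends to treat every TPL
admission with tocolytics and corticosteroids. The electrohysterogram (EHG) —
the uterine myoelectrical activity recorded from abdominal surface electrodes
— changes measurably as labor approaches: burst amplitude grows as more
myometrial cells are recruited, spectral content shifts above 0.34 Hz (the
fast-wave-high band), and the signal becomes more predictable and less
complex. `ehglabor` implements a complete pipeline that exploits those trends
to classify 30-minute EHG recordings from women with TPL into *imminent
delivery* (time to delivery, TTD, of at most 7 days) versus later delivery.

Because clinical EHG databases of this population are private, the package
ships a first-class synthetic cohort generator with the statistical structure
the analysis assumes, so every stage is testable end to end.

## Signal conditioning

Each recording holds two monopolar channels, M1 and M2. The analysis signal
is the bipolar difference `m1 - m2` (common-mode interference cancels),
band-limited to 0.1–4 Hz and resampled to 20 Hz. Design choices here, where
the field leaves the implementer latitude:

* **Filter**: 5th-order Butterworth applied forward–backward
  (`signal::filtfilt`), i.e. zero phase. Zero phase matters because several
  downstream features (time reversibility, Lempel–Ziv, entropies) are
  sensitive to waveform asymmetry, which a causal IIR filter would distort.
* **Decimation**: anti-aliased IIR decimation in chained stages of factor
  ≤ 10 (500 Hz → 20 Hz runs as 5 × 5). A single factor-25 stage is
  numerically fragile.
* **Artifacts**: segments with motion artifacts are excluded via
  machine-readable interval annotations (`valid_intervals` in the JSON
  sidecar); no automatic artifact detector is provided. A 120 s analysis
  window is admitted only if *every* sample is valid — partial windows would
  contaminate the nonlinear estimates.
* Windows are 120 s with 50% overlap, advancing on a fixed 60 s grid from
  the start of the recording; a fully valid 30-minute recording yields 29
  windows of 2400 samples.

## The 23 window parameters

Temporal: peak-to-peak amplitude (`app`).

Spectral (from a mean-removed, Hamming-tapered full-window periodogram,
Δf = 1/120 Hz): dominant frequency in 0.2–1 Hz (`df1`) and 0.34–1 Hz
(`df2`); the high-to-low energy ratio H/L = energy(0.34–1 Hz) /
energy(0.2–0.34 Hz); the deciles `d1`–`d9` of cumulative spectral power over
0.2–1 Hz; and the spectral moment ratio `smr` = M(−1)/M(5) with
M(n) = Σ P(f)·fⁿ over 0.2–1 Hz. The 0.2–1 Hz working band reflects fast-wave
physiology while avoiding cardiac and respiratory interference; the
full-window periodogram is used because the narrow 0.2–0.34 Hz low band needs
the finest available resolution. The moment orders (−1, 5) follow the
Dimitrov-style fatigue index commonly used for this parameter; band edges and
orders are configurable.

Nonlinear/regularity: binary and 6-state Lempel–Ziv complexity (LZ76 phrase
count, normalized as `c(n)·log_α(n)/n`; symbols from the window median or
from 6 within-window equiprobable quantile bins, which makes the symbolization
robust to amplitude nonstationarity); sample entropy and fuzzy entropy
(m = 2, r = 0.15 × window SD, fuzzy gradient 2 — the standard choices in the
EHG literature); normalized spectral entropy over 0.1–4 Hz; time
reversibility (mean cubed lag-1 difference); and the Poincaré descriptors
SD1, SD2 and SD1/SD2.

Undefined values (zero-variance window, no entropy template matches, zero
band power) are recorded as `NA` sentinels and never imputed; a window with a
missing feature is excluded from that feature's aggregation only. The sample
and fuzzy entropy and LZ76 kernels are implemented in C++ for speed and are
validated against brute-force R transcriptions of their definitions to
1e-10 / exact phrase counts.

## Trend-directed aggregation

A 30-minute TPL recording is mostly baseline: contractions are sparse, so the
median of a window feature mainly reflects basal activity. To characterize
the contractile episodes the pipeline also aggregates with *trend-directed*
percentiles: the 90th percentile for features that rise in contractile
periods as labor approaches (amplitude, DF1, DF2, deciles, H/L, time
reversibility) and the 10th percentile for features that fall (SMR, both
Lempel–Ziv measures, the three entropies, SD1, SD2, SD1/SD2). Percentiles use
linear interpolation between order statistics (quantile type 7) — declared
explicitly because percentile dialects differ across software.

Four classifier input sets result: (1) P10–P90 EHG + 6 obstetric covariates,
(2) P50 EHG + obstetric, (3) P10–P90 EHG, (4) P50 EHG — 29 features for sets
1–2, 23 for sets 3–4. The binary label is TTD ≤ 7 days (inclusive).
Recordings with missing obstetric covariates are excluded from sets 1–2 with
the offending field logged; the handling of such records in clinical use is
an open question this package resolves by explicit exclusion.

## Balancing, partitioning, dimensionality reduction

The cohort is imbalanced (30 vs 110; 21.4% minority prevalence). SMOTE with
five minority neighbors grows the minority to a 3:1 ratio of its original
size — 90 synthetic-augmented minority vs 110 majority samples (45%/55%;
exact counts are reported rather than rounded shares). Neighbor distances are
computed on z-scored features so obstetric and EHG scales are commensurate
(the choice of scaling is ours; interpolation happens in the original
space).

Robustness is assessed by a 30-times repeated holdout: each repetition
splits the 200 samples into test = ⌊N/3⌋ = 66, train = ⌊(N−66)·2/3⌋ = 89 and
validation = 45, stratified by class with largest-remainder rounding. The
same 30 partitions are reused for every classifier and both optimization
criteria, which is what makes the paired signed-rank comparisons valid.

Each partition's training subset then defines a PCA map (features
standardized by training mean/SD; minimal number of components reaching 98%
cumulative explained variance) applied to all three subsets. Fitting PCA on
the training subset of each partition — rather than once on all design data —
is our resolution of an underdetermined point.

**Pipeline order and leakage.** By default SMOTE runs on the full table
*before* partitioning, replicating the original design faithfully; synthetic
minority samples can therefore share parents across train/validation/test,
an information leak that inflates apparent performance. `prepare_design(...,
leak_safe = TRUE)` instead partitions the raw table and applies SMOTE and the
PCA fit inside each training fold. The package's tests check the direction of
the effect: leak-safe test F1 does not exceed the default-order test F1
beyond noise.

## Classifiers, seed ledger, optimization criteria

* **Random forest** (ranger backend): bootstrap trees, ⌈√p⌉ features per
  split; tuned over number of trees, maximum depth and minimum node size.
  Score = fraction of trees voting positive.
* **Extreme learning machine**: single hidden layer with input weights and
  biases drawn uniform(−1, 1) and frozen; output weights solve the ±1 target
  least-squares problem by Moore–Penrose pseudoinverse. Tuned over hidden
  width and activation (sigmoid, tanh, ReLU). The raw output is mapped to
  `(raw + 1)/2` so one 0.5 threshold serves all three model kinds.
* **Weighted KNN**: Minkowski distance of order p, distances normalized by
  the (k+1)-th neighbor before kernel weighting (rectangular, triangular,
  Epanechnikov, Gaussian, rank). No training randomness.

For the stochastic learners every (combination × partition) cell is trained
with a ladder of candidate seeds; the seed with the best validation F1 is
stored in a ledger *before* any test data are touched, and test evaluation
reuses exactly the stored seeds. The candidate count defaults to 30 and is
configurable (reports of this protocol are ambiguous about the intended
count). Storing one seed ledger shared by both criteria keeps the two
rankings on identical partitions and seeds.

Two optimization criteria are supported. `f1` picks the combination with the
highest mean validation F1-score. `sensitivity` ranks by mean validation
sensitivity with mean F1 breaking ties (within 1e-9). Descriptions of the
sensitivity criterion in the source literature conflict (best-sensitivity vs
best-F1-as-trade-off); we adopt the reading under which the two criteria can
select different models, which reproduces the reported qualitative behavior,
and by construction the sensitivity-selected model never has lower mean
validation sensitivity than the F1-selected one.

## Evaluation

Per partition and subset: F1 = 100·2TP/(2TP+FP+FN), sensitivity =
100·TP/(TP+FN), specificity = 100·TN/(TN+FP); a zero denominator yields an
`NA` sentinel with the partition logged. Summaries report mean ± SD and the
coefficient of variation (100·SD/mean) across the 30 test partitions.

Pairs of configurations are compared with a two-sided Wilcoxon signed-rank
test on the 30 paired per-partition values: zero differences dropped,
midranks for ties, exact null distribution (by convolution over doubled
midranks) for ≤ 25 nonzero pairs, normal approximation with tie and
continuity correction otherwise. Comparisons cover (a) the same classifier
and input set across criteria and (b) the same classifier and criterion
across input sets, separately within validation and within test — the two
subsets are never mixed. Raw p-values at α = 0.05 are reported without
multiplicity correction, replicating the original protocol; treat the
family-wise error accordingly.

ROC curves are computed per partition by threshold sweep (AUC by trapezoid,
equal to the Mann–Whitney U statistic over n₊n₋) and averaged vertically on
a fixed 101-point false-positive-rate grid; the summary AUC is the mean of
per-partition AUCs.

## The synthetic cohort generator

`synth_config()` defaults emulate the study conditions: 140 recordings
(30 imminent / 110 control), 1800 s at 20 Hz. Each monopolar channel is
1/f-shaped noise band-limited to 0.1–4 Hz (RMS 8 units) plus, with opposite
polarity on the two electrodes, a train of Poisson-arriving EHG bursts:
Tukey-windowed envelopes of duration U(30, 90) s modulating a narrowband
AR(2) resonator carrier. Class differences enter through

* burst amplitude: mean 55 (imminent) vs 40 (control), between-recording SD
  15 — about one SD of separation, chosen to make classification learnable
  but not trivial;
* burst center frequency: 0.45 vs 0.35 Hz (±0.03 Hz per-recording jitter),
  shifting imminent-class energy above the 0.34 Hz fast-wave boundary;
* carrier regularity: AR pole radius 0.985 vs 0.955, making imminent bursts
  narrower-band, hence more predictable and less complex;
* burst rate: 2.5 vs 1.5 per 10 min (active-labor contraction rhythms top
  out near 3 per 10 min);
* cervical length: N(15, 5) mm vs N(27, 6) mm; the other five obstetric
  covariates (gestational age N(31, 2.5) weeks, maternal age N(33, 5),
  gestations/parity/abortions as truncated Poisson counts) are
  class-independent. No distributional description of the clinical cohort is
  available, so these are stipulated, clinically plausible values — they are
  documented as synthetic, not estimates.

TTD is U(0.5, 7) days for the imminent class and U(8, 60) for controls; only
the 7-day threshold matters downstream. `inject_artifacts()` adds
large-amplitude transients over a chosen fraction of the duration and books
the affected intervals out of `valid_intervals`, emulating annotation-driven
artifact exclusion.

What passing tests on this cohort do and do not show: they verify that every
stage — conditioning, the 23 parameters, trend-directed aggregation, SMOTE,
partitioning, PCA, seed-managed model design, paired comparison — behaves as
specified, and that the pipeline recovers class structure of the kind the
physiological literature describes. They do not validate clinical
performance: the generator has no fetal ECG or respiration interference, no
tocolytic-phase dynamics, no electrode-placement variability, and its effect
sizes are assumptions. Headline clinical metrics are not reproducible without
the private recordings.

## Problem sizes and numerical conventions

The test-suite and acceptance runs use the full 140-recording cohort at the
default 30-minute duration for the end-to-end checks, with a trimmed ELM grid
(hidden width {50, 100, 150} × {sigmoid, tanh}, 10 candidate seeds) — wide
enough for the criteria to differentiate, small enough for a desk-scale run;
the generator property checks use 6–20 cohorts at reduced sizes. Intervals
are half-open `[start, end)` in seconds from recording start. Ties in seed
selection resolve to the lowest seed; ties in KNN distances resolve in stable
order. The fuzzy-entropy kernel skips template pairs beyond 8r (membership
< e⁻⁶⁴), far below its 1e-10 validation tolerance.

## Known limitations

No automatic artifact detection; two-electrode montages only; SMR moment
orders, entropy parameters and band edges are literature defaults rather than
values fitted to data; the default pipeline order intentionally reproduces a
leakage-prone design (use `leak_safe = TRUE` for methodological hygiene); and
synthetic-cohort performance figures say nothing quantitative about clinical
recordings.
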