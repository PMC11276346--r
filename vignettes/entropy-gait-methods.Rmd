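---
title: "Methods: entropy features and imbalanced nested cross-validation for EMG and gait kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy features and imbalanced nested cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrogait)
```

## The problem

After a stroke, hemiparesis alters both muscle activation and movement.
Regularity statistics of physiological time series — how often short
patterns repeat, how spread the spectrum is, how much one signal tells
about another — summarize these alterations in a handful of numbers per
subject. `entrogait` implements a complete pipeline around that idea: it
extracts entropy-based complexity features from one gastrocnemius
surface-EMG channel and the three calcaneus marker coordinates of the
paretic (or, in controls, right) side, and evaluates how well those
features separate stroke survivors (SP) from healthy controls (HC) under
a protocol designed for a markedly imbalanced cohort (138 HC vs 50 SP).

Every record is an analysis window of 2000 samples at 1000 Hz — about two
strides. The package does not ship or require any recorded data: a
synthetic cohort generator with the same statistical structure makes
every stage testable end to end.

## Entropy measures

All template statistics operate on a record
\(X = x_1, \dots, x_N\) with embedding dimension \(m\) and tolerance
\(r\) expressed as a fraction of the record's own SD. Defaults are
\(m = 2\), \(r = 0.2\,\mathrm{SD}\), the common choice for short
physiological series (recommended ranges: \(m \in [1,3]\),
\(r \in [0.1, 0.25]\,\mathrm{SD}\), with the series ideally longer than
\(10^m\) samples).

* **Shannon entropy** \(H(X) = -\sum_i p_i \log_2 p_i\) (bits) underlies
  the discrete estimators below.
* **Approximate entropy (ApEn)**
  \(\Phi^m(r) - \Phi^{m+1}(r)\) with
  \(\Phi^m(r) = \frac{1}{N-m+1}\sum_i \ln C_i^m(r)\), where
  \(C_i^m(r)\) is the fraction of templates within strict tolerance of
  template \(i\), self-matches included (so the logarithms are always
  defined).
* **Sample entropy (SampEn)** \(-\ln(A/B)\), the count-ratio form: \(B\)
  and \(A\) are the numbers of template pairs within tolerance at
  lengths \(m\) and \(m+1\), both over the first \(N-m\) origins, with
  self-pairs excluded. If no \((m+1)\)-pair matches, the statistic is
  undefined and the package returns a flagged `NA` rather than erroring;
  downstream feature assembly propagates the flag and the evaluation
  stage drops affected columns with a warning.
* **Fuzzy entropy (FuzzyEn)** replaces the hard threshold with the
  membership \(\mu(d) = e^{-(d/r)^n}\) of the distance between
  baseline-subtracted templates; \(\ln(\Phi^m/\Phi^{m+1})\) with the
  double average over ordered pairs. The fuzzy power \(n\) defaults to 2
  (the common choice; it is configurable).
* **Spectral entropy (SpEn)** is computed per sliding frame: each frame
  is mean-removed, a rectangular-window periodogram is taken, and
  \(-\sum_i p_i \ln p_i\) is evaluated on the normalized
  positive-frequency bins (DC excluded). The statistic is a *vector*
  over frames; its mean, SD, skewness and kurtosis are the features.
  Framing defaults to a 256-sample window with 128-sample hop (14 frames
  per 2000-sample record) — the framing itself is a free design choice,
  as only the existence of the vector is prescribed; the moments are
  stable for any framing that yields at least four frames.
* **Conditional entropy (CondEn)**
  \(H(Y\mid X) = -\sum p(x,y)\log_2 p(y\mid x)\) of a kinematic axis
  given the EMG. Both signals are quantized to equal-width amplitude
  bins over their own observed range (default 6 bins) and paired at equal
  sample indices (zero lag); the plug-in estimate on the joint histogram
  is used. Bin count, binning scheme and lag are configurable; the
  estimator is deliberately the plain plug-in, without bias correction.

Template distance is **Euclidean by default** (Chebyshev available) —
a deliberate choice for fidelity to the method being implemented, even
though much of the entropy literature defaults to Chebyshev. Euclidean
matching is stricter, so match counts are lower and short coarse-grained
series can reach the no-match condition; this is handled by the flagged
`NA` path rather than by loosening the metric.

Degenerate inputs follow fixed conventions: a constant record has zero
ApEn/SampEn/FuzzyEn (perfect regularity; the tolerance \(0.2\,\mathrm{SD}\)
collapses to zero, so this is a convention rather than a limit); a
constant conditioning signal leaves CondEn equal to the marginal
quantized entropy exactly; kurtosis is the raw fourth standardized
moment (normal \(\approx 3\)), not excess.

## Multiscale scheme

Coarser time scales are produced by **decimation**: scale \(n\) keeps
samples \(1, 1+n, 1+2n, \dots\), giving \(\lceil N/n \rceil\) samples at
\(f_s/n\). Factors run 1–20, so a 2000-sample record yields a 20-signal
set whose last member has 100 samples. Two things are deliberate here:

* *No anti-alias filter* — the subsampling is applied to the raw record.
* *Tolerance per scale* — \(r\) is recomputed from each coarse series'
  own SD, consistent with defining \(r\) as a fraction of the SD of the
  series actually analysed.

Costa-style averaging of non-overlapping blocks is available as an
opt-in alternative (`mode = "average"`), since the two coarse-graining
conventions coexist in the literature; decimation is the default because
it is the scheme this pipeline is built around. A coarse series shorter
than \(10^m\) samples triggers a warning but is still evaluated while
\(N \ge m + 2\) holds.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
exercised: 138 HC / 50 SP, 2000 samples at 1000 Hz, per-subject records
that are pure functions of `(spec, subject index)`.

**EMG.** Broadband Gaussian noise multiplied by an activation profile
with a tonic baseline (0.7) and two Gaussian bursts per record (one per
stride, centred at 45% of stance with 3% timing and 15% width jitter) —
the classic surface-EMG amplitude model. The group contrast is carried
by the *carrier*: in SP records it is smoothed by a moving average whose
width grows with `emg_effect` (width \(1 + 2\,\mathrm{effect}\) samples,
with 10% log-normal subject scatter), lowering template-entropy
complexity. At `emg_effect = 0` the groups are identically distributed
by construction. At the default `emg_effect = 2` the SampEn separation
is large (standardized difference well above 1 at 50 subjects per
group), deliberately mirroring a regime in which EMG complexity is
highly discriminative.

**Kinematics.** Each axis is a convex mixture
\((1-c)\cdot\text{stride waveform} + c\cdot\text{EMG envelope} +
\text{noise}\): a two-cycle harmonic stack (three harmonics, axis-specific
mm-scale amplitudes, per-subject random phases) modulated by slow
multiplicative irregularity whose SD doubles per unit `kin_effect` in
SP; the coupling term is the standardized *measured* linear envelope of
the same record's EMG (40 ms rectified moving average), weighted by the
group's coupling \(c\) (defaults: HC 0.6, SP 0.2); and 2.5 mm Gaussian
marker noise. Routing the coupling through the measured envelope makes
the zero-lag CondEn of kinematics given raw EMG genuinely
coupling-sensitive, because the envelope carries the carrier's
randomness, not merely its stride phase.

Two calibration facts shaped the defaults. First, at \(c = 0\) the
plug-in CondEn gap to the marginal entropy does not vanish per record:
smooth, stride-locked signals have far fewer effective samples than
2000, so the finite-sample bias is about 0.03 bits per record; the
independence contract is therefore stated (and tested) on the mean over
records, and the envelope's tonic baseline and burst width were chosen
once so that this bias stays below 0.05 bits. Second, the direction of
every group difference is a parameter, not a constant: which group is
"more complex" per metric is not identifiable from two-sided summary
tables, so the generator only fixes a default (SP less complex EMG,
weaker coupling, more irregular kinematics) and lets the sign be flipped.

What the generator does *not* emulate: real motion-capture artifacts
(marker swaps, soft-tissue motion), nonstationary gait (fatigue, turning),
inter-muscle crosstalk, age structure, and any within-record stride-to-
stride autocorrelation beyond the harmonic + envelope structure. Passing
tests on synthetic cohorts therefore demonstrates that the *machinery*
is correct and calibrated — not that the specific accuracies transfer to
recorded data.

## Feature sets

* `kinematic` (21): per axis (X, Y, Z) — ApEn, SampEn, FuzzyEn and the
  four SpEn moments, named in the `"X axis ApEn"` convention.
* `emg` (64): the same seven base features on the EMG plus multiscale
  ApEn/SampEn/FuzzyEn at factors 2–20 (`"multiscale ApEn (n = 15)"`);
  factor 1 is excluded as it duplicates the base features. Multiscale
  SampEn is included alongside ApEn and FuzzyEn for symmetry of the
  schema.
* `combined` (88): kinematic + EMG + the three `"CondEn EMG-X axis"`
  couplings.

All four SpEn moments are emitted for every kinematic axis (a symmetric
schema); feature selection downstream decides what is used.

## Evaluation machinery

**Balancing.** Every iteration keeps all minority-class subjects and an
equal-size uniform draw from the majority (50 + 50 at study scale), so
no fold ever sees the raw imbalance. The full protocol repeats this 1000
times; the package default is 50 with the count exposed, and the test
suite uses 2–50 per block.

**Nested CV.** Each balanced draw is split into 10 stratified outer
folds (stratification is enforced to exclude one-class folds). Within
each outer-training portion, MRMR ranks features and a grid search tunes
hyperparameters by 5-fold inner stratified CV; the outer test fold is
scored exactly once with the winning configuration. Selected features
and winning configurations are tallied across all folds and iterations
(majority voting); out-of-fold scores are pooled per iteration into
accuracy/precision/recall (positive class SP, percent) and rank-based
AUC, reported as mean ± SD over iterations.

**MRMR.** Greedy selection with two-group ANOVA-F relevance and
mean-absolute-Pearson-correlation redundancy, quotient criterion. One
numerical subtlety: a raw \(F/\overline{|\rho|}\) quotient cannot demote
a near-duplicate of an already selected feature (F is unbounded while
correlation saturates at 1), so the quotient uses the point-biserial
magnitude \(\sqrt{F/(F+n-2)}\) — a monotone transform of F that puts
relevance and redundancy on the same bounded scale. The first pick is
the largest F; ties resolve to the earlier column, making the ranking
deterministic. With many mutually uncorrelated noise features the *mean*
redundancy dilutes the penalty against duplicates — an inherent property
of mean-redundancy MRMR worth knowing when interpreting vote tallies.

**Classifiers.** Seven families behind one fit/score contract, all from
established implementations: coarse decision tree (`rpart`; the
maximum-splits control is mapped to `maxdepth` 1–2 with minimum leaf
sizes spanning 1–39), lasso-regularized logistic regression (`glmnet`),
kernel-density naive Bayes (written in the package — per-feature Gaussian
kernel densities with shared bandwidth on standardized features, since
no installed implementation exists), cubic-polynomial SVM (`e1071`, box
constraint and kernel scale tuned), fine kNN (`class`, k 1–7), bagged
trees (`randomForest` with `mtry = p`, 5–100 trees), and a single-hidden-
layer neural network (`nnet`, size/weight-decay grid, ReLU being
unavailable the logistic hidden unit is used; `nnet` supports exactly one
hidden layer, so the 1–3 layer range collapses to a size grid). Features
are standardized with training-fold statistics before every fit. The
compact default grids span the documented optimization ranges; wider
grids can be passed per call. Data-dependent optimized values (such as a
box constraint near 996) are outputs of the search, never inputs.

**ROC comparison.** `roc_auc` is the Mann–Whitney rank statistic (ties
half). `delong_test` implements the structural-components estimate of
the variance of an AUC difference for *paired* score vectors;
\(z = (\mathrm{AUC}_a - \mathrm{AUC}_b)/\mathrm{SE}\), two-sided normal
p, sign convention first-minus-second. Identical score vectors (or any
degenerate variance below 1e-16) return \(z = 0, p = 1\) by convention —
this matters in practice because two saturated classifiers produce
exactly that degeneracy. When feature sets are compared, every set is
evaluated on identical balanced draws, fold assignments and RNG streams,
so pooled out-of-fold scores are paired subject-by-subject; per-iteration
z statistics are summarized by their mean, with the normal p of that
mean.

**Leakage control.** MRMR, standardization and tuning see only
outer-training data. The dedicated diagnostic (`canary = "test_labels"`)
appends a feature that is pure noise wherever anything is fitted or
selected and equals the labels exactly on each held-out fold: with
leak-free in-loop selection it cannot move accuracy, and the test suite
asserts it does not (within 2 points on a null cohort).

**Group comparisons.** `group_t_tests` runs pooled-variance unpaired
t-tests (SP minus HC) on selected features; zero-variance ties return
\(t = 0, p = 1\). Significance is read at 0.05.

## Problem sizes used by the test suite

The oracle suites run at full prescribed scale (200 random signals for
the template entropies, 1000 bound checks for CondEn, 100 DeLong
instances against `pROC`). Simulation blocks are scaled to a desk-size
budget as their own design choice: the null-calibration pipeline uses a
50/50 cohort with 25 balancing iterations; the signal-recovery block
uses the full 138/50 imbalance with 50 iterations for the accuracy
claims and ten 4-iteration replicates for the DeLong pattern; the
acceptance script uses 20 iterations per feature set. Means over
iterations stabilize quickly at these sizes because each iteration
already pools 100 out-of-fold predictions.

## Known limitations

* SampEn with Euclidean matching and \(r = 0.2\,\mathrm{SD}\) is
  count-starved on near-i.i.d. series shorter than ~150 samples; the
  highest decimation factors of a white-like EMG can return flagged
  `NA`s, which the evaluation drops per column. Chebyshev matching or a
  larger tolerance mitigates this if those features are needed.
* The SpEn vector depends on the (configurable) framing; its moments are
  comparable only within a fixed framing.
* The plug-in CondEn is biased downward on autocorrelated signals; it is
  used as a *comparative* feature at fixed length and binning, not as an
  absolute information estimate.
* The DeLong summary across balancing iterations (mean z) treats
  iterations as exchangeable; it is a pragmatic aggregate, not a single
  U-statistic over all draws.
* Printed performance of the original study (its accuracy tables, t and
  z values) is tied to the recorded dataset and is not reproduced by the
  synthetic cohort; the pipeline reproduces the *structure* of those
  tables and the qualitative EMG-dominance pattern.
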