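# entrogait

Entropy-based complexity features and an imbalanced-cohort nested
cross-validation framework for discriminating stroke survivors (SP) from
healthy controls (HC) using surface EMG and gait kinematics.

## What it does, and for whom

Post-stroke hemiparesis changes both muscle activation and movement.
This package is for gait researchers who want to quantify those changes
with regularity/complexity statistics and evaluate them with a protocol
that is honest about a small, imbalanced patient group. It implements:

* **Entropy features** on uniformly sampled records (one gastrocnemius
  EMG channel and three calcaneus coordinates, 2000 samples at 1000 Hz —
  about two strides):
  - Shannon entropy `H(X) = -Σ pᵢ log₂ pᵢ`;
  - approximate entropy `ApEn = Φᵐ(r) − Φᵐ⁺¹(r)` with self-matches and
    strict Euclidean tolerance `d < r`, `m = 2`, `r = 0.2·SD`;
  - sample entropy `SampEn = −ln(A/B)` (no self-matches);
  - fuzzy entropy with membership `μ(d) = exp(−(d/r)ⁿ)` on
    baseline-removed templates;
  - framewise spectral entropy `SpEn = −Σ pᵢ ln pᵢ` of the normalized
    periodogram, summarized by mean/SD/skewness/kurtosis;
  - conditional entropy `H(kinematics | EMG) = −Σ p(x,y) log₂ p(y|x)`
    by equal-width quantization (neuromuscular coupling);
  - a **multiscale** scheme: the statistics evaluated on decimated
    versions of the record (every n-th sample, n = 1…20).
* **Evaluation machinery** for a 138 HC / 50 SP cohort: repeated
  balanced subsampling (all 50 SP + 50 random HC per iteration), 10-fold
  stratified nested cross-validation with in-loop MRMR feature selection
  and hyperparameter grid search over seven classifier families,
  majority-vote reporting, accuracy/precision/recall/AUC as mean ± SD,
  DeLong tests between correlated ROC curves of the kinematic / EMG /
  combined feature sets, and unpaired group t-tests of selected features.
* **A synthetic cohort generator** — burst-modulated broadband EMG whose
  carrier regularity differs by group, quasi-periodic three-axis
  kinematics coupled to the measured EMG envelope — so the entire
  pipeline is testable without any recorded data.

## Worked example

```r
library(entrogait)

set.seed(1)
sig <- gait_signal(rnorm(2000), fs = 1000)
sample_entropy(sig)
#> [1] 2.592095
round(multiscale_entropy(sig, "SampEn", factors = c(1, 2, 5, 10, 20)), 3)
#>   n=1   n=2   n=5  n=10  n=20
#> 2.592 2.626 2.489 2.359 3.761

coh <- generate_cohort(cohort_spec(n_control = 30, n_patient = 20, seed = 42))
tab <- build_feature_table(coh, "emg")
tab
#> <feature_table> set 'emg': 50 subjects x 64 features (30 HC, 20 SP)
res <- nested_cv(tab, "cubic_svm", n_iters = 5, seed = 1)
summary(res)
#> <nested_cv> cubic_svm on 'emg' set: 5 iterations x 10 outer folds
#>   accuracy  100.00% +/- 0.00
#>   precision 100.00% +/- 0.00
#>   recall    100.00% +/- 0.00
#>   auc         1.00 +/- 0.00
#> top majority-vote features:
#>   FuzzyEn                          50 votes
#>   SampEn                           49 votes
#>   ...
group_t_tests(tab, c("SampEn", "FuzzyEn"))
#>    metric      t         p
#> 1  SampEn -40.15 1.362e-38
#> 2 FuzzyEn -61.39 2.817e-47
```

White noise has a SampEn around 2.6 that stays roughly flat under
decimation (i.i.d. data have no preferred scale; the n=20 value is a
noisy 100-sample estimate). In the synthetic cohort the SP group's EMG
carrier is smoother by construction, so its entropy features separate
the groups: the nested CV — selecting features and tuning the SVM only
inside each training fold — reaches 100% out-of-fold accuracy at this
effect size, FuzzyEn/SampEn top the majority vote, and their group
t-tests (SP − HC) are strongly negative.

The full pipeline (simulate → extract three feature sets → classify →
DeLong comparisons → t-test table) is one call:

```r
res <- run_pipeline(default_config(seed = 1), out_dir = "run1")
```

which writes `features_{set}.csv`, `table1.csv` (performance),
`table2.csv` (group t-tests), `table3.csv` (DeLong comparisons), the
resolved config, a log, and an md5 manifest. A thin command-line wrapper
with `simulate` / `extract` / `classify` / `run-all` subcommands is at
`inst/cli/entrogait.R`.

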