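# Independent transcriptions of the entropy definitions, written
# directly from the printed formulas: an explicit embedded template
# matrix, per-origin distance vectors, strict d < r. They share no code
# with the package internals (which count pairs in compiled code without
# materializing templates) and serve as the reference the fast
# implementations must reproduce to 1e-10.

oracle_embed <- function(x, m) {
  n <- length(x) - m + 1L
  mat <- matrix(0, n, m)
  for (i in seq_len(n)) mat[i, ] <- x[i:(i + m - 1L)]
  mat
}

# distances from template i to every row of Y
oracle_dists <- function(Y, i, metric) {
  D <- Y - matrix(Y[i, ], nrow(Y), ncol(Y), byrow = TRUE)
  if (metric == "euclidean") sqrt(rowSums(D^2))
  else apply(abs(D), 1, max)
}

# ApEn: phi_m = mean over origins of ln(C_i), C_i the fraction of
# templates (self included) within strict tolerance
oracle_apen <- function(x, m, r, metric = "euclidean") {
  phi <- function(mm) {
    Y <- oracle_embed(x, mm)
    n <- nrow(Y)
    logC <- vapply(seq_len(n), function(i)
      log(sum(oracle_dists(Y, i, metric) < r) / n), numeric(1))
    mean(logC)
  }
  phi(m) - phi(m + 1L)
}

# SampEn: -ln(A/B), pair totals over the first N-m origins, no self-pairs
oracle_sampen <- function(x, m, r, metric = "euclidean") {
  n <- length(x) - m
  count_pairs <- function(Y) {
    tot <- 0L
    for (i in seq_len(n - 1L)) {
      d <- oracle_dists(Y[i:n, , drop = FALSE], 1L, metric)
      tot <- tot + sum(d[-1L] < r)
    }
    tot
  }
  B <- count_pairs(oracle_embed(x, m)[seq_len(n), , drop = FALSE])
  A <- count_pairs(oracle_embed(x, m + 1L)[seq_len(n), , drop = FALSE])
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

# FuzzyEn: baseline-removed templates, membership exp(-(d/r)^p),
# phi = mean over i of mean over j != i, both at N - m origins
oracle_fuzzyen <- function(x, m, r, p = 2, metric = "euclidean") {
  phi <- function(mm) {
    n <- length(x) - m
    Y <- oracle_embed(x, mm)[seq_len(n), , drop = FALSE]
    Y <- Y - rowMeans(Y)
    acc <- vapply(seq_len(n), function(i) {
      mu <- exp(-(oracle_dists(Y, i, metric) / r)^p)
      (sum(mu) - 1) / (n - 1) # drop the self term exp(0)
    }, numeric(1))
    mean(acc)
  }
  log(phi(m) / phi(m + 1L))
}

# AUC by exhaustive positive-negative pair counting, ties half
oracle_auc <- function(scores, labels, positive = "SP") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# random signal for oracle sweeps: mixes a tone and noise so match
# counts are neither empty nor saturated
random_test_signal <- function(n) {
  t <- seq_len(n)
  sin(2 * pi * t / stats::runif(1, 5, 50)) +
    stats::rnorm(n, sd = stats::runif(1, 0.2, 1.5))
}

# small cohort + feature tables reused across evaluation tests
make_test_tables <- function(n_per_group = 15, seed = 7, emg_effect = 2,
                             sets = c("kinematic", "emg", "combined"),
                             n_samples = 2000) {
  coh <- generate_cohort(cohort_spec(
    n_control = n_per_group, n_patient = n_per_group,
    n_samples = n_samples, emg_effect = emg_effect, kin_effect = 0,
    coupling_control = 0.4, coupling_patient = 0.4, seed = seed))
  out <- lapply(sets, function(s)
    suppressWarnings(build_feature_table(coh, s)))
  names(out) <- sets
  out
}
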