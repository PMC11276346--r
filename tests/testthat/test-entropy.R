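test_that("Shannon entropy matches closed forms and enforces bounds", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2.0)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0.0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_entropy(c(1.5, -0.5)), "negative")
  set.seed(1)
  for (i in 1:50) {
    k <- sample(2:16, 1)
    p <- stats::runif(k); p <- p / sum(p)
    h <- shannon_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log2(k) + 1e-12)
  }
})

test_that("template match counting honors self-pair and strictness conventions", {
  # five identical samples: every template matches every template
  expect_equal(template_match_counts(rep(0, 5), m = 2, r = 0.1),
               rep(4L, 4))
  expect_equal(template_match_counts(rep(0, 5), m = 2, r = 0.1,
                                     include_self = FALSE),
               rep(3L, 4))
  # strict inequality: r = 0 never matches distinct samples
  expect_equal(template_match_counts(c(3, 1, 4, 1.5, 9), m = 2, r = 0,
                                     include_self = FALSE),
               rep(0L, 4))
  # alternating signal vs exhaustive enumeration
  x <- c(1, 2, 1, 2, 1, 2)
  Y <- oracle_embed(x, 2)
  expected <- vapply(seq_len(nrow(Y)), function(i)
    sum(oracle_dists(Y, i, "euclidean") < 0.5) - 1L, numeric(1))
  expect_equal(template_match_counts(x, 2, 0.5, include_self = FALSE),
               as.integer(expected))
  expect_error(template_match_counts(c(1, 2), m = 2, r = 1), "too short")
})

test_that("ApEn, SampEn, FuzzyEn match independent brute-force oracles", {
  p <- entropy_params()
  x <- rep(c(1, 2), 15)
  r <- 0.2 * sd(x)
  expect_equal(approx_entropy(x, p), oracle_apen(x, 2, r), tolerance = 1e-12)
  x2 <- rep(c(1, 2, 3), 4)
  r2 <- 0.2 * sd(x2)
  expect_equal(sample_entropy(x2, p), oracle_sampen(x2, 2, r2),
               tolerance = 1e-12)
  x3 <- rep(c(1, 2), 4)
  r3 <- 0.2 * sd(x3)
  expect_equal(fuzzy_entropy(x3, p), oracle_fuzzyen(x3, 2, r3, 2),
               tolerance = 1e-12)

  # random sweep over lengths, embedding dimensions and both metrics
  set.seed(42)
  for (i in 1:40) {
    n <- sample(30:200, 1)
    m <- sample(1:3, 1)
    metric <- sample(c("euclidean", "chebyshev"), 1)
    x <- random_test_signal(n)
    r <- 0.2 * sd(x)
    pars <- entropy_params(m = m, metric = metric)
    expect_equal(approx_entropy(x, pars), oracle_apen(x, m, r, metric),
                 tolerance = 1e-10)
    expect_equal(as.numeric(sample_entropy(x, pars)),
                 oracle_sampen(x, m, r, metric), tolerance = 1e-10)
    expect_equal(fuzzy_entropy(x, pars), oracle_fuzzyen(x, m, r, 2, metric),
                 tolerance = 1e-10)
  }
})

test_that("constant signals return zero entropy by convention", {
  p <- entropy_params()
  expect_equal(approx_entropy(rep(3.7, 60), p), 0)
  expect_equal(sample_entropy(rep(3.7, 60), p), 0)
  expect_equal(fuzzy_entropy(rep(3.7, 60), p), 0)
})

test_that("template entropies rank regularity: periodic < noisy periodic < noise", {
  p <- entropy_params()
  hits <- c(ApEn = 0L, SampEn = 0L, FuzzyEn = 0L)
  n_trials <- 100
  kept <- c(ApEn = 0L, SampEn = 0L, FuzzyEn = 0L)
  set.seed(99)
  for (i in seq_len(n_trials)) {
    t <- seq_len(800)
    periodic <- sin(2 * pi * t / 40)
    noisy <- periodic + rnorm(800, sd = 0.2)
    noise <- rnorm(800)
    for (metric in names(hits)) {
      fun <- switch(metric, ApEn = approx_entropy,
                    SampEn = sample_entropy, FuzzyEn = fuzzy_entropy)
      v <- c(fun(periodic, p), fun(noisy, p), fun(noise, p))
      if (anyNA(v)) next
      kept[metric] <- kept[metric] + 1L
      if (v[1] < v[2] && v[2] < v[3]) hits[metric] <- hits[metric] + 1L
    }
  }
  for (metric in names(hits))
    expect_gte(hits[[metric]] / kept[[metric]], 0.95)
})

test_that("larger tolerance yields more template matches and lower SampEn", {
  # the match counts are monotone in r by construction; the -ln(A/B)
  # estimate inherits the trend once counts are estimable, so the
  # statistic is checked on its ensemble mean
  set.seed(7)
  r_grid <- c(0.1, 0.15, 0.2, 0.25)
  sums <- matrix(0, 20, length(r_grid))
  for (i in 1:20) {
    x <- random_test_signal(400)
    counts <- vapply(r_grid, function(rf)
      sum(template_match_counts(x, 2, rf * sd(x), include_self = FALSE)),
      numeric(1))
    expect_true(all(diff(counts) >= 0))
    sums[i, ] <- vapply(r_grid, function(rf)
      as.numeric(sample_entropy(x, entropy_params(r_frac = rf))),
      numeric(1))
  }
  mean_profile <- colMeans(sums, na.rm = TRUE)
  expect_true(all(diff(mean_profile) < 0))
})

test_that("SampEn flags the no-match case instead of erroring", {
  # strongly trending signal: no (m+1)-template pairs within tolerance
  x <- exp(seq(0, 6, length.out = 40))
  v <- sample_entropy(x, entropy_params(r_frac = 0.001))
  expect_true(is.na(v))
  expect_true(isTRUE(attr(v, "no_match")))
})

test_that("FuzzyEn responds continuously to a perturbation crossing r", {
  p <- entropy_params()
  x <- rep(c(0, 1), 30)
  r <- 0.2 * sd(x)
  eps <- seq(0.5 * r, 1.5 * r, length.out = 41)
  vals <- vapply(eps, function(e) {
    y <- x; y[11] <- y[11] + e
    fuzzy_entropy(y, p)
  }, numeric(1))
  steps <- abs(diff(vals))
  # no jump: largest step between adjacent eps is of the same order as
  # the median step
  expect_lt(max(steps), 10 * stats::median(steps) + 1e-9)
})

test_that("spectral entropy profile has the documented framing and limits", {
  expect_length(spectral_entropy_profile(gait_signal(rnorm(2000), 1000)), 14)
  expect_error(spectral_entropy_profile(rnorm(100), window_len = 256),
               "longer than signal")
  # bin-centred sinusoid concentrates in one periodogram bin
  t <- 0:1999
  sine <- sin(2 * pi * 8 * t / 256)
  expect_lt(max(spectral_entropy_profile(sine)), 1e-10)
  # white noise approaches the flat-spectrum maximum; reference value by
  # direct Monte-Carlo of the same statistic on fresh noise
  set.seed(5)
  ref <- replicate(30, mean(spectral_entropy_profile(rnorm(2000))))
  obs <- mean(spectral_entropy_profile(rnorm(2000)))
  expect_lt(abs(obs - mean(ref)), 5 * sd(ref) + 0.05)
  expect_lt(mean(ref), log(128))
  # normalized variant is bounded by 1
  expect_lte(max(spectral_entropy_profile(rnorm(2000), normalize = TRUE)), 1)
})

test_that("moment summary matches closed forms and flags degeneracy", {
  ms <- moment_summary(c(1, 1, 1, 1))
  expect_equal(ms$mean, 1)
  expect_equal(ms$std, 0)
  expect_true(ms$degenerate)
  expect_true(is.na(ms$skew) && is.na(ms$kurt))

  ms2 <- moment_summary(c(1, 2, 3, 4))
  expect_equal(ms2$mean, 2.5)
  expect_equal(ms2$std, sd(c(1, 2, 3, 4)))
  expect_equal(ms2$skew, 0)
  expect_equal(ms2$kurt, 1.64) # m4/m2^2 = 2.5625/1.5625
  expect_error(moment_summary(c(1, 2, 3)), "at least 4")

  set.seed(11)
  ms3 <- moment_summary(rnorm(1e5))
  expect_lt(abs(ms3$kurt - 3), 0.05)
  expect_lt(abs(ms3$skew), 0.05)
})

test_that("conditional entropy reproduces closed forms and bounds", {
  # deterministic dependence
  set.seed(2)
  x <- runif(2000)
  expect_equal(cond_entropy(x, x), 0)
  # hand-specified joint table
  expect_equal(cond_entropy_from_joint(rbind(c(0.5, 0), c(0.25, 0.25))), 0.5)
  expect_error(cond_entropy_from_joint(rbind(c(0.9, 0.2), c(0, 0))),
               "invalid joint")
  # constant conditioning signal gives H(Y) exactly
  y <- runif(500)
  expect_equal(cond_entropy(y, rep(1, 500), 5), quantized_entropy(y, 5))
  # length mismatch
  expect_error(cond_entropy(runif(10), runif(11)), "alignment")
  # independence: plug-in estimate within 0.02 bits of H(Y)
  set.seed(3)
  a <- runif(1e5); b <- runif(1e5)
  expect_lt(quantized_entropy(a, 4) - cond_entropy(a, b, 4), 0.02)
  expect_gte(quantized_entropy(a, 4) - cond_entropy(a, b, 4), 0)
})

test_that("conditional entropy is bounded by the quantized target entropy", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(50:300, 1)
    nb <- sample(2:6, 1)
    y <- random_test_signal(n)
    x <- if (i %% 3 == 0) y + rnorm(n, sd = 0.1) else random_test_signal(n)
    ce <- cond_entropy(y, x, nb)
    expect_gte(ce, 0)
    expect_lte(ce, quantized_entropy(y, nb) + 1e-12)
  }
})
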