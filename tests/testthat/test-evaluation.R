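test_that("balanced subsampling keeps all minority plus an equal majority draw", {
  labels <- factor(c(rep("HC", 138), rep("SP", 50)))
  set.seed(1)
  idx <- balanced_subsample(labels)
  expect_length(idx, 100)
  expect_equal(sum(labels[idx] == "SP"), 50)
  expect_equal(sum(labels[idx] == "HC"), 50)
  expect_true(all(which(labels == "SP") %in% idx))
  # two draws share the minority but differ in the majority
  set.seed(2); idx2 <- balanced_subsample(labels)
  expect_false(identical(idx, idx2))
  expect_true(all(which(labels == "SP") %in% idx2))
  # balanced input is returned whole
  bal <- factor(rep(c("HC", "SP"), each = 10))
  expect_length(balanced_subsample(bal), 20)
  expect_error(balanced_subsample(factor(rep("HC", 10))), "two classes")
})

test_that("MRMR ranks a label-aligned feature first and demotes duplicates", {
  set.seed(5)
  n <- 80
  y <- factor(rep(c("HC", "SP"), each = n / 2))
  informative <- as.numeric(y == "SP") + rnorm(n, sd = 0.05)
  noise <- matrix(rnorm(n * 20), n, 20,
                  dimnames = list(NULL, paste0("noise", 1:20)))
  x <- cbind(informative = informative, noise)
  expect_equal(mrmr_rank(x, k = 1, y = y), "informative")

  # a duplicated informative feature is demoted below an independent
  # weaker-but-novel feature by the redundancy penalty
  weaker <- as.numeric(y == "SP") + rnorm(n, sd = 0.8)
  x2 <- cbind(strong = informative,
              copy = informative + rnorm(n, sd = 0.01),
              weaker = weaker)
  ranked <- mrmr_rank(x2, k = 3, y = y)
  expect_equal(ranked, c("strong", "weaker", "copy"))

  # k = all features returns a permutation; k = 0 an empty ranking
  all_ranked <- mrmr_rank(x, k = ncol(x), y = y)
  expect_setequal(all_ranked, colnames(x))
  expect_length(mrmr_rank(x, k = 0, y = y), 0)

  # constant features never precede informative ones
  x3 <- cbind(flat = rep(1, n), informative = informative)
  expect_equal(mrmr_rank(x3, k = 2, y = y)[1], "informative")
})

test_that("confusion metrics follow the SP-positive convention", {
  m <- matrix(c(50, 0, 0, 50), 2, 2)
  met <- confusion_metrics(m)
  expect_equal(c(met$accuracy, met$precision, met$recall), c(100, 100, 100))
  m2 <- matrix(c(40, 10, 10, 40), 2, 2)
  met2 <- confusion_metrics(m2)
  expect_equal(c(met2$accuracy, met2$precision, met2$recall), c(80, 80, 80))
  # no positive predictions: precision undefined, recall zero
  m3 <- matrix(c(0, 50, 0, 50), 2, 2)
  met3 <- confusion_metrics(m3)
  expect_true(is.na(met3$precision))
  expect_equal(met3$recall, 0)
  expect_error(confusion_metrics(matrix(0, 2, 2)), "empty")
})

test_that("roc_auc equals exhaustive pair counting", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8),
                       factor(c("HC", "HC", "SP", "SP"))), 0.75)
  expect_equal(roc_auc(1:10, factor(rep(c("HC", "SP"), each = 5))), 1.0)
  expect_equal(roc_auc(rep(1, 10), factor(rep(c("HC", "SP"), each = 5))), 0.5)
  expect_error(roc_auc(1:4, factor(rep("SP", 4))), "both classes")
  set.seed(3)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    labels <- factor(c("HC", "SP", sample(c("HC", "SP"), n - 2, TRUE)))
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE) # force ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("delong_test matches pROC and honors its conventions", {
  skip_if_not_installed("pROC")
  # identical scores: degenerate variance convention
  set.seed(4)
  s <- rnorm(30)
  lab <- factor(rep(c("HC", "SP"), 15))
  same <- delong_test(s, s, lab)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  # small fixture with ties
  scores_a <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.4, 0.3, 0.2)
  scores_b <- c(0.6, 0.9, 0.4, 0.7, 0.50, 0.3, 0.5, 0.1)
  labs <- factor(c("SP", "SP", "SP", "SP", "HC", "HC", "HC", "HC"))
  ours <- delong_test(scores_a, scores_b, labs)
  ref <- pROC::roc.test(
    pROC::roc(labs, scores_a, levels = c("HC", "SP"), direction = "<",
              quiet = TRUE),
    pROC::roc(labs, scores_b, levels = c("HC", "SP"), direction = "<",
              quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(ours$z, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
  # random sweep
  set.seed(6)
  for (i in 1:25) {
    n <- sample(c(20, 40), 1)
    labs <- factor(c("HC", "SP", sample(c("HC", "SP"), n - 2, TRUE)))
    truth <- as.numeric(labs == "SP")
    sa <- truth + rnorm(n)
    sb <- truth + rnorm(n, sd = 2)
    ours <- delong_test(sa, sb, labs)
    ref <- pROC::roc.test(
      pROC::roc(labs, sa, levels = c("HC", "SP"), direction = "<",
                quiet = TRUE),
      pROC::roc(labs, sb, levels = c("HC", "SP"), direction = "<",
                quiet = TRUE),
      method = "delong", paired = TRUE)
    expect_equal(ours$z, unname(ref$statistic), tolerance = 1e-8)
  }
  # power + sign: a clearly better score vector gives positive z, small p
  set.seed(8)
  labs <- factor(rep(c("HC", "SP"), each = 250))
  truth <- as.numeric(labs == "SP")
  good <- truth + rnorm(500, sd = 0.5)
  bad <- truth + rnorm(500, sd = 5)
  out <- delong_test(good, bad, labs)
  expect_gt(out$z, 0)
  expect_lt(out$p, 0.05)
})

test_that("unpaired t-test matches the closed form and degenerate case", {
  expect_equal(unpaired_t_test(c(2, 2, 2), c(2, 2, 2)), list(t = 0, p = 1))
  tt <- unpaired_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$p, 2 * stats::pt(-abs(tt$t), 4), tolerance = 1e-12)
  # power: 1 SD true difference detected in nearly all seeds
  set.seed(10)
  hits <- sum(vapply(1:100, function(i)
    unpaired_t_test(rnorm(40), rnorm(40, mean = 1))$p < 0.05, logical(1)))
  expect_gte(hits, 95)
})

test_that("group_t_tests reports SP-minus-HC statistics per feature", {
  tabs <- make_test_tables(n_per_group = 10, sets = "emg", seed = 3)
  res <- group_t_tests(tabs$emg, c("SampEn", "FuzzyEn"))
  expect_equal(res$metric, c("SampEn", "FuzzyEn"))
  # SP is the more regular group by default, so t is negative
  expect_lt(res$t[1], 0)
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("nested CV is deterministic and solves a separable problem", {
  set.seed(20)
  n <- 60
  y <- factor(rep(c("HC", "SP"), each = n / 2))
  x <- cbind(sep = as.numeric(y == "SP") * 4 + rnorm(n, sd = 0.3),
             matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("f", 1:5))))
  tab <- data.frame(subject_id = sprintf("S%02d", 1:n), group = y, x,
                    check.names = FALSE)
  class(tab) <- c("feature_table", "data.frame")
  res <- nested_cv(tab, "fine_knn", n_iters = 3, k_features = 3, seed = 5)
  expect_equal(res$summary$mean[1], 100)
  expect_equal(res$summary$mean[4], 1)
  # majority vote surfaces the separating feature
  expect_equal(names(res$feature_votes)[1], "sep")
  # determinism
  res2 <- nested_cv(tab, "fine_knn", n_iters = 3, k_features = 3, seed = 5)
  expect_identical(res$metrics, res2$metrics)
  expect_identical(res$scores, res2$scores)
})

test_that("nested CV stays at chance on permuted labels", {
  set.seed(21)
  n <- 60
  y <- factor(rep(c("HC", "SP"), each = n / 2))
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  tab <- data.frame(subject_id = sprintf("S%02d", 1:n),
                    group = sample(y), x, check.names = FALSE)
  class(tab) <- c("feature_table", "data.frame")
  res <- nested_cv(tab, "fine_knn", n_iters = 10, k_features = 3, seed = 6)
  expect_gt(res$summary$mean[1], 30)
  expect_lt(res$summary$mean[1], 70)
})

test_that("every classifier family trains and scores through the contract", {
  set.seed(22)
  n <- 40
  y <- factor(rep(c("HC", "SP"), each = n / 2))
  x <- cbind(s1 = as.numeric(y == "SP") * 2 + rnorm(n, sd = 0.5),
             s2 = rnorm(n), s3 = rnorm(n))
  for (fam in c("coarse_tree", "logistic_lasso", "kernel_naive_bayes",
                "cubic_svm", "fine_knn", "bagged_trees", "medium_nn")) {
    grid <- default_grid(fam)
    model <- entrogait:::clf_fit(fam, x, y, as.list(grid[1, , drop = FALSE]))
    pred <- entrogait:::clf_predict(fam, model, x)
    expect_length(pred$score, n)
    expect_s3_class(pred$class, "factor")
    # training-set AUC on a separable-ish problem must beat chance
    expect_gt(roc_auc(pred$score, y), 0.7)
  }
})

test_that("comparing a feature set with itself yields null DeLong results", {
  tabs <- make_test_tables(n_per_group = 12, seed = 15, sets = "kinematic",
                           n_samples = 700)
  two <- list(a = tabs$kinematic, b = tabs$kinematic)
  cmp <- compare_feature_sets(two, "fine_knn", n_iters = 2,
                              outer_folds = 5, inner_folds = 3, seed = 3)
  expect_equal(cmp$comparisons$z, 0)
  expect_equal(cmp$comparisons$p, 1)
  expect_equal(cmp$comparisons$auc_a, cmp$comparisons$auc_b)
})
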