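# Seven classifier families behind a uniform fit/predict contract.
# The contribution of this package is the evaluation machinery around
# them; the learners themselves are the established implementations
# (rpart, glmnet, e1071, class, randomForest, nnet). Each family exposes
#   clf_fit(family, x, y, hyper)     -> opaque model
#   clf_predict(family, model, x)    -> list(class = factor, score = numeric)
# where `score` is oriented toward the positive class "SP". Features are
# standardized by the caller (training-fold statistics), so bandwidths,
# kernel scales and distances are on a comparable scale across features.

CLASSIFIER_FAMILIES <- c("coarse_tree", "logistic_lasso",
                         "kernel_naive_bayes", "cubic_svm", "fine_knn",
                         "bagged_trees", "medium_nn")

#' Default hyperparameter grids
#'
#' Compact search grids spanning the documented optimization ranges of
#' each classifier family (e.g. MinLeaf 1--39 and MaxNumSplits 1--77 for
#' trees, NumTrees 5--100 for bagging, polynomial-kernel box constraint
#' and scale for the cubic SVM). Each row of the returned data frame is
#' one candidate configuration for the inner-loop grid search; supply
#' your own data frame to [nested_cv()] to widen or refine the search.
#'
#' @param family one of `"coarse_tree"`, `"logistic_lasso"`,
#'   `"kernel_naive_bayes"`, `"cubic_svm"`, `"fine_knn"`,
#'   `"bagged_trees"`, `"medium_nn"`.
#' @return A data.frame, one row per hyperparameter combination.
#' @export
default_grid <- function(family = CLASSIFIER_FAMILIES) {
  family <- match.arg(family)
  switch(family,
    coarse_tree = expand.grid(minleaf = c(5L, 20L), maxdepth = c(1L, 2L)),
    logistic_lasso = data.frame(lambda = 10^seq(-4, -1, length.out = 4)),
    kernel_naive_bayes = data.frame(h = c(0.05, 0.1, 0.25, 0.5)),
    cubic_svm = expand.grid(cost = c(1, 100), gamma = c(0.01, 0.1, 1)),
    fine_knn = data.frame(k = c(1L, 3L, 5L, 7L)),
    bagged_trees = expand.grid(ntree = c(25L, 55L, 95L), minleaf = c(1L, 5L)),
    medium_nn = expand.grid(size = c(5L, 25L), decay = c(1e-4, 1e-2)))
}

clf_fit <- function(family, x, y, hyper) {
  switch(family,
    coarse_tree = {
      df <- data.frame(.y = y, x, check.names = TRUE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     minbucket = hyper$minleaf, maxdepth = hyper$maxdepth,
                     minsplit = 2L * hyper$minleaf, cp = 0, xval = 0))
    },
    logistic_lasso = glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                                    lambda = hyper$lambda),
    kernel_naive_bayes = kernel_nb_fit(x, y, hyper$h),
    cubic_svm = e1071::svm(x, y, kernel = "polynomial", degree = 3,
                           coef0 = 1, cost = hyper$cost, gamma = hyper$gamma,
                           scale = FALSE),
    fine_knn = list(train = x, cl = y, k = hyper$k),
    bagged_trees = randomForest::randomForest(
      x, y, ntree = hyper$ntree, mtry = ncol(x),
      nodesize = hyper$minleaf),
    medium_nn = nnet::nnet(x, as.numeric(y == "SP"), size = hyper$size,
                           decay = hyper$decay, maxit = 500,
                           trace = FALSE))
}

clf_predict <- function(family, model, x) {
  switch(family,
    coarse_tree = {
      df <- data.frame(x, check.names = TRUE)
      pr <- stats::predict(model, df, type = "prob")
      score <- if ("SP" %in% colnames(pr)) pr[, "SP"] else rep(0, nrow(x))
      list(class = score_to_class(score), score = score)
    },
    logistic_lasso = {
      score <- as.numeric(stats::predict(model, x, type = "response"))
      list(class = score_to_class(score), score = score)
    },
    kernel_naive_bayes = kernel_nb_predict(model, x),
    cubic_svm = {
      pred <- stats::predict(model, x, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      score <- as.numeric(dv[, 1])
      # e1071 orients the decision value toward the first label in the
      # colname "A/B"; flip so larger means more SP-like
      if (startsWith(colnames(dv)[1], "SP")) score <- score else score <- -score
      list(class = factor(as.character(pred), levels = c("HC", "SP")),
           score = score)
    },
    fine_knn = {
      pred <- class::knn(model$train, x, model$cl, k = model$k, prob = TRUE)
      win <- attr(pred, "prob")
      score <- ifelse(pred == "SP", win, 1 - win)
      list(class = factor(as.character(pred), levels = c("HC", "SP")),
           score = score)
    },
    bagged_trees = {
      pr <- stats::predict(model, x, type = "prob")
      score <- pr[, "SP"]
      list(class = score_to_class(score), score = score)
    },
    medium_nn = {
      score <- as.numeric(stats::predict(model, x))
      list(class = score_to_class(score), score = score)
    })
}

score_to_class <- function(score, threshold = 0.5) {
  factor(ifelse(score > threshold, "SP", "HC"), levels = c("HC", "SP"))
}

# Kernel naive Bayes: per-feature Gaussian kernel density per class with
# shared bandwidth h (features are standardized upstream). No packaged
# kernel-density naive Bayes is available, so the estimator is written
# out directly.
kernel_nb_fit <- function(x, y, h) {
  list(h = h,
       prior = table(y) / length(y),
       train = split.data.frame(as.data.frame(x), y))
}

kernel_nb_predict <- function(model, x) {
  h <- model$h
  classes <- names(model$train)
  ll <- sapply(classes, function(cl) {
    tr <- as.matrix(model$train[[cl]])
    if (nrow(tr) == 0L) return(rep(-Inf, nrow(x)))
    out <- numeric(nrow(x))
    for (j in seq_len(ncol(x))) {
      # mean kernel density of column j at the query points
      dens <- vapply(x[, j], function(q)
        mean(stats::dnorm((q - tr[, j]) / h)) / h, numeric(1))
      out <- out + log(pmax(dens, 1e-300))
    }
    out + log(as.numeric(model$prior[cl]))
  })
  # posterior for SP via log-sum-exp
  mx <- apply(ll, 1, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  score <- post[, "SP"]
  list(class = score_to_class(score), score = score)
}
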