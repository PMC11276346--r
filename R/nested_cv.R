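# Shared driver: repeated class-balanced nested cross-validation over one
# or more feature tables evaluated on IDENTICAL balanced draws and fold
# assignments, so pooled out-of-fold scores are paired across tables and
# DeLong comparisons are valid.
run_balanced_cv <- function(tables, family, outer_folds = 10L,
                            inner_folds = 5L, k_features = 10L,
                            n_iters = 50L, seed = 1L, grid = NULL,
                            canary = c("none", "test_labels")) {
  canary <- match.arg(canary)
  stopifnot(family %in% CLASSIFIER_FAMILIES)
  if (is.null(grid)) grid <- default_grid(family)
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t)
      attr(t, "feature_set") %||% "set", character(1))
  labels <- tables[[1]]$group
  for (t in tables) {
    if (nrow(t) != length(labels) || !all(t$group == labels) ||
        !all(t$subject_id == tables[[1]]$subject_id))
      stop("pairing error: tables must describe the same subjects",
           call. = FALSE)
  }
  mats <- lapply(tables, function(t) {
    m <- feature_matrix(t)
    bad <- !apply(m, 2, function(col) all(is.finite(col)))
    if (any(bad)) {
      warning(sprintf("dropping %d feature(s) with missing values: %s",
                      sum(bad), paste(colnames(m)[bad], collapse = ", ")),
              call. = FALSE)
      m <- m[, !bad, drop = FALSE]
    }
    m
  })
  k_eff <- vapply(mats, function(m) min(k_features, ncol(m)), numeric(1))
  n_min <- min(table(labels))
  if (n_min < outer_folds)
    stop("stratification error: need at least 'outer_folds' subjects per class",
         call. = FALSE)

  sets <- names(tables)
  per_iter <- lapply(sets, function(s) vector("list", n_iters))
  names(per_iter) <- sets
  feat_votes <- stats::setNames(vector("list", length(sets)), sets)
  hyper_votes <- stats::setNames(vector("list", length(sets)), sets)
  confusion <- lapply(sets, function(s)
    matrix(0, 2, 2, dimnames = list(predicted = c("SP", "HC"),
                                    truth = c("SP", "HC"))))
  names(confusion) <- sets

  with_seed(seed, {
    for (it in seq_len(n_iters)) {
      idx <- balanced_subsample(labels)
      y <- droplevels(labels[idx])
      folds <- stratified_folds(y, outer_folds)
      canary_train <- if (canary == "test_labels")
        stats::rnorm(length(idx)) else NULL
      # every set sees the same RNG stream (inner-fold draws, classifier
      # initialization), so identical tables give identical results and
      # pooled scores stay paired across sets
      iter_seed <- sample.int(2147483646L, 1)
      for (s in sets) {
        set.seed(iter_seed)
        x <- mats[[s]][idx, , drop = FALSE]
        res <- cv_one_iteration(x, y, folds, family, grid,
                                inner_folds, k_eff[[s]], canary_train)
        per_iter[[s]][[it]] <- res
        feat_votes[[s]] <- c(feat_votes[[s]], res$selected)
        hyper_votes[[s]] <- c(hyper_votes[[s]], res$hyper)
        cm <- table(factor(res$class, levels = c("SP", "HC")),
                    factor(y, levels = c("SP", "HC")))
        confusion[[s]] <- confusion[[s]] + as.matrix(cm)
      }
    }
  })

  lapply(stats::setNames(sets, sets), function(s) {
    iters <- per_iter[[s]]
    metrics <- do.call(rbind, lapply(iters, function(r)
      data.frame(accuracy = r$accuracy, precision = r$precision,
                 recall = r$recall, auc = r$auc)))
    structure(list(
      family = family, feature_set = s, n_iters = n_iters,
      outer_folds = outer_folds, inner_folds = inner_folds,
      k_features = k_eff[[s]], seed = seed,
      metrics = metrics,
      summary = data.frame(
        metric = c("accuracy", "precision", "recall", "auc"),
        mean = vapply(metrics, mean, numeric(1), USE.NAMES = FALSE),
        sd = vapply(metrics, stats::sd, numeric(1), USE.NAMES = FALSE)),
      confusion = confusion[[s]],
      feature_votes = sort(table(feat_votes[[s]]), decreasing = TRUE),
      hyper_votes = sort(table(hyper_votes[[s]]), decreasing = TRUE),
      scores = lapply(iters, function(r)
        data.frame(label = r$label, score = r$score))),
      class = "nested_cv")
  })
}

# one balanced draw: stratified outer folds, in-loop MRMR + grid search,
# pooled out-of-fold scores
cv_one_iteration <- function(x, y, folds, family, grid, inner_folds,
                             k_features, canary_train = NULL) {
  n <- length(y)
  score <- numeric(n)
  class_pred <- character(n)
  selected_all <- character(0)
  hyper_all <- character(0)
  for (f in sort(unique(folds))) {
    test <- folds == f
    x_tr <- x[!test, , drop = FALSE]
    y_tr <- y[!test]
    x_te <- x[test, , drop = FALSE]
    if (!is.null(canary_train)) {
      # the canary column is noise wherever the model can learn from it
      # and equals the labels exactly on the held-out fold; any test-set
      # leakage into selection or tuning shows up as inflated accuracy
      x_tr <- cbind(x_tr, `.canary` = canary_train[!test])
      x_te <- cbind(x_te, `.canary` = as.numeric(y[test] == "SP"))
    }
    sel <- mrmr_rank(x_tr, k = k_features, y = y_tr)
    x_tr <- x_tr[, sel, drop = FALSE]
    x_te <- x_te[, sel, drop = FALSE]
    mu <- colMeans(x_tr)
    sg <- apply(x_tr, 2, stats::sd)
    sg[sg == 0] <- 1
    x_tr <- sweep(sweep(x_tr, 2, mu), 2, sg, "/")
    x_te <- sweep(sweep(x_te, 2, mu), 2, sg, "/")
    best <- tune_inner(x_tr, y_tr, family, grid, inner_folds)
    model <- clf_fit(family, x_tr, y_tr, best)
    pred <- clf_predict(family, model, x_te)
    score[test] <- pred$score
    class_pred[test] <- as.character(pred$class)
    selected_all <- c(selected_all, sel)
    hyper_all <- c(hyper_all, paste(names(best), unlist(best),
                                    sep = "=", collapse = ","))
  }
  cm <- matrix(c(sum(class_pred == "SP" & y == "SP"),
                 sum(class_pred == "HC" & y == "SP"),
                 sum(class_pred == "SP" & y == "HC"),
                 sum(class_pred == "HC" & y == "HC")), 2, 2)
  met <- confusion_metrics(cm)
  list(accuracy = met$accuracy, precision = met$precision,
       recall = met$recall, auc = roc_auc(score, y),
       score = score, class = class_pred, label = as.character(y),
       selected = selected_all, hyper = hyper_all)
}

# inner stratified CV accuracy per grid row; ties resolve to the first row
tune_inner <- function(x, y, family, grid, inner_folds) {
  if (nrow(grid) == 1L) return(as.list(grid[1, , drop = FALSE]))
  folds <- stratified_folds(y, inner_folds)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hyper <- as.list(grid[g, , drop = FALSE])
    hits <- 0L
    for (f in sort(unique(folds))) {
      te <- folds == f
      model <- tryCatch(
        clf_fit(family, x[!te, , drop = FALSE], y[!te], hyper),
        error = function(e) NULL)
      if (is.null(model)) next
      pred <- clf_predict(family, model, x[te, , drop = FALSE])
      hits <- hits + sum(pred$class == y[te])
    }
    acc[g] <- hits / length(y)
  }
  as.list(grid[which.max(acc), , drop = FALSE])
}

#' Repeated class-balanced nested cross-validation
#'
#' Evaluates one classifier family on a labeled feature table with the
#' full imbalanced-cohort protocol: each iteration draws a balanced
#' subsample (all minority subjects + an equal random draw from the
#' majority), splits it into stratified outer folds, selects features by
#' MRMR and tunes hyperparameters by grid search strictly inside the
#' training portion of each outer fold, and scores the held-out fold
#' once. Out-of-fold scores are pooled per iteration into accuracy,
#' precision, recall (positive class SP, in percent) and rank-based AUC;
#' selected features and winning hyperparameters are tallied across all
#' folds and iterations for majority-vote reporting. Results are
#' reported as mean and SD over iterations.
#'
#' @param table a [build_feature_table()] result.
#' @param family classifier family (see [default_grid()]).
#' @param outer_folds outer folds (default 10).
#' @param inner_folds inner tuning folds (default 5).
#' @param k_features MRMR features retained per fold (default 10).
#' @param n_iters balanced subsampling iterations (default 50; the full
#'   protocol uses 1000).
#' @param seed integer seed making the whole evaluation reproducible.
#' @param grid optional hyperparameter data.frame overriding
#'   [default_grid()].
#' @param canary `"none"` (default) or `"test_labels"`: append a
#'   diagnostic feature that is random noise on every training portion
#'   and equals the labels on each held-out fold. With leak-free in-loop
#'   selection it must not change accuracy; it exists to verify that.
#' @return Object of class `nested_cv`; see [print.nested_cv()].
#' @export
nested_cv <- function(table, family = CLASSIFIER_FAMILIES,
                      outer_folds = 10L, inner_folds = 5L,
                      k_features = 10L, n_iters = 50L, seed = 1L,
                      grid = NULL, canary = c("none", "test_labels")) {
  family <- match.arg(family)
  res <- run_balanced_cv(list(table), family, outer_folds, inner_folds,
                         k_features, n_iters, seed, grid, canary)
  res[[1]]
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf("<nested_cv> %s on '%s' set: %d iterations x %d outer folds\n",
              x$family, x$feature_set, x$n_iters, x$outer_folds))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    unit <- if (s$metric[i] == "auc") "" else "%"
    cat(sprintf("  %-9s %6.2f%s +/- %.2f\n", s$metric[i], s$mean[i], unit,
                s$sd[i]))
  }
  invisible(x)
}

#' @export
summary.nested_cv <- function(object, n_features = 10L, ...) {
  print(object)
  cat("top majority-vote features:\n")
  fv <- utils::head(object$feature_votes, n_features)
  for (i in seq_along(fv))
    cat(sprintf("  %-32s %d votes\n", names(fv)[i], fv[i]))
  cat("top hyperparameter choice:",
      names(object$hyper_votes)[1], "\n")
  invisible(object)
}

#' Compare feature sets with per-iteration DeLong tests
#'
#' Runs the balanced nested-CV protocol for each supplied feature table
#' on identical balanced draws and fold assignments, then compares every
#' pair of feature sets with a DeLong test on the pooled out-of-fold
#' scores of each iteration (the scores are paired subject-by-subject).
#' Per-pair z statistics are summarized by their mean across iterations
#' with the two-sided normal p of that mean; sign convention is first
#' set minus second.
#'
#' @param tables named list of 2+ [build_feature_table()] results over
#'   the same subjects (names default to their `feature_set` attribute).
#' @inheritParams nested_cv
#' @return Object of class `feature_set_comparison`: list with `results`
#'   (per-set `nested_cv` objects) and `comparisons` (data.frame with
#'   columns `pair`, `z`, `p`, `auc_a`, `auc_b`).
#' @export
compare_feature_sets <- function(tables, family = CLASSIFIER_FAMILIES,
                                 outer_folds = 10L, inner_folds = 5L,
                                 k_features = 10L, n_iters = 50L,
                                 seed = 1L, grid = NULL) {
  family <- match.arg(family)
  if (length(tables) < 2L)
    stop("need at least two feature tables to compare", call. = FALSE)
  results <- run_balanced_cv(tables, family, outer_folds, inner_folds,
                             k_features, n_iters, seed, grid)
  sets <- names(results)
  pairs <- utils::combn(sets, 2, simplify = FALSE)
  comparisons <- do.call(rbind, lapply(pairs, function(pr) {
    zs <- vapply(seq_len(results[[1]]$n_iters), function(it) {
      sa <- results[[pr[1]]]$scores[[it]]
      sb <- results[[pr[2]]]$scores[[it]]
      delong_test(sa$score, sb$score, sa$label)$z
    }, numeric(1))
    z <- mean(zs)
    data.frame(pair = paste(pr, collapse = " vs "),
               z = z, p = 2 * stats::pnorm(-abs(z)),
               auc_a = mean(results[[pr[1]]]$metrics$auc),
               auc_b = mean(results[[pr[2]]]$metrics$auc))
  }))
  structure(list(family = family, results = results,
                 comparisons = comparisons),
            class = "feature_set_comparison")
}

#' @export
print.feature_set_comparison <- function(x, ...) {
  cat(sprintf("<feature_set_comparison> %s\n", x$family))
  for (s in names(x$results))
    cat(sprintf("  %-12s accuracy %6.2f%%, AUC %.4f\n", s,
                x$results[[s]]$summary$mean[1],
                x$results[[s]]$summary$mean[4]))
  print(x$comparisons, row.names = FALSE, digits = 4)
  invisible(x)
}
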