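#' Balanced subsample of an imbalanced two-class cohort
#'
#' Returns the indices of all minority-class subjects plus an equal-sized
#' uniform draw (without replacement) from the majority class, so every
#' evaluation iteration trains and tests on `2 x n_minority` subjects
#' (e.g. 50 + 50 from a 138 HC / 50 SP cohort). The minority set is
#' identical across draws; only the majority draw varies with the RNG
#' stream.
#'
#' @param labels factor (or coercible) with exactly two classes present.
#' @return Integer vector of subject indices.
#' @export
balanced_subsample <- function(labels) {
  labels <- as.factor(labels)
  tab <- table(droplevels(labels))
  if (length(tab) != 2L)
    stop("need exactly two classes present", call. = FALSE)
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(names(tab), minority)
  n_min <- min(tab)
  idx_min <- which(labels == minority)
  idx_maj <- which(labels == majority)
  if (length(idx_maj) == n_min) draw <- idx_maj
  else draw <- sample(idx_maj, n_min)
  sort(c(idx_min, draw))
}

# stratified fold assignment: each class spread as evenly as possible
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Greedy minimum-redundancy maximum-relevance feature ranking
#'
#' Ranks features by the quotient of an F-statistic relevance (two-group
#' one-way ANOVA F against the class label) over the mean absolute
#' Pearson correlation with the already selected features (FCQ-style
#' greedy selection). For the quotient the F statistic is mapped to its
#' equivalent point-biserial correlation magnitude
#' \eqn{\sqrt{F / (F + n - 2)}}, which keeps relevance and redundancy on
#' the same bounded scale so that a near-duplicate of an already selected
#' feature is demoted below an independent weaker one. The first pick is
#' the feature with the largest F; subsequent picks maximize
#' relevance / redundancy. Constant features have zero relevance and are
#' never chosen before informative ones. The ranking is deterministic
#' given the table (ties resolve to the earlier column).
#'
#' @param table a [build_feature_table()] result, or a numeric matrix /
#'   data frame of features if `y` is supplied.
#' @param k number of features to select (0 gives an empty ranking).
#' @param y class labels when `table` is a bare matrix.
#' @return Character vector of `k` selected feature names, in selection
#'   order.
#' @export
mrmr_rank <- function(table, k = 10L, y = NULL) {
  if (inherits(table, "feature_table")) {
    x <- feature_matrix(table)
    y <- table$group
  } else {
    x <- as.matrix(table)
    if (is.null(y)) stop("supply 'y' with a bare feature matrix",
                         call. = FALSE)
  }
  y <- droplevels(as.factor(y))
  k <- as.integer(k)
  if (k == 0L) return(character(0))
  if (k > ncol(x)) stop("'k' exceeds the number of features", call. = FALSE)
  relevance <- apply(x, 2, f_stat_two_group, y = y)
  # bounded relevance: point-biserial magnitude equivalent of F
  nn <- nrow(x)
  rel_b <- ifelse(is.finite(relevance),
                  sqrt(relevance / (relevance + nn - 2)), 1)
  selected <- integer(0)
  remaining <- seq_len(ncol(x))
  abs_cor <- NULL # lazily grown redundancy rows
  for (step in seq_len(k)) {
    if (length(selected) == 0L) {
      score <- relevance[remaining]
    } else {
      red <- colMeans(abs_cor[, remaining, drop = FALSE])
      score <- rel_b[remaining] / pmax(red, 1e-12)
    }
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    row <- abs(suppressWarnings(stats::cor(x[, pick], x)))
    row[is.na(row)] <- 0
    abs_cor <- rbind(abs_cor, row)
  }
  colnames(x)[selected]
}

# two-group ANOVA F (equal-variance t^2); 0 for degenerate features
f_stat_two_group <- function(v, y) {
  if (anyNA(v) || !all(is.finite(v))) return(0)
  g1 <- v[y == levels(y)[1]]; g2 <- v[y == levels(y)[2]]
  n1 <- length(g1); n2 <- length(g2)
  sp2 <- ((n1 - 1) * stats::var(g1) + (n2 - 1) * stats::var(g2)) /
    (n1 + n2 - 2)
  num <- (mean(g1) - mean(g2))^2
  if (sp2 == 0) return(if (num == 0) 0 else Inf)
  num / (sp2 * (1 / n1 + 1 / n2))
}

#' Classification metrics from a 2x2 confusion matrix
#'
#' The matrix is indexed `[predicted, truth]` with the positive class
#' (SP) first: `m[1,1]` = true positives, `m[1,2]` = false positives,
#' `m[2,1]` = false negatives, `m[2,2]` = true negatives. Metrics are
#' returned in percent; an undefined ratio (e.g. precision with no
#' positive prediction) is `NA`.
#'
#' @param m 2x2 non-negative count matrix.
#' @return List with `accuracy`, `precision`, `recall` (percent).
#' @export
confusion_metrics <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == 2L) || any(m < 0))
    stop("'m' must be a non-negative 2x2 matrix", call. = FALSE)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- m[1, 1]; fp <- m[1, 2]; fn <- m[2, 1]; tn <- m[2, 2]
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(accuracy = 100 * (tp + tn) / total,
       precision = ratio(tp, tp + fp),
       recall = ratio(tp, tp + fn))
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC: the probability that a random positive-class score
#' exceeds a random negative-class score, ties counted one half.
#'
#' @param scores numeric classifier scores, larger = more positive-like.
#' @param labels two-class labels; the positive class is `"SP"` when
#'   present, otherwise the second factor level.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.factor(labels)
  pos_level <- if ("SP" %in% levels(labels)) "SP"
               else levels(labels)[nlevels(labels)]
  pos <- labels == pos_level
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - m * (m + 1) / 2) / (m * n)
}

# structural components of the AUC U-statistic: V10 over positives,
# V01 over negatives
delong_components <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(theta = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors evaluated on the same subjects
#' via the structural-components estimate of the variance of the AUC
#' difference: \eqn{z = (AUC_a - AUC_b) / SE(AUC_a - AUC_b)}, two-sided p
#' from the standard normal. The sign convention is `a` minus `b`:
#' positive z means the first score vector has the larger AUC. Degenerate
#' variance (e.g. identical score vectors) returns `z = 0, p = 1` by
#' convention.
#'
#' @param scores_a,scores_b paired score vectors on the same subjects.
#' @param labels two-class labels (positive class `"SP"` when present).
#' @return Object of class `roc_comparison`: list with `auc_a`, `auc_b`,
#'   `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.factor(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("score vectors and labels must have equal length", call. = FALSE)
  pos_level <- if ("SP" %in% levels(labels)) "SP"
               else levels(labels)[nlevels(labels)]
  pos <- labels == pos_level
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L)
    stop("both classes must be present", call. = FALSE)
  ca <- delong_components(scores_a, pos)
  cb <- delong_components(scores_b, pos)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$theta - cb$theta
  if (!is.finite(var_diff) || var_diff <= 1e-16) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = ca$theta, auc_b = cb$theta, z = z, p = p),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("<roc_comparison> AUC %.4f vs %.4f: z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$z, x$p))
  invisible(x)
}

#' Unpaired two-sample t-test
#'
#' Independent-samples t-test with pooled variance (the classic group
#' comparison for MRMR-selected features between SP and HC). Zero pooled
#' variance with equal means returns `t = 0, p = 1` rather than erroring.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return List with `t` and two-sided `p`.
#' @export
unpaired_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Group t-tests over feature-table columns
#'
#' Unpaired t-tests (SP minus HC) for each requested feature of a
#' labeled feature table -- the machine twin of a selected-features
#' group-comparison table.
#'
#' @param table a [build_feature_table()] result.
#' @param features feature names to test (default: all).
#' @return data.frame with columns `metric`, `t`, `p`.
#' @export
group_t_tests <- function(table, features = NULL) {
  if (is.null(features)) features <- feature_names(table)
  sp <- table$group == "SP"
  res <- lapply(features, function(f) {
    tt <- unpaired_t_test(table[[f]][sp], table[[f]][!sp])
    data.frame(metric = f, t = tt$t, p = tt$p)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
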