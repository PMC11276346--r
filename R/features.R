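#' @keywords internal
# Four SpEn-moment features named with a prefix ("X axis SpEn mean", ...).
spen_moment_features <- function(sig, prefix, window_len, hop) {
  ms <- moment_summary(spectral_entropy_profile(sig, window_len, hop))
  out <- c(ms$mean, ms$std, ms$skew, ms$kurt)
  names(out) <- paste0(prefix, c("mean", "std", "skew", "kurt"))
  out
}

# base template-entropy triple; SampEn no-match sentinel becomes NA
entropy_triple <- function(sig, params, prefix = "", suffix = "") {
  se <- sample_entropy(sig, params)
  out <- c(approx_entropy(sig, params), as.numeric(se),
           fuzzy_entropy(sig, params))
  names(out) <- paste0(prefix, c("ApEn", "SampEn", "FuzzyEn"), suffix)
  out
}

#' Kinematic complexity features of one subject
#'
#' Per calcaneus axis (X, Y, Z): ApEn, SampEn, FuzzyEn and the four
#' moments of the framewise spectral entropy, 21 features in total with
#' names such as `"X axis ApEn"` and `"Y axis SpEn mean"`.
#'
#' @param rec a subject record (element of a [generate_cohort()] cohort
#'   or the result of [read_subject_csv()]).
#' @param params an [entropy_params()] object.
#' @param spen_window,spen_hop framing of the spectral-entropy profile.
#' @return Named numeric vector of 21 features.
#' @export
extract_kinematic_features <- function(rec, params = entropy_params(),
                                       spen_window = 256L, spen_hop = 128L) {
  axes <- c(kin_x = "X axis ", kin_y = "Y axis ", kin_z = "Z axis ")
  out <- numeric(0)
  for (ch in names(axes)) {
    if (is.null(rec[[ch]]))
      stop(sprintf("record is missing channel '%s'", ch), call. = FALSE)
    sig <- rec[[ch]]
    out <- c(out,
             entropy_triple(sig, params, prefix = axes[[ch]]),
             spen_moment_features(sig, paste0(axes[[ch]], "SpEn "),
                                  spen_window, spen_hop))
  }
  out
}

#' EMG complexity features of one subject
#'
#' ApEn, SampEn, FuzzyEn and the four SpEn moments of the gastrocnemius
#' EMG, plus the multiscale ApEn/SampEn/FuzzyEn profile at decimation
#' factors 2..20 (factor 1 duplicates the base features and is omitted):
#' 7 + 3 x 19 = 64 features, multiscale names carrying their factor,
#' e.g. `"multiscale ApEn (n = 15)"`.
#'
#' @inheritParams extract_kinematic_features
#' @param scales integer decimation factors for the multiscale profile
#'   (default `2:20`).
#' @return Named numeric vector of 64 features (with default scales).
#' @export
extract_emg_features <- function(rec, params = entropy_params(),
                                 scales = 2:20,
                                 spen_window = 256L, spen_hop = 128L) {
  if (is.null(rec$emg))
    stop("record is missing channel 'emg'", call. = FALSE)
  sig <- rec$emg
  out <- c(entropy_triple(sig, params),
           spen_moment_features(sig, "SpEn ", spen_window, spen_hop))
  full <- c(1L, as.integer(scales)) # factor 1 anchors the profile contract
  for (metric in c("ApEn", "SampEn", "FuzzyEn")) {
    prof <- suppressWarnings(
      multiscale_entropy(sig, metric, factors = full, params = params))
    prof <- prof[-1L]
    names(prof) <- sprintf("multiscale %s (n = %d)", metric,
                           as.integer(scales))
    out <- c(out, prof)
  }
  out
}

#' EMG-to-kinematics conditional-entropy features
#'
#' Conditional entropy of each kinematic axis given the EMG channel
#' (zero-lag, equal-width quantization): 3 features named
#' `"CondEn EMG-X axis"` etc. Low values indicate strong neuromuscular
#' coupling (the EMG constrains the movement pattern).
#'
#' @inheritParams extract_kinematic_features
#' @param n_bins amplitude bins for the plug-in estimate (default 6).
#' @return Named numeric vector of 3 features.
#' @export
extract_coupling_features <- function(rec, n_bins = 6L) {
  axes <- c(kin_x = "X", kin_y = "Y", kin_z = "Z")
  out <- vapply(names(axes), function(ch) {
    cond_entropy(rec[[ch]], rec$emg, n_bins = n_bins)
  }, numeric(1))
  names(out) <- sprintf("CondEn EMG-%s axis", axes)
  out
}

#' Assemble a labeled feature table for a cohort
#'
#' Builds one of the three feature sets used by the classification
#' framework: `"kinematic"` (21 columns), `"emg"` (64), or `"combined"`
#' (kinematic + EMG + the 3 conditional-entropy couplings, 88). Rows
#' follow cohort order; a subject whose extraction fails is dropped with
#' a warning naming the subject and reason.
#'
#' @param cohort a `gait_cohort` (or plain list of subject records).
#' @param set_id `"kinematic"`, `"emg"` or `"combined"`.
#' @param params an [entropy_params()] object.
#' @param scales multiscale decimation factors for the EMG set.
#' @param n_bins quantization bins for the coupling features.
#' @param spen_window,spen_hop spectral-entropy framing.
#' @return A `data.frame` of class `feature_table`: column `subject_id`,
#'   factor column `group` (levels HC, SP), then the feature columns;
#'   attribute `feature_set` records `set_id`.
#' @export
build_feature_table <- function(cohort,
                                set_id = c("kinematic", "emg", "combined"),
                                params = entropy_params(), scales = 2:20,
                                n_bins = 6L,
                                spen_window = 256L, spen_hop = 128L) {
  set_id <- match.arg(set_id)
  records <- if (inherits(cohort, "gait_cohort")) cohort$records else cohort
  if (length(records) == 0L) stop("empty cohort", call. = FALSE)
  rows <- list(); ids <- character(0); groups <- character(0)
  for (rec in records) {
    feats <- tryCatch({
      switch(set_id,
        kinematic = extract_kinematic_features(rec, params,
                                               spen_window, spen_hop),
        emg = extract_emg_features(rec, params, scales,
                                   spen_window, spen_hop),
        combined = c(
          extract_kinematic_features(rec, params, spen_window, spen_hop),
          extract_emg_features(rec, params, scales, spen_window, spen_hop),
          extract_coupling_features(rec, n_bins)))
    }, error = function(e) e)
    if (inherits(feats, "error")) {
      warning(sprintf("subject %s excluded: %s", rec$subject_id,
                      conditionMessage(feats)), call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- feats
    ids <- c(ids, rec$subject_id)
    groups <- c(groups, rec$group)
  }
  if (length(rows) == 0L) stop("no subject survived extraction", call. = FALSE)
  mat <- do.call(rbind, rows)
  out <- data.frame(subject_id = ids,
                    group = factor(groups, levels = c("HC", "SP")),
                    mat, check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  attr(out, "feature_set") <- set_id
  out
}

# feature column names of a feature_table (everything but id and label)
feature_names <- function(table) {
  setdiff(colnames(table), c("subject_id", "group"))
}

# numeric feature matrix of a feature_table
feature_matrix <- function(table) {
  as.matrix(table[, feature_names(table), drop = FALSE])
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> set '%s': %d subjects x %d features (%d HC, %d SP)\n",
              attr(x, "feature_set") %||% "?", nrow(x),
              length(feature_names(x)),
              sum(x$group == "HC"), sum(x$group == "SP")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
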