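#' Decimate a signal by an integer factor
#'
#' Keeps every n-th sample starting from the first (indices 1, 1+n,
#' 1+2n, ...), the subsampling scheme used to build the multiscale
#' signal set: factor 1 returns the input unchanged; a 2000-sample record
#' decimated by 20 keeps 100 samples. The sampling frequency of the
#' output is `fs / n`. No anti-alias filter is applied; the coarse series
#' is the raw subsample.
#'
#' @param sig a [gait_signal()] or numeric vector.
#' @param n decimation factor, integer >= 1 and <= signal length.
#' @return A `gait_signal` of length `ceiling(N / n)`.
#' @export
decimate_signal <- function(sig, n) {
  sig <- as_signal(sig)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be an integer >= 1", call. = FALSE)
  if (n > length(sig$samples))
    stop("decimation factor exceeds signal length", call. = FALSE)
  if (ceiling(length(sig$samples) / n) < 2L)
    stop("decimation would leave fewer than 2 samples", call. = FALSE)
  if (n == 1L) return(sig)
  gait_signal(sig$samples[seq.int(1L, length(sig$samples), by = n)],
              sig$fs / n)
}

# Costa-style coarse graining: non-overlapping means of n samples.
coarse_grain_average <- function(sig, n) {
  sig <- as_signal(sig)
  n <- as.integer(n)
  if (n == 1L) return(sig)
  x <- sig$samples
  n_out <- length(x) %/% n
  if (n_out < 2L) stop("signal too short to coarse-grain", call. = FALSE)
  y <- colMeans(matrix(x[seq_len(n_out * n)], nrow = n))
  gait_signal(y, sig$fs / n)
}

#' Multiscale entropy profile by decimation
#'
#' Evaluates a template entropy (ApEn, SampEn or FuzzyEn) on
#' progressively coarser versions of a signal. The default scheme keeps
#' every n-th sample ("decimate"); Costa-style averaging of
#' non-overlapping blocks is available as `mode = "average"`. The
#' tolerance is recomputed from each coarse series' own standard
#' deviation, consistent with expressing r as a fraction of the SD of the
#' series actually analysed. A coarse series shorter than `10^m` samples
#' is flagged with a warning (the value is still computed while the
#' length precondition `N >= m + 2` holds, and is `NA` otherwise).
#'
#' @param sig a [gait_signal()] or numeric vector.
#' @param metric one of `"ApEn"`, `"SampEn"`, `"FuzzyEn"`.
#' @param factors ordered integer decimation factors, starting at 1
#'   (default `1:20`).
#' @param params an [entropy_params()] object.
#' @param mode `"decimate"` (default) or `"average"` coarse graining.
#' @param offset phase of the decimation grid: 0 (default) starts at the
#'   first sample.
#' @return Named numeric vector, one entry per factor (names
#'   `"n=1"`, `"n=2"`, ...). The entry at factor 1 is exactly the plain
#'   statistic on the original signal.
#' @export
multiscale_entropy <- function(sig, metric = c("SampEn", "ApEn", "FuzzyEn"),
                               factors = 1:20,
                               params = entropy_params(),
                               mode = c("decimate", "average"),
                               offset = 0L) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  sig <- as_signal(sig)
  factors <- as.integer(factors)
  if (any(diff(factors) <= 0) || factors[1] < 1L)
    stop("'factors' must be strictly increasing positive integers",
         call. = FALSE)
  offset <- as.integer(offset)
  fun <- switch(metric,
                ApEn = approx_entropy,
                SampEn = sample_entropy,
                FuzzyEn = fuzzy_entropy)
  N <- length(sig$samples)
  out <- vapply(factors, function(n) {
    x <- sig
    if (offset > 0L && n > 1L) {
      keep <- seq.int(1L + (offset %% n), N)
      x <- gait_signal(sig$samples[keep], sig$fs)
    }
    coarse <- if (mode == "decimate") decimate_signal(x, n)
              else coarse_grain_average(x, n)
    len <- length(coarse$samples)
    if (len < 10^params$m)
      warning(sprintf(
        "factor %d: coarse series has %d samples, below the 10^m = %d guidance",
        n, len, 10L^params$m), call. = FALSE)
    if (len < params$m + 2L) return(NA_real_)
    as.numeric(fun(coarse, params))
  }, numeric(1))
  names(out) <- paste0("n=", factors)
  out
}
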