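#' Shannon entropy of a discrete distribution
#'
#' \eqn{H(X) = -\sum_i p_i \log_2 p_i} in bits. Zero-probability outcomes
#' contribute nothing; the maximum \eqn{\log_2 N} is attained by the
#' uniform distribution and the minimum 0 by a deterministic one.
#'
#' @param p numeric probability vector: non-negative, summing to 1
#'   (within 1e-9).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(rep(0.25, 4)) # 2 bits
#' @export
shannon_entropy <- function(p) {
  if (!is.numeric(p) || length(p) == 0L)
    stop("'p' must be a non-empty numeric vector", call. = FALSE)
  if (any(p < 0))
    stop("invalid distribution: negative probabilities", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("invalid distribution: probabilities must sum to 1", call. = FALSE)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-origin template match counts
#'
#' For templates \eqn{y(i) = [x_i, \dots, x_{i+m-1}]} counts, for every
#' origin \eqn{i}, the number of templates within tolerance
#' (strictly \eqn{d < r}). This is the counting kernel shared by
#' approximate and sample entropy; `include_self` switches between the
#' ApEn convention (self-pairs counted, so every count is at least 1) and
#' the SampEn convention (self-pairs excluded).
#'
#' @param sig a [gait_signal()] or numeric vector.
#' @param m template length (embedding dimension).
#' @param r absolute tolerance (same unit as the samples), >= 0.
#' @param include_self count the self-pair? Default `TRUE`.
#' @param metric `"euclidean"` or `"chebyshev"` template distance.
#' @return Integer vector of length \eqn{N - m + 1}.
#' @export
template_match_counts <- function(sig, m, r, include_self = TRUE,
                                  metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  sig <- as_signal(sig)
  x <- sig$samples
  m <- as.integer(m)
  if (length(x) <= m)
    stop(sprintf("signal too short: need N > m (N = %d, m = %d)",
                 length(x), m), call. = FALSE)
  if (r < 0) stop("'r' must be non-negative", call. = FALSE)
  template_match_counts_cpp(x, m, r, include_self, metric == "chebyshev")
}

check_template_length <- function(x, m, what) {
  if (length(x) < m + 2L)
    stop(sprintf("signal too short for %s: need N >= m + 2 (N = %d, m = %d)",
                 what, length(x), m), call. = FALSE)
}

#' Approximate entropy
#'
#' \eqn{ApEn = \Phi^m(r) - \Phi^{m+1}(r)} with
#' \eqn{\Phi^m(r) = (N-m+1)^{-1} \sum_i \ln C_i^m(r)}, where
#' \eqn{C_i^m(r)} is the fraction of templates within tolerance of
#' template \eqn{i}, self-matches included (so every \eqn{C_i^m \ge
#' 1/(N-m+1)} and the logarithms are defined). The tolerance is
#' `r_frac` times the sample SD of the signal. A constant signal is
#' perfectly regular and returns 0 by convention.
#'
#' @param sig a [gait_signal()] or numeric vector.
#' @param params an [entropy_params()] object.
#' @return ApEn in nats.
#' @export
approx_entropy <- function(sig, params = entropy_params()) {
  sig <- as_signal(sig)
  x <- sig$samples
  m <- params$m
  check_template_length(x, m, "ApEn")
  r <- params$r_frac * signal_sd(sig)
  if (r == 0) return(0)
  cheb <- params$metric == "chebyshev"
  phi <- function(mm) {
    n <- length(x) - mm + 1L
    counts <- template_match_counts_cpp(x, mm, r, TRUE, cheb)
    mean(log(counts / n))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy
#'
#' \eqn{SampEn = -\ln(A/B)} where \eqn{B} and \eqn{A} are the total
#' numbers of template pairs (self-pairs excluded) within tolerance at
#' lengths \eqn{m} and \eqn{m+1}, both counted over the first
#' \eqn{N - m} template origins. Compared with ApEn it discards
#' self-matches and is less dependent on record length. When no
#' \eqn{(m+1)}-matches exist the statistic is undefined; the return value
#' is then `NA` carrying attribute `no_match = TRUE` rather than an
#' error, so callers can flag the record. Constant signals return 0.
#'
#' @inheritParams approx_entropy
#' @return SampEn in nats, or a flagged `NA` when no matches exist.
#' @export
sample_entropy <- function(sig, params = entropy_params()) {
  sig <- as_signal(sig)
  x <- sig$samples
  m <- params$m
  check_template_length(x, m, "SampEn")
  r <- params$r_frac * signal_sd(sig)
  if (r == 0) return(0)
  ab <- sampen_pair_counts_cpp(x, m, r, params$metric == "chebyshev")
  A <- ab[1]; B <- ab[2]
  if (A == 0 || B == 0)
    return(structure(NA_real_, no_match = TRUE))
  -log(A / B)
}

#' Fuzzy entropy
#'
#' SampEn-like statistic replacing the hard tolerance threshold with the
#' smooth membership \eqn{\mu(d) = \exp(-(d/r)^n)} of the distance
#' between baseline-subtracted templates
#' \eqn{\bar y(i) = [x_i - \bar x_i, \dots]}:
#' \eqn{FuzzyEn = \ln(\Phi^m / \Phi^{m+1})} with
#' \eqn{\Phi^m = (N-m)^{-1} \sum_i (N-m-1)^{-1} \sum_{j \ne i} D_{ij}^m}.
#' Continuity in \eqn{r} makes it robust for low-amplitude noisy signals
#' such as surface EMG. Constant signals return 0.
#'
#' @inheritParams approx_entropy
#' @return FuzzyEn in nats.
#' @export
fuzzy_entropy <- function(sig, params = entropy_params()) {
  sig <- as_signal(sig)
  x <- sig$samples
  m <- params$m
  check_template_length(x, m, "FuzzyEn")
  r <- params$r_frac * signal_sd(sig)
  if (r == 0) return(0)
  phi <- fuzzy_phi_cpp(x, m, r, params$fuzzy_power,
                       params$metric == "chebyshev")
  log(phi[1] / phi[2])
}

#' Framewise spectral entropy
#'
#' Slides a window across the signal and computes, per frame, the Shannon
#' entropy (natural log) of the normalized periodogram
#' \eqn{p_i = \hat P(\omega_i) / \sum_i \hat P(\omega_i)}:
#' \eqn{SpEn = -\sum_i p_i \ln p_i}. Each frame is mean-removed and the
#' positive-frequency bins (DC excluded) of a rectangular-window
#' periodogram are used, so a bin-centred sinusoid scores near 0 and
#' white noise near the maximum \eqn{\ln(\lfloor w/2 \rfloor)}. The
#' resulting vector is typically summarized by [moment_summary()].
#'
#' @param sig a [gait_signal()] or numeric vector.
#' @param window_len samples per frame (default 256).
#' @param hop samples between frame starts (default 128).
#' @param normalize divide each entry by its maximum \eqn{\ln n_{bins}}
#'   so values lie in `[0, 1]`? Default `FALSE`.
#' @return Numeric vector of length
#'   `floor((N - window_len) / hop) + 1`.
#' @export
spectral_entropy_profile <- function(sig, window_len = 256L, hop = 128L,
                                     normalize = FALSE) {
  sig <- as_signal(sig)
  x <- sig$samples
  window_len <- as.integer(window_len)
  hop <- as.integer(hop)
  if (window_len <= 0L || hop <= 0L || hop > window_len)
    stop("need 0 < hop <= window_len", call. = FALSE)
  if (window_len > length(x))
    stop("window longer than signal", call. = FALSE)
  n_bins <- window_len %/% 2L
  starts <- seq.int(1L, length(x) - window_len + 1L, by = hop)
  vapply(starts, function(s) {
    seg <- x[s:(s + window_len - 1L)]
    seg <- seg - mean(seg)
    pw <- Mod(stats::fft(seg))^2
    pw <- pw[2:(n_bins + 1L)]
    tot <- sum(pw)
    if (tot <= 0) return(0)
    p <- pw / tot
    p <- p[p > 0]
    h <- -sum(p * log(p))
    if (normalize) h / log(n_bins) else h
  }, numeric(1))
}

#' First four moments of a value vector
#'
#' Mean, standard deviation (sample, n-1), skewness and kurtosis. The
#' kurtosis is the raw fourth standardized moment (a normal sample gives
#' ~3), not excess kurtosis. For a zero-variance vector skewness and
#' kurtosis are undefined and returned as `NA` with `degenerate = TRUE`.
#'
#' @param v numeric vector of length >= 4.
#' @return A list of class `moment_summary` with elements `mean`, `std`,
#'   `skew`, `kurt` and logical `degenerate`.
#' @export
moment_summary <- function(v) {
  if (!is.numeric(v) || length(v) < 4L)
    stop("need at least 4 values for the four moments", call. = FALSE)
  mu <- mean(v)
  s <- stats::sd(v)
  d <- v - mu
  m2 <- mean(d^2)
  if (m2 == 0) {
    out <- list(mean = mu, std = 0, skew = NA_real_, kurt = NA_real_,
                degenerate = TRUE)
  } else {
    out <- list(mean = mu, std = s,
                skew = mean(d^3) / m2^1.5,
                kurt = mean(d^4) / m2^2,
                degenerate = FALSE)
  }
  class(out) <- "moment_summary"
  out
}

#' @export
print.moment_summary <- function(x, ...) {
  cat(sprintf("<moment_summary> mean %.4g, std %.4g, skew %.4g, kurt %.4g%s\n",
              x$mean, x$std, x$skew, x$kurt,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# Equal-width quantization of a signal over its own observed range.
# A constant signal maps entirely to bin 1.
quantize_signal <- function(x, n_bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep.int(1L, length(x)))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Conditional entropy from a joint probability table
#'
#' Plug-in \eqn{H(Y|X) = -\sum_{x,y} p(x,y) \log_2 p(y|x)}, i.e. the
#' entropy of the conditional distribution averaged over the
#' conditioning variable. Rows index the conditioning variable X,
#' columns the target Y.
#'
#' @param joint non-negative matrix summing to 1 (within 1e-9).
#' @return Conditional entropy in bits.
#' @examples
#' cond_entropy_from_joint(rbind(c(0.5, 0), c(0.25, 0.25))) # 0.5 bits
#' @export
cond_entropy_from_joint <- function(joint) {
  joint <- as.matrix(joint)
  if (any(joint < 0) || abs(sum(joint) - 1) > 1e-9)
    stop("invalid joint distribution", call. = FALSE)
  px <- rowSums(joint)
  h <- 0
  for (i in seq_len(nrow(joint))) {
    if (px[i] == 0) next
    py_x <- joint[i, ] / px[i]
    py_x <- py_x[py_x > 0]
    h <- h - px[i] * sum(py_x * log2(py_x))
  }
  unname(h)
}

#' Conditional entropy of one signal given another
#'
#' Both signals are quantized to `n_bins` equal-width amplitude bins over
#' their own observed ranges; the joint histogram at equal sample indices
#' (zero lag) yields the plug-in estimate of \eqn{H(Y|X)} in bits. The
#' estimate is bounded by \eqn{0 \le H(Y|X) \le H(Y)}, reaching 0 when Y
#' is (bin-wise) a function of X on the sample and \eqn{H(Y)} when the
#' conditioning signal carries no information (a constant X returns
#' \eqn{H(Y)} exactly). Applied to gait kinematics conditioned on EMG it
#' probes how strongly muscle activity constrains the movement pattern.
#'
#' @param target the signal whose residual uncertainty is measured (Y).
#' @param given the conditioning signal (X); same length as `target`.
#' @param n_bins number of amplitude bins (>= 2, default 6).
#' @return Conditional entropy in bits.
#' @export
cond_entropy <- function(target, given, n_bins = 6L) {
  target <- as_signal(target); given <- as_signal(given)
  if (length(target$samples) != length(given$samples))
    stop("alignment error: signals differ in length", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("'n_bins' must be >= 2", call. = FALSE)
  qy <- quantize_signal(target$samples, n_bins)
  qx <- quantize_signal(given$samples, n_bins)
  joint <- table(factor(qx, levels = seq_len(n_bins)),
                 factor(qy, levels = seq_len(n_bins)))
  cond_entropy_from_joint(joint / sum(joint))
}

#' Shannon entropy of an amplitude-quantized signal
#'
#' Quantizes the signal with the same equal-width scheme as
#' [cond_entropy()] and returns the plug-in Shannon entropy (bits) of the
#' bin occupancy -- the upper bound of `cond_entropy(sig, given, n_bins)`
#' for any conditioning signal.
#'
#' @inheritParams cond_entropy
#' @param sig a [gait_signal()] or numeric vector.
#' @return Entropy in bits.
#' @export
quantized_entropy <- function(sig, n_bins = 6L) {
  sig <- as_signal(sig)
  q <- quantize_signal(sig$samples, as.integer(n_bins))
  shannon_entropy(as.vector(table(q)) / length(q))
}
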