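#' Construct a uniformly sampled signal
#'
#' A `gait_signal` is the unit on which all entropy computations operate:
#' an ordered vector of real samples together with its sampling frequency.
#' EMG channels are typically mV-scale, marker trajectories mm-scale; the
#' entropy statistics are invariant to the unit because tolerances are
#' expressed as fractions of the signal's own standard deviation.
#'
#' @param samples numeric vector of at least two finite values.
#' @param fs sampling frequency in Hz (positive scalar).
#' @return An object of class `gait_signal`: a list with elements
#'   `samples` and `fs`.
#' @examples
#' s <- gait_signal(sin(2 * pi * 5 * seq(0, 1, by = 1e-3)), fs = 1000)
#' s
#' @export
gait_signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a signal needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("all samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a positive scalar (Hz)", call. = FALSE)
  structure(list(samples = samples, fs = as.numeric(fs)),
            class = "gait_signal")
}

#' @export
print.gait_signal <- function(x, ...) {
  cat(sprintf("<gait_signal> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.gait_signal <- function(x) length(x$samples)

# Accept either a gait_signal or a bare numeric vector (fs defaulting to 1)
# so the entropy statistics remain usable on plain vectors.
as_signal <- function(x, fs = 1) {
  if (inherits(x, "gait_signal")) return(x)
  gait_signal(x, fs)
}

#' Parameters for template-based entropy statistics
#'
#' Houses the embedding dimension \eqn{m}, the tolerance expressed as a
#' fraction of the analysed series' standard deviation, the exponent of
#' the fuzzy membership function and the template distance metric.
#' Physiological-signal practice uses \eqn{m} between 1 and 3 and a
#' tolerance of 0.1--0.25 SD; the defaults (`m = 2`, `r_frac = 0.2`) are
#' the settings used throughout the gait/EMG analysis this package
#' implements.
#'
#' @param m embedding dimension, integer >= 1.
#' @param r_frac tolerance as a fraction of the signal SD, in (0, 1).
#' @param fuzzy_power exponent of the fuzzy membership function
#'   \eqn{\mu(d) = \exp(-(d/r)^n)}; >= 1, default 2.
#' @param metric template distance: `"euclidean"` (default) or
#'   `"chebyshev"`.
#' @return An object of class `entropy_params`.
#' @export
entropy_params <- function(m = 2L, r_frac = 0.2, fuzzy_power = 2,
                           metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("'m' must be an integer >= 1", call. = FALSE)
  if (!is.numeric(r_frac) || r_frac <= 0 || r_frac >= 1)
    stop("'r_frac' must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(fuzzy_power) || fuzzy_power < 1)
    stop("'fuzzy_power' must be >= 1", call. = FALSE)
  structure(list(m = m, r_frac = r_frac, fuzzy_power = fuzzy_power,
                 metric = metric),
            class = "entropy_params")
}

#' @export
print.entropy_params <- function(x, ...) {
  cat(sprintf("<entropy_params> m = %d, r = %.3g * SD, fuzzy power = %g, %s distance\n",
              x$m, x$r_frac, x$fuzzy_power, x$metric))
  invisible(x)
}

# Sample SD of a signal; the tolerance basis for all template entropies.
signal_sd <- function(sig) stats::sd(sig$samples)

# run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
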