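#' Specification of a synthetic two-group gait cohort
#'
#' Defines the statistical structure of a simulated cohort of able-bodied
#' controls (HC) and stroke survivors (SP): one gastrocnemius EMG channel
#' and three calcaneus coordinate channels per subject, 2000 samples at
#' 1000 Hz spanning two strides. Group differences are parameterized on a
#' standardized scale: `emg_effect` controls how much more regular (less
#' complex) the SP burst carrier is, `kin_effect` how much more irregular
#' the SP stride trajectory is, and the coupling parameters how strongly
#' the EMG envelope drives the kinematics in each group (SP coupling is
#' weaker by default, reflecting disrupted neuromuscular control; the
#' direction of every difference is configurable because group ordering
#' is not identifiable from summary statistics alone).
#'
#' @param n_control number of HC subjects (default 138).
#' @param n_patient number of SP subjects (default 50).
#' @param fs sampling frequency in Hz (default 1000).
#' @param n_samples record length in samples (default 2000, two strides).
#' @param emg_effect standardized SP-vs-HC difference in EMG carrier
#'   regularity (default 2; 0 gives identically distributed groups).
#' @param kin_effect standardized SP-vs-HC difference in kinematic
#'   irregularity (default 1).
#' @param coupling_control,coupling_patient EMG-envelope-to-kinematics
#'   coupling strength per group, in `[0, 1]` (defaults 0.6 and 0.2).
#' @param seed integer random seed; every generated record is a pure
#'   function of `(spec, subject index)`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 138L, n_patient = 50L, fs = 1000,
                        n_samples = 2000L, emg_effect = 2,
                        kin_effect = 1, coupling_control = 0.6,
                        coupling_patient = 0.2, seed = 1L) {
  stopifnot(n_control >= 1L, n_patient >= 1L, fs > 0, n_samples >= 4L,
            emg_effect >= 0, kin_effect >= 0,
            coupling_control >= 0, coupling_control <= 1,
            coupling_patient >= 0, coupling_patient <= 1)
  structure(list(n_control = as.integer(n_control),
                 n_patient = as.integer(n_patient),
                 fs = fs, n_samples = as.integer(n_samples),
                 emg_effect = emg_effect, kin_effect = kin_effect,
                 coupling_control = coupling_control,
                 coupling_patient = coupling_patient,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d HC / %d SP, %d samples @ %g Hz\n",
                     "  emg_effect %.2f, kin_effect %.2f, coupling HC %.2f / SP %.2f, seed %d\n"),
              x$n_control, x$n_patient, x$n_samples, x$fs,
              x$emg_effect, x$kin_effect, x$coupling_control,
              x$coupling_patient, x$seed))
  invisible(x)
}

# moving-average smoother with edge renormalization
ma_smooth <- function(x, w) {
  if (w <= 1L) return(x)
  k <- rep(1 / w, w)
  as.numeric(stats::filter(x, k, sides = 2, circular = TRUE))
}

# two gaussian burst activation profiles per record ("two subsequent
# strides"), gastrocnemius-like: bursts in late stance, jittered per
# subject; rides on a tonic baseline
emg_envelope <- function(spec) {
  N <- spec$n_samples
  stride <- N / 2
  t <- seq_len(N)
  centers <- (c(0, 1) + 0.45) * stride + stats::rnorm(2, 0, 0.03 * stride)
  widths <- 0.25 * stride * exp(stats::rnorm(2, 0, 0.15))
  # tonic baseline keeps the amplitude histogram of the modulated noise
  # broad, so zero-coupling kinematics stay near-independent of the EMG
  env <- rep(0.7, N)
  for (k in 1:2)
    env <- env + exp(-(t - centers[k])^2 / (2 * widths[k]^2))
  env
}

#' Generate one synthetic EMG record
#'
#' Burst-modulated broadband noise: a baseline-plus-two-bursts activation
#' profile (gastrocnemius over two strides, with per-subject timing and
#' width jitter) multiplies a noise carrier. In the SP group the carrier
#' is smoothed by a moving average whose width grows with `emg_effect`,
#' lowering its template-entropy complexity; with `emg_effect = 0` the
#' two groups are identically distributed. The linear envelope of the
#' result (40 ms rectified moving average, the standard surface-EMG
#' amplitude estimate) is attached as attribute `"envelope"` and is the
#' signal the kinematics couple to. Consumes the current RNG stream;
#' seed it (e.g. via [generate_cohort()]) for reproducibility.
#'
#' @param group `"HC"` or `"SP"`.
#' @param spec a [cohort_spec()].
#' @return A `gait_signal` with the measured linear envelope attached as
#'   attribute `"envelope"`.
#' @export
generate_emg <- function(group = c("HC", "SP"), spec = cohort_spec()) {
  group <- match.arg(group)
  N <- spec$n_samples
  env <- emg_envelope(spec)
  carrier <- stats::rnorm(N)
  if (group == "SP" && spec$emg_effect > 0) {
    w <- 1 + spec$emg_effect * 2 * exp(stats::rnorm(1, 0, 0.1))
    carrier <- ma_smooth(carrier, as.integer(round(w)))
    carrier <- carrier / stats::sd(carrier)
  }
  sig <- gait_signal(0.5 * env * carrier, spec$fs)
  attr(sig, "envelope") <- ma_smooth(abs(sig$samples),
                                     as.integer(round(0.04 * spec$fs)))
  sig
}

#' Generate synthetic three-axis calcaneus kinematics
#'
#' Each axis is a convex mixture of (i) a quasi-periodic two-cycle stride
#' waveform (three harmonics with per-subject random phases, amplitude
#' modulated by slow irregularity noise whose variance grows with
#' `kin_effect` in the SP group) and (ii) the standardized measured EMG
#' envelope, weighted by the group's coupling strength, plus measurement
#' noise. Because the envelope carries the EMG carrier's randomness, the
#' zero-lag conditional entropy of each axis given the raw EMG decreases
#' genuinely with coupling. At coupling 1 and vanishing noise each axis
#' becomes a pointwise function of the envelope (conditional entropy
#' given the envelope tends to 0); at coupling 0 the axes are generated
#' independently of the EMG.
#'
#' @param group `"HC"` or `"SP"`.
#' @param emg_envelope numeric envelope of length `spec$n_samples`
#'   (attribute `"envelope"` of [generate_emg()] output).
#' @param spec a [cohort_spec()].
#' @param meas_noise_sd measurement noise SD in mm (default 2.5).
#' @return Named list of `gait_signal`s: `kin_x`, `kin_y`, `kin_z`.
#' @export
generate_kinematics <- function(group = c("HC", "SP"), emg_envelope,
                                spec = cohort_spec(), meas_noise_sd = 2.5) {
  group <- match.arg(group)
  N <- spec$n_samples
  if (length(emg_envelope) != N)
    stop("alignment error: envelope length must equal n_samples",
         call. = FALSE)
  coupling <- if (group == "SP") spec$coupling_patient
              else spec$coupling_control
  f0 <- spec$fs / (N / 2) # stride frequency, Hz
  t <- (seq_len(N) - 1) / spec$fs
  amps <- list(kin_x = c(20, 8, 3), kin_y = c(10, 4, 2),
               kin_z = c(30, 12, 4)) # mm-scale harmonic amplitudes
  irr_sd <- 0.08 * (1 + if (group == "SP") spec$kin_effect else 0)
  env_std <- (emg_envelope - mean(emg_envelope)) / stats::sd(emg_envelope)
  out <- lapply(amps, function(a) {
    phases <- stats::runif(3, 0, 2 * pi)
    base <- Reduce(`+`, lapply(1:3, function(k)
      a[k] * sin(2 * pi * k * f0 * t + phases[k])))
    irr <- ma_smooth(stats::rnorm(N, 0, irr_sd), 100L)
    irr <- irr * irr_sd / max(stats::sd(irr), 1e-12)
    scale_mm <- sqrt(sum(a^2) / 2) # RMS of the harmonic stack
    x <- (1 - coupling) * base * (1 + irr) +
      coupling * scale_mm * env_std +
      stats::rnorm(N, 0, meas_noise_sd)
    gait_signal(x, spec$fs)
  })
  names(out) <- names(amps)
  out
}

# deterministic child seed per subject, kept inside 32-bit integer range
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 104729) %% 2147483647)
}

#' Generate a full synthetic cohort
#'
#' Produces `n_control + n_patient` subject records, each with one EMG
#' and three kinematic channels sharing sampling rate and length. Every
#' record is a pure function of `(spec, subject index)`: per-subject
#' seeds are derived deterministically from `spec$seed`, so the same spec
#' always yields a bit-identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `gait_cohort`: a list with `spec` and
#'   `records`, the latter a list of subject records (fields
#'   `subject_id`, `group`, `emg`, `kin_x`, `kin_y`, `kin_z`).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_control = 2, n_patient = 1))
#' coh
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c(rep("HC", spec$n_control), rep("SP", spec$n_patient))
  ids <- c(sprintf("HC%03d", seq_len(spec$n_control)),
           sprintf("SP%03d", seq_len(spec$n_patient)))
  records <- lapply(seq_along(groups), function(i) {
    with_seed(child_seed(spec$seed, i), {
      emg <- generate_emg(groups[i], spec)
      kin <- generate_kinematics(groups[i], attr(emg, "envelope"), spec)
      c(list(subject_id = ids[i], group = groups[i], emg = emg), kin)
    })
  })
  structure(list(spec = spec, records = records), class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  groups <- vapply(x$records, `[[`, character(1), "group")
  cat(sprintf("<gait_cohort> %d subjects (%d HC, %d SP), %d samples @ %g Hz\n",
              length(x$records), sum(groups == "HC"), sum(groups == "SP"),
              x$spec$n_samples, x$spec$fs))
  invisible(x)
}

#' @export
length.gait_cohort <- function(x) length(x$records)
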