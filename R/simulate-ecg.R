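#' Exercise-test protocol description
#'
#' Defines the phase structure of the bicycle exercise stress test the
#' generator emulates: a short resting period, a graded exercise phase,
#' and a recovery phase without pedalling.  RR targets give the mean
#' inter-beat interval at rest, at peak exercise, and at full recovery;
#' the generator ramps RR linearly from `rr_rest` to `rr_peak` during
#' exercise and relaxes it exponentially towards `rr_recovery` during
#' recovery (time constant `tau_recovery_s`).
#'
#' @param rest_s,exercise_s,recovery_s phase durations in seconds
#'   (defaults: 15 s rest, 6 min exercise, 1 min recovery).
#' @param rr_rest,rr_peak,rr_recovery RR interval targets in ms; must
#'   satisfy `0 < rr_peak < rr_rest` and `rr_peak < rr_recovery`.
#' @param tau_recovery_s time constant (s) of the exponential RR
#'   relaxation during recovery.
#' @return an object of class `exercise_protocol`.
#' @export
exercise_protocol <- function(rest_s = 15, exercise_s = 360, recovery_s = 60,
                              rr_rest = 1000, rr_peak = 600, rr_recovery = 900,
                              tau_recovery_s = 10) {
  check_positive(rest_s, "rest_s"); check_positive(exercise_s, "exercise_s")
  check_positive(recovery_s, "recovery_s")
  check_positive(rr_rest, "rr_rest"); check_positive(rr_peak, "rr_peak")
  check_positive(rr_recovery, "rr_recovery")
  check_positive(tau_recovery_s, "tau_recovery_s")
  if (!(rr_peak < rr_rest)) stop_invalid("rr_peak must be smaller than rr_rest")
  if (!(rr_peak < rr_recovery)) stop_invalid("rr_peak must be smaller than rr_recovery")
  structure(list(rest_s = rest_s, exercise_s = exercise_s, recovery_s = recovery_s,
                 rr_rest = rr_rest, rr_peak = rr_peak, rr_recovery = rr_recovery,
                 tau_recovery_s = tau_recovery_s),
            class = "exercise_protocol")
}

#' Synthetic QRS-T beat template
#'
#' A stylised single-lead beat: a narrow triphasic QRS (small negative Q,
#' tall R, small negative S Gaussians) followed by a Gaussian T-wave.
#' The Gaussian T-wave gives closed-form fiducials: the steepest
#' post-peak descent is at one T-width (`sigma`) after the apex, and the
#' tangent at that point crosses the baseline at two T-widths after the
#' apex, so the ground-truth Tpeak-to-Tend interval is exactly
#' `2 * t_sigma`.
#'
#' `t_center_offset` is measured from QRS onset; internally QRS onset is
#' 30 ms before the R peak.
#'
#' @param qrs_amplitude R-wave amplitude in mV.
#' @param t_amplitude T-wave amplitude in mV (may be negative for an
#'   inverted T; must be non-zero).
#' @param t_center_offset T-wave apex position, ms after QRS onset.
#' @param t_sigma Gaussian T-wave half-width in ms; ground-truth
#'   Tpe is `2 * t_sigma`.
#' @return an object of class `beat_template`.
#' @export
beat_template <- function(qrs_amplitude = 1.0, t_amplitude = 0.3,
                          t_center_offset = 300, t_sigma = 31) {
  check_positive(qrs_amplitude, "qrs_amplitude")
  check_positive(t_sigma, "t_sigma")
  check_positive(t_center_offset, "t_center_offset")
  if (!is.numeric(t_amplitude) || t_amplitude == 0)
    stop_invalid("t_amplitude must be non-zero")
  structure(list(qrs_amplitude = qrs_amplitude, t_amplitude = t_amplitude,
                 t_center_offset = t_center_offset, t_sigma = t_sigma,
                 qrs_onset_before_r = 30, tpe_true = 2 * t_sigma),
            class = "beat_template")
}

# RR interval (ms) at absolute time t (s) under the protocol.
rr_at <- function(t, protocol) {
  p <- protocol
  t_ex <- p$rest_s
  t_rec <- p$rest_s + p$exercise_s
  ifelse(t < t_ex, p$rr_rest,
         ifelse(t < t_rec,
                p$rr_rest + (p$rr_peak - p$rr_rest) * (t - t_ex) / p$exercise_s,
                p$rr_recovery - (p$rr_recovery - p$rr_peak) *
                  exp(-(t - t_rec) / p$tau_recovery_s)))
}

# Ground-truth Tpe (ms) at absolute time t (s): constant at rest, linear
# ramp during exercise, exponential relaxation during recovery (same time
# constant as RR).
tpe_at <- function(t, protocol, tpe_by_phase) {
  p <- protocol
  t_ex <- p$rest_s
  t_rec <- p$rest_s + p$exercise_s
  ifelse(t < t_ex, tpe_by_phase[1],
         ifelse(t < t_rec,
                tpe_by_phase[1] + (tpe_by_phase[2] - tpe_by_phase[1]) *
                  (t - t_ex) / p$exercise_s,
                tpe_by_phase[3] - (tpe_by_phase[3] - tpe_by_phase[2]) *
                  exp(-(t - t_rec) / p$tau_recovery_s)))
}

# Add a Gaussian bump (centre s, width sigma, both seconds) to `sig`
# in place-ish; evaluated only on its +-8 sigma support (truncation
# error ~1e-14 of the amplitude, so identical beats stay identical to
# numerical precision wherever the support boundary lands).
add_bump <- function(sig, fs, center, sigma, amp) {
  i0 <- max(1L, floor((center - 8 * sigma) * fs) + 1L)
  i1 <- min(length(sig), ceiling((center + 8 * sigma) * fs) + 1L)
  if (i0 > i1) return(sig)
  t <- (seq.int(i0, i1) - 1) / fs
  sig[i0:i1] <- sig[i0:i1] + amp * exp(-((t - center)^2) / (2 * sigma^2))
  sig
}

#' Simulate a single-lead exercise-stress-test ECG
#'
#' Lays down beats whose spacing follows the protocol's RR profile
#' (constant at rest, linear ramp during exercise, exponential
#' relaxation during recovery) and whose T-wave width follows the
#' phase-specific ground-truth Tpe (`tpe_by_phase`, via
#' `t_sigma = tpe / 2`).  Ground truth (beat times, per-beat RR and Tpe)
#' is stored alongside the signal and is never consulted by the
#' processing pipeline.
#'
#' @param protocol an [exercise_protocol()].
#' @param template a [beat_template()].
#' @param tpe_by_phase length-3 numeric: ground-truth Tpe (ms) at rest,
#'   peak exercise, and full recovery.
#' @param noise_sd additive white-noise standard deviation, mV.
#' @param wander_amp amplitude (mV) of a 0.2 Hz baseline-wander sinusoid
#'   with random phase.
#' @param fs sampling rate, Hz (default 500).
#' @param seed RNG seed (used even when both noise terms are zero, for a
#'   uniform interface).
#' @return an object of class `ecg_recording` with elements `signal`
#'   (mV), `fs`, `annotations` (phase, start_s, end_s), and `truth`
#'   (per-beat time, phase, RR, Tpe).
#' @export
simulate_ecg <- function(protocol, template, tpe_by_phase = c(62, 55, 60),
                         noise_sd = 0, wander_amp = 0, fs = 500, seed = 1L) {
  stopifnot(inherits(protocol, "exercise_protocol"),
            inherits(template, "beat_template"))
  check_positive(fs, "fs")
  if (length(tpe_by_phase) != 3L || any(!is.finite(tpe_by_phase)) ||
      any(tpe_by_phase <= 0))
    stop_invalid("tpe_by_phase must be three positive Tpe values (ms)")
  if (noise_sd < 0 || wander_amp < 0)
    stop_invalid("noise_sd and wander_amp must be non-negative")

  total_s <- protocol$rest_s + protocol$exercise_s + protocol$recovery_s
  n <- round(total_s * fs)
  sig <- numeric(n)

  # place beats: first R peak at 0.1 s, stop early enough that the last
  # T-wave has full support inside the record
  beat_t <- numeric(0)
  t <- 0.1
  while (t < total_s - 0.6) {
    beat_t <- c(beat_t, t)
    t <- t + rr_at(t, protocol) / 1000
  }
  rr_ms <- rr_at(beat_t, protocol)
  tpe_ms <- tpe_at(beat_t, protocol, tpe_by_phase)

  t_center <- (template$t_center_offset - template$qrs_onset_before_r) / 1000
  for (k in seq_along(beat_t)) {
    bt <- beat_t[k]
    a <- template$qrs_amplitude
    sig <- add_bump(sig, fs, bt - 0.020, 0.005, -0.12 * a)  # Q
    sig <- add_bump(sig, fs, bt,          0.008,  a)        # R
    sig <- add_bump(sig, fs, bt + 0.022,  0.006, -0.18 * a) # S
    sig <- add_bump(sig, fs, bt + t_center, tpe_ms[k] / 2000,
                    template$t_amplitude)                   # T
  }

  sig <- with_seed(seed, {
    if (wander_amp > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      tt <- (seq_len(n) - 1) / fs
      sig <- sig + wander_amp * sin(2 * pi * 0.2 * tt + ph)
    }
    if (noise_sd > 0) sig <- sig + stats::rnorm(n, 0, noise_sd)
    sig
  })

  ann <- data.frame(
    phase = c("rest", "exercise", "recovery"),
    start_s = c(0, protocol$rest_s, protocol$rest_s + protocol$exercise_s),
    end_s = c(protocol$rest_s, protocol$rest_s + protocol$exercise_s, total_s))
  phase_of <- function(t) ann$phase[findInterval(t, ann$start_s)]

  structure(list(
    signal = sig, fs = fs, annotations = ann,
    truth = data.frame(beat = seq_along(beat_t), time_s = beat_t,
                       phase = phase_of(beat_t), rr_ms = rr_ms,
                       tpe_ms = tpe_ms),
    protocol = protocol, template = template),
    class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> %.1f s @ %g Hz, %d beats (%s)\n",
              length(x$signal) / x$fs, x$fs, nrow(x$truth),
              paste(x$annotations$phase, collapse = "/")))
  invisible(x)
}

#' Simulate an exercise-test ECG cohort
#'
#' Generates `n` recordings under the standard protocol with
#' inter-individual variation in resting / peak / recovery RR and
#' T-wave amplitude, but a common ground-truth Tpe profile (so cohort
#' summaries of the recovered Tpe can be compared against a known
#' generating value).  `measure_ecg_cohort()` runs the full measurement
#' pipeline over such a cohort.
#'
#' @param n number of individuals.
#' @param tpe_by_phase ground-truth Tpe (ms) at rest / peak / recovery,
#'   shared by all individuals.
#' @param noise_sd,wander_amp per-recording noise parameters (mV).
#' @param fs sampling rate, Hz.
#' @param seed RNG seed; individual-level seeds are derived from it.
#' @return list of `ecg_recording` objects (names = individual ids).
#' @export
simulate_ecg_cohort <- function(n, tpe_by_phase = c(62, 55, 60),
                                noise_sd = 0, wander_amp = 0, fs = 500,
                                seed = 1L) {
  check_positive(n, "n")
  pars <- with_seed(seed, data.frame(
    rr_rest = stats::runif(n, 900, 1100),
    rr_peak = stats::runif(n, 550, 680),
    rr_recovery = stats::runif(n, 800, 1000),
    t_amp = stats::runif(n, 0.25, 0.4)))
  recs <- lapply(seq_len(n), function(i) {
    proto <- exercise_protocol(rr_rest = pars$rr_rest[i],
                               rr_peak = pars$rr_peak[i],
                               rr_recovery = pars$rr_recovery[i])
    simulate_ecg(proto, beat_template(t_amplitude = pars$t_amp[i],
                                      t_sigma = tpe_by_phase[1] / 2),
                 tpe_by_phase = tpe_by_phase, noise_sd = noise_sd,
                 wander_amp = wander_amp, fs = fs, seed = seed + i)
  })
  names(recs) <- sprintf("id%06d", seq_len(n))
  recs
}

#' @rdname simulate_ecg_cohort
#' @param recs list of recordings from [simulate_ecg_cohort()].
#' @return `measure_ecg_cohort` returns a data.frame of per-individual
#'   pipeline measurements (one row per recording, `id` column first).
#' @export
measure_ecg_cohort <- function(recs) {
  out <- do.call(rbind, lapply(recs, process_recording))
  cbind(data.frame(id = names(recs), stringsAsFactors = FALSE), out,
        row.names = NULL)
}

#' Write / read an ECG recording as delimited text
#'
#' The signal is written as two tab-separated columns (`time_s`, `mv`)
#' and the phase annotations as a sidecar TSV (`phase`, `start_s`,
#' `end_s`).  `read_ecg` reconstructs an `ecg_recording` (without
#' generator ground truth).
#'
#' @param rec an `ecg_recording`.
#' @param signal_path,annotation_path output/input file paths.
#' @return `read_ecg` returns an `ecg_recording`.
#' @export
write_ecg <- function(rec, signal_path, annotation_path) {
  stopifnot(inherits(rec, "ecg_recording"))
  df <- data.frame(time_s = (seq_along(rec$signal) - 1) / rec$fs,
                   mv = rec$signal)
  utils::write.table(df, signal_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(rec$annotations, annotation_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(signal_path, annotation_path))
}

#' @rdname write_ecg
#' @export
read_ecg <- function(signal_path, annotation_path) {
  df <- utils::read.delim(signal_path)
  ann <- utils::read.delim(annotation_path)
  stopifnot(all(c("time_s", "mv") %in% names(df)),
            all(c("phase", "start_s", "end_s") %in% names(ann)))
  if (nrow(df) < 2L) stop_invalid("signal file has fewer than 2 samples")
  fs <- 1 / stats::median(diff(df$time_s))
  structure(list(signal = df$mv, fs = fs, annotations = ann, truth = NULL,
                 protocol = NULL, template = NULL),
            class = "ecg_recording")
}
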