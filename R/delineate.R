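# Time (ms) of sample i on the beat's own timebase (R peak at 0 for
# beats produced by average_beats()).
beat_times_ms <- function(beat) {
  beat$t0_ms + (seq_along(beat$waveform) - 1) * 1000 / beat$fs
}

# Isoelectric baseline: median of a 40 ms segment ending at `before_ms`
# (typically QRS onset); falls back to the first 40 ms of the beat.
beat_baseline <- function(beat, before_ms = NULL) {
  t <- beat_times_ms(beat)
  if (!is.null(before_ms)) {
    sel <- t >= before_ms - 40 & t < before_ms
    if (sum(sel) >= 3L) return(stats::median(beat$waveform[sel]))
  }
  stats::median(beat$waveform[t < t[1] + 40])
}

# Locate QRS onset/offset around the aligned R peak (time 0) by scanning
# for a sustained (4-sample) return of |x - baseline| below a fraction
# of the R amplitude.  Used only on beats aligned by average_beats().
qrs_bounds <- function(beat, frac = 0.03, run = 4L) {
  t <- beat_times_ms(beat)
  x <- beat$waveform
  base0 <- beat_baseline(beat)
  # R fiducial = largest absolute deviation from baseline (the QRS
  # dominates the T-wave), so the bounds are time-shift invariant
  i_r <- which.max(abs(x - base0))
  dev <- abs(x - base0)
  thr <- frac * dev[i_r]
  below <- dev < thr
  sustained_at <- function(i, dir) {
    js <- i + dir * (0:(run - 1L))
    all(js >= 1L & js <= length(x)) && all(below[js])
  }
  onset <- NA_real_
  for (i in seq(i_r - 1L, 1L)) if (sustained_at(i, -1L)) { onset <- t[i]; break }
  offset <- NA_real_
  for (i in seq(i_r + 1L, length(x))) if (sustained_at(i, 1L)) { offset <- t[i]; break }
  list(onset = onset, offset = offset, i_r = i_r, baseline0 = base0)
}

#' Locate the T-wave apex on an averaged beat
#'
#' The apex is the point of maximum absolute deviation from the
#' isoelectric baseline within the search window, refined by 3-point
#' parabolic interpolation.  Polarity-invariant: an inverted T-wave
#' yields the same apex time.  A flat or monotone window (apex on the
#' window edge) is a QC failure, returned as `NA` with a `qc`
#' attribute.
#'
#' @param beat an `averaged_beat`.
#' @param search_window numeric pair, ms on the beat timebase; should
#'   start after the QRS offset.
#' @param baseline isoelectric level (mV); estimated from the beat start
#'   when `NULL`.
#' @return apex time in ms (attribute `polarity` = +-1), or `NA` with
#'   attribute `qc` on failure.
#' @export
find_t_peak <- function(beat, search_window, baseline = NULL) {
  stopifnot(inherits(beat, "averaged_beat"))
  if (is.null(baseline)) baseline <- beat_baseline(beat)
  t <- beat_times_ms(beat)
  sel <- which(t >= search_window[1] & t <= search_window[2])
  if (length(sel) < 5L)
    return(structure(NA_real_, qc = "search_window_too_short"))
  y <- beat$waveform[sel] - baseline
  if (max(y) - min(y) < 1e-9)
    return(structure(NA_real_, qc = "flat_segment"))
  k <- which.max(abs(y))
  if (k == 1L || k == length(y))
    return(structure(NA_real_, qc = "monotone_segment"))
  pol <- sign(y[k])
  # parabolic vertex through the apex sample and its neighbours
  y3 <- pol * y[(k - 1):(k + 1)]
  denom <- y3[1] - 2 * y3[2] + y3[3]
  delta <- if (abs(denom) < 1e-15) 0 else 0.5 * (y3[1] - y3[3]) / denom
  dt <- 1000 / beat$fs
  structure(t[sel[k]] + delta * dt, polarity = pol)
}

#' Locate the T-wave end by the tangent method
#'
#' Finds the point of steepest slope on the descending limb after the
#' apex (central differences) and intersects the tangent at that point
#' with the isoelectric baseline.  For a Gaussian T-wave of width sigma
#' centred at mu the steepest descent is at `mu + sigma` and the tangent
#' crosses the baseline at exactly `mu + 2 * sigma`.
#'
#' @param beat an `averaged_beat`.
#' @param t_peak apex time (ms) from [find_t_peak()].
#' @param baseline isoelectric level (mV); estimated when `NULL`.
#' @param max_after_ms how far after the apex to search for the steepest
#'   descent (ms).
#' @return T-end time in ms, or `NA` with attribute `qc` when no
#'   descending limb exists.
#' @export
find_t_end <- function(beat, t_peak, baseline = NULL, max_after_ms = 250) {
  stopifnot(inherits(beat, "averaged_beat"))
  if (is.na(t_peak)) return(structure(NA_real_, qc = "no_t_peak"))
  if (is.null(baseline)) baseline <- beat_baseline(beat)
  t <- beat_times_ms(beat)
  dt <- 1000 / beat$fs
  i_pk <- which.min(abs(t - t_peak))
  pol <- sign(beat$waveform[i_pk] - baseline)
  if (pol == 0) return(structure(NA_real_, qc = "flat_at_peak"))
  y <- pol * (beat$waveform - baseline)

  hi <- min(length(y) - 1L, i_pk + round(max_after_ms / dt))
  if (hi <= i_pk + 1L) return(structure(NA_real_, qc = "no_descending_limb"))
  idx <- (i_pk + 1L):hi
  slope <- (y[idx + 1L] - y[idx - 1L]) / (2 * dt)
  k <- which.min(slope)
  if (slope[k] >= 0) return(structure(NA_real_, qc = "no_descending_limb"))
  i_s <- idx[k]
  if (y[i_s] <= 0) return(structure(NA_real_, qc = "descent_below_baseline"))
  t[i_s] + y[i_s] / abs(slope[k])
}

#' Tpeak-to-Tend interval from fiducials
#'
#' @param fiducials list or one-row data frame with `t_peak` and `t_end`
#'   (ms).
#' @return Tpe in ms; `NA` with attribute `qc` when `t_end < t_peak` or
#'   either fiducial is missing (never silently clipped).
#' @export
tpe <- function(fiducials) {
  tp <- fiducials$t_peak; te <- fiducials$t_end
  if (is.null(tp) || is.null(te) || is.na(tp) || is.na(te))
    return(structure(NA_real_, qc = "missing_fiducial"))
  if (te < tp) return(structure(NA_real_, qc = "t_end_before_t_peak"))
  as.numeric(te - tp)
}

#' Delineate an averaged beat
#'
#' Full fiducial extraction: QRS onset/offset around the aligned R peak,
#' baseline from the 40 ms preceding QRS onset, T apex by
#' baseline-deviation argmax with parabolic refinement, T end by the
#' tangent method, and the Tpe interval.
#'
#' @param beat an `averaged_beat` (aligned on the R peak at time 0).
#' @param t_search optional explicit T search window (ms); by default
#'   from 40 ms after QRS offset to 20 ms before the beat end.
#' @return one-row data.frame: `qrs_onset`, `qrs_offset`, `t_peak`,
#'   `t_end`, `tpe` (all ms), `qc_flag` (`"pass"` or a failure reason).
#' @export
delineate_beat <- function(beat, t_search = NULL) {
  stopifnot(inherits(beat, "averaged_beat"))
  fail <- function(why) data.frame(qrs_onset = NA_real_, qrs_offset = NA_real_,
                                   t_peak = NA_real_, t_end = NA_real_,
                                   tpe = NA_real_, qc_flag = why,
                                   stringsAsFactors = FALSE)
  if (!isTRUE(beat$qc_pass)) return(fail(beat$qc_reason))
  qb <- qrs_bounds(beat)
  if (is.na(qb$onset) || is.na(qb$offset)) return(fail("qrs_bounds_not_found"))
  baseline <- beat_baseline(beat, before_ms = qb$onset)
  t <- beat_times_ms(beat)
  if (is.null(t_search)) t_search <- c(qb$offset + 40, max(t) - 20)
  tp <- find_t_peak(beat, t_search, baseline = baseline)
  if (is.na(tp)) return(fail(attr(tp, "qc")))
  te <- find_t_end(beat, tp, baseline = baseline)
  if (is.na(te)) return(fail(attr(te, "qc")))
  iv <- tpe(list(t_peak = tp, t_end = te))
  if (is.na(iv)) return(fail(attr(iv, "qc")))
  data.frame(qrs_onset = qb$onset, qrs_offset = qb$offset,
             t_peak = as.numeric(tp), t_end = as.numeric(te),
             tpe = iv, qc_flag = "pass", stringsAsFactors = FALSE)
}

#' Run the full measurement pipeline on one recording
#'
#' Band-limits the signal, detects QRS complexes, signal-averages the
#' rest / peak-exercise / recovery windows, delineates each averaged
#' beat, and returns the per-window Tpe and RR values needed by the
#' trait module.
#'
#' @param rec an `ecg_recording` (raw; filtering is applied here).
#' @param windows which analysis windows to process.
#' @return one-row data.frame with `tpe_<win>`, `rr_<win>`,
#'   `n_beats_<win>` and `qc_<win>` for each requested window.
#' @export
process_recording <- function(rec, windows = c("rest", "peak", "recovery")) {
  filt <- bandlimit(rec)
  qrs <- detect_qrs(filt)
  out <- list()
  for (w in windows) {
    ab <- average_beats(filt, qrs, w)
    d <- delineate_beat(ab)
    out[[paste0("tpe_", w)]] <- d$tpe
    out[[paste0("rr_", w)]] <- ab$rr_mean
    out[[paste0("n_beats_", w)]] <- ab$n_beats_averaged
    out[[paste0("qc_", w)]] <- d$qc_flag
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
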