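#' Tpe response to exercise
#'
#' Difference between resting and peak-exercise Tpe, normalized by the
#' concurrent RR change: `(tpe_rest - tpe_peak) / delta_rr_ex`, with
#' `delta_rr_ex = rr_rest - rr_peak` stored as a positive magnitude.
#' The response itself may be negative and is never clipped.
#'
#' @param rec one-row data.frame (or list) with `tpe_rest`, `tpe_peak`,
#'   `rr_rest`, `rr_peak` in ms.
#' @return dimensionless response (ms per ms); `NA` with attribute `qc`
#'   when the RR change is not positive.
#' @export
tpe_response_exercise <- function(rec) {
  d_rr <- rec$rr_rest - rec$rr_peak
  if (!is.finite(d_rr) || d_rr <= 0)
    return(structure(NA_real_, qc = "nonpositive_delta_rr_ex"))
  (rec$tpe_rest - rec$tpe_peak) / d_rr
}

#' Tpe response to recovery
#'
#' Difference between peak-exercise and recovery Tpe, normalized by the
#' subsequent RR change: `(tpe_peak - tpe_recovery) / delta_rr_rec`,
#' with `delta_rr_rec = rr_recovery - rr_peak` a positive magnitude.
#'
#' @param rec one-row data.frame (or list) with `tpe_peak`,
#'   `tpe_recovery`, `rr_peak`, `rr_recovery` in ms.
#' @return dimensionless response; `NA` with attribute `qc` when the RR
#'   change is not positive.
#' @export
tpe_response_recovery <- function(rec) {
  d_rr <- rec$rr_recovery - rec$rr_peak
  if (!is.finite(d_rr) || d_rr <= 0)
    return(structure(NA_real_, qc = "nonpositive_delta_rr_rec"))
  (rec$tpe_peak - rec$tpe_recovery) / d_rr
}

#' Assemble per-individual trait records
#'
#' Takes the per-window measurements from [process_recording()] (plus an
#' `id` column) and derives the RR deltas, the two responses, and
#' plausibility-based QC flags.  QC bounds are configurable; a record
#' failing any bound is retained with `qc_pass = FALSE` so exclusions
#' stay auditable.
#'
#' @param measurements data.frame with columns `id`, `tpe_rest`,
#'   `tpe_peak`, `tpe_recovery`, `rr_rest`, `rr_peak`, `rr_recovery`.
#' @param tpe_bounds,rr_bounds plausibility intervals (ms) for measured
#'   Tpe and RR values.
#' @param cohort cohort tag stored on every record (e.g. `"EST"`).
#' @return data.frame of trait records with `delta_rr_ex`,
#'   `delta_rr_rec`, `tpe_resp_ex`, `tpe_resp_rec`, `cohort`, `qc_pass`.
#' @export
build_trait_records <- function(measurements, tpe_bounds = c(20, 200),
                                rr_bounds = c(300, 2000), cohort = "EST") {
  m <- measurements
  need <- c("id", "tpe_rest", "tpe_peak", "tpe_recovery",
            "rr_rest", "rr_peak", "rr_recovery")
  if (!all(need %in% names(m)))
    stop_invalid("measurements must contain: ", paste(need, collapse = ", "))
  m$delta_rr_ex <- m$rr_rest - m$rr_peak
  m$delta_rr_rec <- m$rr_recovery - m$rr_peak
  m$tpe_resp_ex <- ifelse(m$delta_rr_ex > 0,
                          (m$tpe_rest - m$tpe_peak) / m$delta_rr_ex, NA_real_)
  m$tpe_resp_rec <- ifelse(m$delta_rr_rec > 0,
                           (m$tpe_peak - m$tpe_recovery) / m$delta_rr_rec,
                           NA_real_)
  tpe_ok <- function(x) is.finite(x) & x >= tpe_bounds[1] & x <= tpe_bounds[2]
  rr_ok <- function(x) is.finite(x) & x >= rr_bounds[1] & x <= rr_bounds[2]
  m$qc_pass <- tpe_ok(m$tpe_rest) & tpe_ok(m$tpe_peak) & tpe_ok(m$tpe_recovery) &
    rr_ok(m$rr_rest) & rr_ok(m$rr_peak) & rr_ok(m$rr_recovery) &
    is.finite(m$delta_rr_ex) & m$delta_rr_ex > 0 &
    is.finite(m$delta_rr_rec) & m$delta_rr_rec > 0
  m$cohort <- cohort
  m
}

#' Pool resting-Tpe records from two cohorts
#'
#' Concatenates two trait tables with disjoint individual ids, keeping
#' the cohort tag.  Overlapping ids are an error (overlap between the
#' exercise-test and imaging cohorts must be removed upstream).
#'
#' @param est,image trait-record data.frames, each with an `id` column.
#' @return the concatenated data.frame.
#' @export
pool_resting <- function(est, image) {
  stopifnot(is.data.frame(est), is.data.frame(image))
  dup <- intersect(est$id, image$id)
  if (length(dup))
    stop_invalid("duplicate ids across cohorts: ",
                 paste(utils::head(dup, 10), collapse = ", "))
  common <- intersect(names(est), names(image))
  rbind(est[common], image[common])
}

#' Rank-based inverse-normal transformation
#'
#' Maps values to standard-normal quantiles via Blom offsets:
#' `qnorm((rank - 3/8) / (n + 1/4))`, ties getting the average rank.
#' Used on the Tpe traits because their raw distributions are skewed;
#' the output is rank-preserving and invariant to any monotone
#' re-scaling of the input.
#'
#' @param values numeric vector, `n >= 2`, all finite.
#' @return transformed vector of the same length.
#' @export
inverse_normal <- function(values) {
  if (length(values) < 2L) stop_invalid("need at least 2 values")
  if (any(!is.finite(values))) stop_invalid("values must be finite")
  if (max(values) == min(values))
    stop_invalid("all values equal: ranks undefined up to ties")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(values) + 1 / 4))
}

#' Write / read a trait table as TSV
#' @param traits data.frame; @param path file path.
#' @return `read_traits_tsv` returns a data.frame.
#' @export
write_traits_tsv <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traits_tsv
#' @export
read_traits_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)
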