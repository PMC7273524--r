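# Fixture builders shared across test files.  Everything is generated in
# code; no binary fixtures.

# An averaged_beat holding an arbitrary waveform sampled at `fs`,
# starting at `t0_ms` on the beat timebase.
synth_beat <- function(waveform, fs = 500, t0_ms = 0, window = "rest") {
  structure(list(waveform = waveform, fs = fs, window_label = window,
                 n_beats_averaged = 1L, rr_mean = 1000, t0_ms = t0_ms,
                 qc_pass = TRUE, qc_reason = NA_character_),
            class = "averaged_beat")
}

# Gaussian bump evaluated on a time grid (ms).
gauss_ms <- function(t_ms, center_ms, sigma_ms, amp = 1) {
  amp * exp(-((t_ms - center_ms)^2) / (2 * sigma_ms^2))
}

# A full synthetic QRS-T beat on the aligned timebase (R peak at 0 ms),
# matching the span average_beats() produces.
synth_qrst_beat <- function(t_sigma_ms = 31, t_center_ms = 270,
                            t_amp = 0.3, qrs_amp = 1, fs = 500,
                            baseline = 0, t0_ms = -150, end_ms = 480) {
  t <- seq(t0_ms, end_ms, by = 1000 / fs)
  w <- baseline +
    gauss_ms(t, -20, 5, -0.12 * qrs_amp) +
    gauss_ms(t, 0, 8, qrs_amp) +
    gauss_ms(t, 22, 6, -0.18 * qrs_amp) +
    gauss_ms(t, t_center_ms, t_sigma_ms, t_amp)
  synth_beat(w, fs = fs, t0_ms = t0_ms)
}

# A genotype_cohort with externally supplied dosages (for exact-value
# association tests).
manual_cohort <- function(G, trait = NULL, traits_extra = NULL) {
  n <- nrow(G); m <- ncol(G)
  if (is.null(rownames(G))) rownames(G) <- sprintf("id%04d", seq_len(n))
  if (is.null(colnames(G))) colnames(G) <- sprintf("snv%03d", seq_len(m))
  tr <- data.frame(id = rownames(G))
  if (!is.null(trait)) tr$trait <- trait
  if (!is.null(traits_extra)) tr <- cbind(tr, traits_extra)
  structure(list(
    dosages = G,
    variants = data.frame(snv_id = colnames(G),
                          chrom = rep(1L, m), pos = seq_len(m) * 1000000L,
                          ref = "A", alt = "G", eaf = colMeans(G) / 2,
                          stringsAsFactors = FALSE),
    traits = tr, truth = NULL, arch = NULL),
    class = "genotype_cohort")
}

# Association rows for multistage tests.
assoc_rows <- function(snv_id, chrom, pos, p, beta = rep(-0.1, length(p)),
                       se = rep(0.01, length(p))) {
  data.frame(snv_id = snv_id, chrom = chrom, pos = pos,
             ea = "A", aa = "G", eaf = 0.3, beta = beta, se = se, p = p,
             n = 10000L, stringsAsFactors = FALSE)
}
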