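make_rec <- function(signal, fs = 500,
                     ann = data.frame(phase = c("rest", "exercise", "recovery"),
                                      start_s = c(0, 15, 375),
                                      end_s = c(15, 375, 435))) {
  structure(list(signal = signal, fs = fs, annotations = ann, truth = NULL),
            class = "ecg_recording")
}

test_that("bandlimit rejects DC and preserves the passband", {
  fs <- 500
  n <- 20 * fs
  t <- (seq_len(n) - 1) / fs
  mid <- (5 * fs):(15 * fs)  # away from filter transients

  dc <- bandlimit(make_rec(rep(1, n)))
  expect_lt(max(abs(dc$signal[mid])), 1e-3)

  s10 <- bandlimit(make_rec(sin(2 * pi * 10 * t)))
  expect_equal(max(abs(s10$signal[mid])), 1, tolerance = 0.05)

  s100 <- bandlimit(make_rec(sin(2 * pi * 100 * t)))
  att_db <- -20 * log10(max(abs(s100$signal[mid])))
  expect_gt(att_db, 20)
  # oracle: the designed 4th-order low-pass, applied twice (zero-phase),
  # must predict at least this attenuation at 100 Hz
  lp <- signal::butter(4, 50 / (fs / 2), "low")
  z <- exp(-1i * 2 * pi * 100 / fs)
  H <- sum(lp$b * z^(0:4)) / sum(lp$a * z^(0:4))
  expect_gt(att_db, 2 * (-20 * log10(Mod(H))) - 3)
})

test_that("bandlimit refuses sub-Nyquist sampling rates", {
  expect_error(bandlimit(make_rec(rep(0, 500), fs = 90)), "100 Hz")
  expect_error(bandlimit(make_rec(rep(0, 500), fs = 120), high_hz = 60),
               "Nyquist")
})

test_that("QRS detection finds every beat on a clean recording", {
  rec <- simulate_ecg(exercise_protocol(), beat_template(), seed = 1)
  q <- detect_qrs(bandlimit(rec))
  expect_equal(sum(q < 15), 15)  # rest phase beats
  expect_equal(length(q), nrow(rec$truth))
  # RR series from detections reproduces the generator RR within 1 sample
  expect_lt(max(abs(diff(q) * 1000 - head(rec$truth$rr_ms, -1))), 2 + 1e-9)
})

test_that("QRS detection stays above 99% sensitivity and PPV under noise", {
  rec <- simulate_ecg(exercise_protocol(), beat_template(),
                      noise_sd = 0.05, wander_amp = 0.1, seed = 2)
  q <- detect_qrs(bandlimit(rec))
  truth <- rec$truth$time_s
  matched <- vapply(truth, function(tt) any(abs(q - tt) < 0.06), logical(1))
  claimed <- vapply(q, function(tt) any(abs(truth - tt) < 0.06), logical(1))
  expect_gte(mean(matched), 0.99)  # sensitivity
  expect_gte(mean(claimed), 0.99)  # positive predictive value
})

test_that("flat-line input yields zero detections with a QC flag", {
  q <- detect_qrs(make_rec(rep(0, 5000)))
  expect_length(q, 0)
  expect_equal(attr(q, "qc"), "no_qrs_detected")
})

test_that("averaging identical noise-free beats returns the single beat", {
  rec <- simulate_ecg(exercise_protocol(), beat_template(), seed = 1)
  q <- rec$truth$time_s
  ab <- average_beats(rec, q, "rest")
  expect_true(ab$qc_pass)
  # rest beats are identical, so the average equals any one beat
  i <- round(q[5] * rec$fs) + 1L
  pre <- round(0.15 * rec$fs); post <- round(0.48 * rec$fs)
  expect_lt(max(abs(ab$waveform - rec$signal[(i - pre):(i + post)])), 1e-9)
  expect_equal(ab$rr_mean, 1000, tolerance = 1e-6)
})

test_that("averaging is linear in the input signal", {
  rec1 <- simulate_ecg(exercise_protocol(), beat_template(), seed = 1)
  rec2 <- simulate_ecg(exercise_protocol(), beat_template(t_amplitude = 0.2),
                       seed = 1)
  q <- rec1$truth$time_s
  sum_rec <- rec1; sum_rec$signal <- rec1$signal + rec2$signal
  a1 <- average_beats(rec1, q, "rest")
  a2 <- average_beats(rec2, q, "rest")
  a12 <- average_beats(sum_rec, q, "rest")
  expect_equal(a12$waveform, a1$waveform + a2$waveform, tolerance = 1e-12)
})

test_that("signal averaging suppresses i.i.d. noise as 1/sqrt(N)", {
  rec <- simulate_ecg(exercise_protocol(), beat_template(), seed = 1)
  sigma <- 0.05
  noisy <- rec
  set.seed(99)
  noisy$signal <- rec$signal + rnorm(length(rec$signal), 0, sigma)
  q <- rec$truth$time_s
  clean <- average_beats(rec, q, "rest")
  avg <- average_beats(noisy, q, "rest", min_corr = 0.5)
  n_b <- avg$n_beats_averaged
  resid_sd <- sd(avg$waveform - clean$waveform)
  expect_equal(resid_sd, sigma / sqrt(n_b), tolerance = 0.2)
})

test_that("windows with fewer than three beats fail QC", {
  rec <- simulate_ecg(exercise_protocol(), beat_template(), seed = 1)
  q <- rec$truth$time_s[3:4]  # only two usable beats
  ab <- average_beats(rec, q, "rest")
  expect_false(ab$qc_pass)
  expect_match(ab$qc_reason, "fewer_than_3")
})

test_that("window anchors resolve to the documented spans", {
  ann <- data.frame(phase = c("rest", "exercise", "recovery"),
                    start_s = c(0, 15, 375), end_s = c(15, 375, 435))
  expect_equal(tpegwas:::window_span(ann, "rest"), c(0, 15))
  expect_equal(tpegwas:::window_span(ann, "peak"), c(360, 375))
  expect_equal(tpegwas:::window_span(ann, "recovery"), c(417.5, 432.5))
})
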