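test_that("amplitude envelope is the truncated centred mean of |x|", {
  expect_equal(amplitude_envelope(rep(10, 100), fs = 100, w_env = 0.5),
               rep(10, 100))
  expect_equal(amplitude_envelope(rep(0, 100), fs = 100, w_env = 0.5),
               rep(0, 100))
  # 10 Hz sine, peak 10, averaged over whole cycles: mean |sin| = 2/pi
  x <- sine_wave(10, 2, fs = 200, amp = 10)
  env <- amplitude_envelope(x, fs = 200, w_env = 0.5)
  interior <- env[100:300]
  expect_equal(mean(interior), 10 * 2 / pi, tolerance = 0.02)
  expect_true(all(abs(interior - 10 * 2 / pi) < 0.3))
  # window shorter than one sample is a parameter error
  expect_error(amplitude_envelope(1:10, fs = 10, w_env = 0.05),
               "window")
  # one-sample window degenerates to |x|
  expect_equal(amplitude_envelope(c(-3, 2, -1), fs = 10, w_env = 0.1),
               c(3, 2, 1))
})

test_that("suppression detection finds maximal below-threshold runs", {
  p <- detection_params()
  # 10 s of flat zero: one suppression covering the record
  sup <- detect_suppressions(rep(0, 1000), fs = 100, p)
  expect_equal(sup$onset, 0)
  expect_equal(sup$duration, 10)
  # loud sine throughout: nothing
  sup <- detect_suppressions(sine_wave(10, 10, 100, amp = 50), fs = 100, p)
  expect_equal(nrow(sup), 0L)
  # sine / zeros / sine: one interval near [5, 10), boundaries within w/2
  x <- c(sine_wave(10, 5, 100, amp = 50), rep(0, 500),
         sine_wave(10, 5, 100, amp = 50))
  sup <- detect_suppressions(x, fs = 100, p)
  expect_equal(nrow(sup), 1L)
  expect_lt(abs(sup$onset - 5), p$w_env / 2 + 0.02)
  expect_lt(abs(sup$onset + sup$duration - 10), p$w_env / 2 + 0.02)
})

test_that("one-sample-window detection equals the brute-force scan", {
  fs <- 100
  p <- detection_params(w_env = 1 / fs)
  for (seed in 1:20) {
    x <- withr::with_seed(seed, rnorm(10 * fs, sd = 6))
    got <- detect_suppressions(x, fs, p)
    want <- oracle_suppressions(x, fs, p$theta_supp, p$d_supp_min)
    expect_equal(got$onset, want$onset)
    expect_equal(got$duration, want$duration)
  }
})

test_that("phase counting reads half-waves as baseline crossings + 1", {
  fs <- 1000
  # a positive half-cycle crosses its own mean twice: 3 phases under the
  # segment-mean baseline rule
  half <- sin(pi * seq(0, 1, length.out = 500))
  expect_equal(count_phases(half), 3L)
  full <- sine_wave(1, 1, fs)                     # one full cycle
  expect_equal(count_phases(full), 2L)
  # 0.6 s of 10 Hz: 12 half-waves
  expect_equal(count_phases(sine_wave(10, 0.6, fs)), 12L)
  expect_error(count_phases(1), "2 samples")
})

test_that("bursts are gaps between suppressions meeting the ACNS criteria", {
  fs <- 100
  p <- detection_params()
  # suppression, 1 s of 10 Hz activity (>= 4 phases), suppression
  x <- c(rep(0, 300), sine_wave(10, 1, fs, amp = 40), rep(0, 300))
  sup <- detect_suppressions(x, fs, p)
  expect_equal(nrow(sup), 2L)
  b <- detect_bursts(x, fs, sup, p)
  expect_equal(nrow(b), 1L)
  expect_equal(b$onset, 3, tolerance = p$w_env / 2 + 0.02)
  # a 0.3 s gap is too short to be a burst
  x <- c(rep(0, 300), sine_wave(10, 0.3, fs, amp = 40), rep(0, 300))
  sup <- detect_suppressions(x, fs, detection_params(w_env = 1 / fs))
  b <- detect_bursts(x, fs, sup, detection_params(w_env = 1 / fs))
  expect_equal(nrow(b), 0L)
  # no suppressions: no delimiting context, no bursts
  x <- sine_wave(10, 5, fs, amp = 40)
  sup <- detect_suppressions(x, fs, p)
  b <- detect_bursts(x, fs, sup, p)
  expect_equal(nrow(b), 0L)
})

test_that("consensus requires suppression on every channel", {
  fs <- 100; n <- 600
  p <- detection_params(w_env = 1 / fs)
  flat <- detect_suppressions(rep(0, n), fs, p)
  loud <- detect_suppressions(sine_wave(10, 6, fs, amp = 50), fs, p)
  # all four flat: the whole record
  cons <- consensus_suppressions(list(flat, flat, flat, flat), n, fs, p)
  expect_equal(cons$onset, 0)
  expect_equal(cons$duration, 6)
  # one active channel vetoes
  cons <- consensus_suppressions(list(flat, flat, flat, loud), n, fs, p)
  expect_equal(nrow(cons), 0L)
  # channel count mismatch
  expect_error(consensus_suppressions(list(flat, flat), n, fs, p,
                                      n_channels = 4), "channel")
})

test_that("consensus equals the interval-intersection oracle", {
  fs <- 100; n <- 600
  p <- detection_params(w_env = 1 / fs)
  a <- bs_annotations(onset = 0, duration = 4, label = "suppression",
                      channel = "A")
  b <- bs_annotations(onset = 2, duration = 4, label = "suppression",
                      channel = "B")
  full <- bs_annotations(onset = 0, duration = 6, label = "suppression",
                         channel = "C")
  cons <- consensus_suppressions(list(a, b, full, full), n, fs, p)
  expect_equal(cons$onset, 2)
  expect_equal(cons$duration, 2)
  oracle <- burstsupp:::intersect_intervals(a$onset, a$duration,
                                            b$onset, b$duration)
  expect_equal(cons$onset, oracle$onset)
  expect_equal(cons$duration, oracle$duration)
})

test_that("epoch delimitation chains suppressions by the gap bound", {
  p <- detection_params()
  sup <- bs_annotations(onset = c(10, 15), duration = c(2, 2),
                        label = "suppression")
  ep <- delimit_bs_epochs(sup, p)
  expect_equal(ep$onset, 10)
  expect_equal(ep$duration, 7)        # [10, 17)
  sup <- bs_annotations(onset = c(10, 100), duration = c(2, 2),
                        label = "suppression")
  ep <- delimit_bs_epochs(sup, p)     # 88 s gap > 30 s
  expect_equal(nrow(ep), 2L)
  sup <- bs_annotations(onset = 10, duration = 2, label = "suppression")
  ep <- delimit_bs_epochs(sup, p)
  expect_equal(ep$onset, 10)
  expect_equal(ep$duration, 2)
})

test_that("detect_bs summarises suppressed time, epochs and BSR", {
  fs <- 100
  rec <- recording_with_gap(duration = 300, fs = fs, supp_from = 100,
                            supp_to = 130)
  s <- detect_bs(rec, detection_params(w_env = 1 / fs))
  expect_s3_class(s, "bs_summary")
  # near-zero sine samples abutting the silent block may join the run
  expect_lt(abs(s$bs_duration - 30), 0.05)
  expect_lt(abs(s$bsr - 10), 0.02)
  expect_true(s$any_bs)
  expect_equal(nrow(s$episodes), 1L)
  expect_gte(s$epoch_span, s$bs_duration - 1e-9)
  # fully active recording
  rec <- eeg_recording(matrix(rep(sine_wave(10, 10, fs, amp = 50), 2),
                              ncol = 2), fs = fs)
  s <- detect_bs(rec)
  expect_equal(s$bs_duration, 0)
  expect_false(s$any_bs)
  expect_error(detect_bs(rec, detection_params(w_env = 20)), "shorter")
})

test_that("suppressed time is monotone in the threshold and consensus is
           contained in every channel", {
  fs <- 100
  withr::with_seed(33, {
    sig <- matrix(rnorm(fs * 20 * 4, sd = 6), ncol = 4)
  })
  rec <- eeg_recording(sig, fs = fs)
  durs <- vapply(c(2, 4, 6, 8, 10), function(th)
    detect_bs(rec, detection_params(theta_supp = th))$bs_duration,
    numeric(1))
  expect_true(all(diff(durs) >= -1e-9))
  # consensus mask is a subset of each channel's suppression mask
  p <- detection_params(theta_supp = 6)
  s <- detect_bs(rec, p)
  cons_mask <- burstsupp:::intervals_to_mask(
    s$suppressions$onset, s$suppressions$duration, nrow(rec), fs)
  for (trk in s$per_channel) {
    sup <- trk[trk$label == "suppression", ]
    ch_mask <- burstsupp:::intervals_to_mask(sup$onset, sup$duration,
                                             nrow(rec), fs)
    expect_true(all(ch_mask[cons_mask]))
  }
})

test_that("any_bs is exactly bs_duration > 0", {
  fs <- 100
  for (gap in c(0, 2)) {
    rec <- if (gap > 0)
      recording_with_gap(20, fs, supp_from = 5, supp_to = 5 + gap)
    else
      eeg_recording(matrix(rep(sine_wave(10, 20, fs, amp = 50), 4),
                           ncol = 4), fs = fs)
    s <- detect_bs(rec)
    expect_identical(s$any_bs, s$bs_duration > 0)
  }
})
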