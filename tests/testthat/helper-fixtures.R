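# Shared fixtures: tiny deterministic signals and brute-force oracles kept
# deliberately independent of the package's detection path.

sine_wave <- function(freq, duration, fs, amp = 1, phase = 0) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  amp * sin(2 * pi * freq * t + phase)
}

# Brute-force per-sample suppression scan: |x| < theta runs of at least
# d_min seconds, as (onset, duration) in seconds.
oracle_suppressions <- function(x, fs, theta, d_min) {
  below <- abs(x) < theta
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths / fs >= d_min - 1e-9)
  data.frame(onset = (starts[keep] - 1) / fs, duration = r$lengths[keep] / fs)
}

# A four-channel recording that is a loud sine everywhere except a shared
# flat (zero) window [supp_from, supp_to) seconds.
recording_with_gap <- function(duration = 15, fs = 100, supp_from = 5,
                               supp_to = 10, amp = 50) {
  n <- round(duration * fs)
  base <- sine_wave(10, duration, fs, amp = amp)
  idx <- (round(supp_from * fs) + 1):(round(supp_to * fs))
  base[idx] <- 0
  eeg_recording(matrix(rep(base, 4), ncol = 4,
                       dimnames = list(NULL, c("Fp1", "Fp2", "F7", "F8"))),
                fs = fs)
}

random_annotation_track <- function(n = 100, seed = 1) {
  withr::with_seed(seed, {
    onsets <- sort(runif(n, 0, 1000))
    # enforce non-overlap within label/channel by spacing onsets apart
    onsets <- onsets + seq_len(n) * 20
    bs_annotations(onset = round(onsets, 6),
                   duration = round(runif(n, 0.5, 10), 6),
                   label = sample(c("suppression", "burst", "bs_epoch"),
                                  n, replace = TRUE),
                   channel = sample(c("all", "Fp1"), n, replace = TRUE))
  })
}
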