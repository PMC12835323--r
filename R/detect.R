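# Burst-suppression detector: rectified-signal moving-average envelope,
# amplitude thresholding per channel, all-channel consensus, epoch chaining,
# and per-recording summarisation (suppressed time, BSR).

#' Detection parameters for the burst-suppression detector
#'
#' @param theta_supp suppression amplitude threshold in uV. The default 5 uV
#'   follows the convention of amplitude-based BS probability algorithms
#'   (e.g. the BIS detects suppression below 5 uV for more than 0.5 s);
#'   calibration against expert annotations may choose a different value.
#' @param w_env envelope averaging window in seconds (centred moving average
#'   of the rectified signal, edges truncated).
#' @param d_supp_min minimum duration in seconds for a below-threshold run to
#'   count as suppression.
#' @param d_burst_min minimum burst duration in seconds (ACNS: at least 0.5 s).
#' @param n_phases_min minimum number of phases for a burst (ACNS: polyphasic,
#'   at least 4 phases; a phase is one half-wave, counted as baseline
#'   crossings + 1).
#' @param g_max maximum gap in seconds between consecutive suppressions
#'   chained into one BS epoch.
#' @return A list of class `"detection_params"`.
#' @export
detection_params <- function(theta_supp = 5, w_env = 0.5, d_supp_min = 0.5,
                             d_burst_min = 0.5, n_phases_min = 4,
                             g_max = 30) {
  p <- list(theta_supp = theta_supp, w_env = w_env, d_supp_min = d_supp_min,
            d_burst_min = d_burst_min, n_phases_min = n_phases_min,
            g_max = g_max)
  num <- vapply(p, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1L))
  if (!all(num))
    stop("detection parameters must all be single positive numbers; bad: ",
         paste(names(p)[!num], collapse = ", "))
  if (p$n_phases_min < 1) stop("n_phases_min must be >= 1")
  structure(p, class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat("<detection_params> theta_supp=", x$theta_supp, " uV, w_env=", x$w_env,
      " s, d_supp_min=", x$d_supp_min, " s, d_burst_min=", x$d_burst_min,
      " s, n_phases_min=", x$n_phases_min, ", g_max=", x$g_max, " s\n",
      sep = "")
  invisible(x)
}

#' Rectified-signal amplitude envelope
#'
#' Centred moving average of `abs(x)` over a window of `w_env` seconds;
#' at the edges the window is truncated to the available samples (no padding,
#' no phase lag). With `w_env` equal to one sample the envelope is exactly
#' `abs(x)`, which is the brute-force oracle used in tests.
#'
#' @param x numeric vector, one channel in uV.
#' @param fs sampling rate in Hz.
#' @param w_env window length in seconds; `w_env * fs` must be >= 1.
#' @return Numeric vector of the same length, non-negative.
#' @examples
#' amplitude_envelope(rep(10, 100), fs = 100, w_env = 0.5)[1]  # 10
#' @export
amplitude_envelope <- function(x, fs, w_env) {
  L <- round(w_env * fs)
  if (L < 1) stop("envelope window shorter than one sample (w_env * fs < 1)")
  n <- length(x)
  half <- L %/% 2L
  if (half == 0L) return(abs(x))
  cs <- c(0, cumsum(abs(x)))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Logical below-threshold run extraction: runs of TRUE at least min_dur long,
# as half-open sample-aligned intervals in seconds.
mask_to_intervals <- function(mask, fs, min_dur = 0) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths >= ceiling(min_dur * fs - 1e-9))
  data.frame(onset = (starts[keep] - 1L) / fs,
             duration = r$lengths[keep] / fs)
}

intervals_to_mask <- function(onset, duration, n, fs) {
  mask <- logical(n)
  if (length(onset)) {
    from <- pmax(1L, round(onset * fs) + 1L)
    to <- pmin(n, round((onset + duration) * fs))
    for (i in seq_along(from)) if (to[i] >= from[i])
      mask[from[i]:to[i]] <- TRUE
  }
  mask
}

#' Detect suppression intervals on one channel
#'
#' Maximal runs where the amplitude envelope stays below `theta_supp`,
#' retained if they last at least `d_supp_min` seconds. Intervals are
#' half-open, sample-aligned, sorted and disjoint.
#'
#' @param x numeric vector, one channel in uV.
#' @param fs sampling rate in Hz.
#' @param params a [detection_params] object.
#' @param channel channel name recorded on the result.
#' @return A [bs_annotations] track of `"suppression"` intervals.
#' @export
detect_suppressions <- function(x, fs, params = detection_params(),
                                channel = "ch1") {
  env <- amplitude_envelope(x, fs, params$w_env)
  iv <- mask_to_intervals(env < params$theta_supp, fs, params$d_supp_min)
  bs_annotations(onset = iv$onset, duration = iv$duration,
                 label = "suppression", channel = channel)
}

#' Count the phases of a waveform segment
#'
#' A phase is one half-wave: the count is the number of interior baseline
#' crossings of the mean-subtracted segment, plus one. Samples exactly on the
#' baseline are ignored for crossing purposes. One positive half-cycle of a
#' sine counts 1 phase; a full cycle counts 2.
#'
#' @param segment numeric vector with at least 2 samples.
#' @return Integer phase count (>= 1).
#' @export
count_phases <- function(segment) {
  if (length(segment) < 2L) stop("segment must have at least 2 samples")
  s <- sign(segment - mean(segment))
  s <- s[s != 0]
  if (length(s) < 2L) return(1L)
  sum(diff(s) != 0) + 1L
}

#' Identify bursts between suppressions on one channel
#'
#' Candidate bursts are the gaps between consecutive suppression intervals
#' (activity outside the first/last suppression is not a candidate: bursts
#' are defined within the burst-suppression context). A candidate qualifies
#' if it lasts at least `d_burst_min` seconds and its waveform contains at
#' least `n_phases_min` phases.
#'
#' @inheritParams detect_suppressions
#' @param suppressions a [bs_annotations] track of suppressions on this
#'   channel, as produced by [detect_suppressions()].
#' @return A [bs_annotations] track of `"burst"` intervals.
#' @export
detect_bursts <- function(x, fs, suppressions, params = detection_params(),
                          channel = "ch1") {
  sup <- suppressions[suppressions$label == "suppression", , drop = FALSE]
  if (nrow(sup) < 2L)
    return(bs_annotations(label = character(), channel = channel))
  gap_on <- (sup$onset + sup$duration)[-nrow(sup)]
  gap_end <- sup$onset[-1L]
  keep_on <- numeric(); keep_dur <- numeric()
  for (i in seq_along(gap_on)) {
    dur <- gap_end[i] - gap_on[i]
    if (dur < params$d_burst_min - 1e-9) next
    from <- round(gap_on[i] * fs) + 1L
    to <- min(length(x), round(gap_end[i] * fs))
    if (to - from + 1L < 2L) next
    if (count_phases(x[from:to]) >= params$n_phases_min) {
      keep_on <- c(keep_on, gap_on[i])
      keep_dur <- c(keep_dur, dur)
    }
  }
  bs_annotations(onset = keep_on, duration = keep_dur, label = "burst",
                 channel = channel)
}

#' All-channel consensus suppressions
#'
#' Burst suppression is only accepted where it is detected on every channel:
#' per-sample AND of the channel suppression masks, re-extracted as intervals
#' and re-filtered by the minimum suppression duration.
#'
#' @param per_channel list of [bs_annotations] suppression tracks, one per
#'   channel of the recording.
#' @param n_samples number of samples in the recording.
#' @param fs sampling rate in Hz.
#' @param params a [detection_params] object.
#' @param n_channels expected channel count; a mismatch with
#'   `length(per_channel)` is an error.
#' @return A [bs_annotations] track of consensus `"suppression"` intervals
#'   on channel `"all"`.
#' @export
consensus_suppressions <- function(per_channel, n_samples, fs,
                                   params = detection_params(),
                                   n_channels = length(per_channel)) {
  if (length(per_channel) != n_channels)
    stop("suppression lists for ", length(per_channel),
         " channel(s) but recording has ", n_channels)
  if (!length(per_channel)) stop("no channels supplied")
  mask <- rep(TRUE, n_samples)
  for (trk in per_channel) {
    sup <- trk[trk$label == "suppression", , drop = FALSE]
    mask <- mask & intervals_to_mask(sup$onset, sup$duration, n_samples, fs)
  }
  iv <- mask_to_intervals(mask, fs, params$d_supp_min)
  bs_annotations(onset = iv$onset, duration = iv$duration,
                 label = "suppression", channel = "all")
}

#' Delimit burst-suppression epochs
#'
#' Consecutive suppressions separated by no more than `g_max` seconds are
#' chained into one epoch; each epoch runs from the onset of its first
#' suppression to the end of its last (the intervening bursts are inside the
#' epoch).
#'
#' @param suppressions sorted disjoint [bs_annotations] suppressions
#'   (typically the consensus track).
#' @param params a [detection_params] object.
#' @return A [bs_annotations] track of `"bs_epoch"` intervals.
#' @export
delimit_bs_epochs <- function(suppressions, params = detection_params()) {
  sup <- suppressions[suppressions$label == "suppression", , drop = FALSE]
  if (!nrow(sup))
    return(bs_annotations(label = character(), channel = "all"))
  ends <- sup$onset + sup$duration
  gaps <- sup$onset[-1L] - ends[-nrow(sup)]
  grp <- cumsum(c(0, gaps > params$g_max + 1e-9))
  on <- tapply(sup$onset, grp, min)
  en <- tapply(ends, grp, max)
  bs_annotations(onset = as.numeric(on), duration = as.numeric(en - on),
                 label = "bs_epoch", channel = "all")
}

#' Run the full burst-suppression detector on a recording
#'
#' Chains the stages: per-channel envelope and suppression thresholding,
#' all-channel consensus, epoch delimitation, and summarisation. The total
#' suppressed time is the sum of consensus suppression durations; the
#' burst-suppression ratio (BSR) is suppressed time as a percentage of the
#' analysed recording length.
#'
#' @param rec an [eeg_recording].
#' @param params a [detection_params] object.
#' @return An object of class `"bs_summary"`: a list with `bs_duration` (s),
#'   `epoch_span` (s), `bsr` (%), `any_bs`, `analyzed_s`, `suppressions` and
#'   `episodes` ([bs_annotations]), and the `params` used.
#' @examples
#' rec <- eeg_recording(matrix(50 * sin(2 * pi * 10 * (0:999) / 100),
#'                             ncol = 1), fs = 100)
#' detect_bs(rec)$any_bs  # active throughout: FALSE
#' @export
detect_bs <- function(rec, params = detection_params()) {
  fs <- rec_fs(rec)
  if (rec_duration(rec) < params$w_env)
    stop("recording shorter than the envelope window")
  chans <- rec_channels(rec)
  per_ch <- lapply(seq_along(chans), function(j)
    detect_suppressions(rec[, j], fs, params, channel = chans[j]))
  cons <- consensus_suppressions(per_ch, nrow(rec), fs, params,
                                 n_channels = ncol(rec))
  epochs <- delimit_bs_epochs(cons, params)
  bs_dur <- interval_total(cons, "suppression")
  structure(list(
    bs_duration = bs_dur,
    epoch_span = interval_total(epochs, "bs_epoch"),
    bsr = 100 * bs_dur / rec_duration(rec),
    any_bs = bs_dur > 0,
    analyzed_s = rec_duration(rec),
    suppressions = cons,
    episodes = epochs,
    per_channel = per_ch,
    params = params
  ), class = "bs_summary")
}

#' @export
print.bs_summary <- function(x, ...) {
  cat("<bs_summary> ", format(x$analyzed_s, digits = 6), " s analysed\n",
      "  suppressed time: ", format(x$bs_duration, digits = 6), " s (BSR ",
      format(x$bsr, digits = 4), "%)\n",
      "  BS epochs: ", nrow(x$episodes), " spanning ",
      format(x$epoch_span, digits = 6), " s\n",
      "  any BS: ", x$any_bs, "\n", sep = "")
  invisible(x)
}

#' @export
plot.bs_summary <- function(x, rec = NULL, channel = 1L, ...) {
  if (!is.null(rec)) {
    fs <- rec_fs(rec)
    t <- (seq_len(nrow(rec)) - 1L) / fs
    plot(t, rec[, channel], type = "l", col = "grey30",
         xlab = "time (s)", ylab = "amplitude (uV)",
         main = "burst-suppression detection", ...)
  } else {
    plot(NULL, xlim = c(0, x$analyzed_s), ylim = c(-1, 1),
         xlab = "time (s)", ylab = "", yaxt = "n",
         main = "burst-suppression detection", ...)
  }
  usr <- par("usr")
  sup <- x$suppressions
  if (nrow(sup))
    rect(sup$onset, usr[3], sup$onset + sup$duration, usr[4],
         col = grDevices::adjustcolor("red", 0.25), border = NA)
  ep <- x$episodes
  if (nrow(ep))
    segments(ep$onset, usr[4] * 0.95, ep$onset + ep$duration, usr[4] * 0.95,
             lwd = 3, col = "blue")
  invisible(x)
}
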