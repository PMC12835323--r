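# Labelled time intervals: the shared currency between expert annotations,
# detector output and simulator ground truth. Intervals are half-open
# [onset, onset + duration) in seconds from recording start; abutting
# intervals do not overlap.

.bs_labels <- c("suppression", "burst", "bs_epoch")

#' Construct a track of labelled EEG time intervals
#'
#' An annotation track is a data frame of half-open time intervals
#' `[onset, onset + duration)`, each carrying a label from
#' `c("suppression", "burst", "bs_epoch")` and a channel name (`"all"` for
#' intervals that apply to every channel, the convention used for expert
#' burst-suppression annotations and consensus detections). Rows are kept
#' sorted by onset.
#'
#' @param onset numeric, seconds from recording start (>= 0).
#' @param duration numeric, seconds (> 0).
#' @param label character, one of `"suppression"`, `"burst"`, `"bs_epoch"`.
#' @param channel character channel name, default `"all"`.
#' @param recording_id single string identifying the source recording.
#' @return A data frame of class `"bs_annotations"` with columns
#'   `onset`, `duration`, `label`, `channel`, sorted by onset, and an
#'   attribute `recording_id`.
#' @examples
#' trk <- bs_annotations(onset = c(12, 30), duration = c(3.5, 2),
#'                       label = "suppression")
#' trk
#' @export
bs_annotations <- function(onset = numeric(), duration = numeric(),
                           label = character(), channel = "all",
                           recording_id = "") {
  n <- length(onset)
  trk <- data.frame(
    onset = as.numeric(onset),
    duration = as.numeric(duration),
    label = as.character(rep_len(label, n)),
    channel = as.character(rep_len(channel, n)),
    stringsAsFactors = FALSE
  )
  trk <- trk[order(trk$onset, trk$channel, trk$label), , drop = FALSE]
  rownames(trk) <- NULL
  attr(trk, "recording_id") <- as.character(recording_id)
  class(trk) <- c("bs_annotations", "data.frame")
  validate_annotations(trk)
}

#' @rdname bs_annotations
#' @param x object to test or validate.
#' @export
is_bs_annotations <- function(x) inherits(x, "bs_annotations")

#' @rdname bs_annotations
#' @export
validate_annotations <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("onset", "duration", "label", "channel")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("annotation track lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0L) return(x)
  if (any(!is.finite(x$onset)) || any(x$onset < 0))
    stop("annotation onsets must be finite and >= 0")
  if (any(!is.finite(x$duration)) || any(x$duration <= 0))
    stop("annotation durations must be finite and > 0")
  bad <- setdiff(unique(x$label), .bs_labels)
  if (length(bad))
    stop("unknown annotation label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.bs_labels, collapse = "/"), ")")
  if (is.unsorted(x$onset)) stop("annotation intervals must be sorted by onset")
  # same-label, same-channel intervals must not overlap (half-open convention)
  for (key in split(x, list(x$label, x$channel), drop = TRUE)) {
    if (nrow(key) > 1L) {
      ends <- key$onset + key$duration
      if (any(key$onset[-1L] < ends[-nrow(key)] - 1e-9))
        stop("overlapping ", key$label[1L], " intervals on channel ",
             key$channel[1L])
    }
  }
  x
}

#' Read an annotation interval table from CSV
#'
#' Expects columns `onset_s`, `duration_s`, `label`, `channel`. Rows are
#' returned sorted by onset; labels outside
#' `c("suppression", "burst", "bs_epoch")` and non-positive durations are
#' rejected. A header-only file yields an empty track.
#'
#' @param path CSV file path.
#' @param recording_id optional identifier stored on the track.
#' @return A [bs_annotations] track.
#' @export
read_annotations <- function(path, recording_id = "") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "label", "channel")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation CSV lacks column(s): ", paste(miss, collapse = ", "))
  bs_annotations(onset = df$onset_s, duration = df$duration_s,
                 label = df$label, channel = df$channel,
                 recording_id = recording_id)
}

#' Write an annotation track to CSV
#'
#' Writes columns `onset_s,duration_s,label,channel` with fixed six-decimal
#' seconds, so that [read_annotations()] round-trips the track exactly at
#' microsecond resolution and the file bytes are stable across runs.
#'
#' @param track a [bs_annotations] track.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(track, path) {
  track <- validate_annotations(track)
  out <- data.frame(
    onset_s = sprintf("%.6f", track$onset),
    duration_s = sprintf("%.6f", track$duration),
    label = track$label,
    channel = track$channel,
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L)
    out <- out[0L, , drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.bs_annotations <- function(x, ...) {
  rid <- attr(x, "recording_id")
  cat("<bs_annotations>",
      if (nzchar(rid)) paste0(" recording '", rid, "'") else "",
      ": ", nrow(x), " interval(s)\n", sep = "")
  if (nrow(x)) {
    tab <- table(x$label)
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n",
        sep = "")
    print.data.frame(head(as.data.frame(x), 10L))
    if (nrow(x) > 10L) cat("  ... (", nrow(x) - 10L, " more)\n", sep = "")
  }
  invisible(x)
}

# Total duration of intervals with a given label/channel.
interval_total <- function(track, label = "suppression", channel = NULL) {
  keep <- track$label == label
  if (!is.null(channel)) keep <- keep & track$channel == channel
  sum(track$duration[keep])
}

# Intersect two sorted disjoint interval sets (matrices with onset/end use).
# Used as the brute-force oracle for the consensus mask in tests; exported
# via detection internals there.
intersect_intervals <- function(a_on, a_dur, b_on, b_dur) {
  if (!length(a_on) || !length(b_on))
    return(list(onset = numeric(), duration = numeric()))
  on <- numeric(); du <- numeric()
  for (i in seq_along(a_on)) {
    lo <- pmax(a_on[i], b_on)
    hi <- pmin(a_on[i] + a_dur[i], b_on + b_dur)
    keep <- hi > lo
    on <- c(on, lo[keep]); du <- c(du, (hi - lo)[keep])
  }
  o <- order(on)
  list(onset = on[o], duration = du[o])
}
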