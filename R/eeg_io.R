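# EEG recordings: a channels-in-columns numeric matrix in microvolts plus a
# sampling rate. Readers for EDF (European Data Format, 16-bit continuous)
# and for a plain CSV matrix with a "# fs=<Hz>" sidecar comment.

#' Construct a multichannel EEG recording
#'
#' A recording is a numeric matrix (rows = samples, columns = channels) of
#' amplitudes in microvolts, with a sampling frequency `fs` in Hz and ordered
#' channel labels. The frontal montage used throughout is Fp1, Fp2, F7, F8 at
#' 178 Hz, but any channel set and rate are accepted.
#'
#' @param signal numeric matrix or data frame, one column per channel, in uV.
#' @param fs sampling frequency in Hz (> 0).
#' @param channel_labels character vector; defaults to the column names of
#'   `signal`.
#' @param start_offset seconds, time of the first sample (default 0).
#' @return An object of class `"eeg_recording"`: the signal matrix with
#'   attributes `fs`, `channel_labels` and `start_offset`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(400), ncol = 4,
#'                             dimnames = list(NULL, c("Fp1","Fp2","F7","F8"))),
#'                      fs = 100)
#' rec_duration(rec)
#' @export
eeg_recording <- function(signal, fs, channel_labels = NULL,
                          start_offset = 0) {
  if (is.data.frame(signal)) signal <- as.matrix(signal)
  if (!is.matrix(signal)) signal <- matrix(signal, ncol = 1L)
  storage.mode(signal) <- "double"
  if (is.null(channel_labels))
    channel_labels <- colnames(signal)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(ncol(signal)))
  if (length(channel_labels) != ncol(signal))
    stop("channel_labels length (", length(channel_labels),
         ") does not match channel count (", ncol(signal), ")")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  if (ncol(signal) < 1L || nrow(signal) < 1L)
    stop("recording must have at least one channel and one sample")
  bad <- which(colSums(!is.finite(signal)) > 0L)
  if (length(bad))
    stop("non-finite amplitude in channel(s): ",
         paste(channel_labels[bad], collapse = ", "))
  colnames(signal) <- channel_labels
  structure(signal, fs = as.numeric(fs),
            channel_labels = as.character(channel_labels),
            start_offset = as.numeric(start_offset),
            class = c("eeg_recording", "matrix", "array"))
}

#' @rdname eeg_recording
#' @param x an `eeg_recording`.
#' @export
rec_fs <- function(x) attr(x, "fs")

#' @rdname eeg_recording
#' @export
rec_duration <- function(x) nrow(x) / attr(x, "fs")

#' @rdname eeg_recording
#' @export
rec_channels <- function(x) attr(x, "channel_labels")

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", ncol(x), " channel(s) x ", nrow(x), " samples @ ",
      rec_fs(x), " Hz (", format(rec_duration(x), digits = 6), " s)\n",
      sep = "")
  cat("  channels: ", paste(rec_channels(x), collapse = ", "), "\n", sep = "")
  cat("  amplitude range: [", format(min(x), digits = 4), ", ",
      format(max(x), digits = 4), "] uV\n", sep = "")
  invisible(x)
}

#' Read an EEG recording from EDF or CSV
#'
#' `format = "csv"` expects one header row of channel labels and one column
#' per channel, preceded by a comment line `# fs=<Hz>` carrying the sampling
#' rate (or pass `fs` explicitly). `format = "edf"` reads a standard 16-bit
#' continuous European Data Format file and applies its per-signal physical
#' scaling; amplitudes are taken to be microvolts.
#'
#' @param path input file.
#' @param format `"edf"` or `"csv"`; default guesses from the extension.
#' @param fs sampling rate override for CSV files without a sidecar comment.
#' @return An [eeg_recording].
#' @export
read_eeg <- function(path, format = c("auto", "edf", "csv"), fs = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (!file.exists(path)) stop("EEG file not found: ", path)
  switch(format, edf = read_edf(path), csv = read_eeg_csv(path, fs = fs))
}

read_eeg_csv <- function(path, fs = NULL) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (grepl("^#", first)) {
    skip <- 1L
    m <- regmatches(first, regexec("fs\\s*=\\s*([0-9.]+)", first))[[1L]]
    if (length(m) == 2L && is.null(fs)) fs <- as.numeric(m[2L])
  }
  if (is.null(fs))
    stop("CSV carries no sampling rate: add a '# fs=<Hz>' first line ",
         "or pass fs explicitly")
  df <- read.csv(path, skip = skip, stringsAsFactors = FALSE)
  mat <- as.matrix(df)
  nf <- which(colSums(!is.finite(mat)) > 0L)
  if (length(nf)) {
    ch <- colnames(mat)[nf[1L]]
    row <- which(!is.finite(mat[, nf[1L]]))[1L]
    stop("non-finite value in channel ", ch, " at row ", row)
  }
  eeg_recording(mat, fs = fs)
}

#' Write an EEG recording as CSV with an fs sidecar comment
#'
#' @param rec an [eeg_recording].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", rec_fs(rec)), con)
  utils::write.table(as.matrix(unclass(rec)), con, sep = ",",
                     row.names = FALSE, col.names = rec_channels(rec),
                     quote = FALSE)
  invisible(path)
}

# ---- EDF ----------------------------------------------------------------
# Minimal reader/writer for continuous 16-bit EDF: fixed-width ASCII header
# (256 bytes + 256 per signal), then data records of little-endian int16
# with linear physical scaling. All signals must share one sampling rate.

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(nchar) trimws(rawToChar(readBin(con, "raw", nchar)))
  hdr(8L)                                # version
  hdr(80L); hdr(80L); hdr(8L); hdr(8L)   # patient, recording, date, time
  n_header <- as.integer(hdr(8L))
  hdr(44L)                               # reserved
  n_rec <- as.integer(hdr(8L))
  rec_dur <- as.numeric(hdr(8L))
  ns <- as.integer(hdr(4L))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header: ", path)
  field <- function(w) vapply(seq_len(ns), function(i) hdr(w), character(1L))
  labels <- field(16L)
  field(80L); field(8L)                  # transducer, physical dimension
  phys_min <- as.numeric(field(8L)); phys_max <- as.numeric(field(8L))
  dig_min <- as.numeric(field(8L)); dig_max <- as.numeric(field(8L))
  field(80L)                             # prefiltering
  spr <- as.integer(field(8L))           # samples per record
  field(32L)                             # reserved
  if (length(unique(spr)) != 1L)
    stop("EDF signals with unequal sampling rates are not supported")
  seek(con, n_header)
  total <- n_rec * sum(spr)
  raw16 <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                   endian = "little")
  if (length(raw16) < total) stop("truncated EDF data section: ", path)
  sig <- matrix(0, nrow = n_rec * spr[1L], ncol = ns)
  idx <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      block <- raw16[(idx + 1L):(idx + spr[s])]
      sig[((r - 1L) * spr[s] + 1L):(r * spr[s]), s] <- block
      idx <- idx + spr[s]
    }
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (s in seq_len(ns))
    sig[, s] <- phys_min[s] + (sig[, s] - dig_min[s]) * gain[s]
  eeg_recording(sig, fs = spr[1L] / rec_dur, channel_labels = labels)
}

#' Write an EEG recording as a continuous 16-bit EDF file
#'
#' One data record per second (`fs` must be a whole number); the signal is
#' zero-padded to a whole number of records. Physical range is set
#' symmetrically to the peak absolute amplitude, so quantisation error is
#' bounded by `max(abs(signal)) / 32767`.
#'
#' @param rec an [eeg_recording] with integer `fs`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec_fs(rec)
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  sig <- as.matrix(unclass(rec))
  ns <- ncol(sig)
  n_rec <- as.integer(ceiling(nrow(sig) / fs))
  pad <- n_rec * fs - nrow(sig)
  if (pad > 0L) sig <- rbind(sig, matrix(0, pad, ns))
  pmax_ <- max(1e-6, max(abs(sig)))
  dig <- round((sig / pmax_) * 32767)
  f8 <- function(x) formatC(x, width = 8L, flag = "-")
  fw <- function(x, w) formatC(substr(x, 1L, w), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    f8("0"), fw("synthetic", 80L), fw("burstsupp", 80L),
    fw("01.01.26", 8L), fw("00.00.00", 8L),
    f8(as.character(256L + 256L * ns)), fw("", 44L),
    f8(as.character(n_rec)), f8("1"),
    formatC(as.character(ns), width = 4L, flag = "-")
  ), con, eos = NULL)
  wfield <- function(vals, w)
    writeChar(paste(vapply(vals, fw, character(1L), w = w), collapse = ""),
              con, eos = NULL)
  wfield(rec_channels(rec), 16L)
  wfield(rep("", ns), 80L); wfield(rep("uV", ns), 8L)
  wfield(rep(formatC(-pmax_, format = "g", digits = 6), ns), 8L)
  wfield(rep(formatC(pmax_, format = "g", digits = 6), ns), 8L)
  wfield(rep("-32767", ns), 8L); wfield(rep("32767", ns), 8L)
  wfield(rep("", ns), 80L); wfield(rep(as.character(fs), ns), 8L)
  wfield(rep("", ns), 32L)
  for (r in seq_len(n_rec))
    for (s in seq_len(ns))
      writeBin(as.integer(dig[((r - 1L) * fs + 1L):(r * fs), s]), con,
               size = 2L, endian = "little")
  invisible(path)
}
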