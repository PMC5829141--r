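#' Read a continuous single-channel LFP recording
#'
#' Supports two on-disk formats: European Data Format (EDF, 16-bit) and a
#' plain CSV dialect with one header line and columns `time_s,voltage_uV`.
#' For CSV the sampling rate is computed from the median time step, which
#' must be uniform within 1%; for EDF it comes from the signal header.
#'
#' @param path file path.
#' @param format `"auto"` (by file extension), `"csv"` or `"edf"`.
#' @param channel EDF signal index to read (default first).
#' @return list with `trace` (numeric, microvolts) and `fs` (Hz).
#' @export
readContinuous <- function(path, format = c("auto", "csv", "edf"),
                           channel = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", edf = "edf",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format explicitly"))
  }
  if (format == "csv") .read_csv_trace(path) else .read_edf_trace(path, channel)
}

.read_csv_trace <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("time_s", "voltage_uV")
  if (!identical(names(df)[1:2], need))
    stop("CSV header must be 'time_s,voltage_uV'; got '",
         paste(names(df), collapse = ","), "'")
  tt <- df$time_s
  if (length(tt) < 2L) stop("CSV must contain at least two samples")
  dt <- diff(tt)
  bad <- which(dt <= 0)
  if (length(bad))
    stop("time_s is not strictly increasing at data line ", bad[1] + 1L)
  med <- stats::median(dt)
  off <- which(abs(dt - med) / med > 0.01)
  if (length(off))
    stop("non-uniform sampling: time step at data line ", off[1] + 1L,
         " deviates from the median by more than 1%")
  list(trace = df$voltage_uV, fs = 1 / med)
}

#' Write a continuous trace as CSV
#'
#' Writes the `time_s,voltage_uV` dialect with 17 significant digits so the
#' voltages round-trip bit-identically through [readContinuous()].
#'
#' @param trace numeric voltage trace (microvolts).
#' @param fs sampling rate (Hz).
#' @param path output path.
#' @param t_start time of the first sample (s).
#' @return `path`, invisibly
#' @export
writeContinuousCSV <- function(trace, fs, path, t_start = 0) {
  tt <- t_start + (seq_along(trace) - 1) / fs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,voltage_uV", con)
  writeLines(paste(sprintf("%.17g", tt), sprintf("%.17g", trace), sep = ","),
             con)
  invisible(path)
}

## ---- EDF (16-bit European Data Format), minimal single-purpose codec ----

.edf_field <- function(raw, from, len) {
  trimws(rawToChar(raw[from:(from + len - 1L)]))
}

.read_edf_trace <- function(path, channel = 1L) {
  hdr <- readBin(path, "raw", n = 256L)
  if (length(hdr) < 256L) stop("malformed EDF: header shorter than 256 bytes")
  n_rec <- as.integer(.edf_field(hdr, 237L, 8L))
  rec_dur <- as.numeric(.edf_field(hdr, 245L, 8L))
  ns <- as.integer(.edf_field(hdr, 253L, 4L))
  if (is.na(ns) || ns < 1L) stop("malformed EDF: bad signal count field")
  if (is.na(n_rec) || n_rec < 1L) stop("malformed EDF: bad record count field")
  if (is.na(rec_dur) || rec_dur <= 0) stop("malformed EDF: bad record duration field")
  if (channel > ns) stop("requested channel ", channel, " of ", ns)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 256L))
  sig <- readBin(con, "raw", 256L * ns)
  getf <- function(off, len)  # per-signal field block at offset `off`
    vapply(seq_len(ns), function(i)
      .edf_field(sig, off * ns + (i - 1L) * len + 1L, len), character(1))
  phys_min <- as.numeric(getf(16L + 80L + 8L, 8L))
  phys_max <- as.numeric(getf(16L + 80L + 8L + 8L, 8L))
  dig_min <- as.numeric(getf(16L + 80L + 8L + 16L, 8L))
  dig_max <- as.numeric(getf(16L + 80L + 8L + 24L, 8L))
  spr <- as.integer(getf(16L + 80L + 8L + 32L + 80L, 8L))
  if (anyNA(spr)) stop("malformed EDF: bad samples-per-record field")
  if (anyNA(phys_min) || anyNA(phys_max) || anyNA(dig_min) || anyNA(dig_max))
    stop("malformed EDF: bad physical/digital range field for a signal")
  rec_len <- sum(spr)
  dat <- readBin(con, "integer", n = rec_len * n_rec, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(dat) < rec_len * n_rec)
    stop("malformed EDF: data section truncated")
  dat <- matrix(dat, nrow = rec_len)
  first <- cumsum(c(0L, spr))[channel] + 1L
  x_dig <- as.vector(dat[first:(first + spr[channel] - 1L), ])
  g <- (phys_max[channel] - phys_min[channel]) /
       (dig_max[channel] - dig_min[channel])
  list(trace = (x_dig - dig_min[channel]) * g + phys_min[channel],
       fs = spr[channel] / rec_dur)
}

.edf_pad <- function(x, len) {
  x <- as.character(x)
  if (nchar(x) > len) x <- substr(x, 1L, len)
  formatC(x, width = -len, flag = "-")
}

#' Write a continuous trace as single-channel EDF
#'
#' Minimal EDF writer (one signal, 1-s data records). EDF quantises to 16
#' bits over the observed voltage range, so the round trip through
#' [readContinuous()] is exact only to one digitisation step. The trace is
#' padded to a whole number of records by repeating the last sample.
#'
#' @param trace numeric voltage trace (microvolts).
#' @param fs sampling rate (Hz); must be a whole number of samples per second.
#' @param path output path.
#' @param label signal label written to the header.
#' @return `path`, invisibly
#' @export
writeEDF <- function(trace, fs, path, label = "LFP") {
  if (abs(fs - round(fs)) > 1e-9)
    stop("writeEDF requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n_rec <- as.integer(ceiling(length(trace) / fs))
  pad <- n_rec * fs - length(trace)
  x <- c(trace, rep(trace[length(trace)], pad))
  pmin <- min(x); pmax <- max(x)
  if (pmax - pmin < 1e-9) { pmin <- pmin - 1; pmax <- pmax + 1 }
  dmin <- -32768; dmax <- 32767
  dig <- as.integer(round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin))
  hdr <- paste0(
    .edf_pad("0", 8L), .edf_pad("X", 80L), .edf_pad("assrgating", 80L),
    .edf_pad("01.01.26", 8L), .edf_pad("00.00.00", 8L),
    .edf_pad(256L + 256L, 8L), .edf_pad("", 44L),
    .edf_pad(n_rec, 8L), .edf_pad(1L, 8L), .edf_pad(1L, 4L),
    ## signal header block (one signal)
    .edf_pad(label, 16L), .edf_pad("microwire", 80L), .edf_pad("uV", 8L),
    .edf_pad(sprintf("%.8g", pmin), 8L), .edf_pad(sprintf("%.8g", pmax), 8L),
    .edf_pad(dmin, 8L), .edf_pad(dmax, 8L), .edf_pad("BP:1-300Hz", 80L),
    .edf_pad(fs, 8L), .edf_pad("", 32L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

## ---- event sidecars ----

#' Read an event table sidecar
#'
#' Tab-separated file with columns `onset_s`, `label` and optionally
#' `pair_id` (grouping key linking the conditioning and test onsets of one
#' sound pair). Onsets must be strictly increasing; when `pair_id` is
#' present, every pair must consist of a `C` and a `T` onset separated by
#' `isi` seconds within `tol`.
#'
#' @param path TSV file path.
#' @param isi expected conditioning-to-test interval (s).
#' @param tol pairing tolerance (s); default one sample at 1 kHz.
#' @return data.frame with columns `onset_s`, `label` (and `pair_id`)
#' @export
readEvents <- function(path, isi = 0.5, tol = 0.001) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "label") %in% names(ev)))
    stop("event table must have columns onset_s and label")
  validateEvents(ev, isi = isi, tol = tol)
  ev
}

#' Validate an event table
#' @inheritParams readEvents
#' @param events data.frame with `onset_s`, `label`, optional `pair_id`.
#' @return `events`, invisibly; stops on violation
#' @export
validateEvents <- function(events, isi = 0.5, tol = 0.001) {
  bad <- which(diff(events$onset_s) <= 0)
  if (length(bad))
    stop("event onsets not strictly increasing at row ", bad[1] + 1L)
  if ("pair_id" %in% names(events) && any(!is.na(events$pair_id))) {
    for (pid in unique(stats::na.omit(events$pair_id))) {
      sub <- events[!is.na(events$pair_id) & events$pair_id == pid, ]
      cc <- sub$onset_s[sub$label == "C"]
      tt <- sub$onset_s[sub$label == "T"]
      if (length(cc) != 1L || length(tt) != 1L)
        stop("pair_id ", pid, " must contain exactly one C and one T event")
      if (abs(tt - cc - isi) > tol)
        stop(sprintf("pair_id %s: T onset is %.4f s after C, expected %.3f +/- %.3f",
                     pid, tt - cc, isi, tol))
    }
  }
  invisible(events)
}

#' Write an event table sidecar
#' @param events data.frame with `onset_s`, `label`, optional `pair_id`.
#' @param path output TSV path.
#' @return `path`, invisibly
#' @export
writeEvents <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---- epoching ----

#' Cut an EpochSet out of a continuous recording
#'
#' One trial per aligned event. The sample at epoch time 0 is the recording
#' sample nearest the event onset (ties resolved toward the earlier sample);
#' the epoch grid then runs from `round(span[1] * fs)` to
#' `round(span[2] * fs)` samples around it. Events whose span would leave
#' the recording are counted, reported in a single warning and skipped.
#'
#' @param trace numeric voltage trace; sample `i` is at time `(i - 1) / fs`.
#' @param fs sampling rate (Hz).
#' @param events event data.frame (see [readEvents()]).
#' @param span `c(t_min, t_max)` epoch extent (s) around each event.
#' @param alignLabel if non-`NULL`, only events with this `label` are used.
#' @param region,condition,stimulus,sessionId metadata for the resulting
#'   [EpochSet-class]; the span must satisfy the coverage the stimulus type
#'   requires.
#' @return an [EpochSet-class] with `t0 = round(span[1] * fs) / fs`
#' @export
epochTrace <- function(trace, fs, events, span, alignLabel = NULL,
                       region = "AC", condition = "conscious",
                       stimulus = "sound_pair", sessionId = "unlabeled") {
  if (length(span) != 2L || span[1] >= span[2])
    stop("span must be an increasing (t_min, t_max) interval")
  on <- events$onset_s
  if (!is.null(alignLabel)) on <- on[events$label == alignLabel]
  if (length(on) == 0L) stop("no events with label '", alignLabel, "'")
  npre <- round(-span[1] * fs)
  npost <- round(span[2] * fs)
  i0 <- ceiling(on * fs - 0.5) + 1L        # nearest sample, ties earlier
  lo <- i0 - npre
  hi <- i0 + npost
  ok <- lo >= 1L & hi <= length(trace)
  if (any(!ok))
    warning(sum(!ok), " event(s) too close to the recording edge; skipped")
  if (!any(ok)) stop("no event has its full span inside the recording")
  idx <- outer(lo[ok], 0:(npre + npost), `+`)
  EpochSet(matrix(trace[idx], nrow = sum(ok)), fs = fs, t0 = -npre / fs,
           region = region, condition = condition, stimulus = stimulus,
           sessionId = sessionId)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), the standard 1-300 Hz conditioning applied to
#' raw LFP traces. Zero-phase filtering preserves peak latencies.
#'
#' @param trace numeric voltage trace.
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges (Hz); `0 < lo < hi < fs / 2`.
#' @param order filter order per pass.
#' @return filtered trace, same length as the input
#' @export
bandpass <- function(trace, fs, lo = 1, hi = 300, order = 4) {
  if (lo <= 0) stop("lo must be > 0")
  if (hi <= lo) stop("hi must exceed lo")
  if (hi >= fs / 2) stop("hi must be below the Nyquist frequency ", fs / 2, " Hz")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, trace))
}
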