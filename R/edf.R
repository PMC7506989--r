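# Minimal EDF/EDF+ reader and writer (16-bit, standard 256-byte headers).

.norm_label <- function(x) toupper(gsub("\\s+", " ", trimws(x)))

#' Single-channel EEG recording
#'
#' Container for one channel's sample vector together with its sampling rate.
#'
#' @param samples numeric vector of samples (microvolts).
#' @param fs sampling frequency in Hz; must be positive.
#' @param channel channel label.
#' @param source_id free-text provenance tag (usually the file name).
#' @return An object of class `eeg_record` with fields `samples`, `fs`,
#'   `channel` and `source_id`.
#' @export
eeg_record <- function(samples, fs, channel = "EEG", source_id = "") {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("samples must be non-empty")
  if (!all(is.finite(samples))) stop("samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive number")
  structure(list(samples = samples, fs = fs, channel = channel,
                 source_id = source_id),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s: %d samples @ %g Hz (%.1f s) [%s]\n",
              x$channel, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$source_id))
  invisible(x)
}

# Parse an EDF/EDF+ file into header fields, physical-valued ordinary signals
# and raw annotation bytes.  Signal headers are stored field-major after the
# fixed 256-byte record header.
.read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = sz)
  if (length(raw) < 256) stop("unreadable EDF header: file shorter than 256 bytes")
  gs <- function(off, len) rawToChar(raw[(off + 1):(off + len)])
  gn <- function(off, len) suppressWarnings(as.numeric(trimws(gs(off, len))))
  n_records <- gn(236, 8)
  rec_dur <- gn(244, 8)
  ns <- suppressWarnings(as.integer(gn(252, 4)))
  if (is.na(ns) || ns < 1) stop("unreadable EDF header: bad signal count")
  if (length(raw) < 256 + ns * 256) stop("unreadable EDF header: truncated signal headers")
  getf <- function(cum, w)
    vapply(seq_len(ns), function(s) gs(256 + ns * cum + (s - 1) * w, w), "")
  labels <- trimws(getf(0, 16))
  pmin <- as.numeric(trimws(getf(104, 8)))
  pmax <- as.numeric(trimws(getf(112, 8)))
  dmin <- as.numeric(trimws(getf(120, 8)))
  dmax <- as.numeric(trimws(getf(128, 8)))
  nsamp <- as.integer(trimws(getf(216, 8)))
  is_ann <- labels == "EDF Annotations"
  data_off <- 256 + ns * 256
  rec_words <- sum(nsamp)
  avail <- floor((length(raw) - data_off) / (2 * rec_words))
  if (is.na(n_records) || n_records < 0) n_records <- avail
  n_records <- min(n_records, avail)
  if (n_records < 1) stop("EDF file contains no data records")
  body <- raw[(data_off + 1):(data_off + 2 * rec_words * n_records)]
  starts <- cumsum(c(0L, nsamp))
  signals <- vector("list", ns)
  ann_raw <- vector("list", ns)
  ints <- readBin(body, "integer", n = rec_words * n_records, size = 2,
                  signed = TRUE, endian = "little")
  im <- matrix(ints, nrow = rec_words)
  for (s in seq_len(ns)) {
    rows <- (starts[s] + 1):starts[s + 1]
    if (is_ann[s]) {
      # annotation bytes, record by record
      byte_rows <- as.vector(rbind(2 * rows - 1, 2 * rows))
      bm <- matrix(body, nrow = 2 * rec_words)
      ann_raw[[s]] <- as.vector(bm[byte_rows, , drop = FALSE])
    } else {
      dig <- as.vector(im[rows, , drop = FALSE])
      gain <- (pmax[s] - pmin[s]) / (dmax[s] - dmin[s])
      signals[[s]] <- pmin[s] + (dig - dmin[s]) * gain
    }
  }
  list(ns = ns, labels = labels, nsamp = nsamp, rec_dur = rec_dur,
       n_records = n_records, is_annotation = is_ann,
       signals = signals, annotations = ann_raw)
}

#' Load one EEG channel from an EDF/EDF+ file
#'
#' Reads the named channel's full-length sample vector and its sampling
#' rate from the file header.  Channel names are matched exactly after
#' whitespace and case normalization; no fuzzy matching is attempted.
#'
#' @param path path to an EDF or EDF+ file.
#' @param channel channel label, e.g. `"EEG Pz-Oz"`.
#' @return An [eeg_record].
#' @export
load_recording <- function(path, channel) {
  e <- .read_edf(path)
  ordinary <- which(!e$is_annotation)
  hit <- ordinary[.norm_label(e$labels[ordinary]) == .norm_label(channel)]
  if (length(hit) == 0)
    stop("channel '", channel, "' not found in ", path,
         "; available channels: ",
         paste(e$labels[ordinary], collapse = ", "))
  s <- hit[1]
  if (!is.finite(e$rec_dur) || e$rec_dur <= 0)
    stop("unreadable header: bad record duration")
  eeg_record(e$signals[[s]], fs = e$nsamp[s] / e$rec_dur,
             channel = e$labels[s], source_id = basename(path))
}

.edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

# Write a single-signal EDF (plus optional EDF+ annotation channel).
# `annotations` is a character vector with one TAL string per data record;
# when non-NULL the file is marked EDF+C.
.write_edf <- function(samples, fs, channel, path, record_seconds,
                       annotations = NULL, ann_only = FALSE) {
  nsig <- if (ann_only) 0L else 1L
  spr <- as.integer(round(record_seconds * fs))
  if (!ann_only) {
    if (spr <= 0 || length(samples) %% spr != 0)
      stop("sample count must be a whole number of records")
    n_rec <- length(samples) %/% spr
    pmin <- min(samples); pmax <- max(samples)
    if (pmax <= pmin) { pmax <- pmin + 1 }
    # widen a little so round-trip clipping cannot occur
    span <- pmax - pmin
    pmin <- pmin - 0.005 * span; pmax <- pmax + 0.005 * span
  } else {
    n_rec <- length(annotations)
  }
  has_ann <- !is.null(annotations)
  if (has_ann && length(annotations) != n_rec)
    stop("need one annotation TAL per data record")
  ns <- nsig + as.integer(has_ann)
  ann_width <- 0L
  ann_bytes <- NULL
  if (has_ann) {
    ann_bytes <- lapply(annotations, function(a)
      if (is.raw(a)) a else charToRaw(a))
    ann_width <- max(vapply(ann_bytes, length, 1L)) + 2L
    ann_width <- ann_width + (ann_width %% 2L)  # even number of bytes
  }
  hdr <- paste0(
    .edf_field("0", 8),
    .edf_field("X X X X", 80),
    .edf_field("Startdate 01-JAN-2000 X X X", 80),
    "01.01.00", "00.00.00",
    .edf_field(256 + ns * 256, 8),
    .edf_field(if (has_ann) "EDF+C" else "", 44),
    .edf_field(n_rec, 8),
    .edf_num(record_seconds, 8),
    .edf_field(ns, 4))
  lab <- c(if (!ann_only) .edf_field(channel, 16),
           if (has_ann) .edf_field("EDF Annotations", 16))
  tra <- rep(.edf_field("", 80), ns)
  dim_ <- c(if (!ann_only) .edf_field("uV", 8), if (has_ann) .edf_field("", 8))
  pmn <- c(if (!ann_only) .edf_num(pmin, 8), if (has_ann) .edf_num(-1, 8))
  pmx <- c(if (!ann_only) .edf_num(pmax, 8), if (has_ann) .edf_num(1, 8))
  dmn <- c(if (!ann_only) .edf_field(-32768L, 8), if (has_ann) .edf_field(-32768L, 8))
  dmx <- c(if (!ann_only) .edf_field(32767L, 8), if (has_ann) .edf_field(32767L, 8))
  pre <- rep(.edf_field("", 80), ns)
  smp <- c(if (!ann_only) .edf_field(spr, 8),
           if (has_ann) .edf_field(ann_width %/% 2L, 8))
  res <- rep(.edf_field("", 32), ns)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(hdr, paste0(lab, collapse = ""),
                            paste0(tra, collapse = ""), paste0(dim_, collapse = ""),
                            paste0(pmn, collapse = ""), paste0(pmx, collapse = ""),
                            paste0(dmn, collapse = ""), paste0(dmx, collapse = ""),
                            paste0(pre, collapse = ""), paste0(smp, collapse = ""),
                            paste0(res, collapse = ""))), con)
  if (!ann_only) {
    gain <- (pmax - pmin) / 65535
    dig <- as.integer(round((samples - pmin) / gain) - 32768L)
    dig <- pmin(pmax(dig, -32768L), 32767L)
    dm <- matrix(dig, ncol = n_rec)
  }
  for (r in seq_len(n_rec)) {
    if (!ann_only) writeBin(dm[, r], con, size = 2, endian = "little")
    if (has_ann) {
      b <- ann_bytes[[r]]
      writeBin(c(b, raw(ann_width - length(b))), con)
    }
  }
  invisible(path)
}

#' Write an [eeg_record] to a standard EDF file
#'
#' Samples are quantized to 16 bits over the data range, so a read-back
#' agrees with the input to within one quantization step.
#'
#' @param rec an [eeg_record].
#' @param path output file path.
#' @param record_seconds duration of one EDF data record; `record_seconds *
#'   fs` must divide the number of samples.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_seconds = 1) {
  stopifnot(inherits(rec, "eeg_record"))
  .write_edf(rec$samples, rec$fs, rec$channel, path, record_seconds)
}

# Split concatenated TAL bytes into annotation strings.
# TAL: +onset[\x15duration]\x14annotation\x14...\x14\x00
.parse_tals <- function(bytes) {
  if (length(bytes) == 0) return(list())
  chunks <- split(bytes, cumsum(bytes == as.raw(0)) - (bytes == as.raw(0)))
  out <- list()
  for (ch in chunks) {
    ch <- ch[ch != as.raw(0)]
    if (length(ch) == 0) next
    txt <- rawToChar(ch)
    fields <- strsplit(txt, "\x14", fixed = TRUE)[[1]]
    if (length(fields) == 0) next
    head_ <- strsplit(fields[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head_[1]))
    dur <- if (length(head_) > 1) suppressWarnings(as.numeric(head_[2])) else NA_real_
    anns <- fields[-1]
    anns <- anns[nzchar(anns)]
    if (length(anns) > 0 && is.finite(onset))
      out[[length(out) + 1]] <- list(onset = onset, duration = dur, labels = anns)
  }
  out
}

.read_edfplus_events <- function(path) {
  e <- .read_edf(path)
  s <- which(e$is_annotation)
  if (length(s) == 0) stop("no 'EDF Annotations' signal in ", path)
  tals <- .parse_tals(e$annotations[[s[1]]])
  tals
}
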