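# Low-pass filtering and epoch segmentation.

# Zero-phase filtering in the frequency domain.  `gain` is evaluated at the
# one-sided physical frequencies of the length-N DFT grid and applied
# symmetrically, so the output is exactly real, exactly zero-phase and the
# operation is exactly linear.
.fft_apply_gain <- function(x, fs, gain) {
  n <- length(x)
  k <- 0:(n - 1)
  fa <- pmin(k, n - k) * fs / n
  g <- gain(fa)
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
}

.butter_lowpass_gain <- function(cutoff, order) {
  function(f) 1 / (1 + (f / cutoff)^(2 * order))
}

.butter_bandpass_gain <- function(lower, upper, order) {
  function(f) {
    lo <- ifelse(f > 0, 1 / (1 + (lower / f)^(2 * order)), 0)
    hi <- 1 / (1 + (f / upper)^(2 * order))
    lo * hi
  }
}

#' Zero-phase low-pass filter
#'
#' Applies the squared-magnitude response of a Butterworth low-pass filter
#' (the response a forward-backward pass realizes) in the frequency domain.
#' The output has exactly zero phase, unit DC gain, the same length and
#' sampling rate as the input, and the operation is exactly linear.
#'
#' @param rec an [eeg_record].
#' @param cutoff cutoff frequency in Hz (default 35, the standard artifact
#'   rejection band for sleep EEG); must be below Nyquist.
#' @param order Butterworth order of the underlying one-way filter
#'   (default 8); the applied attenuation at frequency f is
#'   `1/(1 + (f/cutoff)^(2*order))`.
#' @return A filtered [eeg_record].
#' @export
lowpass_filter <- function(rec, cutoff = 35, order = 8) {
  stopifnot(inherits(rec, "eeg_record"))
  if (cutoff >= rec$fs / 2)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency ",
         rec$fs / 2, " Hz")
  y <- .fft_apply_gain(rec$samples, rec$fs, .butter_lowpass_gain(cutoff, order))
  eeg_record(y, rec$fs, rec$channel, rec$source_id)
}

#' Matrix of fixed-length epochs
#'
#' @param epochs numeric L x j matrix, one epoch per row.
#' @param te epoch length in seconds.
#' @param fs sampling frequency in Hz; `te * fs` must equal `ncol(epochs)`.
#' @param labels optional integer class index (0-based) per row.
#' @param source_id free-text provenance tag.
#' @param class_names optional class names matching the label coding.
#' @return An object of class `epoch_matrix`.
#' @export
epoch_matrix <- function(epochs, te, fs, labels = NULL, source_id = "",
                         class_names = NULL) {
  epochs <- as.matrix(epochs)
  j <- te * fs
  if (abs(j - round(j)) > 1e-9 || round(j) != ncol(epochs))
    stop("te * fs (", j, ") must equal the epoch length ", ncol(epochs))
  if (nrow(epochs) < 1) stop("need at least one epoch")
  if (!is.null(labels) && length(labels) != nrow(epochs))
    stop("labels length (", length(labels), ") != number of epochs (",
         nrow(epochs), ")")
  structure(list(epochs = epochs, te = te, fs = fs,
                 labels = if (is.null(labels)) NULL else as.integer(labels),
                 source_id = source_id, class_names = class_names),
            class = "epoch_matrix")
}

#' @export
print.epoch_matrix <- function(x, ...) {
  cat(sprintf("<epoch_matrix> %d epochs x %d samples (%gs @ %g Hz)%s\n",
              nrow(x$epochs), ncol(x$epochs), x$te, x$fs,
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' Segment a recording into non-overlapping epochs
#'
#' Divides the sample vector into consecutive windows of `te` seconds.
#' Trailing samples that do not fill a complete epoch are dropped (a
#' message reports how many).
#'
#' @param rec an [eeg_record].
#' @param te epoch length in seconds; `te * fs` must be an integer.
#' @return An [epoch_matrix] with `floor(M / (te*fs))` rows whose
#'   concatenated rows reproduce the first `L*j` input samples exactly.
#' @export
epoch_signal <- function(rec, te) {
  stopifnot(inherits(rec, "eeg_record"))
  j <- te * rec$fs
  if (abs(j - round(j)) > 1e-9) stop("te * fs must be an integer")
  j <- as.integer(round(j))
  m <- length(rec$samples)
  if (m < j) stop("recording (", m, " samples) shorter than one epoch (", j, ")")
  l <- m %/% j
  dropped <- m - l * j
  if (dropped > 0)
    message("epoch_signal: dropped ", dropped,
            " trailing samples that do not fill an epoch")
  mat <- matrix(rec$samples[seq_len(l * j)], nrow = l, byrow = TRUE)
  epoch_matrix(mat, te, rec$fs, source_id = rec$source_id)
}

#' Attach hypnogram-derived labels to an epoch matrix
#'
#' Removes masked (excluded) epochs and attaches the class index of each
#' kept epoch row-wise.
#'
#' @param em an [epoch_matrix] whose row count equals the hypnogram length.
#' @param classes 0-based class indices for the kept epochs (from
#'   [map_labels]).
#' @param mask logical keep-mask over all epochs (from [map_labels]).
#' @param class_names optional class names.
#' @return A labelled [epoch_matrix] with `sum(mask)` rows.
#' @export
align_epochs_labels <- function(em, classes, mask, class_names = NULL) {
  stopifnot(inherits(em, "epoch_matrix"))
  if (nrow(em$epochs) != length(mask))
    stop("epoch count (", nrow(em$epochs), ") != number of hypnogram labels (",
         length(mask), ")")
  if (sum(mask) != length(classes))
    stop("classes length must equal number of kept epochs")
  epoch_matrix(em$epochs[mask, , drop = FALSE], em$te, em$fs,
               labels = classes, source_id = em$source_id,
               class_names = class_names)
}
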