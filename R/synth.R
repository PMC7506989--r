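# Synthetic stage-labelled EEG generator.  A test instrument: epochs are
# sums of band-limited Gaussian noise with stage-dependent band powers and
# amplitudes (plus an optional state-space-coloured component), not a
# claim of physiological realism.

#' Stage profile for the synthetic generator
#'
#' @param name stage name (e.g. `"N3"`).
#' @param bands data frame with columns `lo`, `hi` (Hz, within 0..35) and
#'   `power` (relative band powers, non-negative, summing to 1).
#' @param amplitude_sd overall epoch standard deviation in microvolts.
#' @param dynamics optional [ss_model] whose simulated output is added as
#'   a coloured component.
#' @param dynamics_power fraction of total variance given to the
#'   `dynamics` component.
#' @return An object of class `stage_profile`.
#' @export
stage_profile <- function(name, bands, amplitude_sd = 30,
                          dynamics = NULL, dynamics_power = 0) {
  stopifnot(is.data.frame(bands), all(c("lo", "hi", "power") %in% names(bands)))
  if (any(bands$power < 0)) stop("band powers must be >= 0")
  if (abs(sum(bands$power) - 1) > 1e-8) stop("band powers must sum to 1")
  if (any(bands$lo < 0) || any(bands$hi > 35) || any(bands$hi <= bands$lo))
    stop("bands must lie within 0-35 Hz with hi > lo")
  if (dynamics_power < 0 || dynamics_power >= 1)
    stop("dynamics_power must be in [0, 1)")
  if (dynamics_power > 0 && is.null(dynamics))
    stop("dynamics_power > 0 requires a dynamics model")
  structure(list(name = name, bands = bands, amplitude_sd = amplitude_sd,
                 dynamics = dynamics, dynamics_power = dynamics_power),
            class = "stage_profile")
}

#' Default five-stage profiles
#'
#' Five profiles loosely mimicking the canonical band structure of wake
#' and sleep EEG: wake is alpha/beta dominant at moderate amplitude, REM
#' and N1 are mixed-frequency theta-leaning and low amplitude, N2 adds
#' delta and sigma-range activity, and N3 is high-amplitude delta-dominant
#' slow-wave sleep.  Designed so the stages are separable by their spectra
#' and amplitudes.
#'
#' @return List of five [stage_profile] objects named Awa, REM, N1, N2, N3.
#' @export
default_profiles <- function() {
  bands <- function(delta, theta, alpha, beta)
    data.frame(lo = c(0.5, 4, 8, 13), hi = c(4, 8, 13, 30),
               power = c(delta, theta, alpha, beta))
  list(
    stage_profile("Awa", bands(0.05, 0.10, 0.50, 0.35), amplitude_sd = 30),
    stage_profile("REM", bands(0.15, 0.45, 0.20, 0.20), amplitude_sd = 22),
    stage_profile("N1",  bands(0.25, 0.50, 0.15, 0.10), amplitude_sd = 32),
    stage_profile("N2",  bands(0.45, 0.25, 0.22, 0.08), amplitude_sd = 48),
    stage_profile("N3",  bands(0.80, 0.12, 0.05, 0.03), amplitude_sd = 75))
}

# band-limited unit-variance Gaussian noise via the same zero-phase
# Butterworth-magnitude filters used by the preprocessing module
.band_noise <- function(j, fs, lo, hi) {
  w <- stats::rnorm(j)
  b <- .fft_apply_gain(w, fs, .butter_bandpass_gain(lo, hi, 8))
  s <- stats::sd(b)
  if (s == 0) stop("degenerate band ", lo, "-", hi, " Hz at fs ", fs)
  b / s
}

#' Generate synthetic stage-labelled epochs
#'
#' Each epoch is the sum of band-limited Gaussian noise components
#' weighted by the profile's relative band powers, an optional
#' state-space-coloured component, and a small white-noise floor, scaled
#' to the profile's amplitude.  Epochs are grouped by stage in profile
#' order and labelled with 0-based class indices.
#'
#' @param profiles list of [stage_profile] objects.
#' @param n_per_stage epochs per stage.
#' @param te epoch length in seconds (default 30).
#' @param fs sampling rate in Hz (default 128, which keeps `te * fs`
#'   divisible by `2^7` for all supported wavelet-packet levels).
#' @param seed integer seed; identical seeds give identical matrices.
#' @param noise_frac fraction of variance given to the white-noise floor.
#' @return A labelled [epoch_matrix] with `length(profiles) * n_per_stage`
#'   rows and stage names as `class_names`.
#' @export
generate_stage_epochs <- function(profiles, n_per_stage, te = 30, fs = 128,
                                  seed = 1, noise_frac = 0.05) {
  stopifnot(n_per_stage >= 1)
  j <- te * fs
  if (abs(j - round(j)) > 1e-9) stop("te * fs must be an integer")
  j <- as.integer(round(j))
  for (p in profiles) if (!inherits(p, "stage_profile"))
    stop("profiles must be stage_profile objects")
  nst <- length(profiles)
  .with_seed(seed, {
    mat <- matrix(0, nst * n_per_stage, j)
    labels <- integer(nst * n_per_stage)
    r <- 0L
    for (si in seq_len(nst)) {
      p <- profiles[[si]]
      band_share <- 1 - noise_frac - p$dynamics_power
      for (ei in seq_len(n_per_stage)) {
        x <- numeric(j)
        for (bi in seq_len(nrow(p$bands))) {
          pw <- p$bands$power[bi] * band_share
          if (pw > 0)
            x <- x + sqrt(pw) * .band_noise(j, fs, p$bands$lo[bi],
                                            p$bands$hi[bi])
        }
        if (p$dynamics_power > 0) {
          d <- simulate_ssm(p$dynamics, j, noise_sd = 1)
          x <- x + sqrt(p$dynamics_power) * d / stats::sd(d)
        }
        x <- x + sqrt(noise_frac) * stats::rnorm(j)
        r <- r + 1L
        mat[r, ] <- p$amplitude_sd * x
        labels[r] <- si - 1L
      }
    }
    epoch_matrix(mat, te, fs, labels = labels, source_id = "synthetic",
                 class_names = vapply(profiles, `[[`, "", "name"))
  })
}

#' Write an epoch matrix as an EDF fixture with matching hypnogram
#'
#' Concatenates the epochs into one continuous channel, writes it as a
#' standard EDF (one data record per epoch), and writes the labels as a
#' one-code-per-line hypnogram next to it (`<path stem>_hypnogram.txt`,
#' dreams-style codes).  Reading the pair back with [load_recording],
#' [load_hypnogram] and [epoch_signal] recovers the matrix to within EDF
#' 16-bit quantization and the labels exactly.
#'
#' @param em a labelled [epoch_matrix] (5-class AASM coding: classes
#'   0..4 = Awa, REM, N1, N2, N3).
#' @param path output EDF path.
#' @return List with elements `edf` and `hypnogram` (the two paths).
#' @export
write_fixture_edf <- function(em, path) {
  stopifnot(inherits(em, "epoch_matrix"))
  if (nrow(em$epochs) < 1 || is.null(em$labels))
    stop("need a non-empty labelled epoch matrix")
  samples <- as.vector(t(em$epochs))
  rec <- eeg_record(samples, em$fs, channel = "EEG Synth",
                    source_id = basename(path))
  .write_edf(rec$samples, rec$fs, rec$channel, path, record_seconds = em$te)
  stages <- if (!is.null(em$class_names)) em$class_names
            else .AASM_STAGES
  hyp <- hypnogram(stages[em$labels + 1L], em$te, standard = "AASM")
  hyp_path <- paste0(tools::file_path_sans_ext(path), "_hypnogram.txt")
  write_hypnogram(hyp, hyp_path, dialect = "dreams_txt")
  list(edf = path, hypnogram = hyp_path)
}
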