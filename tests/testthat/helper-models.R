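# Shared constructors for synthetic innovation-form models.

# Observer-canonical innovation model from explicit poles and zeros of the
# ARMA transfer function 1 + B (zI - A)^{-1} K = C(z)/D(z).
make_innovation_model <- function(poles, zeros = c(0, 0)) {
  d <- c(-Re(poles[1] + poles[2]), Re(poles[1] * poles[2]))
  cc <- c(-Re(zeros[1] + zeros[2]), Re(zeros[1] * zeros[2]))
  a <- matrix(c(-d[1], 1, -d[2], 0), 2, 2, byrow = TRUE)
  ss_model(a, B = c(1, 0), K = cc - d)
}

# Random damped-resonance model: complex-conjugate pole pair with modulus
# in [0.8, 0.95] and zeros confined to |z| <= 0.3, so both modes are
# strongly expressed in the output and eigenvalue recovery is well-posed.
# (Freely drawn (B, K) often put MA zeros next to AR poles, which makes
# the modes unidentifiable for any estimator, including exact-ML ARMA.)
random_resonant_model <- function(seed) {
  set.seed(seed)
  r <- runif(1, 0.8, 0.95)
  th <- runif(1, 0.3, 1.2)
  zr <- runif(1, 0, 0.3)
  zth <- runif(1, 0, pi)
  poles <- c(complex(modulus = r, argument = th),
             complex(modulus = r, argument = -th))
  zeros <- c(complex(modulus = zr, argument = zth),
             complex(modulus = zr, argument = -zth))
  list(model = make_innovation_model(poles, zeros), poles = poles)
}

# distance between two complex eigenvalue pairs, up to ordering
eigen_pair_dist <- function(a, b) {
  min(max(Mod(a - b)), max(Mod(a - rev(b))))
}

# second-order resonance at physical frequency f0 (Hz) for sampling rate fs
resonance_model <- function(f0, fs = 128, modulus = 0.97) {
  th <- 2 * pi * f0 / fs
  make_innovation_model(c(complex(modulus = modulus, argument = th),
                          complex(modulus = modulus, argument = -th)))
}

# raw-periodogram band power fraction (independent of the package's
# filtering code): fraction of total power within [lo, hi] Hz
periodogram_band_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  half <- 2:floor(n / 2)          # skip DC, one-sided
  f <- (half - 1) * fs / n
  sum(p[half][f >= lo & f < hi]) / sum(p[half])
}
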