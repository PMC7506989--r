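# Periodized wavelet-packet decomposition and locality-energy features.

#' Names of the supported orthogonal wavelets
#'
#' The 15 candidate bases used throughout the grid searches: `db1`..`db32`
#' (selected orders), `sym2`/`sym8`/`sym16`, `coif1`/`coif3` and `dmey`.
#'
#' @return Character vector of wavelet names.
#' @export
supported_wavelets <- function() names(.wavelet_filters)

.get_filters <- function(wavelet) {
  h <- .wavelet_filters[[wavelet]]
  if (is.null(h))
    stop("unknown wavelet '", wavelet, "'; supported: ",
         paste(names(.wavelet_filters), collapse = ", "))
  lf <- length(h)
  g <- rev(h) * (-1)^(seq_len(lf) - 1)
  list(h = h, g = g)
}

# fold a filter onto length n (circular) and return its DFT
.filter_dft <- function(f, n) {
  if (length(f) <= n) {
    stats::fft(c(f, numeric(n - length(f))))
  } else {
    idx <- ((seq_along(f) - 1) %% n) + 1
    stats::fft(as.vector(tapply(f, idx, sum)[as.character(1:n)]))
  }
}

# One analysis step of the periodized filter bank: circular correlation of
# x with each filter, then downsampling by two.  With a conjugate
# quadrature pair this is an orthonormal map R^N -> R^(N/2) x R^(N/2).
.wpd_split <- function(x, H, G) {
  n <- length(x)
  X <- stats::fft(x)
  lo <- Re(stats::fft(Conj(H) * X, inverse = TRUE)) / n
  hi <- Re(stats::fft(Conj(G) * X, inverse = TRUE)) / n
  ev <- seq(1, n, by = 2)
  list(lo = lo[ev], hi = hi[ev])
}

# transpose (synthesis) of .wpd_split
.wpd_merge <- function(lo, hi, H, G) {
  n <- 2 * length(lo)
  up <- function(a) { v <- numeric(n); v[seq(1, n, by = 2)] <- a; v }
  xl <- Re(stats::fft(stats::fft(up(lo)) * H, inverse = TRUE)) / n
  xh <- Re(stats::fft(stats::fft(up(hi)) * G, inverse = TRUE)) / n
  xl + xh
}

#' Wavelet-packet decomposition of one epoch
#'
#' Expands the full wavelet-packet tree of the epoch to the requested level
#' with a periodized orthonormal filter bank, so that level `l` has exactly
#' `2^l` nodes of length `j/2^l` each and total coefficient energy equals
#' the signal energy.  Nodes are returned in natural (filter-bank) order:
#' node 1 is the repeated low-pass path.
#'
#' @param epoch numeric vector of length `j`; `j` must be divisible by
#'   `2^level`.
#' @param wavelet one of [supported_wavelets()].
#' @param level decomposition depth, `>= 1`.
#' @return An object of class `subband_coefficients` with fields `level`,
#'   `wavelet` and `nodes` (list of `2^level` coefficient vectors).
#' @export
wpd_decompose <- function(epoch, wavelet, level) {
  epoch <- as.numeric(epoch)
  level <- as.integer(level)
  if (level < 1) stop("level must be >= 1")
  j <- length(epoch)
  if (j %% 2^level != 0)
    stop("epoch length ", j, " is not divisible by 2^level = ", 2^level)
  fl <- .get_filters(wavelet)
  nodes <- list(epoch)
  for (l in seq_len(level)) {
    n <- length(nodes[[1]])
    H <- .filter_dft(fl$h, n)
    G <- .filter_dft(fl$g, n)
    nxt <- vector("list", 2 * length(nodes))
    for (m in seq_along(nodes)) {
      sp <- .wpd_split(nodes[[m]], H, G)
      nxt[[2 * m - 1]] <- sp$lo
      nxt[[2 * m]] <- sp$hi
    }
    nodes <- nxt
  }
  structure(list(level = level, wavelet = wavelet, nodes = nodes),
            class = "subband_coefficients")
}

#' Inverse wavelet-packet transform
#'
#' Reconstructs the epoch from its full set of level-`l` sub-band
#' coefficients (the transpose of the orthonormal analysis operator).
#'
#' @param sc a `subband_coefficients` object from [wpd_decompose].
#' @return Numeric vector of the original epoch length.
#' @export
wpd_reconstruct <- function(sc) {
  stopifnot(inherits(sc, "subband_coefficients"))
  fl <- .get_filters(sc$wavelet)
  nodes <- sc$nodes
  for (l in seq_len(sc$level)) {
    n <- 2 * length(nodes[[1]])
    H <- .filter_dft(fl$h, n)
    G <- .filter_dft(fl$g, n)
    nxt <- vector("list", length(nodes) / 2)
    for (m in seq_along(nxt))
      nxt[[m]] <- .wpd_merge(nodes[[2 * m - 1]], nodes[[2 * m]], H, G)
    nodes <- nxt
  }
  nodes[[1]]
}

#' Locality-energy features of a decomposed epoch
#'
#' The locality energy of node `m` is the sum of squared wavelet-packet
#' coefficients in that node, i.e. the energy of the epoch within the
#' node's sub-band.
#'
#' @param sc a `subband_coefficients` object from [wpd_decompose].
#' @return An object of class `le_features` with fields `energies`
#'   (length `2^level`, all `>= 0`), `level` and `wavelet`.
#' @export
locality_energy <- function(sc) {
  stopifnot(inherits(sc, "subband_coefficients"))
  e <- vapply(sc$nodes, function(v) sum(v^2), 0)
  structure(list(energies = e, level = sc$level, wavelet = sc$wavelet),
            class = "le_features")
}
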