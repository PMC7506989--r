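# IMBEF feature construction: locality energies fused with dual
# state-space model parameters.

#' IMBEF feature parameters
#'
#' The four tunable parameters of the feature extractor, defaulting to the
#' operating point selected by grid search on sleep EEG: Haar (`db1`)
#' sub-bands with order-6 state-space models, and `db4` level-5 wavelet
#' packets for the locality energies.
#'
#' @param wavelet_dssm wavelet basis used for the level-1 split whose two
#'   coefficient series are modelled.
#' @param order_dssm state-space model order (5..10).
#' @param wavelet_le wavelet basis for the locality-energy decomposition.
#' @param level_le wavelet-packet level for locality energies (3..7).
#' @param level_mssm level of the sub-band split feeding the state-space
#'   models; fixed at 1 (two models, "dual"), the only case supported.
#' @return An object of class `feature_params`.
#' @export
feature_params <- function(wavelet_dssm = "db1", order_dssm = 6,
                           wavelet_le = "db4", level_le = 5,
                           level_mssm = 1) {
  if (level_mssm != 1)
    stop("only level_mssm = 1 (dual state-space models) is supported")
  if (!(order_dssm %in% 5:10)) stop("order_dssm must be in 5..10")
  if (!(level_le %in% 3:7)) stop("level_le must be in 3..7")
  for (w in c(wavelet_dssm, wavelet_le)) .get_filters(w)
  structure(list(wavelet_dssm = wavelet_dssm,
                 order_dssm = as.integer(order_dssm),
                 wavelet_le = wavelet_le, level_le = as.integer(level_le),
                 level_mssm = 1L),
            class = "feature_params")
}

#' @export
print.feature_params <- function(x, ...) {
  cat(sprintf("<feature_params> DSSM: %s order %d | LE: %s level %d (dim %d)\n",
              x$wavelet_dssm, x$order_dssm, x$wavelet_le, x$level_le,
              feature_dimension(x)))
  invisible(x)
}

#' IMBEF feature-vector dimension
#'
#' `2^level_le` locality energies plus `2 * (n^2 + 2n)` state-space
#' parameters (each of the two models contributes `n^2` entries of A, `n`
#' of B and `n` of K).
#'
#' @param params a [feature_params].
#' @return Integer dimension.
#' @export
feature_dimension <- function(params) {
  n <- params$order_dssm
  as.integer(2^params$level_le + 2^params$level_mssm * (n^2 + 2 * n))
}

#' Dual state-space model features of one epoch
#'
#' Splits the epoch into its two first-level wavelet-packet coefficient
#' series (low and high sub-band), fits an innovation-form state-space
#' model of the given order to each, and concatenates the parameters
#' `[vec(A) | B | K]` of the low-band model followed by the high-band
#' model.  `vec` is row-major over A.
#'
#' @param epoch numeric vector of even length.
#' @param wavelet_dssm wavelet basis for the level-1 split.
#' @param order model order n.
#' @param horizon block-Hankel depth passed to [estimate_ssm].
#' @return Numeric vector of length `2 * (n^2 + 2n)`.
#' @export
dssm_features <- function(epoch, wavelet_dssm = "db1", order = 6,
                          horizon = 2 * order + 1) {
  sc <- wpd_decompose(epoch, wavelet_dssm, level = 1)
  out <- lapply(1:2, function(m) {
    mod <- tryCatch(estimate_ssm(sc$nodes[[m]], order, horizon),
                    error = function(e)
                      stop("sub-band m=", m, ": ", conditionMessage(e),
                           call. = FALSE))
    c(as.vector(t(mod$A)), as.numeric(mod$B), as.numeric(mod$K))
  })
  c(out[[1]], out[[2]])
}

.dssm_names <- function(order) {
  n <- order
  one <- c(paste0("A", rep(1:n, each = n), ".", rep(1:n, n)),
           paste0("B", 1:n), paste0("K", 1:n))
  c(paste0("dssm1_", one), paste0("dssm2_", one))
}

.le_names <- function(level) paste0("le_", seq_len(2^level))

#' Build the IMBEF vector of one epoch
#'
#' Concatenates the `2^level_le` locality energies (computed with
#' `wavelet_le`) with the dual state-space model parameters (computed with
#' `wavelet_dssm` at `order_dssm`), in that order.
#'
#' @param epoch numeric vector; length must be divisible by
#'   `2^level_le` and by 2.
#' @param params a [feature_params].
#' @return Numeric vector of length [feature_dimension(params)][feature_dimension].
#' @export
build_imbef <- function(epoch, params = feature_params()) {
  le <- locality_energy(wpd_decompose(epoch, params$wavelet_le,
                                      params$level_le))$energies
  ds <- dssm_features(epoch, params$wavelet_dssm, params$order_dssm)
  c(le, ds)
}

#' Per-epoch IMBEF feature table
#'
#' @param matrix numeric L x Dim matrix of feature vectors.
#' @param params the [feature_params] that produced it.
#' @param labels optional 0-based class index per row.
#' @param class_names optional class names.
#' @param skipped data frame of skipped epochs (index, reason).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(matrix, params, labels = NULL, class_names = NULL,
                          skipped = NULL) {
  if (ncol(matrix) != feature_dimension(params))
    stop("feature matrix has ", ncol(matrix), " columns but params imply ",
         feature_dimension(params))
  colnames(matrix) <- c(.le_names(params$level_le),
                        .dssm_names(params$order_dssm))
  structure(list(matrix = matrix, params = params,
                 labels = if (is.null(labels)) NULL else as.integer(labels),
                 class_names = class_names,
                 skipped = skipped),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d epochs x %d features (%s/%d + %s/%d)%s\n",
              nrow(x$matrix), ncol(x$matrix), x$params$wavelet_le,
              x$params$level_le, x$params$wavelet_dssm, x$params$order_dssm,
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' Extract IMBEF features for every epoch of a matrix
#'
#' Batch driver over [build_imbef]; row order is preserved and labels are
#' carried through.  Epochs whose features cannot be computed (e.g. a
#' constant sub-band) either abort the run (`on_error = "fail"`) or are
#' dropped with the reason recorded in the result's `skipped` field.
#'
#' @param em a labelled or unlabelled [epoch_matrix].
#' @param params a [feature_params].
#' @param on_error `"fail"` (default) or `"skip"`.
#' @return A [feature_table].
#' @export
extract_features <- function(em, params = feature_params(),
                             on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  stopifnot(inherits(em, "epoch_matrix"))
  l <- nrow(em$epochs)
  if (l == 0) stop("empty epoch matrix")
  dim_ <- feature_dimension(params)
  rows <- vector("list", l)
  bad <- integer(0)
  reasons <- character(0)
  for (i in seq_len(l)) {
    fi <- tryCatch(build_imbef(em$epochs[i, ], params), error = identity)
    if (inherits(fi, "error")) {
      if (on_error == "fail")
        stop("epoch ", i, ": ", conditionMessage(fi), call. = FALSE)
      bad <- c(bad, i)
      reasons <- c(reasons, conditionMessage(fi))
    } else rows[[i]] <- fi
  }
  keep <- setdiff(seq_len(l), bad)
  if (length(keep) == 0) stop("no epoch yielded features")
  mat <- do.call(rbind, rows[keep])
  skipped <- if (length(bad) > 0) data.frame(index = bad, reason = reasons)
             else NULL
  feature_table(mat, params,
                labels = if (is.null(em$labels)) NULL else em$labels[keep],
                class_names = em$class_names, skipped = skipped)
}
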