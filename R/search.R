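# Grid-search model selection: classifier search on DSSM features alone,
# then the two-step parameter grids (wavelet/order for the state-space
# models; wavelet/level for the locality energies).

# feature table holding only the DSSM block (used by the classifier and
# step-1 searches, which deliberately exclude locality energies)
.dssm_table <- function(em, wavelet, order, on_error = "fail") {
  l <- nrow(em$epochs)
  rows <- vector("list", l)
  bad <- integer(0)
  for (i in seq_len(l)) {
    fi <- tryCatch(dssm_features(em$epochs[i, ], wavelet, order),
                   error = identity)
    if (inherits(fi, "error")) {
      if (on_error == "fail")
        stop("epoch ", i, ": ", conditionMessage(fi), call. = FALSE)
      bad <- c(bad, i)
    } else rows[[i]] <- fi
  }
  keep <- setdiff(seq_len(l), bad)
  mat <- do.call(rbind, rows[keep])
  colnames(mat) <- .dssm_names(order)
  list(matrix = mat, labels = em$labels[keep], class_names = em$class_names)
}

# wrap a plain matrix + labels as a feature_table-like object accepted by
# cross_validate (which only touches matrix/labels/class_names/params)
.plain_table <- function(mat, labels, class_names, params) {
  structure(list(matrix = mat, params = params, labels = as.integer(labels),
                 class_names = class_names),
            class = "feature_table")
}

.grid_result <- function(rows) {
  rows <- do.call(rbind, rows)
  ok <- rows[!rows$failed, , drop = FALSE]
  best <- NULL
  if (nrow(ok) > 0) {
    # ties: higher kappa, then smaller order, then candidate list order
    ord <- order(-ok$accuracy, -ok$kappa, ok$order_dssm, ok$candidate)
    best <- ok[ord[1], , drop = FALSE]
  }
  structure(list(rows = rows, best = best), class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d candidates (%d failed)\n", nrow(x$rows),
              sum(x$rows$failed)))
  if (!is.null(x$best)) {
    b <- x$best
    cat(sprintf("  best: %s, dssm %s/%d%s -> accuracy %.2f%%, kappa %.4f\n",
                b$classifier, b$wavelet_dssm, b$order_dssm,
                if (!is.na(b$wavelet_le))
                  sprintf(", le %s/%d", b$wavelet_le, b$level_le) else "",
                100 * b$accuracy, b$kappa))
  }
  invisible(x)
}

.search_grid <- function(em, combos, featurize, k, seed) {
  rows <- vector("list", nrow(combos))
  cache <- new.env(parent = emptyenv())
  for (ci in seq_len(nrow(combos))) {
    cand <- combos[ci, ]
    row <- cbind(cand, candidate = ci, accuracy = NA_real_,
                 kappa = NA_real_, failed = FALSE, error = NA_character_)
    res <- tryCatch({
      ftab <- featurize(cand, cache)
      # folds re-drawn per candidate from the master seed
      cross_validate(ftab, classifier_spec(cand$classifier), k = k,
                     seed = seed + ci)
    }, error = identity)
    if (inherits(res, "error")) {
      row$failed <- TRUE
      row$error <- conditionMessage(res)
    } else {
      row$accuracy <- res$accuracy
      row$kappa <- res$kappa
    }
    rows[[ci]] <- row
  }
  .grid_result(rows)
}

#' Joint classifier / wavelet / order search on DSSM features
#'
#' Exhaustively cross-validates every combination of candidate classifier,
#' sub-band wavelet and model order, using the dual state-space model
#' parameters alone (no locality energies), and reports the best row under
#' the documented tie-breaking (higher accuracy, then higher kappa, then
#' smaller order, then candidate order).
#'
#' @param em a labelled [epoch_matrix].
#' @param classifiers candidate classifier names.
#' @param wavelets candidate wavelet bases.
#' @param orders candidate model orders.
#' @param k folds (default 10).
#' @param seed master seed; each candidate's folds use `seed + index`.
#' @return A `grid_result` with one row per candidate and the `best` row.
#' @export
search_classifier <- function(em, classifiers = .CLASSIFIERS,
                              wavelets = supported_wavelets(),
                              orders = 5:10, k = 10, seed = 1) {
  stopifnot(length(classifiers) > 0, length(wavelets) > 0, length(orders) > 0)
  if (is.null(em$labels)) stop("epoch matrix must be labelled")
  combos <- expand.grid(classifier = classifiers, wavelet_dssm = wavelets,
                        order_dssm = as.integer(orders),
                        wavelet_le = NA_character_, level_le = NA_integer_,
                        stringsAsFactors = FALSE)
  featurize <- function(cand, cache) {
    key <- paste(cand$wavelet_dssm, cand$order_dssm)
    if (is.null(cache[[key]]))
      cache[[key]] <- .dssm_table(em, cand$wavelet_dssm, cand$order_dssm)
    tb <- cache[[key]]
    .plain_table(tb$matrix, tb$labels, tb$class_names,
                 feature_params(wavelet_dssm = cand$wavelet_dssm,
                                order_dssm = cand$order_dssm))
  }
  .search_grid(em, combos, featurize, k, seed)
}

#' Step-1 grid search: sub-band wavelet and model order
#'
#' [search_classifier] restricted to a single classifier; the accuracy
#' grid in orders-by-wavelets layout is available via [accuracy_matrix].
#'
#' @inheritParams search_classifier
#' @param classifier the (fixed) classifier name.
#' @return A `grid_result`.
#' @export
search_dssm_params <- function(em, wavelets = supported_wavelets(),
                               orders = 5:10, classifier = "bagged_trees",
                               k = 10, seed = 1) {
  search_classifier(em, classifiers = classifier, wavelets = wavelets,
                    orders = orders, k = k, seed = seed)
}

#' Step-2 grid search: locality-energy wavelet and level
#'
#' With the state-space block frozen at `frozen_dssm`, evaluates the full
#' IMBEF vector for every candidate locality-energy wavelet and level.
#'
#' @inheritParams search_dssm_params
#' @param levels candidate wavelet-packet levels (default 3:7).
#' @param frozen_dssm list with `wavelet` and `order` of the frozen
#'   state-space block.
#' @return A `grid_result`.
#' @export
search_le_params <- function(em, wavelets = supported_wavelets(),
                             levels = 3:7,
                             frozen_dssm = list(wavelet = "db1", order = 6),
                             classifier = "bagged_trees", k = 10, seed = 1) {
  stopifnot(length(wavelets) > 0, length(levels) > 0)
  if (is.null(em$labels)) stop("epoch matrix must be labelled")
  dssm <- .dssm_table(em, frozen_dssm$wavelet, frozen_dssm$order)
  combos <- expand.grid(classifier = classifier,
                        wavelet_dssm = frozen_dssm$wavelet,
                        order_dssm = as.integer(frozen_dssm$order),
                        wavelet_le = wavelets, level_le = as.integer(levels),
                        stringsAsFactors = FALSE)
  featurize <- function(cand, cache) {
    key <- paste(cand$wavelet_le, cand$level_le)
    if (is.null(cache[[key]])) {
      le <- t(apply(em$epochs, 1, function(ep)
        locality_energy(wpd_decompose(ep, cand$wavelet_le,
                                      cand$level_le))$energies))
      cache[[key]] <- le
    }
    params <- feature_params(wavelet_dssm = cand$wavelet_dssm,
                             order_dssm = cand$order_dssm,
                             wavelet_le = cand$wavelet_le,
                             level_le = cand$level_le)
    mat <- cbind(cache[[key]], dssm$matrix)
    colnames(mat) <- c(.le_names(cand$level_le), .dssm_names(cand$order_dssm))
    .plain_table(mat, dssm$labels, dssm$class_names, params)
  }
  .search_grid(em, combos, featurize, k, seed)
}

#' Accuracy grid of a parameter search
#'
#' Reshapes a `grid_result` into the familiar orders-by-wavelets (step 1)
#' or levels-by-wavelets (step 2) accuracy matrix, in percent.
#'
#' @param gr a `grid_result` from [search_dssm_params] or
#'   [search_le_params].
#' @return Numeric matrix of accuracies (%).
#' @export
accuracy_matrix <- function(gr) {
  r <- gr$rows
  if (all(is.na(r$wavelet_le))) {
    rowv <- sort(unique(r$order_dssm)); colv <- unique(r$wavelet_dssm)
    m <- matrix(NA_real_, length(rowv), length(colv),
                dimnames = list(order = rowv, wavelet = colv))
    for (ri in seq_len(nrow(r)))
      m[as.character(r$order_dssm[ri]), r$wavelet_dssm[ri]] <-
        100 * r$accuracy[ri]
  } else {
    rowv <- sort(unique(r$level_le)); colv <- unique(r$wavelet_le)
    m <- matrix(NA_real_, length(rowv), length(colv),
                dimnames = list(level = rowv, wavelet = colv))
    for (ri in seq_len(nrow(r)))
      m[as.character(r$level_le[ri]), r$wavelet_le[ri]] <- 100 * r$accuracy[ri]
  }
  m
}
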