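# Classifiers, cross-validation and confusion-matrix metrics.

.CLASSIFIERS <- c("linear_discriminant", "quadratic_discriminant",
                  "quadratic_svm", "fine_knn", "bagged_trees",
                  "rusboosted_trees")

#' Build a confusion matrix from truth/prediction pairs
#'
#' Rows are the expert (true) classes, columns the automatic
#' classification, following the usual sleep-scoring table layout.
#'
#' @param truth vector of true class labels.
#' @param predicted vector of predicted class labels, same length.
#' @param class_names class name order; defaults to the sorted union of
#'   observed labels.
#' @return An integer C x C matrix of class `confusion_matrix` with
#'   dimnames `expert` x `automatic`.
#' @export
confusion_matrix <- function(truth, predicted, class_names = NULL) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length")
  if (is.null(class_names))
    class_names <- as.character(sort(unique(c(truth, predicted))))
  ft <- factor(as.character(truth), levels = class_names)
  fp <- factor(as.character(predicted), levels = class_names)
  m <- unclass(table(expert = ft, automatic = fp))
  as_confusion_matrix(m)
}

#' Mark a square count matrix as a confusion matrix
#'
#' @param m square non-negative count matrix (rows = expert classes,
#'   columns = automatic classes).
#' @return The validated matrix with class `confusion_matrix`.
#' @export
as_confusion_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0)) stop("confusion matrix counts must be non-negative")
  storage.mode(m) <- "double"
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Overall accuracy of a confusion matrix
#'
#' Trace over total: the fraction of epochs on the diagonal.  For two
#' classes this is the familiar (TP+TN)/(TP+TN+FP+FN).
#'
#' @param cm a `confusion_matrix`.
#' @return Accuracy as a fraction in `[0, 1]`.
#' @export
accuracy_from_confusion <- function(cm) {
  total <- sum(cm)
  if (total < 1) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed accuracy and `p_e` the chance agreement computed from the row
#' and column marginals.
#'
#' @param cm a `confusion_matrix`.
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_from_confusion <- function(cm) {
  total <- sum(cm)
  if (total < 1) stop("empty confusion matrix")
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < .Machine$double.eps)
    stop("degenerate confusion matrix: chance agreement is 1")
  (accuracy_from_confusion(cm) - pe) / (1 - pe)
}

#' Per-class sensitivity (recall)
#'
#' `diag(cm) / rowSums(cm)`.  Classes with no expert epochs get `NA`.
#'
#' @param cm a `confusion_matrix`.
#' @return Named numeric vector of fractions.
#' @export
sensitivity_per_class <- function(cm) {
  rs <- rowSums(cm)
  s <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  names(s) <- rownames(cm)
  s
}

#' All confusion-matrix metrics at once
#'
#' @param cm a `confusion_matrix`.
#' @return List with `accuracy` and `sensitivity` in percent, and `kappa`.
#' @export
confusion_metrics <- function(cm) {
  list(accuracy = 100 * accuracy_from_confusion(cm),
       kappa = kappa_from_confusion(cm),
       sensitivity = 100 * sensitivity_per_class(cm))
}

#' Read / write a confusion matrix as CSV
#'
#' The CSV convention matches the printed sleep-scoring tables: first
#' column holds the expert class names, remaining columns the automatic
#' classification counts.
#'
#' @param path CSV file.
#' @return For `read_confusion_csv`, a `confusion_matrix`.
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(expert = df[[1]], automatic = colnames(m))
  as_confusion_matrix(m)
}

#' @rdname read_confusion_csv
#' @param cm a `confusion_matrix` to write.
#' @export
write_confusion_csv <- function(cm, path) {
  df <- data.frame(expert = rownames(cm), as.data.frame(unclass(cm)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classifier specification
#'
#' @param name one of `linear_discriminant`, `quadratic_discriminant`,
#'   `quadratic_svm`, `fine_knn`, `bagged_trees`, `rusboosted_trees`.
#' @param ... hyperparameters.  `bagged_trees`: `n_trees` (default 30).
#'   `fine_knn`: `k` (default 1).  `rusboosted_trees`: `n_learners`
#'   (default 30), `maxdepth` (default 5).  `quadratic_svm`: `cost`
#'   (default 1).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = "bagged_trees", ...) {
  if (!(name %in% .CLASSIFIERS))
    stop("unknown classifier '", name, "'; supported: ",
         paste(.CLASSIFIERS, collapse = ", "))
  defaults <- switch(name,
    bagged_trees = list(n_trees = 30),
    fine_knn = list(k = 1),
    rusboosted_trees = list(n_learners = 30, maxdepth = 5),
    quadratic_svm = list(cost = 1),
    list())
  structure(list(name = name,
                 hyper = utils::modifyList(defaults, list(...))),
            class = "classifier_spec")
}

.as_spec <- function(spec) {
  if (inherits(spec, "classifier_spec")) spec else classifier_spec(spec)
}

.check_features <- function(x, y) {
  if (any(!is.finite(x))) stop("feature matrix contains non-finite values")
  if (length(unique(y)) < 2) stop("need at least 2 classes to train")
}

.fit_rusboost <- function(x, y, n_learners, maxdepth) {
  cls <- levels(y)
  nc <- length(cls)
  l <- length(y)
  w <- rep(1 / l, l)
  m_target <- min(table(y))
  df <- data.frame(.y = y, x, check.names = FALSE)
  learners <- list()
  alphas <- numeric(0)
  for (t in seq_len(n_learners)) {
    idx <- unlist(lapply(cls, function(cc) {
      ic <- which(y == cc)
      if (length(ic) <= m_target) ic
      else sample(ic, m_target, prob = w[ic] / sum(w[ic]))
    }))
    fit <- rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE],
                        method = "class",
                        control = rpart::rpart.control(maxdepth = maxdepth,
                                                       cp = 0, xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w[pred != y]) / sum(w)
    if (err >= 1 - 1 / nc) next        # weaker than chance: discard
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(nc - 1)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    learners[[length(learners) + 1]] <- fit
    alphas <- c(alphas, alpha)
  }
  if (length(learners) == 0) stop("boosting failed: no learner beat chance")
  list(learners = learners, alphas = alphas, classes = cls)
}

.predict_rusboost <- function(fit, newx) {
  df <- as.data.frame(newx, check.names = FALSE)
  votes <- matrix(0, nrow(df), length(fit$classes),
                  dimnames = list(NULL, fit$classes))
  for (t in seq_along(fit$learners)) {
    p <- match(as.character(predict(fit$learners[[t]], df, type = "class")),
               fit$classes)
    idx <- cbind(seq_len(nrow(df)), p)
    votes[idx] <- votes[idx] + fit$alphas[t]
  }
  factor(fit$classes[max.col(votes, ties.method = "first")],
         levels = fit$classes)
}

#' Train a classifier on a feature table
#'
#' The six supported classifiers mirror the common preset palette for
#' tabular biosignal features; bagged trees (bootstrap-aggregated decision
#' trees with all features considered at every split) is the default used
#' throughout.
#'
#' @param ft a labelled [feature_table] (or a plain matrix via `x`/`y`
#'   internals).
#' @param spec a [classifier_spec] or classifier name.
#' @param seed integer seed making the fit reproducible.
#' @return An object of class `imbef_classifier` with a [predict] method
#'   taking a feature matrix.
#' @export
train_classifier <- function(ft, spec = classifier_spec(), seed = 1) {
  spec <- .as_spec(spec)
  x <- ft$matrix
  if (is.null(ft$labels)) stop("feature table has no labels")
  y <- factor(ft$labels)
  .check_features(x, y)
  h <- spec$hyper
  fit <- .with_seed(seed, switch(spec$name,
    linear_discriminant = MASS::lda(x, grouping = y),
    quadratic_discriminant = MASS::qda(x, grouping = y),
    quadratic_svm = e1071::svm(x, y, kernel = "polynomial", degree = 2,
                               coef0 = 1, cost = h$cost, scale = FALSE),
    fine_knn = list(train = x, cl = y, k = h$k),
    bagged_trees = randomForest::randomForest(x, y, ntree = h$n_trees,
                                              mtry = ncol(x)),
    rusboosted_trees = .fit_rusboost(x, y, h$n_learners, h$maxdepth)))
  structure(list(spec = spec, fit = fit, classes = levels(y), seed = seed),
            class = "imbef_classifier")
}

#' @export
predict.imbef_classifier <- function(object, newx, ...) {
  if (inherits(newx, "feature_table")) newx <- newx$matrix
  p <- switch(object$spec$name,
    linear_discriminant = predict(object$fit, newx)$class,
    quadratic_discriminant = predict(object$fit, newx)$class,
    quadratic_svm = predict(object$fit, newx),
    fine_knn = class::knn(object$fit$train, newx, object$fit$cl,
                          k = object$fit$k),
    bagged_trees = predict(object$fit, newx),
    rusboosted_trees = .predict_rusboost(object$fit, newx))
  factor(as.character(p), levels = object$classes)
}

#' K-fold cross-validated evaluation
#'
#' Rows are randomly partitioned into `k` folds of near-equal size (sizes
#' differ by at most one); each fold is held out once, the classifier is
#' trained on the remainder, and the held-out predictions are pooled into
#' a single confusion matrix from which accuracy, Cohen's kappa and
#' per-class sensitivity are computed.  Per-fold accuracies and their mean
#' are also returned.
#'
#' @param ft a labelled [feature_table].
#' @param spec a [classifier_spec] or name.
#' @param k number of folds (default 10).
#' @param seed integer seed controlling fold assignment and classifier
#'   randomness.
#' @param stratified if `TRUE`, folds are drawn within each class.
#' @return An object of class `eval_report`: fields `accuracy`, `kappa`,
#'   `sensitivity`, `confusion`, `fold_accuracies`, `mean_fold_accuracy`,
#'   `protocol`.
#' @export
cross_validate <- function(ft, spec = classifier_spec(), k = 10, seed = 1,
                           stratified = FALSE) {
  spec <- .as_spec(spec)
  l <- nrow(ft$matrix)
  if (k < 2) stop("k must be >= 2")
  if (k > l) stop("k (", k, ") exceeds the number of epochs (", l, ")")
  y <- factor(ft$labels)
  folds <- .with_seed(seed, {
    if (stratified) {
      f <- integer(l)
      for (cc in levels(y)) {
        ic <- which(y == cc)
        f[ic] <- sample(rep_len(seq_len(k), length(ic)))
      }
      f
    } else sample(rep_len(seq_len(k), l))
  })
  pred <- factor(rep(NA_character_, l), levels = levels(y))
  for (fold in seq_len(k)) {
    tr <- folds != fold
    sub <- ft
    sub$matrix <- ft$matrix[tr, , drop = FALSE]
    sub$labels <- ft$labels[tr]
    mod <- train_classifier(sub, spec, seed = seed + fold)
    pred[!tr] <- predict(mod, ft$matrix[!tr, , drop = FALSE])
  }
  if (!is.null(ft$class_names) &&
      all(ft$labels %in% (seq_along(ft$class_names) - 1L))) {
    nm <- ft$class_names
    truth_named <- nm[ft$labels + 1L]
    pred_named <- nm[as.integer(as.character(pred)) + 1L]
  } else {
    nm <- levels(y)
    truth_named <- as.character(y)
    pred_named <- as.character(pred)
  }
  cm <- confusion_matrix(truth_named, pred_named, class_names = nm)
  fold_acc <- vapply(seq_len(k), function(fold) {
    sel <- folds == fold
    mean(pred[sel] == y[sel])
  }, 0)
  structure(list(accuracy = accuracy_from_confusion(cm),
                 kappa = kappa_from_confusion(cm),
                 sensitivity = sensitivity_per_class(cm),
                 confusion = cm,
                 fold_accuracies = fold_acc,
                 mean_fold_accuracy = mean(fold_acc),
                 protocol = sprintf("%d-fold CV, %s, seed %d%s", k,
                                    spec$name, seed,
                                    if (stratified) ", stratified" else "")),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$protocol, "\n",
      sprintf("  accuracy %.2f%%  kappa %.4f\n", 100 * x$accuracy, x$kappa),
      sep = "")
  sen <- paste(sprintf("%s %.1f%%", names(x$sensitivity),
                       100 * x$sensitivity), collapse = "  ")
  cat("  sensitivity:", sen, "\n")
  invisible(x)
}
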