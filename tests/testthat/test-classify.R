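# Confusion-matrix metrics, classifier training and cross-validation.

test_that("metrics have the expected closed-form values on simple matrices", {
  d <- as_confusion_matrix(diag(c(5, 7, 9)))
  expect_equal(accuracy_from_confusion(d), 1)
  expect_equal(kappa_from_confusion(d), 1)
  expect_equal(unname(sensitivity_per_class(d)), rep(1, 3))
  flat <- as_confusion_matrix(matrix(4, 3, 3))
  expect_equal(kappa_from_confusion(flat), 0)
  expect_error(accuracy_from_confusion(as_confusion_matrix(matrix(0, 2, 2))),
               "empty")
  expect_error(kappa_from_confusion(as_confusion_matrix(matrix(c(5, 0, 0, 0), 2))),
               "degenerate")
  # a class with no expert epochs has undefined sensitivity
  m <- as_confusion_matrix(matrix(c(3, 0, 1, 0), 2))
  expect_true(is.na(sensitivity_per_class(m)[2]))
})

test_that("kappa agrees with brute-force p_o/p_e from raw pairs", {
  set.seed(51)
  for (rep_ in 1:20) {
    n <- 200
    nc <- sample(2:6, 1)
    truth <- sample(letters[1:nc], n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.6, truth, sample(letters[1:nc], n, replace = TRUE))
    cm <- confusion_matrix(truth, pred, class_names = letters[1:nc])
    po <- mean(truth == pred)
    pe <- sum(vapply(letters[1:nc], function(cc)
      mean(truth == cc) * mean(pred == cc), 0))
    expect_equal(kappa_from_confusion(cm), (po - pe) / (1 - pe),
                 tolerance = 1e-12)
    expect_equal(accuracy_from_confusion(cm), po, tolerance = 1e-12)
  }
})

test_that("permuting class order permutes sensitivities, fixes accuracy and kappa", {
  set.seed(52)
  m <- matrix(rpois(25, 20), 5)
  cm <- as_confusion_matrix(m)
  p <- sample(5)
  cmp <- as_confusion_matrix(m[p, p])
  expect_equal(accuracy_from_confusion(cmp), accuracy_from_confusion(cm))
  expect_equal(kappa_from_confusion(cmp), kappa_from_confusion(cm))
  expect_equal(unname(sensitivity_per_class(cmp)),
               unname(sensitivity_per_class(cm))[p])
})

test_that("confusion CSV round-trips through the table convention", {
  cm <- confusion_matrix(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(cm, path)
  back <- read_confusion_csv(path)
  expect_equal(unclass(back), unclass(cm), ignore_attr = "class")
})

# small separable feature table used across classifier tests
.sep_table <- function(n = 30, seed = 53) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 4, 0), ncol = 4),
             matrix(rnorm(n * 4, 4), ncol = 4))
  colnames(x) <- paste0("f", 1:4)
  structure(list(matrix = x, params = feature_params(),
                 labels = rep(0:1, each = n), class_names = c("lo", "hi")),
            class = "feature_table")
}

test_that("all six classifiers train, predict reproducibly, and errors are clear", {
  ft <- .sep_table()
  probe <- ft$matrix + 0.01
  for (nm in c("linear_discriminant", "quadratic_discriminant",
               "quadratic_svm", "fine_knn", "bagged_trees",
               "rusboosted_trees")) {
    m1 <- train_classifier(ft, nm, seed = 7)
    m2 <- train_classifier(ft, nm, seed = 7)
    p1 <- predict(m1, probe)
    expect_identical(p1, predict(m2, probe), label = nm)
    expect_gt(mean(p1 == factor(ft$labels)), 0.95, label = nm)
  }
  expect_error(train_classifier(ft, "super_forest"),
               "linear_discriminant.*rusboosted_trees")
  ft1 <- ft; ft1$labels <- rep(0L, nrow(ft$matrix))
  expect_error(train_classifier(ft1, "bagged_trees"), "2 classes")
  ftn <- ft; ftn$matrix[1, 1] <- NA
  expect_error(train_classifier(ftn, "bagged_trees"), "non-finite")
})

test_that("cross-validation partitions rows into near-equal disjoint folds", {
  ft <- .sep_table(n = 50)
  rep_ <- cross_validate(ft, "fine_knn", k = 10, seed = 3)
  expect_equal(sum(rep_$confusion), 100)   # every row validated exactly once
  expect_length(rep_$fold_accuracies, 10)
  expect_equal(rep_$accuracy, accuracy_from_confusion(rep_$confusion))
  # fold sizes differ by at most one (checked through the fold assignment)
  folds <- imbef:::.with_seed(3, sample(rep_len(1:10, 100)))
  expect_true(max(table(folds)) - min(table(folds)) <= 1)
  expect_error(cross_validate(ft, "fine_knn", k = 1000), "exceeds")
  expect_error(cross_validate(ft, "fine_knn", k = 1), ">= 2")
})

test_that("well-separated classes are classified near-perfectly, shuffled labels at chance", {
  ft <- .sep_table(n = 100)
  rep_ <- cross_validate(ft, "bagged_trees", k = 10, seed = 5)
  expect_gt(rep_$accuracy, 0.9)
  shuf <- ft
  shuf$labels <- imbef:::.with_seed(99, sample(ft$labels))
  rep0 <- cross_validate(shuf, "bagged_trees", k = 10, seed = 5)
  expect_lt(abs(rep0$accuracy - 0.5), 0.1)
})
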