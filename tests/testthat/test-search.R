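# Grid-search model selection.

# tiny labelled dataset, cached across tests in this file
.search_em <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_stage_epochs(default_profiles(), 10, te = 10,
                                      fs = 128, seed = 17)
    cache
  }
})

test_that("grid search is exhaustive, reproducible, and best dominates its rows", {
  em <- .search_em()
  gr <- search_dssm_params(em, wavelets = c("db1", "db2"), orders = c(5, 6),
                           k = 5, seed = 3)
  expect_equal(nrow(gr$rows), 4)           # product of candidate list lengths
  expect_true(all(!gr$rows$failed))
  expect_true(all(gr$rows$accuracy >= 0 & gr$rows$accuracy <= 1))
  expect_gte(gr$best$accuracy, max(gr$rows$accuracy[!gr$rows$failed]))
  gr2 <- search_dssm_params(em, wavelets = c("db1", "db2"), orders = c(5, 6),
                            k = 5, seed = 3)
  expect_identical(gr$rows$accuracy, gr2$rows$accuracy)
  am <- accuracy_matrix(gr)
  expect_equal(dim(am), c(2, 2))           # orders x wavelets layout
  expect_equal(am["5", "db1"],
               100 * gr$rows$accuracy[gr$rows$order_dssm == 5 &
                                      gr$rows$wavelet_dssm == "db1"])
})

test_that("a one-candidate grid returns that candidate", {
  em <- .search_em()
  gr <- search_classifier(em, classifiers = "fine_knn", wavelets = "db1",
                          orders = 6, k = 5, seed = 2)
  expect_equal(nrow(gr$rows), 1)
  expect_equal(gr$best$classifier, "fine_knn")
  expect_equal(gr$best$order_dssm, 6L)
})

test_that("ties break toward higher kappa, then smaller order", {
  rows <- data.frame(classifier = "bagged_trees", wavelet_dssm = "db1",
                     order_dssm = c(7L, 5L, 6L), wavelet_le = NA,
                     level_le = NA, candidate = 1:3,
                     accuracy = c(0.9, 0.9, 0.9),
                     kappa = c(0.8, 0.8, 0.7),
                     failed = FALSE, error = NA)
  gr <- imbef:::.grid_result(list(rows))
  expect_equal(gr$best$order_dssm, 5L)     # kappa tie at 0.8 -> smaller order
})

test_that("classes that differ only in dynamics are separated by DSSM features", {
  # same band powers, different planted resonance frequency
  bsame <- data.frame(lo = c(0.5, 30), hi = c(30, 35), power = c(0.9, 0.1))
  pA <- stage_profile("theta6", bsame, 30, dynamics = resonance_model(6),
                      dynamics_power = 0.5)
  pB <- stage_profile("alpha11", bsame, 30, dynamics = resonance_model(11),
                      dynamics_power = 0.5)
  em <- generate_stage_epochs(list(pA, pB), 30, te = 10, fs = 128, seed = 5)
  gr <- search_dssm_params(em, wavelets = "db1", orders = c(2, 6),
                           k = 5, seed = 2)
  expect_gt(gr$best$accuracy, 0.9)
})

test_that("adding the LE block improves on DSSM features when classes differ only in scale", {
  # identical spectral shape, amplitudes 30 vs 32 uV: locality energies
  # carry the scale cleanly, state-space parameters only weakly.
  # calibration (one run, then frozen): DSSM-only 0.783, IMBEF 0.850.
  bands <- data.frame(lo = c(0.5, 4, 8, 13), hi = c(4, 8, 13, 30),
                      power = rep(0.25, 4))
  pA <- stage_profile("lowamp", bands, amplitude_sd = 30)
  pB <- stage_profile("highamp", bands, amplitude_sd = 32)
  em <- generate_stage_epochs(list(pA, pB), 60, te = 10, fs = 128, seed = 5)
  gr_d <- search_dssm_params(em, wavelets = "db1", orders = 6, k = 5, seed = 2)
  gr_le <- search_le_params(em, wavelets = "db4", levels = 5,
                            frozen_dssm = list(wavelet = "db1", order = 6),
                            k = 5, seed = 2)
  expect_equal(nrow(gr_le$rows), 1)
  expect_gt(gr_le$best$accuracy, gr_d$best$accuracy)
})

test_that("failed candidates are recorded, not fatal", {
  mat <- matrix(rnorm(8 * 256), 8)
  mat[, ] <- mat
  em <- epoch_matrix(mat, te = 2, fs = 128, labels = rep(0:1, 4))
  # order 10 with default horizon needs 210 samples per sub-band; the
  # 128-sample sub-bands are too short, so every candidate fails
  gr <- search_dssm_params(em, wavelets = "db1", orders = 10, k = 2, seed = 1)
  expect_true(all(gr$rows$failed))
  expect_match(gr$rows$error[1], "too short")
  expect_null(gr$best)
})
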