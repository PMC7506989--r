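# IMBEF construction: dimensions, determinism, propagation of errors.

test_that("feature dimension equals 2^l_LE + 2(n^2 + 2n) across the full grid", {
  expect_equal(feature_dimension(feature_params(level_le = 5, order_dssm = 6)), 128)
  expect_equal(feature_dimension(feature_params(level_le = 3, order_dssm = 5)), 78)
  for (lev in 3:7) for (n in 5:10) {
    p <- feature_params(level_le = lev, order_dssm = n)
    expect_equal(feature_dimension(p), 2^lev + 2 * (n^2 + 2 * n))
  }
})

test_that("realized feature vectors match the declared dimension", {
  set.seed(41)
  epoch <- rnorm(1280)
  for (lev in c(3, 5, 7)) for (n in c(5, 8, 10)) {
    p <- feature_params(level_le = lev, order_dssm = n)
    expect_length(build_imbef(epoch, p), feature_dimension(p))
  }
  expect_length(dssm_features(epoch, "db1", 6), 96)  # 2(36+12)
})

test_that("the vector is [LE block | DSSM block] and extraction is deterministic", {
  set.seed(42)
  epoch <- rnorm(1280)
  p <- feature_params()
  v1 <- build_imbef(epoch, p)
  v2 <- build_imbef(epoch, p)
  expect_identical(v1, v2)
  le <- locality_energy(wpd_decompose(epoch, p$wavelet_le, p$level_le))$energies
  expect_identical(v1[1:32], le)
  # negating the epoch leaves the LE block identical (squared magnitudes);
  # the DSSM block is also invariant because the canonical SVD sign
  # convention absorbs an overall sign flip of the series
  vneg <- build_imbef(-epoch, p)
  expect_identical(vneg[1:32], v1[1:32])
  expect_equal(vneg[33:128], v1[33:128])
})

test_that("sub-band failures are tagged and constant epochs are rejected", {
  expect_error(dssm_features(rep(1, 1280), "db1", 6), "sub-band m=1")
})

test_that("batch extraction preserves rows, labels, and honours on_error", {
  set.seed(43)
  mat <- matrix(rnorm(10 * 1280), 10)
  mat[4, ] <- 2  # constant epoch cannot be modelled
  em <- epoch_matrix(mat, te = 10, fs = 128, labels = rep(0:1, 5))
  expect_error(extract_features(em, on_error = "fail"), "epoch 4")
  ft <- extract_features(em, on_error = "skip")
  expect_equal(nrow(ft$matrix), 9)
  expect_equal(ft$skipped$index, 4)
  expect_equal(ft$labels, rep(0:1, 5)[-4])
  # rows are bitwise reproducible
  ft2 <- extract_features(em, on_error = "skip")
  expect_identical(ft$matrix, ft2$matrix)
  expect_error(epoch_matrix(matrix(numeric(0), 0, 1280), 10, 128),
               "at least one")
})

test_that("LE block scales exactly as c^2 under epoch scaling", {
  set.seed(44)
  epoch <- rnorm(1280)
  p <- feature_params(level_le = 4)
  a <- build_imbef(epoch, p)[1:16]
  b <- build_imbef(3 * epoch, p)[1:16]
  expect_equal(b, 9 * a)
})
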