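# Synthetic stage-labelled EEG generator.

test_that("generated epochs have the requested shape, labels and determinism", {
  em <- generate_stage_epochs(default_profiles(), 100, te = 30, fs = 100,
                              seed = 8)
  expect_equal(dim(em$epochs), c(500, 3000))
  expect_equal(as.integer(table(em$labels)), rep(100L, 5))
  em2 <- generate_stage_epochs(default_profiles(), 100, te = 30, fs = 100,
                               seed = 8)
  expect_identical(em$epochs, em2$epochs)
  em3 <- generate_stage_epochs(default_profiles(), 2, te = 30, fs = 100,
                               seed = 9)
  expect_false(isTRUE(all.equal(em$epochs[1, ], em3$epochs[1, ])))
})

test_that("epochs are finite and zero-mean within sampling error", {
  em <- generate_stage_epochs(default_profiles(), 20, te = 10, fs = 128,
                              seed = 10)
  expect_true(all(is.finite(em$epochs)))
  sds <- apply(em$epochs, 1, sd)
  expect_true(all(abs(rowMeans(em$epochs)) < 0.2 * sds))
})

test_that("default profiles are five distinct unit-sum band maps", {
  pr <- default_profiles()
  expect_length(pr, 5)
  for (p in pr) expect_equal(sum(p$bands$power), 1)
  sig <- vapply(pr, function(p) paste(p$bands$power, collapse = ","), "")
  expect_equal(length(unique(sig)), 5)
})

test_that("deep-sleep-like epochs carry more relative delta power than wake-like", {
  pr <- default_profiles()
  names(pr) <- vapply(pr, `[[`, "", "name")
  em <- generate_stage_epochs(pr[c("Awa", "N3")], 50, te = 10, fs = 128,
                              seed = 12)
  delta <- apply(em$epochs, 1, periodogram_band_fraction, fs = 128,
                 lo = 0.5, hi = 4)
  wake_delta <- delta[em$labels == 0]
  n3_delta <- delta[em$labels == 1]
  frac <- mean(outer(n3_delta, wake_delta, ">"))
  expect_gte(frac, 0.99)
})

test_that("invalid profiles are rejected", {
  b <- data.frame(lo = 1, hi = 10, power = 0.5)
  expect_error(stage_profile("x", b), "sum to 1")
  b2 <- data.frame(lo = 1, hi = 40, power = 1)
  expect_error(stage_profile("x", b2), "0-35")
  expect_error(generate_stage_epochs(list(1), 5), "stage_profile")
})

test_that("the EDF fixture round-trips signal (to quantization) and labels (exactly)", {
  em <- generate_stage_epochs(default_profiles(), 4, te = 30, fs = 128,
                              seed = 13)
  path <- withr::local_tempfile(fileext = ".edf")
  p <- write_fixture_edf(em, path)
  rec <- load_recording(p$edf, "EEG Synth")
  em2 <- epoch_signal(rec, 30)
  qstep <- (max(em$epochs) - min(em$epochs)) * 1.01 / 65535
  expect_lt(max(abs(em2$epochs - em$epochs)), qstep)
  hyp <- load_hypnogram(p$hypnogram, "dreams_txt", 30, standard = "AASM")
  ml <- map_labels(hyp, label_scheme("AASM", 5))
  expect_equal(ml$classes, em$labels)
  bad <- epoch_matrix(matrix(1:100, 1), te = 100, fs = 1)
  expect_error(write_fixture_edf(bad, tempfile()), "labelled")
})
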