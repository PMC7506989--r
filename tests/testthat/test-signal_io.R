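# EDF reading, hypnogram dialects and label-scheme mapping.

test_that("EDF written by the package reads back with correct header and samples", {
  set.seed(11)
  fs <- 200
  rec <- eeg_record(rnorm(fs * 60, sd = 40), fs, channel = "EEG Test")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path, record_seconds = 1)
  back <- load_recording(path, "EEG Test")
  expect_equal(back$fs, 200)
  expect_length(back$samples, 12000)   # fs x duration
  qstep <- (max(rec$samples) - min(rec$samples)) * 1.01 / 65535
  expect_lt(max(abs(back$samples - rec$samples)), qstep)
})

test_that("channel matching normalizes case/whitespace and reports available channels", {
  rec <- eeg_record(sin(1:1000), 100, channel = "EEG Pz-Oz")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path, record_seconds = 1)
  expect_equal(load_recording(path, "eeg  pz-oz")$channel, "EEG Pz-Oz")
  expect_error(load_recording(path, "EEG Fpz-Cz"), "EEG Pz-Oz")
  expect_error(load_recording("/nonexistent/file.edf", "x"), "not found")
})

test_that("text hypnogram dialects parse one label per token and preserve exclusions", {
  path <- withr::local_tempfile()
  writeLines(c("W", "W", "R", "1", "2", "3"), path)
  hyp <- load_hypnogram(path, "dreams_txt", 20)
  expect_length(hyp$labels, 6)
  expect_equal(hyp$labels, c("Awa", "Awa", "REM", "S1", "S2", "S3"))

  writeLines(c("W", "9", "R"), path)
  hyp <- load_hypnogram(path, "dreams_txt", 20)
  expect_equal(hyp$labels[2], "excluded")

  writeLines(c("W", "Q", "R"), path)
  expect_error(load_hypnogram(path, "dreams_txt", 20), "unknown stage code 'Q' at line 2")

  writeLines(character(0), path)
  expect_error(load_hypnogram(path, "dreams_txt", 20), "zero labels")

  writeLines(c("0", "1", "2", "3", "5"), path)
  expect_equal(load_hypnogram(path, "isruc_txt", 30)$labels,
               c("Awa", "N1", "N2", "N3", "REM"))
})

test_that("hypnograms round-trip through every dialect", {
  rk <- hypnogram(c("Awa", "REM", "S1", "S2", "S3", "S4", "excluded", "Awa"),
                  30, "R&K")
  aasm <- hypnogram(c("Awa", "REM", "N1", "N2", "N3", "excluded"), 30, "AASM")
  for (d in c("dreams_txt", "edfplus")) {
    path <- withr::local_tempfile(fileext = if (d == "edfplus") ".edf" else ".txt")
    write_hypnogram(rk, path, d)
    expect_identical(load_hypnogram(path, d, 30, standard = "R&K")$labels,
                     rk$labels, label = d)
  }
  path <- withr::local_tempfile()
  write_hypnogram(aasm, path, "isruc_txt")
  expect_identical(load_hypnogram(path, "isruc_txt", 30)$labels, aasm$labels)
})

test_that("EDF+ annotation hypnograms honour stage event durations", {
  # a single 90 s wake event at 30 s epochs expands to three labels
  hyp <- hypnogram(rep(c("Awa", "REM"), c(3, 2)), 30, "R&K")
  path <- withr::local_tempfile(fileext = ".edf")
  write_hypnogram(hyp, path, "edfplus")
  back <- load_hypnogram(path, "edfplus", 30, standard = "R&K")
  expect_identical(back$labels, hyp$labels)
})

test_that("label schemes merge stages exactly as the class tables specify", {
  rk <- c("Awa", "REM", "S1", "S2", "S3", "S4")
  hyp <- hypnogram(rk, 30, "R&K")
  expect_equal(map_labels(hyp, label_scheme("R&K", 6))$classes, 0:5)
  expect_equal(map_labels(hyp, label_scheme("R&K", 5))$classes,
               c(0L, 1L, 2L, 3L, 4L, 4L))
  expect_equal(map_labels(hyp, label_scheme("R&K", 4))$classes,
               c(0L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(map_labels(hyp, label_scheme("R&K", 3))$classes,
               c(0L, 1L, 2L, 2L, 2L, 2L))
  expect_equal(map_labels(hyp, label_scheme("R&K", 2))$classes,
               c(0L, 1L, 1L, 1L, 1L, 1L))
  aasm <- hypnogram(c("Awa", "REM", "N1", "N2", "N3"), 30, "AASM")
  expect_equal(map_labels(aasm, label_scheme("AASM", 5))$classes, 0:4)
  expect_equal(map_labels(aasm, label_scheme("AASM", 4))$classes,
               c(0L, 1L, 2L, 2L, 3L))
  expect_equal(map_labels(aasm, label_scheme("AASM", 2))$classes,
               c(0L, 1L, 1L, 1L, 1L))
})

test_that("the image of every scheme is contiguous from 0 when all stages occur", {
  for (std in c("R&K", "AASM")) {
    maxc <- if (std == "R&K") 6 else 5
    stages <- if (std == "R&K") c("Awa", "REM", "S1", "S2", "S3", "S4")
              else c("Awa", "REM", "N1", "N2", "N3")
    hyp <- hypnogram(stages, 30, std)
    for (nc in 2:maxc) {
      cl <- map_labels(hyp, label_scheme(std, nc))$classes
      expect_setequal(cl, 0:(nc - 1))
    }
  }
})

test_that("excluded epochs are masked, never mapped, and counts add up", {
  hyp <- hypnogram(c("Awa", "excluded", "REM", "excluded", "S2"), 30, "R&K")
  ml <- map_labels(hyp, label_scheme("R&K", 6))
  expect_equal(sum(ml$keep) + sum(!ml$keep), length(hyp$labels))
  expect_length(ml$classes, 3)
  expect_error(map_labels(hyp, label_scheme("AASM", 5)), "does not match")
})
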