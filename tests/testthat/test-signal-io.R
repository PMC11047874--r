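# Record I/O round trips, format validation, segmentation arithmetic,
# normalisation, and the 12-lead linear derivation.

test_that("write/read round-trips a record to better than 1e-6", {
  set.seed(21)
  rec <- ecg_record(matrix(rnorm(8 * 5000), 8), 500, LEADS_8)
  path <- tempfile(fileext = ".csv")
  write_record(rec, path)
  back <- read_record(path)
  expect_lt(max(abs(back$signal - rec$signal)), 1e-6)
  expect_equal(back$fs, 500)
  expect_identical(back$lead_names, LEADS_8)
  unlink(path)
})

test_that("malformed record files raise format errors", {
  p <- tempfile(fileext = ".csv")
  # 7 columns: missing a lead
  writeLines(c("# fs=500", paste(LEADS_8[1:7], collapse = ","),
               paste(rep("0.1", 7), collapse = ",")), p)
  expect_error(read_record(p), class = "ecgdnn_format_error")
  # empty file
  writeLines(character(0), p)
  expect_error(read_record(p), class = "ecgdnn_format_error")
  # non-numeric cell, error names the offending row
  writeLines(c("# fs=500", paste(LEADS_8, collapse = ","),
               paste(rep("0.1", 8), collapse = ","),
               paste(c("oops", rep("0.2", 7)), collapse = ",")), p)
  expect_error(read_record(p), "row 2", class = "ecgdnn_format_error")
  # missing file
  expect_error(read_record(tempfile()), class = "ecgdnn_format_error")
  unlink(p)
})

test_that("12-lead derivation follows the Einthoven/Goldberger identities", {
  # constant worked example: I = 1, II = 2
  sig <- matrix(0, 8, 10, dimnames = list(LEADS_8, NULL))
  sig["I", ] <- 1
  sig["II", ] <- 2
  d <- derive_12_lead(ecg_record(sig, 100, LEADS_8))
  expect_identical(nrow(d$signal), 12L)
  expect_equal(unique(d$signal["III", ]), 1)
  expect_equal(unique(d$signal["aVR", ]), -1.5)
  expect_equal(unique(d$signal["aVL", ]), 0)
  expect_equal(unique(d$signal["aVF", ]), 1.5)
  # all-zero I/II give all-zero derived leads
  z <- derive_12_lead(ecg_record(matrix(0, 8, 5), 100, LEADS_8))
  expect_true(all(z$signal[9:12, ] == 0))
  # identities hold exactly on integer-valued inputs
  set.seed(22)
  im <- matrix(sample(-5:5, 8 * 64, TRUE), 8, dimnames = list(LEADS_8, NULL))
  rec <- ecg_record(im, 100, LEADS_8)
  d2 <- derive_12_lead(rec)
  expect_lt(max(abs(d2$signal["III", ] - (im["II", ] - im["I", ]))), 1e-12)
  expect_lt(max(abs(d2$signal["aVF", ] - (im["II", ] - im["I", ] / 2))),
            1e-12)
  expect_identical(d2$signal[1:8, ], rec$signal)
  expect_error(derive_12_lead(ecg_record(matrix(0, 2, 5), 100, c("X", "Y"))),
               class = "ecgdnn_param_error")
})

test_that("segment count follows floor((T - window)/hop) + 1", {
  rec <- ecg_record(matrix(rnorm(8 * 5000), 8, dimnames =
                             list(LEADS_8, NULL)), 500, LEADS_8)
  expect_length(segment(rec, segmentation_config(2500, 2500)), 2L)
  expect_length(segment(rec, segmentation_config(2000, 1000)), 4L)
  short <- ecg_record(matrix(rnorm(8 * 100), 8), 500, LEADS_8)
  expect_length(segment(short, segmentation_config(200)), 0L)
  # zero_pad adds one padded tail window
  segs <- segment(rec, segmentation_config(3000, 3000,
                                           pad_policy = "zero_pad"))
  expect_length(segs, 2L)
  expect_true(all(segs[[2]]$signal[, 2001:3000] == 0))
  expect_true(all(vapply(segs, function(s) ncol(s$signal), numeric(1)) ==
                    3000))
})

test_that("normalisation modes behave and z-score is idempotent", {
  set.seed(23)
  sig <- rbind(rnorm(100, 5, 2), rep(3, 100))
  rec <- ecg_record(sig, 100, c("I", "II"))
  z <- normalize_record(rec, "zscore")
  expect_equal(mean(z$signal[1, ]), 0, tolerance = 1e-12)
  expect_equal(mean(z$signal[1, ]^2), 1, tolerance = 1e-8)
  expect_true(all(z$signal[2, ] == 0))        # constant lead -> zeros
  z2 <- normalize_record(z, "zscore")
  expect_equal(z2$signal, z$signal, tolerance = 1e-10)
  m <- normalize_record(rec, "minmax")
  expect_equal(max(m$signal[1, ]), 1)
  expect_equal(min(m$signal[1, ]), -1)
})

test_that("datasets round-trip through the directory format", {
  ds <- make_dataset(3, seed = 4, duration_s = 2, fs = 100,
                     noise = default_noise(5))
  dir <- tempfile()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "labels.csv")))
  back <- read_dataset(dir)
  expect_length(back$records, 3L)
  expect_equal(back$records[[2]]$clean$signal, ds$records[[2]]$clean$signal,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$records[[2]]$labels, ds$records[[2]]$labels)
  expect_false(is.null(back$records[[1]]$noisy))
  unlink(dir, recursive = TRUE)
})
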