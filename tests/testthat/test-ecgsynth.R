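# Synthetic ECG generation, noise corruption with exact SNR targeting, and
# dataset assembly.

test_that("generation is deterministic for a fixed seed", {
  spec <- rhythm_spec(75, 0)
  a <- generate_clean(spec, 4, 250, seed = 5)
  b <- generate_clean(spec, 4, 250, seed = 5)
  expect_identical(a$signal, b$signal)
  expect_identical(dim(a$signal), c(8L, 1000L))
  expect_identical(a$lead_names, LEADS_8)
})

test_that("R-peak count matches the programmed heart rate", {
  rec <- generate_clean(rhythm_spec(60, 0), 10, 500, seed = 42)
  n_peaks <- length(detect_r_peaks(rec))
  expect_gte(n_peaks, 9L)
  expect_lte(n_peaks, 11L)
  fast <- generate_clean(rhythm_spec(120, 0, active_labels = 2L), 10, 500,
                         seed = 7)
  expect_gte(length(detect_r_peaks(fast)), 19L)
  expect_lte(length(detect_r_peaks(fast)), 21L)
})

test_that("rate labels are attached consistently at construction", {
  expect_equal(rhythm_spec(150, 0.05)$active_labels, 2L)   # tachycardia
  expect_equal(rhythm_spec(45, 0.05)$active_labels, 3L)    # bradycardia
  expect_equal(rhythm_spec(75, 0.3)$active_labels, 4L)     # sinus arrhythmia
  expect_equal(rhythm_spec(75, 0.05)$active_labels, 1L)    # sinus rhythm
  # supplied labels must agree with the rate-derived ones
  expect_error(rhythm_spec(150, 0.05, active_labels = 1L),
               class = "ecgdnn_param_error")
  rec <- generate_clean(rhythm_spec(150, 0), 5, 250, seed = 1)
  expect_equal(which(labels_of(rec) == 1L), 2L)
})

test_that("rate labels recomputed from detected RR intervals match", {
  for (k in c(1L, 2L, 3L, 5L, 6L, 12L)) {
    rec <- ecgdnn:::with_seed(100 + k, {
      generate_clean(class_rhythm_spec(k), 10, 250)
    })
    implied <- rate_labels_from_signal(rec)
    emitted <- intersect(which(labels_of(rec) == 1L), c(2L, 3L, 4L))
    expect_equal(sort(implied), sort(emitted), info = paste("class", k))
  }
})

test_that("corrupt hits any target SNR in [-10, 20] dB within 0.1 dB", {
  rec <- generate_clean(rhythm_spec(80, 0.05), 5, 250, seed = 3)
  for (kind in c("gaussian_white", "baseline_wander", "impulse")) {
    for (target in c(-10, -5, 0, 10, 20)) {
      out <- corrupt(rec, noise_spec(kind, target_snr_db = target,
                                     seed = 17))
      expect_lt(abs(snr(rec, out$noisy) - target), 0.1)
    }
  }
  comp <- corrupt(rec, default_noise(0, seed = 2))
  expect_lt(abs(snr(rec, comp$noisy)), 0.1)
})

test_that("0 dB corruption equalises signal and residual power", {
  rec <- generate_clean(rhythm_spec(70, 0), 5, 250, seed = 9)
  out <- corrupt(rec, noise_spec("gaussian_white", target_snr_db = 0,
                                 seed = 1))
  expect_equal(sum(rec$signal^2), sum(out$residual$signal^2),
               tolerance = 0.02)
  # determinism + clean record untouched
  out2 <- corrupt(rec, noise_spec("gaussian_white", target_snr_db = 0,
                                  seed = 1))
  expect_identical(out$residual$signal, out2$residual$signal)
  expect_identical(rec$signal, generate_clean(rhythm_spec(70, 0), 5, 250,
                                              seed = 9)$signal)
})

test_that("baseline wander residual has its spectral peak at the programmed
           frequency", {
  rec <- generate_clean(rhythm_spec(70, 0), 20, 250, seed = 4)
  out <- corrupt(rec, noise_spec("baseline_wander", target_snr_db = 0,
                                 params = list(freqs = 0.3, rel_amp = 1),
                                 seed = 5))
  sp <- stats::spec.pgram(stats::ts(out$residual$signal[1, ], frequency = 250),
                          plot = FALSE, taper = 0)
  peak_hz <- sp$freq[which.max(sp$spec)]
  expect_lt(abs(peak_hz - 0.3), 0.05)
})

test_that("noise specs validate their invariants", {
  expect_error(noise_spec("gaussian_white"), class = "ecgdnn_param_error")
  expect_error(noise_spec("gaussian_white", target_snr_db = 0,
                          amplitude = 1), class = "ecgdnn_param_error")
  expect_error(noise_spec("composite", target_snr_db = 0,
                          children = list(noise_spec("impulse",
                                                     amplitude = 1))),
               class = "ecgdnn_param_error")
})

test_that("make_dataset respects one-hot class frequencies and size", {
  freqs <- numeric(34)
  freqs[7] <- 1
  ds <- make_dataset(10, freqs, seed = 2, duration_s = 4, fs = 125)
  expect_length(ds$records, 10L)
  labs <- dataset_labels(ds)
  expect_true(all(labs[, 7] == 1))
  expect_true(all(labs[, -7] == 0))
  expect_true(all(rowSums(labs) >= 1))
})

test_that("empirical class split lies inside the binomial 99% CI", {
  freqs <- numeric(34)
  freqs[1] <- 0.8
  freqs[2] <- 0.2
  ds <- make_dataset(1000, freqs, seed = 31, duration_s = 2, fs = 100)
  n2 <- sum(dataset_labels(ds)[, 2])
  ci <- stats::qbinom(c(0.005, 0.995), 1000, 0.2)
  expect_gte(n2, ci[1])
  expect_lte(n2, ci[2])
})

test_that("dataset generation is reproducible and validates inputs", {
  a <- make_dataset(5, seed = 8, duration_s = 2, fs = 100)
  b <- make_dataset(5, seed = 8, duration_s = 2, fs = 100)
  expect_identical(dataset_labels(a), dataset_labels(b))
  expect_identical(a$records[[3]]$clean$signal, b$records[[3]]$clean$signal)
  expect_error(make_dataset(0), class = "ecgdnn_param_error")
  expect_error(make_dataset(3, numeric(34)), class = "ecgdnn_param_error")
})
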