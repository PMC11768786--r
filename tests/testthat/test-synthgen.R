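test_that("EMG generation is deterministic and honours degenerate calibrations", {
  cal <- emg_calibration("A")
  s1 <- generate_emg(cal, duration = 2, fs = 1000, seed = 42)
  s2 <- generate_emg(cal, duration = 2, fs = 1000, seed = 42)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_s3_class(s1, "sampled_signal")
  expect_equal(length(s1), 2000)

  s3 <- generate_emg(cal, duration = 2, fs = 1000, seed = 43)
  expect_false(identical(as.numeric(s1), as.numeric(s3)))

  zero <- emg_calibration("A", targets = list(
    arv = c(0, 0), iemg = c(0, 0), rms = c(0, 0),
    mpf = c(125, 0), mf = c(64, 0)))
  expect_equal(as.numeric(generate_emg(zero, duration = 1, seed = 1)),
               rep(0, 1000))

  expect_error(generate_emg(cal, duration = 2, fs = 260, seed = 1),
               "at least 500")
  # MPF band must fit under Nyquist: state-A VL target is 125.68 Hz
  expect_error(generate_emg(cal, duration = 2, fs = 500, band_sd = 60,
                            seed = 1), "too low")
})

test_that("clean EMG reproduces the calibrated RMS and MPF targets", {
  cal <- emg_calibration("A")
  s <- generate_emg(cal, duration = 10, fs = 1000, seed = 1,
                    draw_targets = FALSE)
  expect_equal(emg_rms(s), cal$targets$rms[1], tolerance = 0.02)
  expect_equal(mpf(estimate_psd(s, seg_s = 1)), cal$targets$mpf[1],
               tolerance = 0.02)
})

test_that("generated features preserve the monotone fatigue structure", {
  # RMS strictly rises A -> B -> C, MPF strictly falls, in the mean
  seeds <- 1:20
  stats_by_state <- sapply(c("A", "B", "C"), function(st) {
    cal <- emg_calibration(st)
    vals <- sapply(seeds, function(sd) {
      s <- generate_emg(cal, duration = 2, fs = 1000, seed = sd)
      c(rms = emg_rms(s), mpf = mpf(estimate_psd(s, seg_s = 1)))
    })
    rowMeans(vals)
  })
  expect_true(stats_by_state["rms", "A"] < stats_by_state["rms", "B"])
  expect_true(stats_by_state["rms", "B"] < stats_by_state["rms", "C"])
  expect_true(stats_by_state["mpf", "A"] > stats_by_state["mpf", "B"])
  expect_true(stats_by_state["mpf", "B"] > stats_by_state["mpf", "C"])
})

test_that("contaminants are added additively and only when enabled", {
  cal <- emg_calibration("A")
  clean <- generate_emg(cal, duration = 2, seed = 9)
  cont <- contaminant_spec(mains_amp = 2, mains_freq = 50)
  dirty <- generate_emg(cal, duration = 2, contaminants = cont, seed = 9)
  # the added component is a pure 50 Hz tone of amplitude 2
  diffsig <- as.numeric(dirty) - as.numeric(clean)
  p <- estimate_psd(diffsig, fs = 1000, seg_s = 1)
  expect_equal(p$freqs[which.max(p$power)], 50)
  expect_equal(emg_rms(diffsig), 2 / sqrt(2), tolerance = 1e-3)
  expect_error(contaminant_spec(drift_amp = -1), ">= 0")
  expect_error(contaminant_spec(drift_freq = 5), "below 3")
})

test_that("constant-RR ECG has the requested beat count and exact HR", {
  s <- generate_ecg(constant_hr_cal(60), duration = 10.6, seed = 1)
  expect_equal(length(attr(s, "beat_times")), 10)
  rr <- detect_r_peaks(remove_ecg_baseline(s))
  expect_equal(length(rr$peak_times), 10)
  expect_equal(heart_rate(rr), 60, tolerance = 1e-6)
})

test_that("ECG generation validates duration against HRV calibration", {
  expect_error(generate_ecg(ecg_calibration("A"), duration = 5, seed = 1),
               "at least 10")
  expect_error(generate_ecg(ecg_calibration("A"), duration = 20, seed = 1),
               "LF cycle")
  # no HRV requested: short recordings are fine
  expect_s3_class(generate_ecg(constant_hr_cal(70), duration = 12, seed = 1),
                  "sampled_signal")
  s1 <- generate_ecg(ecg_calibration("B"), duration = 30, seed = 5)
  s2 <- generate_ecg(ecg_calibration("B"), duration = 30, seed = 5)
  expect_identical(as.numeric(s1), as.numeric(s2))
})

test_that("feature datasets have requested composition, shapes and seeding", {
  d <- generate_feature_dataset(c(30, 28, 28), seq_len = 10, seed = 1)
  expect_equal(length(d$x), 86)
  expect_equal(as.integer(table(d$y)), c(30, 28, 28))
  expect_true(all(vapply(d$x, function(m) all(dim(m) == c(10, 5)), TRUE)))
  expect_equal(colnames(d$x[[1]]), c("rms", "mpf", "hr", "lf", "hf"))

  d1 <- generate_feature_dataset(c(1, 1, 1), seq_len = 1, seed = 2)
  expect_equal(length(d1$x), 3)
  expect_true(all(vapply(d1$x, function(m) all(dim(m) == c(1, 5)), TRUE)))

  da <- generate_feature_dataset(c(2, 2, 2), seq_len = 4, seed = 10)
  db <- generate_feature_dataset(c(2, 2, 2), seq_len = 4, seed = 11)
  expect_identical(da$y, db$y)
  expect_false(identical(da$x, db$x))
  dc <- generate_feature_dataset(c(2, 2, 2), seq_len = 4, seed = 10)
  expect_identical(da$x, dc$x)

  expect_error(generate_feature_dataset(c(0, 1, 1), seed = 1), "positive")

  # optional constant subject covariates ride along but never enter x
  dcov <- generate_feature_dataset(c(2, 2, 2), seq_len = 3, seed = 1,
                                   covariates = TRUE)
  expect_equal(dim(dcov$covariates), c(6, 3))
  expect_equal(names(dcov$covariates), c("age", "height", "weight"))
  expect_equal(ncol(dcov$x[[1]]), 5)
})

test_that("signal-mode datasets run the real extraction chain", {
  d <- generate_feature_dataset(c(1, 1, 1), seq_len = 3, seed = 4,
                                method = "signal")
  expect_equal(length(d$x), 3)
  expect_true(all(is.finite(unlist(d$x))))
  # HR should reflect the state ordering even from 3 signal samples
  hrs <- vapply(d$x, function(m) m[1, "hr"], 0)
  expect_true(hrs[1] < hrs[3])
})

test_that("fatigue state table is fixed", {
  st <- fatigue_states()
  expect_equal(st$label, c("A", "B", "C"))
  expect_equal(st$rpe, c(8L, 13L, 18L))
})
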