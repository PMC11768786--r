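test_that("high-pass filter meets its stop- and pass-band specification", {
  fs <- 1000
  low <- tone(1, fs, 4)
  hp <- highpass_emg(low)
  expect_lt(central_rms(hp), 0.01 * central_rms(low))   # >= 40 dB at 1 Hz

  pass <- tone(80, fs, 4)
  hp80 <- highpass_emg(pass)
  expect_lt(abs(central_rms(hp80) - central_rms(pass)) / central_rms(pass),
            0.11)                                       # <= 1 dB at 80 Hz

  zeros <- sampled_signal(rep(0, fs), fs, "emg")
  expect_equal(as.numeric(highpass_emg(zeros)), rep(0, fs))
  expect_error(highpass_emg(sampled_signal(rnorm(100), 30, "emg")),
               "Nyquist")
})

test_that("notch removes mains and spares neighbouring frequencies", {
  fs <- 1000
  mains <- tone(50, fs, 4)
  expect_lt(central_rms(notch_mains(mains)), 0.032 * central_rms(mains))
  for (f in c(35, 65)) {
    tn <- tone(f, fs, 4)
    out <- notch_mains(tn)
    expect_gt(central_rms(out), 10^(-3 / 20) * central_rms(tn))  # <= 3 dB
  }
  zeros <- sampled_signal(rep(0, fs), fs, "emg")
  expect_equal(as.numeric(notch_mains(zeros)), rep(0, fs))
})

test_that("broadband power is reduced only near the mains frequency", {
  set.seed(7)
  s <- sampled_signal(rnorm(8000), 1000, "emg")
  p_in <- estimate_psd(s, seg_s = 1)
  p_out <- estimate_psd(notch_mains(s), seg_s = 1)
  away <- p_in$freqs < 40 | p_in$freqs > 60
  # away from the notch the PSD is essentially untouched
  expect_equal(sum(p_out$power[away]), sum(p_in$power[away]),
               tolerance = 0.02)
  near <- p_in$freqs >= 48 & p_in$freqs <= 52
  expect_lt(sum(p_out$power[near]), 0.2 * sum(p_in$power[near]))
})

test_that("fast median filter matches hand-evaluated and trivial cases", {
  expect_equal(fast_median_filter(c(0, 0, 9, 0, 0), K = 1), rep(0, 5))
  for (K in c(1, 3, 7))
    expect_equal(fast_median_filter(rep(2.5, 40), K), rep(2.5, 40))
  expect_error(fast_median_filter(1:5, K = 3), "exceeds")
  expect_error(fast_median_filter(1:5, K = 0), "positive integer")
})

test_that("incremental median filter equals the full-sort oracle everywhere", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    K <- sample(seq_len((n - 1) %/% 2), 1)
    x <- if (rep %% 2 == 0) rnorm(n) else as.numeric(sample(0:3, n, TRUE))
    expect_identical(fast_median_filter(x, K), naive_median_filter(x, K))
  }
  # large instance, tie-heavy
  x <- as.numeric(sample(0:9, 10000, TRUE))
  got <- fast_median_filter(x, K = 50)
  expect_identical(got, naive_median_filter(x, K = 50))
  # independent cross-check of the interior against stats::runmed
  rm_ <- as.numeric(stats::runmed(x, 101))
  expect_identical(got[51:9950], rm_[51:9950])
})

test_that("per-step work is logarithmic comparisons, never a full sort", {
  set.seed(3)
  x <- rnorm(3000)
  K <- 50
  L <- 2 * K + 1
  inst <- fast_median_filter(x, K, instrumented = TRUE)
  expect_identical(as.numeric(inst), fast_median_filter(x, K))
  cmps <- attr(inst, "comparisons")[-1]
  # two binary searches of a length-L buffer per step
  expect_lte(max(cmps), 2 * (floor(log2(L)) + 2))
  # far below the (2K+1) comparisons of a per-window selection
  expect_lt(mean(cmps), L / 2)
})

test_that("filters are scale-equivariant", {
  set.seed(21)
  x <- rnorm(1500)
  s <- sampled_signal(x, 1000, "emg")
  s5 <- sampled_signal(5 * x, 1000, "emg")
  expect_equal(as.numeric(highpass_emg(s5)), 5 * as.numeric(highpass_emg(s)))
  expect_equal(as.numeric(notch_mains(s5)), 5 * as.numeric(notch_mains(s)))
  expect_equal(fast_median_filter(5 * x, 20), 5 * fast_median_filter(x, 20))
})

test_that("median baseline removal suppresses drift and keeps R peaks", {
  cal <- constant_hr_cal(70)
  cont <- contaminant_spec(drift_amp = 0.5, drift_freq = 0.3)
  dirty <- generate_ecg(cal, duration = 30, contaminants = cont, seed = 8)
  clean <- generate_ecg(cal, duration = 30, seed = 8)
  corrected <- remove_ecg_baseline(dirty)

  # sub-1 Hz band power collapses relative to the contaminated signal
  p_dirty <- estimate_psd(dirty, seg_s = 10)
  p_corr <- estimate_psd(corrected, seg_s = 10)
  sub1 <- function(p) band_power(p, c(0.05, 1))
  expect_lt(sub1(p_corr), 0.01 * sub1(p_dirty))

  # R amplitudes preserved within 10%
  bt <- attr(dirty, "beat_times")
  idx <- round(bt * 500) + 1
  expect_lt(max(abs(corrected[idx] - clean[idx])), 0.1)

  # drift-free input passes through nearly unchanged
  corr2 <- remove_ecg_baseline(clean)
  expect_lt(max(abs(as.numeric(corr2) - as.numeric(clean))), 0.1)

  # pure drift with no beats is removed almost entirely (interior; the
  # reflect-padded edges carry a larger transient)
  t <- seq(0, 30, by = 1 / 500)
  drift <- sampled_signal(0.5 * sin(2 * pi * 0.3 * t), 500, "ecg")
  resid <- as.numeric(remove_ecg_baseline(drift))
  nn <- length(resid)
  expect_lt(max(abs(resid[500:(nn - 500)])), 0.05)
})
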