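# Independent oracles used across the suite.

# Naive median filter: full sort of every window, reflect padding.
naive_median_filter <- function(x, K) {
  n <- length(x)
  xp <- c(rev(x[2:(K + 1)]), x, rev(x[(n - K):(n - 1)]))
  vapply(seq_len(n), function(i) stats::median(xp[i:(i + 2 * K)]), 0)
}

# Central finite-difference gradient of the mean cross-entropy w.r.t. the
# flattened parameter vector.
numeric_lstm_gradient <- function(params, x, y, h = 1e-4) {
  v <- exfatigue:::params_to_vector(params)
  f <- function(vv)
    lstm_gradients(exfatigue:::vector_to_params(vv, params), x, y)$loss
  vapply(seq_along(v), function(k) {
    vp <- v; vm <- v
    vp[k] <- v[k] + h
    vm[k] <- v[k] - h
    (f(vp) - f(vm)) / (2 * h)
  }, 0)
}

# Pure tone as a sampled_signal.
tone <- function(freq, fs, duration, amp = 1, kind = "emg") {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  sampled_signal(amp * sin(2 * pi * freq * t), fs = fs, kind = kind)
}

# RMS over the central half of a signal (skips filter edge transients).
central_rms <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  emg_rms(x[floor(n / 4):ceiling(3 * n / 4)])
}

# ECG calibration with fixed heart rate and no HRV modulation.
constant_hr_cal <- function(hr) {
  ecg_calibration("A", targets = list(hr = c(hr, 0), hf = c(0, 0),
                                      lf = c(0, 0), lf_hf = c(0, 0)))
}

# A linearly separable two-class toy sequence problem.
toy_sequences <- function(n_per_class = 6, T_ = 3, F_ = 2, seed = 1) {
  set.seed(seed)
  x <- list(); y <- character(0)
  for (cls in 1:2) {
    mu <- if (cls == 1) 0.2 else 0.8
    for (i in seq_len(n_per_class)) {
      x[[length(x) + 1]] <- matrix(stats::rnorm(T_ * F_, mu, 0.05), T_, F_,
                                   dimnames = list(NULL, paste0("f", 1:F_)))
      y <- c(y, c("lo", "hi")[cls])
    }
  }
  list(x = x, y = factor(y, levels = c("lo", "hi")))
}
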