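#' Digital filters for surface EMG
#'
#' `highpass_emg()` removes baseline drift (0.15 Hz to a few Hz) and motion
#' artifacts (3-14 Hz) with a zero-phase Butterworth high-pass whose default
#' 20 Hz cutoff sits just below the 20-150 Hz band that carries the EMG
#' energy. `notch_mains()` suppresses mains interference with a zero-phase
#' Butterworth band-stop centred on the power-line frequency. Both are
#' applied forward-backward (`signal::filtfilt`), so they are zero-phase
#' and their stop-band attenuation is doubled relative to a single pass.
#'
#' @param signal A [sampled_signal()] (any kind; EMG is the intended use).
#' @param cutoff High-pass cutoff frequency in Hz (default 20).
#' @param order Butterworth order (default 4 for the high-pass, 2 for the
#'   band-stop prototype).
#' @param mains Mains frequency in Hz (default 50).
#' @param bandwidth Full stop-band width in Hz around `mains` (default 4).
#' @return A filtered [sampled_signal()] of the same length and rate.
#' @examples
#' t <- seq(0, 1, by = 1 / 1000)
#' s <- sampled_signal(sin(2 * pi * 1 * t) + sin(2 * pi * 80 * t), 1000, "emg")
#' out <- highpass_emg(s)            # the 1 Hz component is removed
#' @export
highpass_emg <- function(signal, cutoff = 20, order = 4) {
  stopifnot(inherits(signal, "sampled_signal"))
  fs <- signal_fs(signal)
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop(sprintf("cutoff %g Hz must lie in (0, Nyquist = %g Hz)",
                 cutoff, fs / 2))
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  with_samples(signal, signal::filtfilt(bf, as.numeric(signal)))
}

#' @rdname highpass_emg
#' @export
notch_mains <- function(signal, mains = 50, bandwidth = 4, order = 2) {
  stopifnot(inherits(signal, "sampled_signal"))
  fs <- signal_fs(signal)
  if (mains + bandwidth / 2 >= fs / 2)
    stop(sprintf("notch at %g Hz does not fit below Nyquist (%g Hz)",
                 mains, fs / 2))
  band <- c(mains - bandwidth / 2, mains + bandwidth / 2) / (fs / 2)
  bf <- signal::butter(order, band, type = "stop")
  with_samples(signal, signal::filtfilt(bf, as.numeric(signal)))
}

# Leftmost-insertion binary search with an explicit comparison counter:
# returns the number of elements of sorted `buf` that are <= v, and the
# comparisons spent. Identical result to findInterval(v, buf).
bsearch_count <- function(v, buf) {
  lo <- 0L; hi <- length(buf); cmp <- 0L
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    cmp <- cmp + 1L
    if (buf[mid] <= v) lo <- mid else hi <- mid - 1L
  }
  c(pos = lo, cmp = cmp)
}

#' Incremental sliding-window median filter
#'
#' Order-statistic filter: `y[n]` is the median of the length `2K + 1`
#' window of `x` centred at `n`, with reflected edges. Rather than sorting
#' each window from scratch (`(N - 2K) * (2K + 1)` comparisons overall), the
#' filter keeps the current window as a sorted buffer and, per output
#' sample, deletes the outgoing sample and binary-search-inserts the
#' incoming one — O(log L) comparisons plus one O(L) element shift per step.
#' The output is bit-identical to the naive full-sort median.
#'
#' @param x A [sampled_signal()] or numeric vector.
#' @param K Positive integer half-width; the window length is `2K + 1` and
#'   must not exceed `length(x)`.
#' @param instrumented If TRUE, attach attribute `"comparisons"` — the
#'   per-step comparison counts of the binary searches — for complexity
#'   auditing (slower; uses an R-level counting search instead of
#'   `findInterval`).
#' @return Filtered signal, same class and length as `x`.
#' @examples
#' fast_median_filter(c(0, 0, 9, 0, 0), K = 1)  # impulse removed
#' @export
fast_median_filter <- function(x, K, instrumented = FALSE) {
  sig <- NULL
  if (inherits(x, "sampled_signal")) { sig <- x; x <- as.numeric(x) }
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K))
    stop("'K' must be a positive integer")
  K <- as.integer(K)
  n <- length(x)
  L <- 2L * K + 1L
  if (L > n) stop(sprintf("window length %d exceeds signal length %d", L, n))
  xp <- c(rev(x[2:(K + 1L)]), x, rev(x[(n - K):(n - 1L)]))
  buf <- sort(xp[1:L])
  out <- numeric(n)
  out[1] <- buf[K + 1L]
  cmps <- if (instrumented) integer(n) else NULL
  for (i in 2:n) {
    out_val <- xp[i - 1L]
    in_val <- xp[i + L - 1L]
    if (out_val != in_val) {
      if (instrumented) {
        d <- bsearch_count(out_val, buf)
        buf <- buf[-d[["pos"]]]
        ins <- bsearch_count(in_val, buf)
        buf <- append(buf, in_val, after = ins[["pos"]])
        cmps[i] <- d[["cmp"]] + ins[["cmp"]]
      } else {
        buf <- buf[-findInterval(out_val, buf)]
        buf <- append(buf, in_val, after = findInterval(in_val, buf))
      }
    }
    out[i] <- buf[K + 1L]
  }
  if (instrumented) attr(out, "comparisons") <- cmps
  if (!is.null(sig)) {
    res <- with_samples(sig, out)
    if (instrumented) attr(res, "comparisons") <- cmps
    res
  } else out
}

#' Remove ECG baseline drift by median filtering
#'
#' Estimates the baseline as the running median over a window wide enough to
#' straddle any single QRS complex (default 0.6 s) and subtracts it, which
#' suppresses sub-Hz drift while leaving the R-peak amplitudes essentially
#' untouched.
#'
#' @param signal An ECG [sampled_signal()].
#' @param K Median half-width in samples; default gives a window of about
#'   0.6 s, rounded to an odd sample count.
#' @return Baseline-corrected [sampled_signal()].
#' @examples
#' cal <- ecg_calibration("A")
#' cont <- contaminant_spec(drift_amp = 0.5, drift_freq = 0.3)
#' s <- generate_ecg(cal, duration = 30, contaminants = cont, seed = 2)
#' clean <- remove_ecg_baseline(s)
#' @export
remove_ecg_baseline <- function(signal, K = NULL) {
  stopifnot(inherits(signal, "sampled_signal"))
  fs <- signal_fs(signal)
  if (is.null(K)) K <- max(1L, round(0.3 * fs))
  base <- fast_median_filter(as.numeric(signal), K)
  with_samples(signal, as.numeric(signal) - base)
}
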