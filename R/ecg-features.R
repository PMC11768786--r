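#' Detect R peaks with an adaptive-threshold (Pan-Tompkins style) detector
#'
#' Classic QRS emphasis chain: band-pass (5-15 Hz) to isolate QRS energy,
#' differentiation, squaring, and a 150 ms moving-window integration; peaks
#' of the integrated signal are then accepted or rejected by running signal
#' and noise levels (exponentially updated), with a 200 ms refractory
#' period. Accepted detections are refined to the local maximum of the
#' band-passed signal within +/- 100 ms.
#'
#' @param signal A baseline-corrected ECG [sampled_signal()].
#' @param refractory Minimum inter-beat interval in seconds (default 0.2).
#' @return An object of class `rr_series`: list with `peak_times` (s),
#'   `rr_ms` (successive RR intervals, ms, cleaned to the physiological
#'   250-2000 ms range), `n_removed` (intervals dropped by cleaning), and
#'   `status` (`"ok"` or `"no_peaks"`). No detected peak yields an explicit
#'   `"no_peaks"` status rather than a silent zero heart rate.
#' @examples
#' cal <- ecg_calibration("A", targets = list(hr = c(60, 0), hf = c(0, 0),
#'                                            lf = c(0, 0), lf_hf = c(0, 0)))
#' s <- generate_ecg(cal, duration = 12, seed = 1)
#' rr <- detect_r_peaks(s)
#' heart_rate(rr)
#' @export
detect_r_peaks <- function(signal, refractory = 0.2) {
  stopifnot(inherits(signal, "sampled_signal"))
  fs <- signal_fs(signal)
  x <- as.numeric(signal)
  n <- length(x)
  if (n < fs) stop("recording too short for R-peak detection")
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x)
  xd <- c(0, diff(xb))
  xs <- xd^2
  wi <- max(3L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(xs, rep(1 / wi, wi), sides = 2))
  integ[is.na(integ)] <- 0
  # candidate local maxima of the integrated signal
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  if (!length(cand) || max(integ) <= 0)
    return(empty_rr())
  # adaptive running thresholds, initialised from the first 2 s
  init <- integ[seq_len(min(n, round(2 * fs)))]
  spk <- max(init)
  npk <- mean(init) * 0.5
  thr <- npk + 0.25 * (spk - npk)
  ref_n <- refractory * fs
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last < ref_n) next
    if (integ[i] > thr) {
      spk <- 0.125 * integ[i] + 0.875 * spk
      peaks <- c(peaks, i)
      last <- i
    } else {
      npk <- 0.125 * integ[i] + 0.875 * npk
    }
    thr <- npk + 0.25 * (spk - npk)
  }
  if (!length(peaks)) return(empty_rr())
  # refine each detection to the band-passed local maximum (+/- 100 ms)
  half <- round(0.1 * fs)
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(xb[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period after refinement
  keep <- c(TRUE, diff(refined) >= ref_n)
  refined <- refined[keep]
  pt <- (refined - 1L) / fs
  rr <- diff(pt) * 1000
  ok <- rr >= 250 & rr <= 2000
  structure(list(peak_times = pt, rr_ms = rr[ok], rr_times = pt[-1][ok],
                 n_removed = sum(!ok), status = "ok", fs = fs),
            class = "rr_series")
}

empty_rr <- function() {
  structure(list(peak_times = numeric(0), rr_ms = numeric(0),
                 rr_times = numeric(0),
                 n_removed = 0L, status = "no_peaks", fs = NA_real_),
            class = "rr_series")
}

#' Build an RR series from explicit peak times or intervals
#'
#' Convenience constructor used when RR intervals come from elsewhere (for
#' example a prescribed tachogram in a validation study).
#'
#' @param peak_times Strictly increasing R-peak times in seconds, or `NULL`
#'   if `rr_ms` is given.
#' @param rr_ms Successive RR intervals in ms (derived from `peak_times`
#'   when those are supplied).
#' @return An `rr_series`.
#' @export
rr_series <- function(peak_times = NULL, rr_ms = NULL) {
  if (!is.null(peak_times)) {
    if (is.unsorted(peak_times, strictly = TRUE))
      stop("'peak_times' must be strictly increasing")
    rr_ms <- diff(peak_times) * 1000
  } else if (!is.null(rr_ms)) {
    if (any(rr_ms <= 0)) stop("'rr_ms' must be positive")
    peak_times <- cumsum(c(0, rr_ms)) / 1000
  } else stop("give either 'peak_times' or 'rr_ms'")
  structure(list(peak_times = peak_times, rr_ms = rr_ms,
                 rr_times = peak_times[-1],
                 n_removed = 0L, status = if (length(peak_times)) "ok"
                 else "no_peaks", fs = NA_real_),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  if (x$status == "no_peaks") cat("<rr_series> no peaks detected\n")
  else cat(sprintf("<rr_series> %d peaks over %.1f s, mean RR %.0f ms\n",
                   length(x$peak_times), diff(range(x$peak_times)),
                   mean(x$rr_ms)))
  invisible(x)
}

#' Mean heart rate from an RR series
#'
#' `HR = 60000 / mean(RR)` with RR in ms.
#'
#' @param rr An `rr_series`.
#' @return Heart rate in beats/min.
#' @examples
#' heart_rate(rr_series(rr_ms = c(800, 1000, 1200)))  # 60
#' @export
heart_rate <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  if (rr$status == "no_peaks" || !length(rr$rr_ms))
    stop("no R peaks available: cannot compute a heart rate")
  60000 / mean(rr$rr_ms)
}

#' HRV spectral band powers from an RR series
#'
#' The RR tachogram is interpolated onto a uniform 4 Hz grid (cubic
#' spline), linearly detrended, and its Welch PSD integrated over the
#' low-frequency (0.04-0.15 Hz) and high-frequency (0.15-0.4 Hz) bands.
#' Powers are in ms^2; the LF/HF ratio indexes sympathovagal balance and
#' falls as fatigue deepens.
#'
#' @param rr An `rr_series` spanning at least `min_span` seconds.
#' @param resample_fs Tachogram resampling rate in Hz (default 4).
#' @param min_span Minimum span of the RR series in seconds (default 100,
#'   i.e. four full LF cycles; shorter series give meaningless LF power and
#'   raise an error naming this minimum).
#' @param seg_s Welch segment length in seconds (default 120).
#' @return List of class `ecg_features`: `hr` (beats/min), `lf`, `hf`
#'   (ms^2) and `lf_hf` (ratio, `NA` when HF is zero).
#' @examples
#' t <- seq(0, 300, by = 1)                      # one beat per second
#' rr <- rr_series(peak_times = t + 0.015 * sin(2 * pi * 0.1 * t))
#' hrv_band_powers(rr)$lf                        # about 450 ms^2
#' @export
hrv_band_powers <- function(rr, resample_fs = 4, min_span = 100,
                            seg_s = 120) {
  stopifnot(inherits(rr, "rr_series"))
  if (rr$status == "no_peaks" || length(rr$rr_ms) < 2)
    stop("no usable RR intervals for HRV analysis")
  span <- diff(range(rr$peak_times))
  if (span < min_span)
    stop(sprintf(paste0("RR series spans %.1f s; HRV band powers need at ",
                        "least %g s (four LF cycles)"), span, min_span))
  # tachogram: RR value at the time of the closing beat of each interval
  tt <- rr$rr_times
  grid <- seq(tt[1], tt[length(tt)], by = 1 / resample_fs)
  tach <- stats::spline(tt, rr$rr_ms, xout = grid, method = "natural")$y
  tach <- stats::lsfit(grid, tach)$residuals     # linear detrend
  psd <- estimate_psd(tach, fs = resample_fs,
                      seg_s = min(seg_s, length(grid) / resample_fs),
                      overlap = 0.5)
  lf <- band_power(psd, c(0.04, 0.15))
  hf <- band_power(psd, c(0.15, 0.40), closed = TRUE)
  structure(list(hr = heart_rate(rr), lf = lf, hf = hf,
                 lf_hf = if (hf > 0) lf / hf else NA_real_),
            class = "ecg_features")
}

#' @export
print.ecg_features <- function(x, ...) {
  cat(sprintf("<ecg_features> HR %.1f bpm, LF %.1f ms^2, HF %.1f ms^2, LF/HF %.2f\n",
              x$hr, x$lf, x$hf, x$lf_hf))
  invisible(x)
}

#' Full ECG feature extraction for one recording
#'
#' Baseline removal (median filter), R-peak detection, heart rate and HRV
#' band powers in one call.
#'
#' @param signal A raw ECG [sampled_signal()].
#' @param remove_baseline Apply [remove_ecg_baseline()] first (default TRUE).
#' @param ... Passed to [hrv_band_powers()].
#' @return An `ecg_features` list (`hr`, `lf`, `hf`, `lf_hf`).
#' @export
ecg_features <- function(signal, remove_baseline = TRUE, ...) {
  if (remove_baseline) signal <- remove_ecg_baseline(signal)
  rr <- detect_r_peaks(signal)
  hrv_band_powers(rr, ...)
}
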