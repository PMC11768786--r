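#' Time-domain EMG fatigue indicators
#'
#' The three standard amplitude indicators of surface EMG computed over one
#' analysis window: the average rectified value
#' \deqn{ARV = \frac{1}{N}\sum_{i=1}^{N} |x_i|,}
#' the integrated EMG
#' \deqn{IEMG = \sum_{i=1}^{N} |x_i| \, \Delta t = ARV \cdot T,}
#' and the root mean square
#' \deqn{RMS = \sqrt{\frac{1}{N}\sum_{i=1}^{N} x_i^2}.}
#' All three rise with muscular fatigue. By Cauchy-Schwarz,
#' `emg_rms(x) >= emg_arv(x)` for every window.
#'
#' @param x Numeric vector (one analysis window) or a [sampled_signal()].
#' @param fs Sampling rate in Hz, required by `emg_iemg()` for plain
#'   numeric input.
#' @return A single numeric value (amplitude units; `emg_iemg` in
#'   amplitude-seconds).
#' @examples
#' emg_arv(c(1, -1, 2, -2))            # 1.5
#' emg_rms(c(1, -1, 2, -2))            # sqrt(2.5)
#' emg_iemg(c(1, -1, 2, -2), fs = 4)   # 1.5
#' @export
emg_arv <- function(x) {
  x <- feature_window(x)
  mean(abs(x))
}

#' @rdname emg_arv
#' @export
emg_iemg <- function(x, fs = NULL) {
  if (inherits(x, "sampled_signal")) fs <- signal_fs(x)
  if (is.null(fs)) stop("'fs' is required for plain numeric input")
  x <- feature_window(x)
  sum(abs(x)) / fs
}

#' @rdname emg_arv
#' @export
emg_rms <- function(x) {
  x <- feature_window(x)
  sqrt(mean(x^2))
}

feature_window <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L) stop("empty analysis window")
  x
}

#' Frequency-domain EMG fatigue indicators
#'
#' Mean power frequency (the power-weighted spectral centroid)
#' \deqn{MPF = \frac{\int_0^\infty f \, PSD(f)\, df}{\int_0^\infty PSD(f)\, df}}
#' and median frequency, the smallest frequency at which the cumulative
#' power reaches half the total
#' \deqn{\int_0^{MF} PSD(f)\, df \ge \tfrac12 \int_0^\infty PSD(f)\, df.}
#' Both shift downward as the muscle fatigues. Ties at exactly half power
#' resolve to the lower frequency (the `>=` rule).
#'
#' @param psd A `psd_estimate` from [estimate_psd()].
#' @return Frequency in Hz.
#' @examples
#' p <- structure(list(freqs = c(50, 150), power = c(1, 1), df = 100),
#'                class = "psd_estimate")
#' mpf(p)  # 100
#' mf(p)   # 50
#' @export
mpf <- function(psd) {
  stopifnot(inherits(psd, "psd_estimate"))
  tot <- sum(psd$power)
  if (tot <= 0) stop("MPF is undefined for an all-zero PSD")
  sum(psd$freqs * psd$power) / tot
}

#' @rdname mpf
#' @export
mf <- function(psd) {
  stopifnot(inherits(psd, "psd_estimate"))
  tot <- sum(psd$power)
  if (tot <= 0) stop("MF is undefined for an all-zero PSD")
  cum <- cumsum(psd$power)
  psd$freqs[which(cum >= tot / 2)[1]]
}

#' All five EMG fatigue indicators, per analysis window
#'
#' Slices the recording into consecutive windows and computes ARV, IEMG,
#' RMS (time domain) and MPF, MF (frequency domain, Welch PSD) for each.
#'
#' @param signal An EMG [sampled_signal()].
#' @param window_s Window length in seconds; `NULL` treats the whole
#'   recording as a single window.
#' @param psd_seg_s Welch segment length in seconds (default 1, 50% overlap,
#'   Hann taper), capped at the window length.
#' @return A data.frame with columns `t` (window start, s), `arv`, `iemg`,
#'   `rms`, `mpf`, `mf`.
#' @examples
#' cal <- emg_calibration("A")
#' s <- generate_emg(cal, duration = 2, fs = 1000, seed = 1)
#' emg_features(s, window_s = 1)
#' @export
emg_features <- function(signal, window_s = 1, psd_seg_s = 1) {
  stopifnot(inherits(signal, "sampled_signal"))
  fs <- signal_fs(signal)
  x <- as.numeric(signal)
  n <- length(x)
  nw <- if (is.null(window_s)) n else round(window_s * fs)
  if (nw < 8 || nw > n) stop("invalid window length for this recording")
  starts <- seq(1L, n - nw + 1L, by = nw)
  seg_s <- min(psd_seg_s, nw / fs)
  rows <- lapply(starts, function(s) {
    w <- x[s:(s + nw - 1L)]
    psd <- estimate_psd(w, fs = fs, seg_s = seg_s)
    zero <- sum(psd$power) <= 0
    data.frame(t = (s - 1) / fs,
               arv = emg_arv(w), iemg = emg_iemg(w, fs), rms = emg_rms(w),
               mpf = if (zero) NA_real_ else mpf(psd),
               mf = if (zero) NA_real_ else mf(psd))
  })
  do.call(rbind, rows)
}
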