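#' Welch power spectral density estimate
#'
#' Averaged modified periodogram (Welch) estimate with a Hann taper and
#' density scaling, so that `sum(power) * df` equals the signal variance
#' (Parseval). Used both for the EMG spectral indicators and for HRV band
#' powers of the resampled RR tachogram.
#'
#' @param x A [sampled_signal()] or numeric vector.
#' @param fs Sampling rate in Hz (ignored when `x` is a `sampled_signal`).
#' @param seg_s Segment length in seconds (default 1 s).
#' @param overlap Fractional segment overlap in `[0, 1)` (default 0.5).
#' @param demean Subtract the mean of each segment before tapering
#'   (default TRUE; the DC bin then carries no mean power).
#'
#' @return An object of class `psd_estimate`: list with `freqs` (Hz,
#'   ascending from 0), `power` (one-sided density, units^2/Hz), and `df`
#'   (grid resolution, Hz).
#' @examples
#' x <- sin(2 * pi * 100 * seq(0, 2, by = 1e-3))
#' p <- estimate_psd(x, fs = 1000)
#' p$freqs[which.max(p$power)]  # 100 Hz
#' @export
estimate_psd <- function(x, fs = NULL, seg_s = 1, overlap = 0.5,
                         demean = TRUE) {
  if (inherits(x, "sampled_signal")) {
    fs <- signal_fs(x)
    x <- as.numeric(x)
  }
  if (is.null(fs)) stop("'fs' is required for plain numeric input")
  n <- length(x)
  nseg <- round(seg_s * fs)
  if (nseg < 8) stop("PSD segment too short: need at least 8 samples")
  if (n < nseg)
    stop(sprintf("window of %d samples is shorter than one PSD segment (%d)",
                 n, nseg))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- hann_window(nseg)
  u <- sum(w^2)                     # window power normalisation
  nf <- nseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    if (demean) seg <- seg - mean(seg)
    sp <- Mod(stats::fft(seg * w))^2
    acc <- acc + sp[seq_len(nf)]
  }
  pxx <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  scale2 <- rep(2, nf)
  scale2[1] <- 1
  if (nseg %% 2L == 0L) scale2[nf] <- 1
  pxx <- pxx * scale2
  structure(list(freqs = (seq_len(nf) - 1) * fs / nseg,
                 power = pxx, df = fs / nseg),
            class = "psd_estimate")
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins, df=%.4g Hz, total power %.4g\n",
              length(x$freqs), x$df, sum(x$power) * x$df))
  invisible(x)
}

#' Integrate a PSD over a frequency band
#'
#' @param psd A `psd_estimate`.
#' @param band Two-element `c(lo, hi)` in Hz; bins with `lo <= f < hi` are
#'   summed (the upper edge is included for the last band of a partition
#'   only if `closed = TRUE`).
#' @param closed Include the upper edge bin (default FALSE).
#' @return Band power, in squared signal units.
#' @export
band_power <- function(psd, band, closed = FALSE) {
  f <- psd$freqs
  sel <- f >= band[1] & (if (closed) f <= band[2] else f < band[2])
  sum(psd$power[sel]) * psd$df
}
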