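# Seed hygiene: run code under a private RNG state, restoring the caller's.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Normal draw truncated below at `lo` (rejection; falls back to lo + |N|).
rnorm_trunc <- function(n, mean, sd, lo = 0) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lo)
  for (k in seq_len(50)) {
    if (!length(bad)) break
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out <= lo)
  }
  if (length(bad)) out[bad] <- lo + abs(stats::rnorm(length(bad), 0, sd))
  out
}

# Gaussian noise with power confined to [band[1], band[2]] Hz, scaled to
# unit variance, length n at rate fs. Built by masking white noise in the
# frequency domain.
band_noise <- function(n, fs, band, shape = NULL) {
  z <- stats::rnorm(n)
  f <- (0:(n - 1)) * fs / n
  fsym <- pmin(f, fs - f)           # two-sided grid folded to [0, fs/2]
  mask <- if (is.null(shape)) {
    as.numeric(fsym >= band[1] & fsym <= band[2])
  } else {
    shape(fsym) * (fsym >= band[1] & fsym <= band[2])
  }
  x <- Re(stats::fft(stats::fft(z) * mask, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  (x - mean(x)) / s
}

# Centroid of the Gaussian-bump PSD mask with centre `centre` and width
# `band_sd`, truncated to [lo, hi], evaluated on a fine grid.
shaped_centroid <- function(centre, band_sd, lo, hi) {
  f <- seq(lo, hi, length.out = 4096L)
  p <- exp(-(f - centre)^2 / (2 * band_sd^2))
  sum(f * p) / sum(p)
}

#' Generate a synthetic surface EMG recording
#'
#' Produces band-limited Gaussian noise whose power spectrum is a Gaussian
#' bump inside the EMG energy band, positioned so that the spectral centroid
#' (mean power frequency, MPF) matches the calibrated target, and scaled so
#' the RMS amplitude matches the calibrated target. This reproduces the two
#' indices used for fatigue classification — amplitude rising and spectral
#' centre falling with fatigue — while remaining the simplest stochastic
#' model consistent with them. Per-recording targets are drawn from the
#' calibration's `(mean, sd)` so that repeated recordings reproduce the
#' calibration table's between-recording spread; set `draw_targets = FALSE`
#' to pin every recording at the calibrated means.
#'
#' @param cal An [emg_calibration()].
#' @param duration Recording length in seconds (default 10).
#' @param fs Sampling rate in Hz (default 1000; must be at least 500 and
#'   high enough that the shaped band fits below Nyquist).
#' @param contaminants A [contaminant_spec()], or `NULL` for a clean signal.
#' @param seed Integer seed; identical `(cal, duration, fs, contaminants,
#'   seed)` give bit-identical output.
#' @param band_sd Spectral width (Hz) of the Gaussian PSD bump (default 25).
#' @param draw_targets Draw per-recording RMS/MPF targets from the
#'   calibration distribution (default TRUE).
#' @return A [sampled_signal()] of kind `"emg"` with provenance in `meta`.
#' @examples
#' s <- generate_emg(emg_calibration("A"), duration = 2, seed = 7)
#' emg_rms(s)
#' @export
generate_emg <- function(cal, duration = 10, fs = 1000, contaminants = NULL,
                         seed = 1L, band_sd = 25, draw_targets = TRUE) {
  stopifnot(inherits(cal, "emg_calibration"))
  if (duration <= 0) stop("'duration' must be positive")
  if (fs < 500) stop("EMG sampling rate must be at least 500 Hz")
  f_lo <- 20
  f_hi <- 0.45 * fs
  mpf_mu <- cal$targets$mpf[1]
  if (mpf_mu + 2 * band_sd > f_hi)
    stop(sprintf(paste0("fs = %g Hz is too low for the target MPF band ",
                        "(%g Hz + spectral width); raise fs"), fs, mpf_mu))
  n <- round(fs * duration)
  with_seed(seed, {
    rms_t <- if (draw_targets)
      rnorm_trunc(1, cal$targets$rms[1], cal$targets$rms[2], lo = 0)
    else cal$targets$rms[1]
    mpf_t <- if (draw_targets)
      rnorm_trunc(1, mpf_mu, cal$targets$mpf[2], lo = f_lo + 5)
    else mpf_mu
    if (cal$targets$rms[1] == 0 && cal$targets$rms[2] == 0) {
      x <- numeric(n)
    } else {
      # centre the PSD bump so its truncated-band centroid equals mpf_t
      centre <- stats::uniroot(
        function(cc) shaped_centroid(cc, band_sd, f_lo, f_hi) - mpf_t,
        lower = f_lo - 4 * band_sd, upper = f_hi + 4 * band_sd,
        tol = 1e-6)$root
      shape <- function(f) exp(-(f - centre)^2 / (4 * band_sd^2))
      x <- band_noise(n, fs, c(f_lo, f_hi), shape = shape) * rms_t
    }
    x <- add_contaminants(x, fs, contaminants)
    sampled_signal(x, fs = fs, kind = "emg",
                   meta = list(state = cal$state, muscle = cal$muscle,
                               seed = seed, rms_target = rms_t,
                               mpf_target = mpf_t))
  })
}

add_contaminants <- function(x, fs, spec) {
  if (is.null(spec)) return(x)
  stopifnot(inherits(spec, "contaminant_spec"))
  n <- length(x)
  t <- (0:(n - 1)) / fs
  if (spec$drift_amp > 0)
    x <- x + spec$drift_amp *
      sin(2 * pi * spec$drift_freq * t + stats::runif(1, 0, 2 * pi))
  if (spec$mains_amp > 0)
    x <- x + spec$mains_amp *
      sin(2 * pi * spec$mains_freq * t + stats::runif(1, 0, 2 * pi))
  if (spec$motion_amp > 0)
    x <- x + spec$motion_amp * band_noise(n, fs, spec$motion_band)
  x
}

# PQRST beat template: sum of Gaussians around the R peak at relative time 0.
# P and T offsets scale with the local RR interval so beats stay well formed
# at high heart rates. Returns a function of time-from-R (seconds).
beat_template <- function(rr_s) {
  comps <- list(
    p = c(a = 0.12, mu = -0.25 * rr_s, s = 0.02 + 0.015 * rr_s),
    q = c(a = -0.12, mu = -0.028, s = 0.010),
    r = c(a = 1.00, mu = 0.000, s = 0.011),
    s = c(a = -0.18, mu = 0.028, s = 0.010),
    t = c(a = 0.30, mu = 0.30 * rr_s, s = 0.03 + 0.03 * rr_s))
  function(dt) {
    v <- 0
    for (cp in comps) v <- v + cp["a"] * exp(-(dt - cp["mu"])^2 / (2 * cp["s"]^2))
    unname(v)
  }
}

#' Generate a synthetic ECG recording
#'
#' Places a fixed sum-of-Gaussians PQRST beat template at R-peak times driven
#' by an RR tachogram with a prescribed mean heart rate and prescribed HRV
#' band powers: the tachogram is the mean RR interval plus two independent
#' narrowband Gaussian processes, one confined to the LF band (0.04-0.15 Hz)
#' and one to the HF band (0.15-0.4 Hz), each variance-scaled to its target
#' power in ms^2. Per-recording targets for heart rate, HF power and the
#' LF/HF ratio are drawn from the calibration distribution (LF power is set
#' as ratio x HF so the ratio calibration is honoured; see the methods
#' vignette).
#'
#' @param cal An [ecg_calibration()].
#' @param duration Recording length in seconds. At least 10 s; at least one
#'   LF cycle (25 s) whenever nonzero band powers are requested (120 s or
#'   more is needed for stable band-power estimates).
#' @param fs Sampling rate in Hz (default 500).
#' @param contaminants A [contaminant_spec()] or `NULL`.
#' @param seed Integer seed (bit-reproducible output).
#' @param draw_targets Draw per-recording targets from the calibration
#'   distribution (default TRUE); if FALSE, the calibrated means are used.
#' @return A [sampled_signal()] of kind `"ecg"` (mV). True R-peak times are
#'   attached as attribute `"beat_times"`; the drawn targets are in `meta`.
#' @examples
#' cal <- ecg_calibration("A")
#' s <- generate_ecg(cal, duration = 30, seed = 3)
#' length(attr(s, "beat_times"))
#' @export
generate_ecg <- function(cal, duration = 120, fs = 500, contaminants = NULL,
                         seed = 1L, draw_targets = TRUE) {
  stopifnot(inherits(cal, "ecg_calibration"))
  if (duration < 10) stop("'duration' must be at least 10 s")
  wants_hrv <- cal$targets$hf[1] > 0 || cal$targets$lf[1] > 0
  if (wants_hrv && duration < 25)
    stop("HRV band-power calibration needs at least one LF cycle (25 s)")
  n <- round(fs * duration)
  with_seed(seed, {
    if (draw_targets) {
      hr_t <- rnorm_trunc(1, cal$targets$hr[1], cal$targets$hr[2], lo = 25)
      hf_t <- if (cal$targets$hf[1] > 0)
        rnorm_trunc(1, cal$targets$hf[1], cal$targets$hf[2], lo = 1) else 0
      ratio_t <- if (cal$targets$lf_hf[1] > 0)
        rnorm_trunc(1, cal$targets$lf_hf[1], cal$targets$lf_hf[2], lo = 0.05)
      else 0
      lf_t <- if (hf_t > 0) ratio_t * hf_t
      else if (cal$targets$lf[1] > 0)
        rnorm_trunc(1, cal$targets$lf[1], cal$targets$lf[2], lo = 1) else 0
    } else {
      hr_t <- cal$targets$hr[1]
      hf_t <- cal$targets$hf[1]
      lf_t <- if (hf_t > 0 && cal$targets$lf_hf[1] > 0)
        cal$targets$lf_hf[1] * hf_t else cal$targets$lf[1]
      ratio_t <- if (hf_t > 0) lf_t / hf_t else 0
    }
    rr_mean_ms <- 60000 / hr_t
    # RR tachogram on a 4 Hz grid, in ms
    fs_tach <- 4
    nt <- ceiling(duration * fs_tach) + 8L
    rr_ms <- rep(rr_mean_ms, nt)
    if (lf_t > 0)
      rr_ms <- rr_ms + sqrt(lf_t) * band_noise(nt, fs_tach, c(0.04, 0.15))
    if (hf_t > 0)
      rr_ms <- rr_ms + sqrt(hf_t) * band_noise(nt, fs_tach, c(0.15, 0.40))
    rr_ms <- pmin(pmax(rr_ms, 250), 2000)
    tach_t <- (0:(nt - 1)) / fs_tach
    # place beats by stepping through the tachogram
    beats <- numeric(0)
    tcur <- 0.35
    while (tcur < duration - 0.35) {
      beats <- c(beats, tcur)
      rr_here <- stats::approx(tach_t, rr_ms, xout = tcur, rule = 2)$y / 1000
      tcur <- tcur + rr_here
    }
    x <- numeric(n)
    tgrid <- (0:(n - 1)) / fs
    for (k in seq_along(beats)) {
      rr_loc <- if (k < length(beats)) beats[k + 1] - beats[k]
      else if (k > 1) beats[k] - beats[k - 1] else rr_mean_ms / 1000
      tmpl <- beat_template(rr_loc)
      lo <- max(1L, floor((beats[k] - 0.45 * rr_loc) * fs) + 1L)
      hi <- min(n, ceiling((beats[k] + 0.55 * rr_loc) * fs) + 1L)
      idx <- lo:hi
      x[idx] <- x[idx] + tmpl(tgrid[idx] - beats[k])
    }
    x <- add_contaminants(x, fs, contaminants)
    out <- sampled_signal(x, fs = fs, kind = "ecg",
                          meta = list(state = cal$state, seed = seed,
                                      hr_target = hr_t, lf_target = lf_t,
                                      hf_target = hf_t,
                                      lf_hf_target = ratio_t))
    attr(out, "beat_times") <- beats
    out
  })
}

#' Generate a labelled sequence-sample feature dataset
#'
#' Builds the dataset the LSTM classifier consumes: for each fatigue state,
#' `n_per_class` sequence samples, each a `seq_len` x 5 feature matrix with
#' columns `rms`, `mpf` (EMG), `hr`, `lf`, `hf` (ECG) and a state label.
#' The default `"gaussian"` method draws each row independently from the
#' per-state calibration Gaussians (the fast path used for the experiments);
#' `"signal"` synthesises actual EMG/ECG recordings per sample and runs the
#' package's own feature extractors, which is slower but exercises the whole
#' chain.
#'
#' @param n_per_class Named or unnamed length-3 integer vector of per-class
#'   sample counts in state order A, B, C (all at least 1).
#' @param seq_len Rows (1 s feature windows) per sequence sample
#'   (default 10).
#' @param seed Integer seed.
#' @param muscle EMG calibration muscle (default vastus lateralis).
#' @param method `"gaussian"` (default) or `"signal"`.
#' @param calibrations Calibration list as from [default_calibrations()].
#' @param covariates Also draw constant per-sample subject covariates
#'   (`age` years, `height` cm, `weight` kg), stored as a data.frame in the
#'   result's `covariates` element. The default classifier ignores them;
#'   they exist so dataset compositions listing subject information can be
#'   emulated. Default FALSE.
#' @param id_prefix Prefix for generated sample IDs.
#' @return An object of class `feature_dataset`: list with `x` (list of
#'   `seq_len` x 5 matrices), `y` (factor with levels A/B/C), `ids`
#'   (character), plus the generating settings. `as.data.frame()` flattens
#'   it to the delimited-table layout (`sample_id`, `t`, features, `label`).
#' @examples
#' d <- generate_feature_dataset(c(2, 2, 2), seq_len = 3, seed = 1)
#' dim(d$x[[1]])
#' table(d$y)
#' @export
generate_feature_dataset <- function(n_per_class = c(A = 30, B = 28, C = 28),
                                     seq_len = 10, seed = 1L,
                                     muscle = "vastus_lateralis",
                                     method = c("gaussian", "signal"),
                                     calibrations = NULL,
                                     covariates = FALSE,
                                     id_prefix = "s") {
  method <- match.arg(method)
  if (length(n_per_class) != 3L || any(n_per_class < 1))
    stop("'n_per_class' must give a positive count for each of the 3 states")
  if (seq_len < 1) stop("'seq_len' must be at least 1")
  if (is.null(calibrations)) calibrations <- default_calibrations()
  states <- fatigue_labels()
  xs <- list(); ys <- character(0); ids <- character(0)
  cov <- NULL
  with_seed(seed, {
    if (covariates) {
      ntot <- sum(n_per_class)
      cov <- data.frame(age = round(rnorm_trunc(ntot, 24, 4, lo = 16)),
                        height = round(rnorm_trunc(ntot, 175, 8, lo = 140)),
                        weight = round(rnorm_trunc(ntot, 70, 9, lo = 40)))
    }
    counter <- 0L
    for (si in seq_along(states)) {
      st <- states[si]
      ec <- ecg_calibration(st, targets = calibrations$ecg[[st]])
      mc <- emg_calibration(st, muscle,
                            targets = calibrations$emg[[muscle]][[st]])
      for (j in seq_len(n_per_class[si])) {
        counter <- counter + 1L
        m <- if (method == "gaussian")
          gaussian_feature_matrix(mc, ec, seq_len)
        else
          signal_feature_matrix(mc, ec, seq_len,
                                seed = sample.int(.Machine$integer.max, 1))
        xs[[counter]] <- m
        ys <- c(ys, st)
        ids <- c(ids, sprintf("%s%04d", id_prefix, counter))
      }
    }
  })
  structure(list(x = xs, y = factor(ys, levels = states), ids = ids,
                 seq_len = seq_len, method = method, seed = seed,
                 muscle = muscle, covariates = cov),
            class = "feature_dataset")
}

feature_names <- function() c("rms", "mpf", "hr", "lf", "hf")

gaussian_feature_matrix <- function(mc, ec, seq_len) {
  m <- cbind(
    rms = rnorm_trunc(seq_len, mc$targets$rms[1], mc$targets$rms[2]),
    mpf = rnorm_trunc(seq_len, mc$targets$mpf[1], mc$targets$mpf[2]),
    hr  = rnorm_trunc(seq_len, ec$targets$hr[1], ec$targets$hr[2]),
    lf  = rnorm_trunc(seq_len, ec$targets$lf[1], ec$targets$lf[2]),
    hf  = rnorm_trunc(seq_len, ec$targets$hf[1], ec$targets$hf[2]))
  m
}

signal_feature_matrix <- function(mc, ec, seq_len, seed) {
  emg <- generate_emg(mc, duration = seq_len, seed = seed)
  ef <- emg_features(emg, window_s = 1)
  ecg <- generate_ecg(ec, duration = 120, seed = seed + 1L)
  corrected <- remove_ecg_baseline(ecg)
  rr <- detect_r_peaks(corrected)
  hv <- hrv_band_powers(rr)
  cbind(rms = ef$rms[seq_len(seq_len)], mpf = ef$mpf[seq_len(seq_len)],
        hr = rep(hv$hr, seq_len), lf = rep(hv$lf, seq_len),
        hf = rep(hv$hf, seq_len))
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %d samples (%s), seq_len=%d, method=%s\n",
              length(x$x),
              paste(sprintf("%s:%d", levels(x$y), table(x$y)), collapse = " "),
              x$seq_len, x$method))
  invisible(x)
}

#' @export
as.data.frame.feature_dataset <- function(x, ...) {
  rows <- mapply(function(m, id, lab) {
    data.frame(sample_id = id, t = seq_len(nrow(m)) - 1L, m,
               label = lab, stringsAsFactors = FALSE)
  }, x$x, x$ids, as.character(x$y), SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and write feature datasets as delimited tables
#'
#' Tab-separated layout with columns `sample_id`, `t`, `rms`, `mpf`, `hr`,
#' `lf`, `hf`, `label`; one row per 1 s feature window.
#'
#' @param x A `feature_dataset`.
#' @param path File path.
#' @return `read_feature_dataset()` returns a `feature_dataset`.
#' @export
write_feature_dataset <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_dataset
#' @export
read_feature_dataset <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  ids <- unique(d$sample_id)
  xs <- list(); ys <- character(0)
  for (k in seq_along(ids)) {
    sub <- d[d$sample_id == ids[k], , drop = FALSE]
    sub <- sub[order(sub$t), , drop = FALSE]
    xs[[k]] <- as.matrix(sub[, feature_names()])
    ys <- c(ys, sub$label[1])
  }
  structure(list(x = xs, y = factor(ys, levels = fatigue_labels()),
                 ids = ids, seq_len = nrow(xs[[1]]), method = "file",
                 seed = NA_integer_, muscle = NA_character_),
            class = "feature_dataset")
}
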