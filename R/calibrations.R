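#' The three exercise fatigue states
#'
#' The package discriminates three fatigue states on the Borg rate of
#' perceived exertion (RPE) scale: A = very relaxed (RPE 8), B = slightly
#' tired (RPE 13), C = very tired (RPE 18).
#'
#' @return A data.frame with columns `label`, `rpe`, `description`.
#' @examples
#' fatigue_states()
#' @export
fatigue_states <- function() {
  data.frame(label = c("A", "B", "C"),
             rpe = c(8L, 13L, 18L),
             description = c("very relaxed", "slightly tired", "very tired"),
             stringsAsFactors = FALSE)
}

fatigue_labels <- function() c("A", "B", "C")

calibration_file <- function() {
  system.file("extdata", "calibrations.yaml", package = "exfatigue",
              mustWork = TRUE)
}

# Cache the parsed YAML for the session.
the <- new.env(parent = emptyenv())

#' Default calibration tables
#'
#' Per-state calibration targets (mean and SD across recordings) used by the
#' synthetic-signal generator: the five EMG indicators for three thigh
#' muscles, and HR / HF / LF / LF-to-HF for the ECG. Shipped as a YAML config
#' (`system.file("extdata", "calibrations.yaml", package = "exfatigue")`) so
#' users can supply their own calibration file with the same layout.
#'
#' @param path Optional path to an alternative calibration YAML.
#' @return A nested list with elements `states`, `emg` (by muscle, then
#'   state), and `ecg` (by state); each leaf is `c(mean, sd)`.
#' @export
default_calibrations <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(the$calib)) the$calib <- yaml::read_yaml(calibration_file())
    return(the$calib)
  }
  yaml::read_yaml(path)
}

#' EMG and ECG per-state calibrations
#'
#' Build the calibration object for one fatigue state, either from the
#' shipped defaults or from explicit targets. `emg_calibration()` carries the
#' five EMG indicator targets (the generator reproduces `rms` and `mpf`
#' exactly in expectation; see the methods vignette); `ecg_calibration()`
#' carries heart rate and HRV band-power targets.
#'
#' @param state Fatigue state label, one of `"A"`, `"B"`, `"C"`.
#' @param muscle One of `"vastus_lateralis"`, `"rectus_femoris"`,
#'   `"vastus_medialis"`.
#' @param targets Optional named list overriding the defaults; each element
#'   `c(mean, sd)`.
#' @return An object of class `emg_calibration` or `ecg_calibration`: a list
#'   with `state`, `muscle` (EMG only), and a `targets` list of
#'   `c(mean, sd)` pairs.
#' @examples
#' emg_calibration("A")$targets$rms
#' ecg_calibration("C")$targets$hr
#' @export
emg_calibration <- function(state = c("A", "B", "C"),
                            muscle = c("vastus_lateralis", "rectus_femoris",
                                       "vastus_medialis"),
                            targets = NULL) {
  state <- match.arg(state)
  muscle <- match.arg(muscle)
  if (is.null(targets))
    targets <- default_calibrations()$emg[[muscle]][[state]]
  targets <- lapply(targets, as.numeric)
  check_targets(targets, c("arv", "iemg", "rms", "mpf", "mf"))
  if (targets$rms[1] < targets$arv[1])
    stop("calibration must satisfy rms >= arv")
  structure(list(state = state, muscle = muscle, targets = targets),
            class = "emg_calibration")
}

#' @rdname emg_calibration
#' @export
ecg_calibration <- function(state = c("A", "B", "C"), targets = NULL) {
  state <- match.arg(state)
  if (is.null(targets))
    targets <- default_calibrations()$ecg[[state]]
  targets <- lapply(targets, as.numeric)
  check_targets(targets, c("hr", "hf", "lf", "lf_hf"))
  if (targets$hr[1] <= 0) stop("mean heart rate must be positive")
  structure(list(state = state, targets = targets),
            class = "ecg_calibration")
}

check_targets <- function(targets, need) {
  miss <- setdiff(need, names(targets))
  if (length(miss))
    stop("calibration is missing targets: ", paste(miss, collapse = ", "))
  for (nm in need) {
    v <- targets[[nm]]
    if (length(v) != 2L || !all(is.finite(v)) || v[2] < 0)
      stop("calibration target '", nm, "' must be c(mean, sd) with sd >= 0")
  }
  invisible(targets)
}

#' Contaminant specification for synthetic signals
#'
#' Describes the three additive contaminants that corrupt wearable
#' recordings: low-frequency baseline drift (respiration/electrode
#' polarisation, 0.15 Hz to a few Hz), 50 Hz mains interference, and motion
#' artifacts concentrated in the 3-14 Hz band. Amplitudes of zero disable a
#' component; `none` disables all three.
#'
#' @param drift_amp,drift_freq Baseline drift amplitude (signal units) and
#'   frequency in Hz (must stay below 3 Hz).
#' @param mains_amp,mains_freq Mains interference amplitude and frequency
#'   (default 50 Hz).
#' @param motion_amp Motion-artifact amplitude (band-limited noise in
#'   `motion_band`).
#' @param motion_band Two-element frequency band for motion artifacts, Hz.
#' @return An object of class `contaminant_spec`.
#' @examples
#' contaminant_spec(drift_amp = 0.5, drift_freq = 0.3)
#' @export
contaminant_spec <- function(drift_amp = 0, drift_freq = 0.3,
                             mains_amp = 0, mains_freq = 50,
                             motion_amp = 0, motion_band = c(3, 14)) {
  if (any(c(drift_amp, mains_amp, motion_amp) < 0))
    stop("contaminant amplitudes must be >= 0")
  if (drift_freq >= 3)
    stop("baseline drift frequency must be below 3 Hz")
  if (length(motion_band) != 2L || motion_band[1] >= motion_band[2])
    stop("'motion_band' must be an increasing (lo, hi) pair in Hz")
  structure(list(drift_amp = drift_amp, drift_freq = drift_freq,
                 mains_amp = mains_amp, mains_freq = mains_freq,
                 motion_amp = motion_amp, motion_band = motion_band),
            class = "contaminant_spec")
}

no_contaminants <- function() contaminant_spec()
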