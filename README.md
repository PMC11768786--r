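# exfatigue

Discrimination of exercise fatigue states from wearable surface EMG and ECG
recordings, for researchers in physiological signal processing and sports
science who need a fully reproducible, end-to-end reference pipeline.

Exercise fatigue is graded into three states on the Borg rate-of-perceived-
exertion scale — **A** very relaxed (RPE 8), **B** slightly tired (RPE 13),
**C** very tired (RPE 18). As fatigue deepens, surface EMG amplitude rises
while its spectrum shifts downward, and heart rate rises while
heart-rate-variability (HRV) spectral power falls. The package covers the
whole chain:

* **Synthetic signal generation** calibrated to per-state indicator tables
  (EMG for three thigh muscles; ECG heart rate and HRV band powers), with
  injectable contaminants (sub-Hz baseline drift, 50 Hz mains, 3–14 Hz
  motion artifacts). Subject-level recordings of this kind are typically
  unavailable, so the simulator is a first-class, tested module.
* **Preprocessing**: zero-phase Butterworth 20 Hz high-pass and 50 Hz
  band-stop for EMG; an incremental sliding-window median filter
  (sorted buffer, delete + binary-search insert per step, bit-identical to
  the naive full-sort median) for ECG baseline removal.
* **EMG fatigue indicators** per analysis window:
  `ARV = mean(|x|)`, `IEMG = Σ|x|/fs`, `RMS = sqrt(mean(x²))`, and from the
  Welch power spectrum the mean power frequency
  `MPF = ∫ f·PSD(f) df / ∫ PSD(f) df` and the median frequency MF (the
  half-power split).
* **ECG indicators**: Pan–Tompkins-style adaptive-threshold R-peak
  detection, `HR = 60000 / mean(RR ms)`, and HRV band powers
  LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz) in ms² with their LF/HF ratio.
* **A from-scratch LSTM sequence classifier** (gated cell, softmax output,
  cross-entropy loss, exact backpropagation through time, plain full-batch
  gradient descent) with the classic modelling interface: `fatigue_lstm()`
  returns an object with `print`, `summary`, `coef`, `predict` and `plot`
  methods. Default architecture: 5 input features → hidden layers
  [10, 20] → 3 states, at most 200 epochs.
* **An experiment pipeline** (`run_experiment()`, `compare_domains()`)
  reproducing the time-domain vs frequency-domain vs time–frequency
  feature comparison on identical data splits, byte-reproducible from
  `(config, seed)`.

## Worked example

```r
library(exfatigue)

## a clean 10 s EMG recording for the relaxed state, and its indicators
s <- generate_emg(emg_calibration("A"), duration = 10, seed = 1)
s
#> <sampled_signal> kind=emg fs=1000 Hz n=10000 (10.000 s)
round(head(emg_features(s, window_s = 1), 3), 2)
#>   t   arv  iemg   rms    mpf  mf
#> 1 0 16.80 16.80 21.23 124.82 124
#> 2 1 15.74 15.74 19.39 126.65 128
#> 3 2 17.01 17.01 20.84 124.95 125

## ECG of the very-tired state: elevated HR, depressed LF/HF
ecg <- generate_ecg(ecg_calibration("C"), duration = 120, seed = 1)
ecg_features(ecg)
#> <ecg_features> HR 122.3 bpm, LF 30.1 ms^2, HF 55.2 ms^2, LF/HF 0.55

## end-to-end: simulate 86 training + 25 test sequence samples,
## train the LSTM on all five features, evaluate held out
rep <- run_experiment(experiment_config(seed = 1))
rep
#> Exercise-fatigue classification run
#>   feature domain: time_frequency (rms, mpf, hr, lf, hf)
#>   seed: 1   package version: 0.1.0
#>   test accuracy: 100.00%
#>   confusion (true x predicted):
#>     predicted
#> true A B C
#>    A 9 0 0
#>    B 0 8 0
#>    C 0 0 8
```

The per-window RMS values near 21 and MPF values near 126 Hz reflect the
state-A calibration (RMS 22.62 ± 4.25, MPF 125.68 ± 5.36 in normalized
units); the very-tired ECG shows the calibrated tachycardia (HR target
126.57 ± 6.87 bpm) and an LF/HF ratio below 1. The classifier separates
the three states perfectly on this synthetic task because the calibrated
between-state differences are large relative to their SDs.

## Command-line usage

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fatigue-pipeline.R", package = "exfatigue"))')
Rscript $CLI simulate --kind ecg --state C --duration 120 --seed 1 --out ecg.tsv
Rscript $CLI preprocess --in ecg.tsv --kind ecg --out clean.tsv
Rscript $CLI features --in clean.tsv --kind ecg --out feats.tsv
Rscript $CLI compare-domains --seed 1 --out domains.tsv
```

Signals travel as two-column delimited text with a `#` header carrying the
sampling rate; feature datasets as tab-separated tables; fitted models as
JSON documents (`write_lstm()` / `read_lstm()`).

See the methods vignette (`vignettes/exfatigue-methods.Rmd`) for the
generative models, estimator choices, tuning rationale and known
limitations.
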