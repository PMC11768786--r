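#' Configuration for an end-to-end fatigue-classification experiment
#'
#' Bundles every knob of the simulate / train / evaluate chain so that a
#' `(config, seed)` pair fully determines an experiment. Default sample
#' counts follow the study composition: 30/28/28 training samples for
#' states A/B/C and 25 test samples split 9/8/8.
#'
#' @param train_counts Per-class training sample counts (A, B, C).
#' @param test_counts Per-class test sample counts.
#' @param feature_domain `"time_frequency"` (all five features),
#'   `"time"` (RMS, HR) or `"frequency"` (MPF, LF, HF).
#' @param seq_len Time steps per sequence sample (default 10, i.e. one 1 s
#'   feature window per second of a 10 s recording).
#' @param hidden,epochs,lr LSTM training configuration (defaults
#'   `c(10, 20)`, 200, 1).
#' @param seed Master seed; all randomness in the experiment derives from
#'   it.
#' @param muscle EMG calibration muscle.
#' @param method Dataset generation method, `"gaussian"` or `"signal"`
#'   (see [generate_feature_dataset()]).
#' @param calibrations Calibration list (default [default_calibrations()]).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(train_counts = c(A = 30, B = 28, C = 28),
                              test_counts = c(A = 9, B = 8, C = 8),
                              feature_domain = c("time_frequency", "time",
                                                 "frequency"),
                              seq_len = 10, hidden = c(10, 20),
                              epochs = 200, lr = 1, seed = 1L,
                              muscle = "vastus_lateralis",
                              method = "gaussian", calibrations = NULL) {
  feature_domain <- match.arg(feature_domain)
  structure(list(train_counts = train_counts, test_counts = test_counts,
                 feature_domain = feature_domain, seq_len = seq_len,
                 hidden = hidden, epochs = epochs, lr = lr,
                 seed = as.integer(seed), muscle = muscle, method = method,
                 calibrations = calibrations),
            class = "experiment_config")
}

#' Feature columns belonging to each feature domain
#'
#' Time-domain features are the amplitude-type indicators (EMG RMS, heart
#' rate); frequency-domain features are the spectral indicators (EMG MPF,
#' HRV LF and HF powers); `time_frequency` uses all five.
#'
#' @param domain One of `"time"`, `"frequency"`, `"time_frequency"`.
#' @return Character vector of feature column names.
#' @export
domain_features <- function(domain = c("time_frequency", "time",
                                       "frequency")) {
  switch(match.arg(domain),
         time = c("rms", "hr"),
         frequency = c("mpf", "lf", "hf"),
         time_frequency = c("rms", "mpf", "hr", "lf", "hf"))
}

#' Run one end-to-end classification experiment
#'
#' Generates disjoint training and test datasets from the per-state
#' calibrations, restricts them to the configured feature domain, fits the
#' LSTM on the training set (normalisation fitted on training data only),
#' and evaluates on the held-out test set. Rerunning with the same config
#' reproduces the report exactly.
#'
#' @param config An [experiment_config()].
#' @param verbose Print training progress.
#' @return An object of class `run_report`: `accuracy`, `confusion`,
#'   `recall`, `loss` (training trajectory), `model`, `config`, `seed`,
#'   and the package `version`.
#' @examples
#' cfg <- experiment_config(train_counts = c(6, 6, 6),
#'                          test_counts = c(3, 3, 3), seq_len = 4,
#'                          hidden = 4, epochs = 30, seed = 1)
#' run_experiment(cfg)$accuracy
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  ds <- experiment_datasets(config)
  feats <- domain_features(config$feature_domain)
  model <- fatigue_lstm(ds$train, features = feats, hidden = config$hidden,
                        epochs = config$epochs, lr = config$lr,
                        seed = config$seed, verbose = verbose)
  ev <- evaluate_model(model, ds$test)
  structure(list(accuracy = ev$accuracy, confusion = ev$confusion,
                 recall = ev$recall, loss = model$loss, model = model,
                 config = config, seed = config$seed,
                 version = as.character(utils::packageVersion("exfatigue"))),
            class = "run_report")
}

# Train and test sets from one master seed; test IDs are disjoint from
# train IDs by construction and the generator seeds are distinct streams.
experiment_datasets <- function(config) {
  train <- generate_feature_dataset(config$train_counts,
                                    seq_len = config$seq_len,
                                    seed = config$seed,
                                    muscle = config$muscle,
                                    method = config$method,
                                    calibrations = config$calibrations,
                                    id_prefix = "train_")
  test <- generate_feature_dataset(config$test_counts,
                                   seq_len = config$seq_len,
                                   seed = config$seed + 99991L,
                                   muscle = config$muscle,
                                   method = config$method,
                                   calibrations = config$calibrations,
                                   id_prefix = "test_")
  list(train = train, test = test)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Exercise-fatigue classification run\n")
  cat(sprintf("  feature domain: %s (%s)\n", x$config$feature_domain,
              paste(domain_features(x$config$feature_domain),
                    collapse = ", ")))
  cat(sprintf("  seed: %d   package version: %s\n", x$seed, x$version))
  cat(sprintf("  test accuracy: %.2f%%\n", 100 * x$accuracy))
  cat("  confusion (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Compare feature domains on identical data splits
#'
#' Reruns the experiment for the time-, frequency- and time-frequency-
#' domain feature sets on byte-identical train/test splits (only the
#' selected feature columns differ), optionally replicated over several
#' seeds.
#'
#' @param config An [experiment_config()]; its `feature_domain` is ignored.
#' @param seeds Integer vector of replicate seeds (default the config
#'   seed).
#' @return A data.frame with one row per domain: mean accuracy (and SD when
#'   several seeds are given), plus per-seed accuracies as an attribute
#'   `"runs"`.
#' @examples
#' cfg <- experiment_config(train_counts = c(6, 6, 6),
#'                          test_counts = c(3, 3, 3), seq_len = 4,
#'                          hidden = 4, epochs = 30)
#' compare_domains(cfg)
#' @export
compare_domains <- function(config, seeds = config$seed) {
  stopifnot(inherits(config, "experiment_config"))
  domains <- c("time", "frequency", "time_frequency")
  acc <- matrix(NA_real_, length(seeds), length(domains),
                dimnames = list(NULL, domains))
  for (k in seq_along(seeds)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[k])
    ds <- experiment_datasets(cfg)
    for (d in domains) {
      model <- fatigue_lstm(ds$train, features = domain_features(d),
                            hidden = cfg$hidden, epochs = cfg$epochs,
                            lr = cfg$lr, seed = cfg$seed)
      acc[k, d] <- evaluate_model(model, ds$test)$accuracy
    }
  }
  out <- data.frame(domain = domains,
                    features = vapply(domains, function(d)
                      paste(domain_features(d), collapse = "+"),
                      character(1)),
                    accuracy = colMeans(acc),
                    sd = if (length(seeds) > 1) apply(acc, 2, stats::sd)
                    else NA_real_,
                    row.names = NULL)
  attr(out, "runs") <- acc
  out
}
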