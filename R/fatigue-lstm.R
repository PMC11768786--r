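#' Fit the LSTM exercise-fatigue classifier
#'
#' Trains the from-scratch stacked LSTM on labelled sequence samples
#' (each a `T x F` feature matrix) by full-batch gradient descent on the
#' mean cross-entropy, with gradients from backpropagation through time.
#' The default architecture mirrors the fatigue-discrimination model: five
#' input features (RMS, MPF, HR, LF, HF), two hidden layers of 10 and 20
#' units, three output states, at most 200 training epochs.
#'
#' Features are min-max normalised to `[0, 1]` using ranges fitted on the
#' training data only; the fitted ranges travel with the model and are
#' re-applied by `predict()`, so test data never influence the scaling.
#'
#' @param x A `feature_dataset` (from [generate_feature_dataset()] or
#'   [read_feature_dataset()]) or a list of `T x F` feature matrices.
#' @param y Class labels (factor); taken from `x$y` when `x` is a
#'   `feature_dataset`.
#' @param features Optional character vector of feature columns to use
#'   (e.g. `c("rms", "hr")` for time-domain only); default all columns.
#' @param hidden Hidden layer sizes (default `c(10, 20)`).
#' @param epochs Maximum training epochs (default 200).
#' @param lr Learning rate for plain gradient descent (default 1).
#' @param seed Integer seed for weight initialisation; fitting is fully
#'   deterministic given `(x, y, seed)`.
#' @param normalize Min-max normalise features (default TRUE).
#' @param tol Stop early once the training loss falls below this value
#'   (default 0: run all epochs).
#' @param verbose Print loss every 25 epochs.
#'
#' @return An object of class `fatigue_lstm`: list with the fitted
#'   `params`, the per-epoch `loss` trajectory, the normalisation `norm`,
#'   class `levels`, selected `features`, training accuracy and the call.
#' @examples
#' d <- generate_feature_dataset(c(6, 6, 6), seq_len = 4, seed = 1)
#' fit <- fatigue_lstm(d, hidden = c(4), epochs = 40, seed = 1)
#' fit
#' predict(fit, d)[1:3]
#' @export
fatigue_lstm <- function(x, y = NULL, features = NULL, hidden = c(10, 20),
                         epochs = 200, lr = 1, seed = 1L,
                         normalize = TRUE, tol = 0, verbose = FALSE) {
  cl <- match.call()
  dat <- resolve_sequences(x, y, features)
  if (epochs < 1) stop("'epochs' must be at least 1")
  norm <- if (normalize) fit_minmax(dat$x) else NULL
  xs <- if (normalize) apply_minmax(dat$x, norm) else dat$x
  n_class <- nlevels(dat$y)
  params <- lstm_init_params(ncol(xs[[1]]), hidden = hidden,
                             n_class = n_class, seed = seed)
  fit <- lstm_train(params, xs, dat$y, epochs = epochs, lr = lr, tol = tol,
                    verbose = verbose)
  probs <- lstm_forward(fit$params, xs)
  pred <- levels(dat$y)[max.col(probs)]
  obj <- structure(list(params = fit$params, loss = fit$loss,
                        hidden = hidden, lr = lr, epochs = epochs,
                        seed = seed, norm = norm,
                        levels = levels(dat$y), features = dat$features,
                        train_accuracy = mean(pred == as.character(dat$y)),
                        n_train = length(xs), call = cl),
                   class = "fatigue_lstm")
  obj
}

resolve_sequences <- function(x, y, features = NULL, need_y = TRUE) {
  if (inherits(x, "feature_dataset")) {
    if (is.null(y)) y <- x$y
    x <- x$x
  }
  if (!is.list(x) || !all(vapply(x, is.matrix, logical(1))))
    stop("'x' must be a feature_dataset or a list of T x F matrices")
  if (is.null(y) && need_y) stop("labels 'y' are required")
  if (!is.null(y)) {
    y <- if (is.factor(y)) droplevels(y) else factor(y)
    if (length(y) != length(x)) stop("lengths of 'x' and 'y' differ")
  }
  if (!is.null(features)) {
    x <- lapply(x, function(m) {
      miss <- setdiff(features, colnames(m))
      if (length(miss))
        stop("feature columns not present: ", paste(miss, collapse = ", "))
      m[, features, drop = FALSE]
    })
  }
  if (anyNA(unlist(x))) stop("feature matrices contain missing values")
  list(x = x, y = y,
       features = if (is.null(features)) colnames(x[[1]]) else features)
}

fit_minmax <- function(xs) {
  all_rows <- do.call(rbind, xs)
  list(min = apply(all_rows, 2, min), max = apply(all_rows, 2, max))
}

apply_minmax <- function(xs, norm) {
  rng <- pmax(norm$max - norm$min, .Machine$double.eps)
  lapply(xs, function(m) sweep(sweep(m, 2, norm$min), 2, rng, "/"))
}

#' @export
print.fatigue_lstm <- function(x, ...) {
  cat("LSTM exercise-fatigue classifier\n")
  cat(sprintf("  features: %s\n", paste(x$features, collapse = ", ")))
  cat(sprintf("  architecture: %d -> [%s] -> %d states\n",
              length(x$features), paste(x$hidden, collapse = ", "),
              length(x$levels)))
  cat(sprintf("  epochs run: %d (lr %g, seed %d)\n",
              length(x$loss), x$lr, x$seed))
  cat(sprintf("  final training loss: %.4f  training accuracy: %.3f\n",
              x$loss[length(x$loss)], x$train_accuracy))
  invisible(x)
}

#' @export
summary.fatigue_lstm <- function(object, ...) {
  np <- length(params_to_vector(object$params))
  structure(list(model = object, n_params = np), class = "summary.fatigue_lstm")
}

#' @export
print.summary.fatigue_lstm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  parameters: %d  training samples: %d\n",
              x$n_params, x$model$n_train))
  cat(sprintf("  loss: start %.4f -> end %.4f over %d epochs\n",
              x$model$loss[1], x$model$loss[length(x$model$loss)],
              length(x$model$loss)))
  invisible(x)
}

#' @export
coef.fatigue_lstm <- function(object, ...) object$params

#' Predict fatigue states for new sequence samples
#'
#' @param object A fitted [fatigue_lstm()].
#' @param newdata A `feature_dataset` or list of `T x F` matrices (the
#'   model's feature columns are selected automatically from wider
#'   matrices).
#' @param type `"class"` (default) for hard labels, `"prob"` for the
#'   softmax probability matrix.
#' @param ... Unused.
#' @return A factor of predicted states, or a samples x states probability
#'   matrix.
#' @export
predict.fatigue_lstm <- function(object, newdata,
                                 type = c("class", "prob"), ...) {
  type <- match.arg(type)
  dat <- resolve_sequences(newdata, y = NULL, features = object$features,
                           need_y = FALSE)
  xs <- if (!is.null(object$norm)) apply_minmax(dat$x, object$norm) else dat$x
  probs <- lstm_forward(object$params, xs)
  colnames(probs) <- object$levels
  if (type == "prob") return(probs)
  factor(object$levels[max.col(probs)], levels = object$levels)
}

#' @export
plot.fatigue_lstm <- function(x, ...) {
  graphics::plot(seq_along(x$loss), x$loss, type = "l",
                 xlab = "epoch", ylab = "training loss (cross-entropy)",
                 main = "LSTM training loss", ...)
  invisible(x)
}

#' Evaluate a fitted classifier on labelled data
#'
#' @param model A fitted [fatigue_lstm()].
#' @param newdata A `feature_dataset` or list of matrices.
#' @param y True labels (taken from `newdata$y` when absent).
#' @return List with `accuracy` (fraction correct), `confusion` (true x
#'   predicted table) and `recall` (per-class diagonal / row total).
#' @export
evaluate_model <- function(model, newdata, y = NULL) {
  if (inherits(newdata, "feature_dataset") && is.null(y)) y <- newdata$y
  if (is.null(y)) stop("true labels are required for evaluation")
  y <- factor(as.character(y), levels = model$levels)
  pred <- predict(model, newdata)
  confusion <- table(true = y, predicted = pred)
  recall <- diag(confusion) / pmax(rowSums(confusion), 1)
  list(accuracy = mean(pred == y), confusion = confusion, recall = recall)
}

# ---- portable text serialisation -----------------------------------------

ser_leaf <- function(p) {
  if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
  else list(dim = length(p), data = as.numeric(p))
}

deser_leaf <- function(l) {
  d <- unlist(l$dim)
  v <- unlist(l$data)
  if (length(d) == 2) matrix(v, d[1], d[2]) else as.numeric(v)
}

#' Save and load a fitted model as structured text
#'
#' Weights, shapes, configuration and normalisation ranges are written as a
#' JSON document, so fitted models are portable and diff-able.
#'
#' @param model A fitted [fatigue_lstm()].
#' @param path File path (`.json`).
#' @return `read_lstm()` returns the restored `fatigue_lstm`.
#' @export
write_lstm <- function(model, path) {
  stopifnot(inherits(model, "fatigue_lstm"))
  doc <- list(
    layers = lapply(model$params$layers, function(ly)
      lapply(ly[gate_fields], ser_leaf)),
    w_y = ser_leaf(model$params$w_y),
    b_y = ser_leaf(model$params$b_y),
    sizes = model$params$sizes,
    hidden = model$hidden, lr = model$lr, epochs = model$epochs,
    seed = model$seed, levels = model$levels, features = model$features,
    loss = model$loss, train_accuracy = model$train_accuracy,
    n_train = model$n_train,
    norm = if (is.null(model$norm)) NULL else
      list(min = as.numeric(model$norm$min), max = as.numeric(model$norm$max)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lstm
#' @export
read_lstm <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  layers <- lapply(doc$layers, function(ly)
    stats::setNames(lapply(gate_fields, function(f) deser_leaf(ly[[f]])),
                    gate_fields))
  params <- structure(list(layers = layers, w_y = deser_leaf(doc$w_y),
                           b_y = deser_leaf(doc$b_y),
                           sizes = list(input = unlist(doc$sizes$input),
                                        hidden = unlist(doc$sizes$hidden),
                                        n_class = unlist(doc$sizes$n_class))),
                      class = "lstm_params")
  feats <- as.character(unlist(doc$features))
  norm <- if (is.null(doc$norm)) NULL else
    list(min = stats::setNames(as.numeric(unlist(doc$norm$min)), feats),
         max = stats::setNames(as.numeric(unlist(doc$norm$max)), feats))
  structure(list(params = params, loss = as.numeric(unlist(doc$loss)),
                 hidden = as.numeric(unlist(doc$hidden)), lr = doc$lr,
                 epochs = doc$epochs, seed = doc$seed, norm = norm,
                 levels = as.character(unlist(doc$levels)),
                 features = feats,
                 train_accuracy = doc$train_accuracy,
                 n_train = doc$n_train, call = NULL),
            class = "fatigue_lstm")
}
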