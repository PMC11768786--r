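# ---- LSTM built from first principles ------------------------------------
#
# One layer holds the four gate parameter triplets (input weights, recurrent
# weights, bias): forget f, input i, candidate c', output e. The cell update
# is
#   f_t  = sigmoid(w_fx x_t + w_fh h_{t-1} + b_f)
#   i_t  = sigmoid(w_ix x_t + w_ih h_{t-1} + b_i)
#   c'_t = tanh   (w_cx x_t + w_ch h_{t-1} + b_c)
#   C_t  = f_t * C_{t-1} + i_t * c'_t
#   e_t  = sigmoid(w_ex x_t + w_eh h_{t-1} + b_e)
#   h_t  = e_t * tanh(C_t)
# Classification reads the top layer's final hidden state through an affine
# map and a softmax; training is full-batch gradient descent on the mean
# cross-entropy, with gradients from backpropagation through time.

sigmoid <- function(z) 1 / (1 + exp(-z))

gate_fields <- c("w_fx", "w_fh", "b_f", "w_ix", "w_ih", "b_i",
                 "w_cx", "w_ch", "b_c", "w_ex", "w_eh", "b_e")

#' Initialise LSTM parameters
#'
#' All gate weight matrices, gate biases, and the softmax output layer,
#' drawn i.i.d. uniform on `(-scale, scale)` from the given seed.
#'
#' @param input_size Number of input features per time step.
#' @param hidden Integer vector of hidden-layer sizes (stacked layers;
#'   default `c(10, 20)`).
#' @param n_class Number of output classes (default 3).
#' @param seed Integer seed.
#' @param scale Half-width of the uniform initialisation (default 0.1).
#' @return An object of class `lstm_params`: list with `layers` (each a list
#'   of `w_fx, w_fh, b_f, ..., w_ex, w_eh, b_e`), output layer `w_y`, `b_y`,
#'   and `sizes`.
#' @export
lstm_init_params <- function(input_size, hidden = c(10, 20), n_class = 3,
                             seed = 1L, scale = 0.1) {
  stopifnot(input_size >= 1, all(hidden >= 1), n_class >= 2)
  with_seed(seed, {
    ru <- function(r, c) matrix(stats::runif(r * c, -scale, scale), r, c)
    layers <- list()
    fan_in <- input_size
    for (h in hidden) {
      ly <- list()
      for (g in c("f", "i", "c", "e")) {
        ly[[paste0("w_", g, "x")]] <- ru(h, fan_in)
        ly[[paste0("w_", g, "h")]] <- ru(h, h)
        ly[[paste0("b_", g)]] <- stats::runif(h, -scale, scale)
      }
      layers[[length(layers) + 1L]] <- ly
      fan_in <- h
    }
    structure(list(layers = layers,
                   w_y = ru(n_class, fan_in),
                   b_y = stats::runif(n_class, -scale, scale),
                   sizes = list(input = input_size, hidden = hidden,
                                n_class = n_class)),
              class = "lstm_params")
  })
}

#' One LSTM cell update
#'
#' Applies the gated cell equations for a single time step. Works on a
#' single input vector or on a batch (features x samples matrix; the state
#' then holds hidden x samples matrices).
#'
#' @param layer One element of `lstm_params$layers`.
#' @param x Input vector (length F) or F x B matrix.
#' @param prev Previous state: list with `h` and `c` (zeros to start).
#' @return List with `h`, `c` and the intermediate activations `f`, `i`,
#'   `cp` (candidate), `e`, `tc` (`tanh(c)`); all gate activations lie
#'   strictly in (0, 1).
#' @examples
#' p <- lstm_init_params(2, hidden = 3, n_class = 2, seed = 1)
#' st <- lstm_cell_step(p$layers[[1]], c(0.1, -0.2),
#'                      list(h = rep(0, 3), c = rep(0, 3)))
#' range(st$f)
#' @export
lstm_cell_step <- function(layer, x, prev) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  h <- prev$h; c0 <- prev$c
  if (is.null(dim(h))) h <- matrix(h, ncol = ncol(x))
  if (is.null(dim(c0))) c0 <- matrix(c0, ncol = ncol(x))
  if (nrow(x) != ncol(layer$w_fx) || nrow(h) != nrow(layer$w_fx))
    stop("shape mismatch between input/state and layer parameters")
  f <- sigmoid(layer$w_fx %*% x + layer$w_fh %*% h + layer$b_f)
  i <- sigmoid(layer$w_ix %*% x + layer$w_ih %*% h + layer$b_i)
  cp <- tanh(layer$w_cx %*% x + layer$w_ch %*% h + layer$b_c)
  cc <- f * c0 + i * cp
  e <- sigmoid(layer$w_ex %*% x + layer$w_eh %*% h + layer$b_e)
  tc <- tanh(cc)
  list(h = e * tc, c = cc, f = f, i = i, cp = cp, e = e, tc = tc)
}

#' Softmax probability normalisation
#'
#' Maps a vector of scores to the probability simplex,
#' `exp(z_i) / sum_j exp(z_j)`, computed with max-subtraction for numerical
#' stability (so it is invariant to adding a constant to all scores).
#'
#' @param z Numeric vector of scores, or a matrix whose rows are score
#'   vectors.
#' @return Probabilities of the same shape; each (row) sums to 1.
#' @examples
#' softmax(c(0, 0, 0))
#' @export
softmax <- function(z) {
  if (is.matrix(z)) return(t(col_softmax(t(z))))
  e <- exp(z - max(z))
  e / sum(e)
}

col_softmax <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Cross-entropy loss
#'
#' `-sum_i B_i log f(X_i)` for one-hot true distribution `B` and predicted
#' probabilities `f(X)`; zero exactly when the true class has probability 1.
#' Probabilities are clipped below at `1e-12` (with a warning) so a zero
#' predicted probability yields a large finite loss.
#'
#' @param probs Probability vector for one sample, or a matrix with one row
#'   per sample.
#' @param label One-hot vector/matrix, or integer class indices / factor.
#' @return Mean cross-entropy over the samples (natural log).
#' @examples
#' cross_entropy(c(1 / 3, 1 / 3, 1 / 3), 2)        # log(3)
#' cross_entropy(c(0.5, 0.25, 0.25), 1)            # log(2)
#' @export
cross_entropy <- function(probs, label) {
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
  n_class <- ncol(probs)
  onehot <- to_onehot(label, n_class, nrow(probs))
  if (any(probs[onehot > 0] < 1e-12))
    warning("predicted probability of a true class underflowed; clipped at 1e-12")
  lg <- matrix(0, nrow(probs), ncol(probs))
  nz <- onehot > 0
  lg[nz] <- log(pmax(probs[nz], 1e-12))
  -mean(rowSums(onehot * lg))
}

to_onehot <- function(label, n_class, n_samples) {
  if (is.matrix(label)) return(label)
  if (is.factor(label)) label <- as.integer(label)
  if (length(label) == n_class && n_samples == 1 && any(label == 1) &&
      all(label %in% c(0, 1)) && sum(label) == 1)
    return(matrix(label, nrow = 1))
  out <- matrix(0, n_samples, n_class)
  out[cbind(seq_len(n_samples), label)] <- 1
  out
}

# Batch a list of T x F sample matrices into a time-major list of
# F x B matrices.
time_major <- function(xs) {
  T_ <- nrow(xs[[1]]); F_ <- ncol(xs[[1]])
  lapply(seq_len(T_), function(t) {
    m <- vapply(xs, function(mm) as.numeric(mm[t, ]), numeric(F_))
    matrix(m, nrow = F_)
  })
}

lstm_forward_cache <- function(params, xlist) {
  T_ <- length(xlist); B <- ncol(xlist[[1]])
  nl <- length(params$layers)
  states <- vector("list", nl)
  inp <- xlist
  for (l in seq_len(nl)) {
    H <- nrow(params$layers[[l]]$w_fx)
    prev <- list(h = matrix(0, H, B), c = matrix(0, H, B))
    outs <- vector("list", T_)
    for (t in seq_len(T_)) {
      st <- lstm_cell_step(params$layers[[l]], inp[[t]], prev)
      outs[[t]] <- st
      prev <- st
    }
    states[[l]] <- outs
    inp <- lapply(outs, `[[`, "h")
  }
  hT <- states[[nl]][[T_]]$h
  logits <- params$w_y %*% hT + params$b_y
  list(states = states, logits = logits, probs = col_softmax(logits),
       x = xlist)
}

#' Forward pass: sequence to class probabilities
#'
#' Unrolls the stacked LSTM over the `T` time steps of each sample and maps
#' the top layer's final hidden state through the affine output layer and a
#' softmax.
#'
#' @param params An `lstm_params`.
#' @param x One `T x F` feature matrix, or a list of them.
#' @return A matrix of class probabilities, one row per sample (rows sum
#'   to 1).
#' @export
lstm_forward <- function(params, x) {
  if (is.matrix(x)) x <- list(x)
  cache <- lstm_forward_cache(params, time_major(x))
  t(cache$probs)
}

zero_like <- function(p) {
  if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
}

layer_backward <- function(layer, xlist, states, dh_out) {
  T_ <- length(xlist)
  H <- nrow(layer$w_fx); B <- ncol(states[[1]]$h)
  g <- lapply(layer[gate_fields], zero_like)
  dh_next <- matrix(0, H, B)
  dc_next <- matrix(0, H, B)
  dx <- vector("list", T_)
  for (t in rev(seq_len(T_))) {
    st <- states[[t]]
    hprev <- if (t > 1) states[[t - 1]]$h else matrix(0, H, B)
    cprev <- if (t > 1) states[[t - 1]]$c else matrix(0, H, B)
    dh <- dh_next + if (is.null(dh_out[[t]])) 0 else dh_out[[t]]
    de_pre <- dh * st$tc * st$e * (1 - st$e)
    dc <- dh * st$e * (1 - st$tc^2) + dc_next
    df_pre <- dc * cprev * st$f * (1 - st$f)
    di_pre <- dc * st$cp * st$i * (1 - st$i)
    dcp_pre <- dc * st$i * (1 - st$cp^2)
    dc_next <- dc * st$f
    x <- xlist[[t]]
    g$w_fx <- g$w_fx + df_pre %*% t(x)
    g$w_fh <- g$w_fh + df_pre %*% t(hprev)
    g$b_f <- g$b_f + rowSums(df_pre)
    g$w_ix <- g$w_ix + di_pre %*% t(x)
    g$w_ih <- g$w_ih + di_pre %*% t(hprev)
    g$b_i <- g$b_i + rowSums(di_pre)
    g$w_cx <- g$w_cx + dcp_pre %*% t(x)
    g$w_ch <- g$w_ch + dcp_pre %*% t(hprev)
    g$b_c <- g$b_c + rowSums(dcp_pre)
    g$w_ex <- g$w_ex + de_pre %*% t(x)
    g$w_eh <- g$w_eh + de_pre %*% t(hprev)
    g$b_e <- g$b_e + rowSums(de_pre)
    dx[[t]] <- t(layer$w_fx) %*% df_pre + t(layer$w_ix) %*% di_pre +
      t(layer$w_cx) %*% dcp_pre + t(layer$w_ex) %*% de_pre
    dh_next <- t(layer$w_fh) %*% df_pre + t(layer$w_ih) %*% di_pre +
      t(layer$w_ch) %*% dcp_pre + t(layer$w_eh) %*% de_pre
  }
  list(grads = g, dx = dx)
}

#' Backpropagation through time
#'
#' Exact gradients of the mean cross-entropy over a batch with respect to
#' every LSTM parameter (all gate weights and biases of every layer, plus
#' the output layer), obtained by unrolling the network over the sequence
#' and propagating the loss backwards through both the layer stack and
#' time.
#'
#' @param params An `lstm_params`.
#' @param x A `T x F` matrix or list of them (the batch).
#' @param y Class labels: factor, integer indices, or one-hot matrix.
#' @return List with `grads` (same structure as `params`), `loss` (mean
#'   cross-entropy at `params`), and `probs` (batch probabilities, one row
#'   per sample).
#' @export
lstm_gradients <- function(params, x, y) {
  if (is.matrix(x)) x <- list(x)
  xlist <- time_major(x)
  B <- length(x)
  T_ <- length(xlist)
  cache <- lstm_forward_cache(params, xlist)
  onehot <- t(to_onehot(y, params$sizes$n_class, B))      # C x B
  probs <- cache$probs
  loss <- cross_entropy(t(probs), t(onehot))
  if (!is.finite(loss)) stop("non-finite loss in backward pass")
  dlogits <- (probs - onehot) / B
  nl <- length(params$layers)
  hT <- cache$states[[nl]][[T_]]$h
  g_wy <- dlogits %*% t(hT)
  g_by <- rowSums(dlogits)
  dh_out <- vector("list", T_)
  dh_out[[T_]] <- t(params$w_y) %*% dlogits
  glayers <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    below <- if (l == 1) xlist else lapply(cache$states[[l - 1]], `[[`, "h")
    lb <- layer_backward(params$layers[[l]], below, cache$states[[l]], dh_out)
    glayers[[l]] <- lb$grads
    dh_out <- lb$dx
  }
  grads <- structure(list(layers = glayers, w_y = g_wy, b_y = g_by,
                          sizes = params$sizes), class = "lstm_params")
  bad <- !all(is.finite(unlist(glayers, use.names = FALSE)))
  if (bad || !all(is.finite(g_wy)) || !all(is.finite(g_by)))
    stop("non-finite gradient encountered in BPTT")
  list(grads = grads, loss = loss, probs = t(probs))
}

# Flatten parameters to a single numeric vector (fixed field order) and
# back; used by the optimiser and by finite-difference checks.
params_to_vector <- function(params) {
  v <- numeric(0)
  for (ly in params$layers) for (f in gate_fields) v <- c(v, as.numeric(ly[[f]]))
  c(v, as.numeric(params$w_y), as.numeric(params$b_y))
}

vector_to_params <- function(v, template) {
  out <- template
  pos <- 1L
  take <- function(n) {
    r <- v[pos:(pos + n - 1L)]
    pos <<- pos + n
    r
  }
  for (l in seq_along(template$layers)) {
    for (f in gate_fields) {
      p <- template$layers[[l]][[f]]
      n <- length(p)
      out$layers[[l]][[f]] <- if (is.matrix(p))
        matrix(take(n), nrow(p), ncol(p)) else take(n)
    }
  }
  out$w_y <- matrix(take(length(template$w_y)), nrow(template$w_y))
  out$b_y <- take(length(template$b_y))
  stopifnot(pos == length(v) + 1L)
  out
}

lstm_train <- function(params, x, y, epochs = 200, lr = 0.05, tol = 0,
                       verbose = FALSE) {
  losses <- numeric(0)
  for (ep in seq_len(epochs)) {
    bp <- lstm_gradients(params, x, y)
    losses <- c(losses, bp$loss)
    if (!is.finite(bp$loss))
      stop(sprintf("training diverged at epoch %d (non-finite loss)", ep))
    if (verbose && ep %% 25 == 0)
      message(sprintf("epoch %4d  loss %.5f", ep, bp$loss))
    if (bp$loss < tol) break
    params <- vector_to_params(
      params_to_vector(params) - lr * params_to_vector(bp$grads), params)
  }
  list(params = params, loss = losses)
}
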