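test_that("cell update honours the gate semantics", {
  p <- lstm_init_params(2, hidden = 3, n_class = 3, seed = 1)
  ly <- p$layers[[1]]
  prev <- list(h = c(0.3, -0.2, 0.5), c = c(1.0, -2.0, 0.7))
  x <- c(0.4, -0.6)

  # forget gate saturated open, input gate shut: cell state carried intact
  keep <- ly
  keep$b_f <- rep(40, 3); keep$b_i <- rep(-40, 3)
  st <- lstm_cell_step(keep, x, prev)
  expect_equal(as.numeric(st$c), prev$c, tolerance = 1e-12)

  # both gates shut: cell state fully cleared
  drop <- ly
  drop$b_f <- rep(-40, 3); drop$b_i <- rep(-40, 3)
  st2 <- lstm_cell_step(drop, x, prev)
  expect_equal(as.numeric(st2$c), rep(0, 3), tolerance = 1e-12)

  # all-zero parameters from zero state: h = 0.5 * tanh(0) = 0
  z <- lapply(ly, function(w) w * 0)
  st3 <- lstm_cell_step(z, x, list(h = rep(0, 3), c = rep(0, 3)))
  expect_equal(as.numeric(st3$h), rep(0, 3))
  expect_equal(as.numeric(st3$f), rep(0.5, 3))

  expect_error(lstm_cell_step(ly, c(1, 2, 3), prev), "shape")
})

test_that("gate activations stay strictly inside (0, 1) on random runs", {
  set.seed(30)
  for (i in 1:20) {
    p <- lstm_init_params(3, hidden = c(4, 3), n_class = 3, seed = i)
    x <- lapply(1:2, function(j) matrix(rnorm(5 * 3, sd = 2), 5, 3))
    cache <- exfatigue:::lstm_forward_cache(p, exfatigue:::time_major(x))
    for (l in seq_along(cache$states)) for (st in cache$states[[l]]) {
      expect_true(all(st$f > 0 & st$f < 1))
      expect_true(all(st$i > 0 & st$i < 1))
      expect_true(all(st$e > 0 & st$e < 1))
      expect_true(all(abs(st$cp) <= 1))
    }
  }
})

test_that("softmax normalises, is shift-invariant and symmetric", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  z <- c(1.2, -0.7, 3.1)
  expect_equal(softmax(z + 5), softmax(z), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    p <- softmax(rnorm(sample(2:6, 1), sd = 10))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0 & p < 1))
  }
  m <- softmax(matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE))
  expect_equal(m[1, ], rep(1 / 3, 3))
})

test_that("cross-entropy matches closed forms and clips safely", {
  expect_equal(cross_entropy(c(1, 0, 0), 1), 0)
  expect_equal(cross_entropy(rep(1 / 3, 3), 2), log(3))
  expect_equal(cross_entropy(c(0.5, 0.25, 0.25), 1), log(2))
  expect_warning(l <- cross_entropy(c(0, 1), 1), "clipped")
  expect_true(is.finite(l) && l > 20)
})

test_that("forward pass yields proper probabilities", {
  p <- lstm_init_params(5, hidden = c(10, 20), n_class = 3, seed = 2)
  set.seed(3)
  x <- lapply(1:7, function(i) matrix(rnorm(10 * 5), 10, 5))
  probs <- lstm_forward(p, x)
  expect_equal(dim(probs), c(7, 3))
  expect_equal(rowSums(probs), rep(1, 7), tolerance = 1e-12)
  expect_true(all(probs > 0 & probs < 1))
})

test_that("BPTT gradients match central finite differences", {
  # single-step, output layer only: gradient is (softmax - onehot) x hidden
  p <- lstm_init_params(2, hidden = 3, n_class = 3, seed = 7)
  x <- matrix(c(0.3, -0.5), 1, 2)
  bp <- lstm_gradients(p, x, factor("B", levels = c("A", "B", "C")))
  cache <- exfatigue:::lstm_forward_cache(p, exfatigue:::time_major(list(x)))
  h <- cache$states[[1]][[1]]$h
  expected_wy <- (cache$probs - c(0, 1, 0)) %*% t(h)
  expect_equal(bp$grads$w_y, expected_wy, tolerance = 1e-12)

  # full-network agreement across random small configurations
  set.seed(99)
  worst <- 0
  for (i in 1:30) {
    Fi <- sample(1:3, 1); Ti <- sample(1:4, 1); Bi <- sample(1:3, 1)
    hid <- sample(2:4, sample(1:2, 1), replace = TRUE)
    p <- lstm_init_params(Fi, hidden = hid, n_class = 3, seed = i)
    x <- lapply(seq_len(Bi), function(j) matrix(rnorm(Ti * Fi), Ti, Fi))
    y <- factor(sample(c("A", "B", "C"), Bi, TRUE),
                levels = c("A", "B", "C"))
    ana <- exfatigue:::params_to_vector(lstm_gradients(p, x, y)$grads)
    num <- numeric_lstm_gradient(p, x, y, h = 1e-4)
    expect_lt(sqrt(sum((ana - num)^2)) / max(sqrt(sum(num^2)), 1e-12), 1e-5)
    worst <- max(worst, max(abs(ana - num) / pmax(abs(num), abs(ana), 1e-4)))
  }
  expect_lt(worst, 1e-5)
})

test_that("gradients vanish when predictions already equal the labels", {
  # drive the output layer to near-one-hot and check the output gradient
  p <- lstm_init_params(2, hidden = 2, n_class = 2, seed = 5)
  p$w_y <- matrix(0, 2, 2)
  p$b_y <- c(50, -50)                     # probs ~ (1, 0) regardless of h
  x <- matrix(rnorm(4), 2, 2)
  bp <- lstm_gradients(p, x, factor("a", levels = c("a", "b")))
  expect_lt(max(abs(exfatigue:::params_to_vector(bp$grads))), 1e-12)
  expect_lt(bp$loss, 1e-12)
})

test_that("training is deterministic, inert at lr 0 and solves a separable toy", {
  toy <- toy_sequences()
  f1 <- fatigue_lstm(toy$x, toy$y, hidden = 4, epochs = 60, seed = 3)
  f2 <- fatigue_lstm(toy$x, toy$y, hidden = 4, epochs = 60, seed = 3)
  expect_identical(exfatigue:::params_to_vector(f1$params),
                   exfatigue:::params_to_vector(f2$params))
  expect_identical(f1$loss, f2$loss)

  f0 <- fatigue_lstm(toy$x, toy$y, hidden = 4, epochs = 20, lr = 0, seed = 3)
  expect_equal(diff(range(f0$loss)), 0)

  f3 <- fatigue_lstm(toy$x, toy$y, hidden = 4, epochs = 200, seed = 3)
  expect_equal(f3$train_accuracy, 1.0)
})

test_that("loss is non-increasing under a sufficiently small learning rate", {
  toy <- toy_sequences(n_per_class = 4, seed = 9)
  fit <- fatigue_lstm(toy$x, toy$y, hidden = 3, epochs = 50, lr = 0.05,
                      seed = 2)
  expect_true(all(diff(fit$loss) <= 1e-10))
})

test_that("early stopping honours the loss tolerance", {
  toy <- toy_sequences()
  fit <- fatigue_lstm(toy$x, toy$y, hidden = 4, epochs = 500, tol = 0.2,
                      seed = 3)
  expect_lt(length(fit$loss), 500)
  expect_lt(fit$loss[length(fit$loss)], 0.2)
})

test_that("evaluation reports accuracy, confusion and recalls", {
  toy <- toy_sequences()
  fit <- fatigue_lstm(toy$x, toy$y, hidden = 4, epochs = 200, seed = 3)
  ev <- evaluate_model(fit, toy$x, toy$y)
  expect_equal(ev$accuracy, 1)
  expect_equal(sum(diag(ev$confusion)), length(toy$y))
  expect_equal(unname(ev$recall), c(1, 1))

  ev1 <- evaluate_model(fit, toy$x[1], toy$y[1])
  expect_equal(sum(ev1$confusion != 0), 1)
})

test_that("model methods print, plot, coef and predict coherently", {
  d <- generate_feature_dataset(c(4, 4, 4), seq_len = 4, seed = 2)
  fit <- fatigue_lstm(d, hidden = 4, epochs = 30, seed = 1)
  expect_output(print(fit), "architecture: 5 -> \\[4\\] -> 3")
  expect_output(print(summary(fit)), "parameters:")
  expect_s3_class(coef(fit), "lstm_params")
  pr <- predict(fit, d, type = "prob")
  expect_equal(dim(pr), c(12, 3))
  expect_equal(colnames(pr), c("A", "B", "C"))
  cl <- predict(fit, d)
  expect_s3_class(cl, "factor")
  expect_equal(levels(cl), c("A", "B", "C"))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("fitted models round-trip through the JSON serialisation", {
  d <- generate_feature_dataset(c(3, 3, 3), seq_len = 3, seed = 7)
  fit <- fatigue_lstm(d, hidden = c(3, 4), epochs = 15, seed = 2)
  path <- tempfile(fileext = ".json")
  write_lstm(fit, path)
  back <- read_lstm(path)
  expect_equal(exfatigue:::params_to_vector(back$params),
               exfatigue:::params_to_vector(fit$params))
  expect_equal(predict(back, d, type = "prob"),
               predict(fit, d, type = "prob"))
  expect_equal(back$levels, fit$levels)
  expect_equal(back$norm$min, fit$norm$min, tolerance = 1e-12)
})
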