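# Independent per-timestep oracle for the gated recurrence, written as
# plain scalar loops against the textbook equations.
reference_lstm <- function(params, sequence) {
  H <- params$hidden
  Tn <- nrow(sequence)
  h <- numeric(H); C <- numeric(H)
  out <- list(f = matrix(0, Tn, H), u = matrix(0, Tn, H),
              o = matrix(0, Tn, H), cbar = matrix(0, Tn, H),
              C = matrix(0, Tn, H), h = matrix(0, Tn, H))
  sig <- function(z) 1 / (1 + exp(-z))
  for (t in seq_len(Tn)) {
    z <- c(h, sequence[t, ])
    f <- sig(as.numeric(z %*% params$Wf) + params$bf)
    u <- sig(as.numeric(z %*% params$Wu) + params$bu)
    o <- sig(as.numeric(z %*% params$Wo) + params$bo)
    cb <- tanh(as.numeric(z %*% params$Wc) + params$bc)
    C <- f * C + u * cb
    h <- o * tanh(C)
    out$f[t, ] <- f; out$u[t, ] <- u; out$o[t, ] <- o
    out$cbar[t, ] <- cb; out$C[t, ] <- C; out$h[t, ] <- h
  }
  out
}

test_that("the forward trajectory matches an independent per-timestep calculator", {
  withr::with_seed(10, {
    params <- erpdecode:::lstm_params(5, 4)
    x <- matrix(rnorm(3 * 4), 3)
  })
  got <- lstm_forward(params, x)
  ref <- reference_lstm(params, x)
  for (nm in names(ref))
    expect_equal(got[[nm]], ref[[nm]], tolerance = 1e-12)
  # gates strictly inside (0, 1); |h| < 1 from the tanh/gate bounds
  expect_true(all(got$f > 0 & got$f < 1))
  expect_true(all(got$u > 0 & got$u < 1))
  expect_true(all(got$o > 0 & got$o < 1))
  expect_true(all(abs(got$h) < 1))
  expect_error(lstm_forward(params, matrix(0, 2, 7)), "features")
})

test_that("the zero-parameter network is fully neutral", {
  p0 <- erpdecode:::lstm_params(4, 3, init = FALSE)
  x <- matrix(rnorm(5 * 3), 5)
  fw <- lstm_forward(p0, x)
  expect_true(all(fw$f == 0.5) && all(fw$u == 0.5) && all(fw$o == 0.5))
  expect_true(all(fw$cbar == 0) && all(fw$C == 0) && all(fw$h == 0))

  cfg <- network_config(layer_lstm(4), layer_dense(2))
  params <- init_params(cfg, 3, seed = 1)
  params[[1]][c("Wf", "Wc", "Wu", "Wo")] <-
    lapply(params[[1]][c("Wf", "Wc", "Wu", "Wo")], function(m) m * 0)
  params[[2]]$W <- params[[2]]$W * 0
  probs <- network_forward(cfg, params,
                           array(rnorm(6 * 2 * 3), dim = c(6, 2, 3)))
  expect_equal(probs, matrix(0.5, 6, 2))
  # uniform loss is log 2 per trial
  lg <- loss_and_gradients(cfg, params,
                           array(rnorm(6 * 2 * 3), dim = c(6, 2, 3)),
                           rep(1:2, 3))
  expect_equal(lg$loss, log(2), tolerance = 1e-12)
})

test_that("every parameter gradient matches central finite differences", {
  withr::with_seed(11, x <- array(rnorm(4 * 2 * 4), dim = c(4, 2, 4)))
  y <- c(1, 2, 1, 2)
  cfg <- network_config(layer_lstm(3), layer_dense(2))
  params <- init_params(cfg, 4, seed = 2)
  expect_lt(max_grad_rel_err(cfg, params, x, y), 1e-4)
})

test_that("the stacked sequence-to-sequence front end also passes the gradient check", {
  withr::with_seed(12, x <- array(rnorm(3 * 2 * 3), dim = c(3, 2, 3)))
  y <- c(1, 2, 2)
  cfg <- network_config(layer_lstm(3, "sequence_to_sequence"),
                        layer_lstm(2), layer_dense(2))
  params <- init_params(cfg, 3, seed = 3)
  expect_lt(max_grad_rel_err(cfg, params, x, y), 1e-4)
})

test_that("network configurations are validated", {
  expect_error(network_config(layer_lstm(4)), "dense")
  expect_error(network_config(layer_lstm(4), layer_dense(3)), "n_classes")
  expect_error(network_config(layer_lstm(4, "sequence_to_sequence"),
                              layer_dense(2)), "sequence_to_label")
  expect_error(network_config(layer_lstm(4), layer_lstm(3),
                              layer_dense(2)), "exactly one")
})

test_that("dropout is identity in evaluation and unbiased in training", {
  cfg <- network_config(layer_lstm(4), layer_dropout(0.2), layer_dense(2))
  params <- init_params(cfg, 3, seed = 4)
  x <- array(rnorm(8 * 2 * 3), dim = c(8, 2, 3))
  p1 <- network_forward(cfg, params, x, training = FALSE)
  p2 <- network_forward(cfg, params, x, training = FALSE)
  expect_identical(p1, p2)
  # Monte-Carlo expectation of the inverted-scaling mask is 1
  masks <- withr::with_seed(5, replicate(2000, {
    m <- (runif(50) >= 0.2) / 0.8
    mean(m)
  }))
  expect_equal(mean(masks), 1, tolerance = 0.02)
})

test_that("softmax ties give uniform probabilities and argmax picks labels", {
  probs <- erpdecode:::softmax_rows(matrix(c(1, 1, 3, 3), 2, byrow = TRUE))
  expect_equal(probs, matrix(0.5, 2, 2))
})

test_that("training runs the exact iteration count and a zero rate is a no-op", {
  sep <- separable_sequences(n = 20)
  cfg <- network_config(layer_lstm(4), layer_dense(2))
  tc <- train_config(learning_rate = 0, epochs = 3, batch_size = 8, seed = 6)
  fit <- lstm_train(cfg, sep$x, labels = sep$labels, train_cfg = tc)
  expect_equal(nrow(fit$history), 3 * ceiling(20 / 8))
  expect_equal(fit$params, init_params(cfg, 3, seed = 6), tolerance = 1e-15)
})

test_that("training separates a linearly separable toy problem and is reproducible", {
  sep <- separable_sequences(n = 40)
  cfg <- network_config(layer_lstm(6), layer_dropout(0.2), layer_dense(2))
  tc <- train_config(learning_rate = 0.05, epochs = 20, batch_size = 20,
                     seed = 7)
  fit <- lstm_train(cfg, sep$x, labels = sep$labels, train_cfg = tc)
  pred <- predict(fit, sep$x)
  expect_gte(mean(pred$labels == sep$labels), 0.99)
  fit2 <- lstm_train(cfg, sep$x, labels = sep$labels, train_cfg = tc)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$history, fit2$history)
})

test_that("prediction is batch-size invariant and probabilities sum to 1", {
  sep <- separable_sequences(n = 12)
  cfg <- network_config(layer_lstm(4), layer_dense(2))
  tc <- train_config(learning_rate = 0.05, epochs = 2, batch_size = 6,
                     seed = 8)
  fit <- lstm_train(cfg, sep$x, labels = sep$labels, train_cfg = tc)
  all_p <- predict(fit, sep$x)
  one_p <- predict(fit, sep$x[3, , , drop = FALSE])
  expect_equal(one_p$probabilities[1, ], all_p$probabilities[3, ],
               tolerance = 1e-14)
  expect_equal(rowSums(all_p$probabilities), rep(1, 12), tolerance = 1e-12)
  # accuracy equals the confusion-matrix trace ratio
  cm <- table(all_p$labels, sep$labels)
  expect_equal(mean(all_p$labels == sep$labels), sum(diag(cm)) / sum(cm))
  expect_error(predict(fit, sep$x[, , 1:2, drop = FALSE]), "features")
})

test_that("labels outside the class set are rejected", {
  cfg <- network_config(layer_lstm(3), layer_dense(2))
  params <- init_params(cfg, 2, seed = 9)
  x <- array(rnorm(2 * 2 * 2), dim = c(2, 2, 2))
  expect_error(loss_and_gradients(cfg, params, x, c(1, 3)), "label")
})
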