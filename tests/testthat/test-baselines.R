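test_that("PCA features match an eigendecomposition oracle up to sign", {
  withr::with_seed(20, X <- matrix(rnorm(60 * 30), 60))
  S <- pca_features(X, 5)
  expect_equal(dim(S), c(60, 5))
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / (60 - 1), symmetric = TRUE)
  ref <- Xc %*% ev$vectors[, 1:5]
  for (j in 1:5)
    expect_equal(abs(S[, j]), abs(ref[, j]), tolerance = 1e-8)
  # deterministic sign convention: dominant loading positive
  expect_identical(pca_features(X, 5), S)
  # exact low-rank data reconstructs exactly
  B <- matrix(rnorm(40 * 2), 40) %*% matrix(rnorm(2 * 10), 2)
  S2 <- pca_features(B, 2)
  Bc <- sweep(B, 2, colMeans(B))
  # scores are an orthogonal projection: for data lying in a 2-plane the
  # residual energy ||Bc||^2 - ||scores||^2 must vanish
  expect_lt(sqrt(max(0, sum(Bc^2) - sum(S2^2))), 1e-9)
  expect_error(pca_features(X, 30), "min\\(n, m\\)")
})

test_that("FastICA recovers known sources and decorrelates components", {
  t <- seq(0, 1, length.out = 400)
  s1 <- sin(2 * pi * 7 * t)
  s2 <- 2 * ((5 * t) %% 1) - 1                 # sawtooth
  withr::with_seed(21, {
    A <- matrix(rnorm(8), 4, 2)
    X <- cbind(s1, s2) %*% t(A) + matrix(rnorm(400 * 4, sd = 0.01), 400)
  })
  S <- ica_features(X, 2, seed = 9)
  expect_equal(dim(S), c(400, 2))
  cors <- abs(cor(S, cbind(s1, s2)))
  expect_gt(max(cors[, 1]), 0.99)
  expect_gt(max(cors[, 2]), 0.99)
  expect_lt(abs(cor(S)[1, 2]), 1e-6)
  expect_identical(ica_features(X, 2, seed = 9), S)   # seeded determinism
})

test_that("the RBF SVM separates clusters and matches an independent solver", {
  withr::with_seed(22, {
    tr <- rbind(matrix(rnorm(40, 4), 20, 2), matrix(rnorm(40, -4), 20, 2))
    te <- rbind(matrix(rnorm(20, 4), 10, 2), matrix(rnorm(20, -4), 10, 2))
  })
  y <- rep(c("accept", "reject"), each = 20)
  truth <- rep(c("accept", "reject"), each = 10)
  pred <- svm_rbf(tr, y, te, gamma = 0.5, cost = 1)
  expect_equal(mean(pred == truth), 1)
  expect_error(svm_rbf(tr, rep("accept", 40), te), "single class")
  # kernel of identical points is exp(0) = 1 by definition
  expect_equal(exp(-0.5 * sum((tr[1, ] - tr[1, ])^2)), 1)

  skip_if_not_installed("kernlab")
  # independent dual solver on a small instance
  withr::with_seed(23, {
    tr2 <- rbind(matrix(rnorm(20, 2), 10, 2), matrix(rnorm(20, -2), 10, 2))
    te2 <- rbind(matrix(rnorm(10, 2), 5, 2), matrix(rnorm(10, -2), 5, 2))
  })
  y2 <- factor(rep(c("accept", "reject"), each = 10))
  ref_fit <- kernlab::ksvm(tr2, y2, kernel = "rbfdot",
                           kpar = list(sigma = 0.5), C = 1, scaled = FALSE)
  ref <- kernlab::predict(ref_fit, te2)
  got <- svm_rbf(tr2, y2, te2, gamma = 0.5, cost = 1)
  expect_equal(as.character(got), as.character(ref))
})

test_that("the BP network has the printed layer sizes and learns separable data", {
  withr::with_seed(24, {
    tr <- rbind(matrix(rnorm(60, 2), 30, 2), matrix(rnorm(60, -2), 30, 2))
    te <- rbind(matrix(rnorm(20, 2), 10, 2), matrix(rnorm(20, -2), 10, 2))
  })
  y <- rep(c("accept", "reject"), each = 30)
  truth <- rep(c("accept", "reject"), each = 10)
  tc <- train_config(learning_rate = 0.1, epochs = 50, batch_size = 20,
                     seed = 3)
  res <- bp_classifier(tr, y, te, train_cfg = tc)
  expect_gte(mean(res$labels == truth), 0.99)
  sizes <- vapply(res$fit$config$layers, function(l)
    if (l$type == "dense") l$units else NA_integer_, integer(1))
  expect_equal(sizes, c(20L, 10L, 2L))
  # literal 1-unit sigmoid head variant
  res1 <- bp_classifier(tr, y, te, output = "sigmoid1", train_cfg = tc)
  expect_gte(mean(res1$labels == truth), 0.99)
})

test_that("zero-initialized BP head is symmetric before training", {
  cfg <- network_config(layer_dense(20, "sigmoid"), layer_dense(10, "sigmoid"),
                        layer_dense(2))
  params <- init_params(cfg, 5, seed = 1)
  params[[3]]$W <- params[[3]]$W * 0
  probs <- network_forward(cfg, params, matrix(rnorm(20), 4, 5))
  expect_equal(probs, matrix(0.5, 4, 2))
})

test_that("the Morlet scalogram localizes a pure tone and is linear", {
  fs <- 500
  tt <- seq_len(1000) / fs
  img <- cwt_image(matrix(sin(2 * pi * 10 * tt), 1), sampling_rate = fs)
  expect_equal(dim(img), c(32, 1000))
  freqs <- attr(img, "frequencies")
  ridge <- which.max(rowMeans(img))
  step <- freqs[2] / freqs[1]
  expect_lt(abs(log(freqs[ridge] / 10)), log(step) * 1.5)
  expect_equal(max(cwt_image(matrix(0, 3, 200), fs)), 0)
  expect_error(cwt_image(matrix(0, 1, 1)), "degenerate")
})

test_that("convolving a centered delta reproduces the flipped kernel", {
  withr::with_seed(26, K <- matrix(rnorm(9), 3))
  I <- matrix(0, 7, 7); I[4, 4] <- 1
  out <- conv2d_valid(I, K)
  expect_equal(dim(out), c(5, 5))
  expect_equal(out[2:4, 2:4], K[3:1, 3:1])
  expect_true(all(out[1, ] == 0) && all(out[, 1] == 0))
  expect_error(conv2d_valid(matrix(0, 2, 2), K), "smaller")
})

test_that("the CNN trains on small separable images", {
  withr::with_seed(25, {
    n <- 24
    imgs <- lapply(seq_len(n), function(i) {
      base <- matrix(rnorm(10 * 10, sd = 0.3), 10)
      if (i <= n / 2) base[3:7, 3:7] <- base[3:7, 3:7] + 1.5
      base
    })
  })
  lab <- rep(c("accept", "reject"), each = 12)
  tr_i <- c(1:9, 13:21); te_i <- c(10:12, 22:24)
  res <- cnn_classifier(imgs[tr_i], lab[tr_i], imgs[te_i],
                        train_cfg = train_config(learning_rate = 0.02,
                                                 epochs = 30, batch_size = 9,
                                                 seed = 5),
                        n_filters = 4, kernel_size = 3)
  expect_gte(mean(res$labels == lab[te_i]), 0.8)
  expect_error(cnn_classifier(list(matrix(0, 2, 2)), "accept",
                              list(matrix(0, 2, 2)),
                              kernel_size = 5), "smaller")
})

test_that("the deep-LSTM front end preserves sequence length with 120-unit default", {
  spec <- baseline_spec("deep_lstm")
  expect_equal(spec$deep_hidden, 120)
  # seq-to-seq layer output covers every step
  params <- erpdecode:::lstm_params(4, 3)
  A <- array(rnorm(2 * 5 * 3), dim = c(2, 5, 3))
  fw <- erpdecode:::lstm_layer_forward(params, A)
  expect_equal(dim(fw$Hseq), c(2, 5, 4))
})
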