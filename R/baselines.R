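#' Principal-component features
#'
#' Centers the datapoint rows and projects them onto the top `k`
#' principal axes (via singular value decomposition). Component signs are
#' fixed deterministically: each axis is flipped so that its
#' largest-magnitude loading is positive.
#'
#' @param X a `datapoint_matrix` or plain numeric matrix (rows =
#'   datapoints).
#' @param k number of components (default 5).
#' @return n x k score matrix.
#' @export
pca_features <- function(X, k = 5) {
  if (inherits(X, "datapoint_matrix")) X <- X$X
  X <- as.matrix(X)
  if (k >= min(dim(X)))
    stop2("k = %d must be below min(n, m) = %d", k, min(dim(X)))
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = k)
  V <- sv$v
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  Xc %*% V
}

#' Independent-component features (FastICA)
#'
#' Whitens the centered rows to `k` dimensions and runs the fixed-point
#' FastICA iteration with the tanh negentropy contrast and symmetric
#' orthogonalization, stopping when the unmixing matrix changes by less
#' than `tol` or after `max_iter` sweeps (with a warning; the best
#' iterate is returned). Components are mutually uncorrelated by
#' construction; their order and signs are fixed by the seeded
#' initialization plus a deterministic convention (decreasing
#' non-Gaussianity, largest-magnitude loading positive).
#'
#' @param X a `datapoint_matrix` or plain matrix.
#' @param k number of components (default 5).
#' @param seed integer seed for the random orthogonal initialization.
#' @param tol convergence tolerance on the unmixing update (default 1e-6).
#' @param max_iter sweep limit (default 500).
#' @return n x k source matrix (unit variance columns).
#' @export
ica_features <- function(X, k = 5, seed = 1, tol = 1e-6, max_iter = 500) {
  if (inherits(X, "datapoint_matrix")) X <- X$X
  X <- as.matrix(X)
  n <- nrow(X)
  if (k >= min(dim(X))) stop2("k = %d too large for a %d x %d matrix",
                              k, n, ncol(X))
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = k, nv = 0)
  dvals <- sv$d[seq_len(k)]
  if (any(dvals < 1e-12 * sv$d[1]))
    stop2("data rank below k; cannot whiten to %d components", k)
  Z <- sv$u * sqrt(n)                   # n x k, whitened: cov(Z) = I
  W <- with_seed(seed, {
    M <- matrix(rnorm(k * k), k, k)
    qr.Q(qr(M))                         # random orthogonal start
  })
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), k) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)                    # n x k projections
    G <- tanh(WX)
    Gp <- 1 - G^2
    W1 <- crossprod(G, Z) / n - diag(colMeans(Gp), k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("FastICA did not converge in %d sweeps; returning best iterate",
                    max_iter))
  S <- Z %*% t(W)
  # deterministic order/sign: decreasing non-Gaussianity, peak positive
  ng <- abs(colMeans(log(cosh(S))) - 0.3746)   # E[log cosh] of N(0,1)
  ord <- order(ng, decreasing = TRUE)
  S <- S[, ord, drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(S[, j]))
    if (S[i, j] < 0) S[, j] <- -S[, j]
  }
  S
}

#' RBF-kernel support vector classification
#'
#' Trains a soft-margin SVM with the radial basis kernel
#' `exp(-gamma ||u - v||^2)` on the training features and predicts the
#' test features. The dual problem is solved by the libsvm SMO solver
#' (package e1071) to its KKT tolerance.
#'
#' @param train_x n x d training features.
#' @param train_y training labels (factor or character).
#' @param test_x test features.
#' @param gamma RBF width (default `1/d`).
#' @param cost soft-margin cost parameter C (default 1).
#' @return factor of predicted test labels.
#' @export
svm_rbf <- function(train_x, train_y, test_x, gamma = NULL, cost = 1) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- droplevels(as.factor(train_y))
  if (nlevels(train_y) < 2)
    stop2("training set contains a single class; SVM needs both")
  gamma <- gamma %||% (1 / ncol(train_x))
  fit <- e1071::svm(train_x, train_y, kernel = "radial", gamma = gamma,
                    cost = cost, scale = FALSE, tolerance = 1e-6)
  predict(fit, test_x)
}

#' Back-propagation network on extracted features
#'
#' A small dense classifier: fully connected layers of 20 and 10 hidden
#' units (sigmoid activations) and a softmax output head, trained with
#' the shared sgdm settings. The printed architecture this mirrors ends
#' in a 1-unit output followed by softmax, which is degenerate (softmax
#' over one unit is constant); the default realizes it as a 2-unit
#' softmax head, and `output = "sigmoid1"` provides the literal 1-unit
#' variant with a logistic output and binary cross-entropy.
#'
#' @param train_x n x d training features.
#' @param train_y training labels.
#' @param test_x test features.
#' @param hidden hidden layer sizes (default `c(20, 10)`).
#' @param output `"softmax2"` (default) or `"sigmoid1"`.
#' @param train_cfg a [train_config()].
#' @return list with `labels` (factor of test predictions) and `fit`.
#' @export
bp_classifier <- function(train_x, train_y, test_x, hidden = c(20, 10),
                          output = c("softmax2", "sigmoid1"),
                          train_cfg = train_config()) {
  output <- match.arg(output)
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- droplevels(as.factor(train_y))
  if (output == "softmax2") {
    layers <- c(lapply(hidden, layer_dense, activation = "sigmoid"),
                list(layer_dense(nlevels(train_y))))
    cfg <- network_config(layers, n_classes = nlevels(train_y))
    fit <- lstm_train(cfg, train_x, labels = train_y, train_cfg = train_cfg)
    pred <- predict(fit, test_x)
    list(labels = factor(as.character(pred$labels), levels = levels(train_y)),
         fit = fit)
  } else {
    fit <- sigmoid1_train(train_x, as.integer(train_y) - 1L, hidden,
                          train_cfg)
    p <- sigmoid1_forward(fit$params, test_x)$p
    list(labels = factor(levels(train_y)[(p > 0.5) + 1L],
                         levels = levels(train_y)),
         fit = fit)
  }
}

# Literal 1-unit-output variant: sigmoid head + binary cross-entropy.
sigmoid1_forward <- function(params, x) {
  acts <- list()
  cur <- x
  for (i in seq_along(params)) {
    a <- cur %*% params[[i]]$W + rep(params[[i]]$b, each = nrow(cur))
    cur <- if (i < length(params)) sigmoid(a) else sigmoid(a)
    acts[[i]] <- list(input = if (i == 1) x else acts[[i - 1]]$out, out = cur)
  }
  list(p = cur[, 1], acts = acts)
}

sigmoid1_train <- function(x, y01, hidden, train_cfg) {
  sizes <- c(ncol(x), hidden, 1L)
  params <- with_seed(train_cfg$seed, lapply(seq_len(length(sizes) - 1),
    function(i) {
      lim <- sqrt(6 / (sizes[i] + sizes[i + 1]))
      list(W = matrix(runif(sizes[i] * sizes[i + 1], -lim, lim),
                      sizes[i], sizes[i + 1]),
           b = numeric(sizes[i + 1]))
    }))
  n <- nrow(x)
  nb <- ceiling(n / train_cfg$batch_size)
  vel <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  with_seed(derive_seed(train_cfg$seed, "sigmoid1"), {
    for (ep in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n)
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1) * train_cfg$batch_size + 1):
                     min(b * train_cfg$batch_size, n)]
        xb <- x[idx, , drop = FALSE]; yb <- y01[idx]
        fw <- sigmoid1_forward(params, xb)
        m <- length(idx)
        # delta at each sigmoid layer; output: (p - y)/m
        deltas <- vector("list", length(params))
        deltas[[length(params)]] <- matrix((fw$p - yb) / m, ncol = 1)
        for (i in rev(seq_len(length(params) - 1))) {
          out <- fw$acts[[i]]$out
          deltas[[i]] <- (deltas[[i + 1]] %*% t(params[[i + 1]]$W)) *
            out * (1 - out)
        }
        for (i in seq_along(params)) {
          inp <- fw$acts[[i]]$input
          gW <- crossprod(inp, deltas[[i]])
          gb <- colSums(deltas[[i]])
          vel[[i]]$W <- train_cfg$momentum * vel[[i]]$W -
            train_cfg$learning_rate * gW
          vel[[i]]$b <- train_cfg$momentum * vel[[i]]$b -
            train_cfg$learning_rate * gb
          params[[i]]$W <- params[[i]]$W + vel[[i]]$W
          params[[i]]$b <- params[[i]]$b + vel[[i]]$b
        }
      }
    }
  })
  list(params = params)
}

#' Continuous-wavelet scalogram of one trial
#'
#' Transforms a single trial to a time-frequency image with a Morlet
#' wavelet (center frequency parameter `omega0 = 6`): for each of
#' `n_scales` log-spaced analysis frequencies between `freq_range[1]` and
#' `freq_range[2]` Hz, the magnitude of the FFT-domain wavelet transform
#' is computed per channel and averaged across channels into one image.
#' Deterministic; rows are scales (low to high frequency), columns time
#' samples.
#'
#' @param trial channels x samples numeric matrix (a single trial).
#' @param sampling_rate Hz.
#' @param freq_range analysis band in Hz (default `c(1, 30)`, matching
#'   the low-pass band of the preprocessing chain).
#' @param n_scales number of log-spaced scales (default 32).
#' @param omega0 Morlet center frequency parameter (default 6).
#' @param time_downsample keep every `time_downsample`-th column
#'   (default 1 = none); reduces image width for the CNN.
#' @return `cwt_image` matrix (n_scales x n_kept_samples) with attribute
#'   `"frequencies"`.
#' @export
cwt_image <- function(trial, sampling_rate = 1000, freq_range = c(1, 30),
                      n_scales = 32, omega0 = 6, time_downsample = 1) {
  trial <- as.matrix(trial)
  if (ncol(trial) < 2 || nrow(trial) < 1) stop2("empty or degenerate trial")
  N <- ncol(trial)
  freqs <- exp(seq(log(freq_range[1]), log(freq_range[2]),
                   length.out = n_scales))
  scales <- omega0 / (2 * pi * freqs) * sampling_rate   # in samples
  k <- c(seq(0, floor(N / 2)), seq(-ceiling(N / 2) + 1, -1))
  omega <- 2 * pi * k / N                               # rad/sample
  img <- matrix(0, n_scales, N)
  for (ch in seq_len(nrow(trial))) {
    Xf <- fft(trial[ch, ])
    for (s in seq_len(n_scales)) {
      # analytic Morlet: support on positive frequencies only
      psi <- ifelse(omega > 0,
                    pi^(-0.25) * exp(-(scales[s] * omega - omega0)^2 / 2),
                    0)
      w <- fft(Xf * psi, inverse = TRUE) / N
      img[s, ] <- img[s, ] + Mod(w)
    }
  }
  img <- img / nrow(trial)
  if (time_downsample > 1)
    img <- img[, seq(1, N, by = time_downsample), drop = FALSE]
  structure(img, frequencies = freqs, class = c("cwt_image", "matrix"))
}
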