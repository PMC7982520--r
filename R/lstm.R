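#' Network layer constructors
#'
#' Building blocks for the recurrent classifier and its variants. A
#' network is an ordered layer stack ending in an implicit softmax +
#' classification head. `layer_lstm` implements the standard gated
#' recurrence: at each timestep, forget gate
#' `f_t = sigmoid(W_f [h_(t-1), I_t] + b_f)`, update gate
#' `U_t = sigmoid(W_U [.] + b_U)`, candidate `cbar_t = tanh(W_c [.] + b_c)`,
#' cell `C_t = f_t * C_(t-1) + U_t * cbar_t`, output gate
#' `O_t = sigmoid(W_o [.] + b_o)` and hidden state
#' `h_t = O_t * tanh(C_t)` (all products elementwise; `h_0 = C_0 = 0`).
#'
#' @param hidden number of hidden units.
#' @param mode `"sequence_to_label"` (only the final hidden state is passed
#'   on) or `"sequence_to_sequence"` (the whole hidden trajectory is).
#' @param rate dropout rate in `[0, 1)`; inverted scaling, identity in
#'   evaluation mode.
#' @param units dense-layer output units.
#' @param activation dense-layer activation.
#' @return a layer specification (plain list).
#' @name layers
NULL

#' @rdname layers
#' @export
layer_lstm <- function(hidden, mode = c("sequence_to_label",
                                        "sequence_to_sequence")) {
  stopifnot(is_count(hidden))
  list(type = "lstm", hidden = as.integer(hidden), mode = match.arg(mode))
}

#' @rdname layers
#' @export
layer_dropout <- function(rate = 0.2) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate)
}

#' @rdname layers
#' @export
layer_dense <- function(units, activation = c("linear", "sigmoid", "relu")) {
  stopifnot(is_count(units))
  list(type = "dense", units = as.integer(units),
       activation = match.arg(activation))
}

#' Assemble and validate a network configuration
#'
#' @param ... layer specifications from [layer_lstm()], [layer_dropout()],
#'   [layer_dense()], in order. A softmax + classification head over
#'   `n_classes` is implicit at the end; the final dense layer must output
#'   `n_classes` units.
#' @param n_classes number of classes (default 2).
#' @return a `network_config`.
#' @examples
#' # the standard recurrent t-SNE classifier head
#' cfg <- network_config(layer_lstm(80), layer_dropout(0.2), layer_dense(2))
#' @export
network_config <- function(..., n_classes = 2) {
  layers <- list(...)
  if (length(layers) == 1 && is.null(layers[[1]]$type))
    layers <- layers[[1]]
  types <- vapply(layers, `[[`, character(1), "type")
  if (length(layers) == 0 || types[length(types)] != "dense")
    stop2("network must end in a dense layer (before the implicit softmax)")
  if (layers[[length(layers)]]$units != n_classes)
    stop2("final dense layer must have n_classes = %d units", n_classes)
  lstm_modes <- vapply(layers[types == "lstm"], `[[`, character(1), "mode")
  if (length(lstm_modes) > 0) {
    if (sum(lstm_modes == "sequence_to_label") != 1)
      stop2("need exactly one sequence_to_label LSTM collapse before the dense layers")
    collapse_at <- which(types == "lstm")[lstm_modes == "sequence_to_label"]
    later <- which(types == "lstm")
    if (any(later > collapse_at))
      stop2("no LSTM layer may follow the sequence_to_label collapse")
  }
  structure(list(layers = layers, n_classes = as.integer(n_classes)),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat("<network_config>\n")
  for (l in x$layers) {
    cat("  ", switch(l$type,
      lstm = sprintf("lstm(%d, %s)", l$hidden, l$mode),
      dropout = sprintf("dropout(%.2g)", l$rate),
      dense = sprintf("dense(%d, %s)", l$units, l$activation)), "\n")
  }
  cat(sprintf("  softmax + classification (%d classes)\n", x$n_classes))
  invisible(x)
}

#' Initialize network parameters
#'
#' Glorot-uniform weights (limit `sqrt(6 / (fan_in + fan_out))`) and zero
#' biases, drawn under `seed`.
#'
#' @param config a [network_config()].
#' @param input_features feature dimension of the input sequences.
#' @param seed integer seed.
#' @return list of per-layer parameter lists (`lstm_params` entries carry
#'   `Wf`, `Wc`, `Wu`, `Wo` acting on the concatenation `[h, x]`, and
#'   biases `bf`, `bc`, `bu`, `bo`).
#' @export
init_params <- function(config, input_features, seed = 1) {
  stopifnot(inherits(config, "network_config"))
  with_seed(seed, {
    fin <- input_features
    lapply(config$layers, function(l) {
      switch(l$type,
        lstm = {
          p <- lstm_params(l$hidden, fin)
          fin <<- l$hidden
          p
        },
        dropout = list(type = "dropout"),
        dense = {
          lim <- sqrt(6 / (fin + l$units))
          p <- list(type = "dense",
                    W = matrix(runif(fin * l$units, -lim, lim), fin, l$units),
                    b = numeric(l$units))
          fin <<- l$units
          p
        })
    })
  })
}

# Glorot-uniform LSTM gate parameters on the concatenation [h, x].
lstm_params <- function(hidden, input_features, init = TRUE) {
  H <- hidden; Fi <- input_features
  lim <- sqrt(6 / (H + Fi + H))
  mk <- function() if (init)
    matrix(runif((H + Fi) * H, -lim, lim), H + Fi, H)
  else matrix(0, H + Fi, H)
  list(type = "lstm", hidden = H, input_features = Fi,
       Wf = mk(), Wc = mk(), Wu = mk(), Wo = mk(),
       bf = numeric(H), bc = numeric(H), bu = numeric(H), bo = numeric(H))
}

#' Run one sequence through an LSTM layer, exposing the gate trajectory
#'
#' Mainly a verification surface: computes, for each timestep, the forget,
#' update and output gates, the candidate, the cell state and the hidden
#' state, exactly in the order the recurrence defines them.
#'
#' @param params an LSTM parameter list (element of [init_params()] output,
#'   or built via the internal constructor with zero weights).
#' @param sequence steps x features numeric matrix.
#' @return list of steps x hidden matrices: `f`, `u`, `o`, `cbar`, `C`, `h`.
#' @export
lstm_forward <- function(params, sequence) {
  sequence <- as.matrix(sequence)
  if (ncol(sequence) != params$input_features)
    stop2("sequence has %d features; params expect %d",
          ncol(sequence), params$input_features)
  A <- array(sequence, dim = c(1, nrow(sequence), ncol(sequence)))
  fw <- lstm_layer_forward(params, A)
  squeeze <- function(lst) do.call(rbind, lapply(lst, function(m) m[1, ]))
  list(f = squeeze(fw$f), u = squeeze(fw$u), o = squeeze(fw$o),
       cbar = squeeze(fw$cbar), C = squeeze(fw$C), h = squeeze(fw$h))
}

# Batched LSTM forward. A: n x T x F array. Returns per-step caches.
lstm_layer_forward <- function(params, A) {
  n <- dim(A)[1]; T <- dim(A)[2]; Fi <- dim(A)[3]
  H <- params$hidden
  if (Fi != params$input_features)
    stop2("input features %d do not match params (%d)", Fi,
          params$input_features)
  Hprev <- matrix(0, n, H); Cprev <- matrix(0, n, H)
  Z <- f <- u <- o <- cbar <- C <- h <- vector("list", T)
  Hseq <- array(0, dim = c(n, T, H))
  for (t in seq_len(T)) {
    Zt <- cbind(Hprev, matrix(A[, t, ], nrow = n))
    ft <- sigmoid(Zt %*% params$Wf + rep(params$bf, each = n))
    ut <- sigmoid(Zt %*% params$Wu + rep(params$bu, each = n))
    ot <- sigmoid(Zt %*% params$Wo + rep(params$bo, each = n))
    cbt <- tanh(Zt %*% params$Wc + rep(params$bc, each = n))
    Ct <- ft * Cprev + ut * cbt
    ht <- ot * tanh(Ct)
    Z[[t]] <- Zt; f[[t]] <- ft; u[[t]] <- ut; o[[t]] <- ot
    cbar[[t]] <- cbt; C[[t]] <- Ct; h[[t]] <- ht
    Hseq[, t, ] <- ht
    Hprev <- ht; Cprev <- Ct
  }
  list(Z = Z, f = f, u = u, o = o, cbar = cbar, C = C, h = h,
       Hseq = Hseq, n = n, T = T, Fi = Fi, H = H)
}

# Backpropagation through time. dH_out: for sequence_to_label a n x H
# matrix (gradient at the final hidden state); for sequence_to_sequence a
# n x T x H array. Returns parameter gradients and dX (n x T x F).
lstm_layer_backward <- function(params, cache, dH_out, mode) {
  n <- cache$n; T <- cache$T; Fi <- cache$Fi; H <- cache$H
  g <- list(Wf = matrix(0, H + Fi, H), Wc = matrix(0, H + Fi, H),
            Wu = matrix(0, H + Fi, H), Wo = matrix(0, H + Fi, H),
            bf = numeric(H), bc = numeric(H), bu = numeric(H), bo = numeric(H))
  dX <- array(0, dim = c(n, T, Fi))
  dH_carry <- matrix(0, n, H)
  dC_carry <- matrix(0, n, H)
  for (t in rev(seq_len(T))) {
    dh <- dH_carry
    if (mode == "sequence_to_label") {
      if (t == T) dh <- dh + dH_out
    } else {
      dh <- dh + matrix(dH_out[, t, ], nrow = n)
    }
    f <- cache$f[[t]]; u <- cache$u[[t]]; o <- cache$o[[t]]
    cb <- cache$cbar[[t]]; C <- cache$C[[t]]
    Cprev <- if (t > 1) cache$C[[t - 1]] else matrix(0, n, H)
    tC <- tanh(C)
    do <- dh * tC
    dC <- dC_carry + dh * o * (1 - tC^2)
    df <- dC * Cprev
    du <- dC * cb
    dcb <- dC * u
    dC_carry <- dC * f
    daf <- df * f * (1 - f)
    dau <- du * u * (1 - u)
    dao <- do * o * (1 - o)
    dac <- dcb * (1 - cb^2)
    Z <- cache$Z[[t]]
    g$Wf <- g$Wf + crossprod(Z, daf); g$bf <- g$bf + colSums(daf)
    g$Wu <- g$Wu + crossprod(Z, dau); g$bu <- g$bu + colSums(dau)
    g$Wo <- g$Wo + crossprod(Z, dao); g$bo <- g$bo + colSums(dao)
    g$Wc <- g$Wc + crossprod(Z, dac); g$bc <- g$bc + colSums(dac)
    dZ <- daf %*% t(params$Wf) + dau %*% t(params$Wu) +
      dao %*% t(params$Wo) + dac %*% t(params$Wc)
    dH_carry <- dZ[, seq_len(H), drop = FALSE]
    dX[, t, ] <- dZ[, H + seq_len(Fi), drop = FALSE]
  }
  list(grads = g, dX = dX)
}

# Full network forward with caches. `x` is n x T x F (sequence input) or
# n x F (flat features). Dropout masks are drawn from the current RNG
# stream when training.
network_forward_cached <- function(config, params, x, training = FALSE) {
  caches <- vector("list", length(config$layers))
  cur <- x
  for (i in seq_along(config$layers)) {
    l <- config$layers[[i]]
    if (l$type == "lstm") {
      if (length(dim(cur)) != 3) stop2("LSTM layer %d expects sequences", i)
      fw <- lstm_layer_forward(params[[i]], cur)
      caches[[i]] <- fw
      cur <- if (l$mode == "sequence_to_label") fw$h[[fw$T]] else fw$Hseq
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        mask <- array(
          (runif(length(cur)) >= l$rate) / (1 - l$rate),
          dim = dim(cur) %||% length(cur))
        caches[[i]] <- mask
        cur <- cur * mask
      } else caches[[i]] <- NULL        # identity in evaluation mode
    } else if (l$type == "dense") {
      if (length(dim(cur)) == 3)
        stop2("dense layer %d received a sequence; collapse it first", i)
      a <- cur %*% params[[i]]$W + rep(params[[i]]$b, each = nrow(cur))
      out <- switch(l$activation,
                    linear = a, sigmoid = sigmoid(a), relu = pmax(a, 0))
      caches[[i]] <- list(input = cur, pre = a, out = out)
      cur <- out
    }
  }
  probs <- softmax_rows(cur)
  list(logits = cur, probs = probs, caches = caches)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass of a configured network
#'
#' @param config a [network_config()].
#' @param params matching parameters from [init_params()].
#' @param x input batch: array `n x steps x features` for sequence input,
#'   a [feature_sequences] object, or a plain `n x features` matrix.
#' @param training when `TRUE`, dropout layers are active (inverted
#'   scaling); when `FALSE` they are the identity.
#' @param seed optional seed for the dropout masks.
#' @return n x n_classes matrix of class probabilities (rows sum to 1).
#' @export
network_forward <- function(config, params, x, training = FALSE,
                            seed = NULL) {
  if (inherits(x, "feature_sequences")) x <- x$sequences
  run <- function() network_forward_cached(config, params, x, training)$probs
  if (!is.null(seed)) with_seed(seed, run()) else run()
}

#' Loss and parameter gradients for a labeled batch
#'
#' Mean categorical cross-entropy of the softmax output over the batch,
#' and its gradient with respect to every weight and bias, computed by
#' backpropagation (through time, for recurrent layers). Agreement with
#' central finite differences is the binding correctness contract and is
#' enforced by the test suite.
#'
#' @param config a [network_config()].
#' @param params matching parameters.
#' @param x input batch (see [network_forward()]).
#' @param labels per-trial class index in `1..n_classes`, or a factor.
#' @param training activate dropout (default `FALSE`, so the loss is
#'   deterministic).
#' @return list with `loss` (scalar) and `grads` (same structure as
#'   `params`).
#' @export
loss_and_gradients <- function(config, params, x, labels, training = FALSE) {
  if (inherits(x, "feature_sequences")) x <- x$sequences
  y <- label_indices(labels, config$n_classes)
  n <- if (length(dim(x)) == 3) dim(x)[1] else nrow(x)
  if (length(y) != n) stop2("labels length %d does not match batch size %d",
                            length(y), n)
  fw <- network_forward_cached(config, params, x, training)
  probs <- fw$probs
  eps <- 1e-12
  loss <- -mean(log(pmax(probs[cbind(seq_len(n), y)], eps)))
  onehot <- matrix(0, n, config$n_classes)
  onehot[cbind(seq_len(n), y)] <- 1
  dcur <- (probs - onehot) / n
  grads <- vector("list", length(config$layers))
  for (i in rev(seq_along(config$layers))) {
    l <- config$layers[[i]]
    if (l$type == "dense") {
      cache <- fw$caches[[i]]
      da <- switch(l$activation,
                   linear = dcur,
                   sigmoid = dcur * cache$out * (1 - cache$out),
                   relu = dcur * (cache$pre > 0))
      grads[[i]] <- list(W = crossprod(cache$input, da), b = colSums(da))
      dcur <- da %*% t(params[[i]]$W)
    } else if (l$type == "dropout") {
      mask <- fw$caches[[i]]
      if (!is.null(mask)) dcur <- dcur * mask
      grads[[i]] <- list()
    } else if (l$type == "lstm") {
      bw <- lstm_layer_backward(params[[i]], fw$caches[[i]], dcur, l$mode)
      grads[[i]] <- bw$grads
      dcur <- bw$dX
    }
  }
  list(loss = loss, grads = grads, probs = probs)
}

label_indices <- function(labels, n_classes) {
  if (is.factor(labels)) return(as.integer(labels))
  if (is.character(labels)) return(as.integer(as_decision_labels(labels)))
  y <- as.integer(labels)
  if (any(y < 1 | y > n_classes))
    stop2("label outside 1..%d", n_classes)
  y
}

#' Training settings for gradient-descent classifiers
#'
#' Defaults follow the study setup: stochastic gradient descent with
#' momentum (sgdm), learning rate 0.001, dropout handled by the network's
#' dropout layers, batch size 100, stop after exactly 20 epochs with
#' per-epoch shuffling. The momentum coefficient is 0.9.
#'
#' @param learning_rate step size.
#' @param momentum momentum coefficient of the velocity term.
#' @param epochs number of passes over the training data; training runs
#'   exactly `epochs * ceiling(n / batch_size)` iterations.
#' @param batch_size trials per batch.
#' @param seed integer seed governing shuffling, initialization and
#'   dropout.
#' @param validation_every record validation accuracy every this many
#'   iterations (and at the end).
#' @return a `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, momentum = 0.9, epochs = 20,
                         batch_size = 100, seed = 1, validation_every = 10) {
  stopifnot(learning_rate >= 0, is_count(epochs), is_count(batch_size),
            momentum >= 0, momentum < 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 validation_every = as.integer(validation_every)),
            class = "train_config")
}

#' Train a network by stochastic gradient descent with momentum
#'
#' Runs sgdm (`velocity = momentum * velocity - lr * gradient;
#' params = params + velocity`) over shuffled batches for exactly
#' `epochs * ceiling(n / batch_size)` iterations. Per-iteration training
#' accuracy (on the current batch) and periodic validation accuracy are
#' recorded. Bit-reproducible for a fixed seed.
#'
#' @param config a [network_config()].
#' @param data training [feature_sequences] (or array/matrix input).
#' @param labels training labels (taken from `data` when it carries them).
#' @param train_cfg a [train_config()].
#' @param validation optional validation [feature_sequences].
#' @param validation_labels labels for `validation` when not carried.
#' @return an `lstm_fit` with elements `params`, `config`, `history`
#'   (data.frame: iteration, epoch, loss, train_acc, val_acc),
#'   `label_levels`, `train_cfg`.
#' @export
lstm_train <- function(config, data, labels = NULL,
                       train_cfg = train_config(), validation = NULL,
                       validation_labels = NULL) {
  stopifnot(inherits(config, "network_config"))
  x <- if (inherits(data, "feature_sequences")) data$sequences else data
  labels <- labels %||%
    (if (inherits(data, "feature_sequences")) data$labels else NULL)
  if (is.null(labels)) stop2("training labels are required")
  label_levels <- if (is.factor(labels)) levels(labels) else
    levels(as_decision_labels(labels))
  y <- label_indices(labels, config$n_classes)
  n <- if (length(dim(x)) == 3) dim(x)[1] else nrow(x)
  if (n == 0) stop2("empty training set")
  vx <- NULL; vy <- NULL
  if (!is.null(validation)) {
    vx <- if (inherits(validation, "feature_sequences"))
      validation$sequences else validation
    vl <- validation_labels %||%
      (if (inherits(validation, "feature_sequences")) validation$labels else NULL)
    vy <- label_indices(vl, config$n_classes)
  }
  input_features <- if (length(dim(x)) == 3) dim(x)[3] else ncol(x)
  n_batches <- ceiling(n / train_cfg$batch_size)
  total_iter <- train_cfg$epochs * n_batches
  hist <- data.frame(iteration = seq_len(total_iter), epoch = NA_integer_,
                     loss = NA_real_, train_acc = NA_real_,
                     val_acc = NA_real_)
  take <- function(arr, idx) {
    if (length(dim(arr)) == 3) arr[idx, , , drop = FALSE]
    else arr[idx, , drop = FALSE]
  }
  params <- init_params(config, input_features, seed = train_cfg$seed)
  with_seed(derive_seed(train_cfg$seed, "sgdm"), {
    velocity <- zero_like(params)
    it <- 0L
    for (ep in seq_len(train_cfg$epochs)) {
      order_ <- sample.int(n)
      for (b in seq_len(n_batches)) {
        it <- it + 1L
        idx <- order_[((b - 1) * train_cfg$batch_size + 1):
                        min(b * train_cfg$batch_size, n)]
        lg <- loss_and_gradients(config, params, take(x, idx), y[idx],
                                 training = TRUE)
        velocity <- combine_params(velocity, lg$grads, function(v, g)
          train_cfg$momentum * v - train_cfg$learning_rate * g)
        params <- combine_params(params, velocity, `+`, keep_meta = TRUE)
        pred <- max.col(lg$probs, ties.method = "first")
        hist$epoch[it] <- ep
        hist$loss[it] <- lg$loss
        hist$train_acc[it] <- mean(pred == y[idx])
        if (!is.null(vx) &&
            (it %% train_cfg$validation_every == 0 || it == total_iter)) {
          vp <- network_forward_cached(config, params, vx, FALSE)$probs
          hist$val_acc[it] <- mean(max.col(vp, ties.method = "first") == vy)
        }
      }
    }
  })
  structure(list(params = params, config = config, history = hist,
                 label_levels = label_levels, train_cfg = train_cfg,
                 input_features = input_features),
            class = "lstm_fit")
}

zero_like <- function(params) {
  lapply(params, function(p)
    lapply(p, function(q) if (is.numeric(q)) q * 0 else q))
}

# Elementwise combine two parameter structures; numeric leaves only.
combine_params <- function(a, b, fun, keep_meta = FALSE) {
  mapply(function(pa, pb) {
    out <- pa
    for (nm in names(pa)) {
      if (is.numeric(pa[[nm]]) && !is.null(pb[[nm]]) && nm != "hidden" &&
          nm != "input_features")
        out[[nm]] <- fun(pa[[nm]], pb[[nm]])
    }
    out
  }, a, b, SIMPLIFY = FALSE)
}

#' @export
print.lstm_fit <- function(x, ...) {
  h <- x$history
  last_val <- rev(h$val_acc[!is.na(h$val_acc)])
  cat(sprintf("<lstm_fit> trained %d iterations (%d epochs)\n",
              nrow(h), max(h$epoch)))
  cat(sprintf("  final batch accuracy %.3f%s\n", h$train_acc[nrow(h)],
              if (length(last_val)) sprintf(", validation accuracy %.3f",
                                            last_val[1]) else ""))
  invisible(x)
}

#' @export
summary.lstm_fit <- function(object, ...) {
  h <- object$history
  cat("Recurrent classifier fit\n")
  print(object$config)
  cat(sprintf("iterations: %d, final loss %.4f\n", nrow(h), h$loss[nrow(h)]))
  cat(sprintf("mean training accuracy (last epoch): %.3f\n",
              mean(h$train_acc[h$epoch == max(h$epoch)])))
  vv <- h$val_acc[!is.na(h$val_acc)]
  if (length(vv)) cat(sprintf("final validation accuracy: %.3f\n",
                              vv[length(vv)]))
  invisible(object)
}

#' @export
coef.lstm_fit <- function(object, ...) object$params

#' @export
plot.lstm_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$iteration, h$train_acc, type = "l", ylim = c(0, 1),
                 xlab = "iteration", ylab = "accuracy",
                 main = "Training progress", ...)
  ok <- !is.na(h$val_acc)
  if (any(ok)) {
    graphics::lines(h$iteration[ok], h$val_acc[ok], lty = 2)
    graphics::legend("bottomright", c("training (batch)", "validation"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Predict class labels from a trained network
#'
#' @param object an `lstm_fit`.
#' @param newdata a [feature_sequences], array or matrix batch.
#' @param ... unused.
#' @return list with `labels` (factor) and `probabilities`
#'   (n x n_classes; rows sum to 1). Predictions are batch-size
#'   invariant: predicting one trial alone equals predicting it inside a
#'   batch.
#' @export
predict.lstm_fit <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_sequences")) newdata$sequences else newdata
  fdim <- if (length(dim(x)) == 3) dim(x)[3] else ncol(x)
  if (fdim != object$input_features)
    stop2("newdata has %d features; model expects %d", fdim,
          object$input_features)
  probs <- network_forward_cached(object$config, object$params, x, FALSE)$probs
  idx <- max.col(probs, ties.method = "first")
  list(labels = factor(object$label_levels[idx],
                       levels = object$label_levels),
       probabilities = probs)
}
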