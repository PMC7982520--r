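#' 2-D convolution of an image with a kernel (valid region)
#'
#' Convolution in the CNN sense (sliding inner product, no kernel flip),
#' restricted to the fully overlapping region: the output at `(x, y)` is
#' `sum_(a,b) K[a, b] I[x + a - 1, y + b - 1]`. Convolving a centered
#' delta image therefore reproduces the 180-degree-flipped kernel — the
#' impulse response of this operator.
#'
#' @param image h x w numeric matrix.
#' @param kernel kh x kw numeric matrix.
#' @return `(h - kh + 1) x (w - kw + 1)` matrix.
#' @export
conv2d_valid <- function(image, kernel) {
  image <- as.matrix(image); kernel <- as.matrix(kernel)
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (nrow(image) < kh || ncol(image) < kw)
    stop2("image (%d x %d) smaller than kernel (%d x %d)",
          nrow(image), ncol(image), kh, kw)
  col <- im2col(image, kh, kw)
  matrix(col %*% as.numeric(kernel),
         nrow(image) - kh + 1, ncol(image) - kw + 1)
}

# Patch matrix: one row per output position (column-major over the output
# grid), columns = flattened kh x kw patch (column-major).
im2col <- function(image, kh, kw) {
  oh <- nrow(image) - kh + 1
  ow <- ncol(image) - kw + 1
  col <- matrix(0, oh * ow, kh * kw)
  p <- 0
  for (j in seq_len(kw))
    for (i in seq_len(kh)) {
      p <- p + 1
      col[, p] <- as.numeric(image[i:(i + oh - 1), j:(j + ow - 1)])
    }
  col
}

#' Convolutional classifier on time-frequency images
#'
#' The comparison architecture for scalogram input: one 2-D convolution
#' layer (`n_filters` kernels of `kernel_size x kernel_size`, stride 1,
#' valid padding), batch normalization per filter channel across the
#' mini-batch, ReLU (values below 0 set to 0), a fully connected 2-unit
#' layer and softmax, trained with the shared sgdm settings. No pooling
#' layer is present, so the dense layer connects directly to the
#' rectified feature maps.
#'
#' @param train_images list of equal-sized matrices (or an
#'   `n x h x w` array) of training images.
#' @param train_y training labels.
#' @param test_images test images (same sizes).
#' @param train_cfg a [train_config()].
#' @param n_filters number of convolution filters (default 20).
#' @param kernel_size square kernel side (default 5).
#' @return list with `labels` (factor of test predictions) and `fit`
#'   (parameters and training history).
#' @export
cnn_classifier <- function(train_images, train_y, test_images,
                           train_cfg = train_config(), n_filters = 20,
                           kernel_size = 5) {
  tr <- as_image_array(train_images)
  te <- as_image_array(test_images)
  train_y <- droplevels(as.factor(train_y))
  n_classes <- nlevels(train_y)
  y <- as.integer(train_y)
  h <- dim(tr)[2]; w <- dim(tr)[3]
  if (h < kernel_size || w < kernel_size)
    stop2("images (%d x %d) smaller than the %d x %d kernel",
          h, w, kernel_size, kernel_size)
  oh <- h - kernel_size + 1; ow <- w - kernel_size + 1
  kk <- kernel_size^2
  n <- dim(tr)[1]

  # precompute patch matrices once per image
  cols <- lapply(seq_len(n), function(i)
    im2col(matrix(tr[i, , ], h, w), kernel_size, kernel_size))

  params <- with_seed(train_cfg$seed, {
    lim <- sqrt(6 / (kk + n_filters))
    limd <- sqrt(6 / (oh * ow * n_filters + n_classes))
    list(Wc = matrix(runif(kk * n_filters, -lim, lim), kk, n_filters),
         bc = numeric(n_filters),
         gamma = rep(1, n_filters), beta = numeric(n_filters),
         Wd = matrix(runif(oh * ow * n_filters * n_classes, -limd, limd),
                     oh * ow * n_filters, n_classes),
         bd = numeric(n_classes))
  })
  running <- list(mean = numeric(n_filters), var = rep(1, n_filters))
  eps <- 1e-5
  nb <- ceiling(n / train_cfg$batch_size)
  vel <- lapply(params, function(p) p * 0)

  forward <- function(cols_b, params, training) {
    m <- length(cols_b)
    # conv: per image, (oh*ow) x n_filters
    conv <- lapply(cols_b, function(cl)
      cl %*% params$Wc + rep(params$bc, each = nrow(cl)))
    A <- array(unlist(conv), dim = c(oh * ow, n_filters, m))
    if (training) {
      mu <- apply(A, 2, mean)
      v <- apply(A, 2, function(x) mean((x - mean(x))^2))
      running$mean <<- 0.9 * running$mean + 0.1 * mu
      running$var <<- 0.9 * running$var + 0.1 * v
    } else {
      mu <- running$mean; v <- running$var
    }
    xhat <- sweep(sweep(A, 2, mu), 2, sqrt(v + eps), "/")
    bn <- sweep(sweep(xhat, 2, params$gamma, "*"), 2, params$beta, "+")
    relu <- pmax(bn, 0)
    flat <- t(matrix(relu, oh * ow * n_filters, m))   # m x features
    logits <- flat %*% params$Wd + rep(params$bd, each = m)
    list(probs = softmax_rows(logits), A = A, xhat = xhat, bn = bn,
         relu = relu, flat = flat, mu = mu, v = v, m = m)
  }

  with_seed(derive_seed(train_cfg$seed, "cnn"), {
    for (ep in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n)
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1) * train_cfg$batch_size + 1):
                     min(b * train_cfg$batch_size, n)]
        fw <- forward(cols[idx], params, TRUE)
        m <- fw$m
        onehot <- matrix(0, m, n_classes)
        onehot[cbind(seq_len(m), y[idx])] <- 1
        dlog <- (fw$probs - onehot) / m
        g <- list()
        g$Wd <- crossprod(fw$flat, dlog)
        g$bd <- colSums(dlog)
        dflat <- dlog %*% t(params$Wd)
        drelu <- array(t(dflat), dim = c(oh * ow, n_filters, m))
        dbn <- drelu * (fw$bn > 0)
        g$gamma <- apply(dbn * fw$xhat, 2, sum)
        g$beta <- apply(dbn, 2, sum)
        # batch-norm backward over the (positions x batch) axis per filter
        dA <- array(0, dim = dim(dbn))
        for (f in seq_len(n_filters)) {
          dxh <- matrix(dbn[, f, ], oh * ow, m) * params$gamma[f]
          xh <- matrix(fw$xhat[, f, ], oh * ow, m)
          dA[, f, ] <- (dxh - mean(dxh) - xh * mean(dxh * xh)) /
            sqrt(fw$v[f] + eps)
        }
        g$Wc <- matrix(0, kk, n_filters)
        g$bc <- numeric(n_filters)
        for (ii in seq_len(m)) {
          dci <- matrix(dA[, , ii], oh * ow, n_filters)
          g$Wc <- g$Wc + crossprod(cols[idx][[ii]], dci)
          g$bc <- g$bc + colSums(dci)
        }
        for (nm in names(params)) {
          vel[[nm]] <- train_cfg$momentum * vel[[nm]] -
            train_cfg$learning_rate * g[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
      }
    }
  })

  predict_images <- function(imgs) {
    m <- dim(imgs)[1]
    cls <- lapply(seq_len(m), function(i)
      im2col(matrix(imgs[i, , ], h, w), kernel_size, kernel_size))
    fw <- forward(cls, params, FALSE)
    factor(levels(train_y)[max.col(fw$probs, ties.method = "first")],
           levels = levels(train_y))
  }
  list(labels = predict_images(te),
       fit = list(params = params, running = running))
}

as_image_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.list(x)) {
    h <- nrow(x[[1]]); w <- ncol(x[[1]])
    arr <- array(0, dim = c(length(x), h, w))
    for (i in seq_along(x)) {
      if (nrow(x[[i]]) != h || ncol(x[[i]]) != w)
        stop2("images must share one size")
      arr[i, , ] <- x[[i]]
    }
    return(arr)
  }
  stop2("images must be a list of matrices or an n x h x w array")
}
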