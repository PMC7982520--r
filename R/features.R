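#' Stack epoch time series into a datapoint matrix
#'
#' Each (trial, channel) time series becomes one datapoint (row) for the
#' feature extractor, so an epoch set with `T` trials and `C` channels
#' yields a `T*C x samples` matrix. Rows are ordered trial-major: row
#' `(t-1)*C + c` holds trial `t`, channel `c` (montage order).
#'
#' @param epochs a non-empty [epoch_set].
#' @return a `datapoint_matrix`: list with `X` (the matrix) and
#'   `row_index`, a data.frame mapping row -> (trial, channel).
#' @export
build_datapoints <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[1] == 0) stop2("empty epoch_set")
  n <- d[1] * d[2]
  X <- matrix(0, n, d[3])
  row_index <- data.frame(row = seq_len(n),
                          trial = rep(seq_len(d[1]), each = d[2]),
                          channel = rep(seq_len(d[2]), times = d[1]))
  for (t in seq_len(d[1]))
    X[((t - 1) * d[2] + 1):(t * d[2]), ] <- matrix(epochs$data[t, , ],
                                                   nrow = d[2])
  structure(list(X = X, row_index = row_index,
                 n_trials = d[1], n_channels = d[2]),
            class = "datapoint_matrix")
}

#' @export
print.datapoint_matrix <- function(x, ...) {
  cat(sprintf("<datapoint_matrix> %d rows (%d trials x %d channels) x %d samples\n",
              nrow(x$X), x$n_trials, x$n_channels, ncol(x$X)))
  invisible(x)
}

#' Embed all (trial, channel) datapoints with t-SNE
#'
#' Runs the t-SNE extractor over the datapoint rows and returns one
#' low-dimensional feature vector per (trial, channel). Two modes:
#' `"transductive"` (default) embeds every row jointly in one t-SNE run —
#' the extractor is unsupervised, so labels never leak; `"inductive"`
#' embeds only the rows of training trials and places held-out rows with
#' the out-of-sample kernel map, for leakage-free generalization
#' measurement.
#'
#' @param X a `datapoint_matrix` from [build_datapoints()].
#' @param dims embedding dimensionality (default 5).
#' @param mode `"transductive"` or `"inductive"`.
#' @param train_trials for inductive mode, the trial indices whose rows
#'   may be used to fit the embedding.
#' @param kernel_bandwidth bandwidth of the out-of-sample map (inductive
#'   mode); default: median training-pair distance.
#' @param ... further arguments passed to [run_tsne()] (perplexity,
#'   iterations, seed, ...).
#' @return matrix of embedded coordinates, one row per datapoint row of
#'   `X`, with the `row_index` attached as attribute `"row_index"`.
#' @export
embed_trials <- function(X, dims = 5, mode = c("transductive", "inductive"),
                         train_trials = NULL, kernel_bandwidth = NULL, ...) {
  stopifnot(inherits(X, "datapoint_matrix"))
  mode <- match.arg(mode)
  if (mode == "transductive") {
    emb <- run_tsne(X$X, dims = dims, ...)
    Y <- emb$Y
  } else {
    if (is.null(train_trials))
      stop2("inductive mode needs `train_trials`")
    tr_rows <- which(X$row_index$trial %in% train_trials)
    if (length(tr_rows) == 0 || length(tr_rows) == nrow(X$X))
      stop2("`train_trials` must strictly partition the rows")
    emb <- run_tsne(X$X[tr_rows, , drop = FALSE], dims = dims, ...)
    Y <- matrix(0, nrow(X$X), dims)
    Y[tr_rows, ] <- emb$Y
    new_rows <- setdiff(seq_len(nrow(X$X)), tr_rows)
    if (is.null(kernel_bandwidth)) {
      D2 <- sq_dists(X$X[tr_rows, , drop = FALSE])
      kernel_bandwidth <- sqrt(stats::median(D2[upper.tri(D2)]))
      if (!is.finite(kernel_bandwidth) || kernel_bandwidth <= 0)
        kernel_bandwidth <- 1
    }
    Y[new_rows, ] <- out_of_sample_embed(X$X[tr_rows, , drop = FALSE],
                                         emb, X$X[new_rows, , drop = FALSE],
                                         kernel_bandwidth)
  }
  attr(Y, "row_index") <- X$row_index
  attr(Y, "embedding") <- emb
  Y
}

#' Kernel-weighted out-of-sample embedding
#'
#' t-SNE has no native parametric map, so held-out datapoints are placed
#' at the Gaussian-kernel-weighted average of the training embeddings,
#' with weights computed from high-dimensional distances:
#' `y_new = sum_i k(x_new, x_i) y_i / sum_i k(x_new, x_i)`,
#' `k(u, v) = exp(-||u - v||^2 / (2 bandwidth^2))`.
#'
#' @param train_X training datapoints (rows) the embedding was fitted on.
#' @param train_Y a `tsne_embedding` (or a plain coordinate matrix) whose
#'   rows correspond to `train_X`.
#' @param new_X datapoints to place.
#' @param kernel_bandwidth positive kernel bandwidth.
#' @return coordinates for the rows of `new_X`.
#' @export
out_of_sample_embed <- function(train_X, train_Y, new_X, kernel_bandwidth) {
  if (inherits(train_Y, "tsne_embedding")) train_Y <- train_Y$Y
  train_X <- as.matrix(train_X); new_X <- as.matrix(new_X)
  train_Y <- as.matrix(train_Y)
  if (nrow(train_X) != nrow(train_Y))
    stop2("train_X and train_Y row counts differ")
  if (!is.numeric(kernel_bandwidth) || kernel_bandwidth <= 0)
    stop2("kernel_bandwidth must be positive")
  r_tr <- rowSums(train_X^2)
  r_new <- rowSums(new_X^2)
  D2 <- outer(r_new, r_tr, "+") - 2 * new_X %*% t(train_X)
  D2[D2 < 0] <- 0
  # subtract the row minimum inside exp for numerical stability
  L <- -D2 / (2 * kernel_bandwidth^2)
  L <- L - apply(L, 1, max)
  K <- exp(L)
  (K / rowSums(K)) %*% train_Y
}

#' Assemble per-trial feature sequences for the recurrent classifier
#'
#' Orders the embedded 5-vectors into one sequence per trial. In the
#' default `channels_as_steps` orientation each trial becomes a sequence
#' of length `N_chan` (montage order) with the embedding coordinates as
#' the per-step features; `embedding_as_steps` transposes that.
#'
#' @param embedded matrix of embedded coordinates from [embed_trials()]
#'   (with its `row_index` attribute), or a plain matrix plus `row_index`.
#' @param epochs the [epoch_set] the datapoints came from (provides labels
#'   and channel order).
#' @param orientation `"channels_as_steps"` (default) or
#'   `"embedding_as_steps"`.
#' @param row_index optional explicit row -> (trial, channel) map.
#' @return a `feature_sequences` object: list with `sequences` (array
#'   trials x steps x features), `labels`, `orientation`.
#' @export
assemble_sequences <- function(embedded, epochs,
                               orientation = c("channels_as_steps",
                                               "embedding_as_steps"),
                               row_index = NULL) {
  orientation <- match.arg(orientation)
  row_index <- row_index %||% attr(embedded, "row_index")
  if (is.null(row_index)) stop2("no row_index available")
  d <- dim(epochs$data)
  emb <- as.matrix(embedded)
  if (nrow(emb) != d[1] * d[2])
    stop2("embedded rows (%d) do not cover %d trials x %d channels",
          nrow(emb), d[1], d[2])
  f <- ncol(emb)
  arr <- array(0, dim = c(d[1], d[2], f))
  for (r in seq_len(nrow(emb)))
    arr[row_index$trial[r], row_index$channel[r], ] <- emb[r, ]
  if (orientation == "embedding_as_steps")
    arr <- aperm(arr, c(1, 3, 2))
  structure(list(sequences = arr, labels = epochs$labels,
                 orientation = orientation,
                 channel_names = epochs$channel_names),
            class = "feature_sequences")
}

#' @export
print.feature_sequences <- function(x, ...) {
  d <- dim(x$sequences)
  cat(sprintf("<feature_sequences> %d trials, %d steps x %d features (%s)\n",
              d[1], d[2], d[3], x$orientation))
  invisible(x)
}

#' Scalp feature map
#'
#' Summarizes where on the scalp the extracted features carry signal, per
#' condition: for each channel, the embedding magnitudes (mean of the
#' absolute values of the 5 coordinates) are averaged over the
#' condition's trials and then normalized by the maximum over channels,
#' so the per-condition maximum is 1.
#'
#' @param embedded embedded coordinates from [embed_trials()] (with
#'   `row_index` attribute).
#' @param epochs the labeled [epoch_set].
#' @param row_index optional explicit row map.
#' @return a `scalp_map`: matrix channels x conditions of normalized
#'   feature values in `[0, 1]`.
#' @export
scalp_feature_map <- function(embedded, epochs, row_index = NULL) {
  if (is.null(epochs$labels)) stop2("scalp_feature_map needs labels")
  row_index <- row_index %||% attr(embedded, "row_index")
  if (is.null(row_index)) stop2("no row_index available")
  emb <- as.matrix(embedded)
  d <- dim(epochs$data)
  conds <- levels(epochs$labels)
  out <- matrix(NA_real_, nrow = d[2], ncol = length(conds),
                dimnames = list(epochs$channel_names, conds))
  mag <- rowMeans(abs(emb))    # mean |coordinate| per (trial, channel)
  for (ci in seq_along(conds)) {
    tr <- which(epochs$labels == conds[ci])
    if (length(tr) == 0) {
      warning(sprintf("condition '%s' has no trials; omitted", conds[ci]))
      next
    }
    per_ch <- vapply(seq_len(d[2]), function(ch) {
      rows <- row_index$row[row_index$trial %in% tr & row_index$channel == ch]
      mean(mag[rows])
    }, numeric(1))
    mx <- max(per_ch)
    out[, ci] <- if (mx > 0) per_ch / mx else per_ch
  }
  keep <- colSums(is.na(out)) < nrow(out)
  structure(out[, keep, drop = FALSE], class = "scalp_map")
}

#' @export
print.scalp_map <- function(x, ...) {
  cat("<scalp_map> normalized feature value per channel and condition\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' @export
plot.scalp_map <- function(x, ...) {
  m <- unclass(x)
  graphics::barplot(t(m), beside = TRUE, legend.text = colnames(m),
                    las = 2, ylab = "normalized feature value", ...)
  invisible(x)
}
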