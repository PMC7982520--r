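#' Build a cross-validation plan
#'
#' Produces `k` repeated random sub-sampling rounds (Monte-Carlo
#' cross-validation): each round draws a fresh `test_fraction` test set
#' and splits the remainder into training and validation at
#' `train_val_ratio`. This matches a design that reserves 20% for
#' testing in each of 10 validations with a 9:1 train/validation split —
#' arithmetic that disjoint 10-fold partitioning cannot satisfy.
#' Classical disjoint k-fold test sets are available via
#' `method = "kfold"`, and `scheme = "subject_holdout"` assigns whole
#' subjects to the test set.
#'
#' Rounding is deterministic: `test = floor(n * test_fraction)`,
#' `train = floor(remaining * ratio)`, remainder to validation. Test
#' draws are stratified by label when labels are supplied.
#'
#' @param n_trials number of trials (or an [epoch_set], from which
#'   labels/subjects are also taken).
#' @param scheme `"trial_holdout"` (default) or `"subject_holdout"`.
#' @param k number of rounds (default 10).
#' @param test_fraction fraction reserved for testing each round
#'   (default 0.2).
#' @param train_val_ratio length-2 ratio for the remainder (default
#'   `c(9, 1)`).
#' @param seed integer seed; identical seeds give identical plans.
#' @param labels optional per-trial labels for stratification.
#' @param subjects per-trial subject ids (required for subject_holdout).
#' @param method `"monte_carlo"` (default) or `"kfold"`.
#' @return a `cv_plan`: list of folds, each with `test`, `train`,
#'   `validation` index vectors partitioning `1..n`.
#' @export
make_splits <- function(n_trials, scheme = c("trial_holdout",
                                             "subject_holdout"),
                        k = 10, test_fraction = 0.2,
                        train_val_ratio = c(9, 1), seed = 1,
                        labels = NULL, subjects = NULL,
                        method = c("monte_carlo", "kfold")) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  if (inherits(n_trials, "epoch_set")) {
    labels <- labels %||% n_trials$labels
    subjects <- subjects %||% n_trials$subjects
    n_trials <- dim(n_trials$data)[1]
  }
  n <- n_trials
  r <- train_val_ratio[1] / sum(train_val_ratio)
  n_test <- floor(n * test_fraction)
  if (n_test < 1 || n - n_test < 2)
    stop2("n = %d too small for test_fraction %g", n, test_fraction)
  if (scheme == "subject_holdout" && is.null(subjects))
    stop2("subject_holdout needs per-trial subjects")
  folds <- with_seed(seed, {
    if (scheme == "subject_holdout") {
      subj <- unique(subjects)
      n_test_subj <- max(1, floor(length(subj) * test_fraction))
      lapply(seq_len(k), function(i) {
        ts <- sample(subj, n_test_subj)
        test <- which(subjects %in% ts)
        rest <- sample(setdiff(seq_len(n), test))
        n_tr <- floor(length(rest) * r)
        list(test = sort(test), train = sort(rest[seq_len(n_tr)]),
             validation = sort(rest[-seq_len(n_tr)]))
      })
    } else if (method == "kfold") {
      perm <- sample.int(n)
      bounds <- floor(seq(0, n, length.out = k + 1))
      lapply(seq_len(k), function(i) {
        test <- perm[(bounds[i] + 1):bounds[i + 1]]
        rest <- sample(setdiff(seq_len(n), test))
        n_tr <- floor(length(rest) * r)
        list(test = sort(test), train = sort(rest[seq_len(n_tr)]),
             validation = sort(rest[-seq_len(n_tr)]))
      })
    } else {
      lapply(seq_len(k), function(i) {
        test <- stratified_sample(n, n_test, labels)
        rest <- sample(setdiff(seq_len(n), test))
        n_tr <- floor(length(rest) * r)
        list(test = sort(test), train = sort(rest[seq_len(n_tr)]),
             validation = sort(rest[-seq_len(n_tr)]))
      })
    }
  })
  structure(list(folds = folds, n_trials = n, scheme = scheme, k = k,
                 test_fraction = test_fraction,
                 train_val_ratio = train_val_ratio, method = method,
                 stratified = !is.null(labels), seed = seed),
            class = "cv_plan")
}

# Draw `size` indices from 1..n, proportionally per label class with
# largest-remainder rounding so the total is exact.
stratified_sample <- function(n, size, labels) {
  if (is.null(labels)) return(sample.int(n, size))
  labels <- as.factor(labels)
  per <- table(labels) * size / n
  base <- floor(per)
  rem <- size - sum(base)
  if (rem > 0) {
    extra <- names(sort(per - base, decreasing = TRUE))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  unlist(lapply(levels(labels), function(l) {
    pool <- which(labels == l)
    sample(pool, min(base[[l]], length(pool)))
  }), use.names = FALSE)
}

#' @export
print.cv_plan <- function(x, ...) {
  f1 <- x$folds[[1]]
  cat(sprintf("<cv_plan> %d rounds of %s (%s), n = %d\n", x$k, x$scheme,
              x$method, x$n_trials))
  cat(sprintf("  per round: %d test / %d train / %d validation%s\n",
              length(f1$test), length(f1$train), length(f1$validation),
              if (x$stratified) " (stratified test draw)" else ""))
  invisible(x)
}

#' Restrict an epoch set to a montage
#'
#' Keeps only the montage's channels, reordered to the montage order
#' (which defines the recurrent classifier's step order). Everything
#' else is unchanged.
#'
#' @param epochs an [epoch_set].
#' @param montage a [montage] (or preset name) whose channels must all be
#'   present.
#' @return the restricted [epoch_set].
#' @export
select_channels <- function(epochs, montage) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.character(montage) && length(montage) == 1 &&
      !inherits(montage, "montage"))
    montage <- load_montage(montage)
  miss <- setdiff(as.character(montage), epochs$channel_names)
  if (length(miss) > 0)
    stop2("montage channel(s) missing from data: %s",
          paste(miss, collapse = ", "))
  idx <- match(as.character(montage), epochs$channel_names)
  epoch_set(epochs$data[, idx, , drop = FALSE], labels = epochs$labels,
            channel_names = epochs$channel_names[idx],
            sampling_rate = epochs$sampling_rate,
            epoch_window = epochs$epoch_window,
            subject_id = epochs$subject_id, subjects = epochs$subjects)
}

#' Specify a decoding pipeline
#'
#' A pipeline is a feature extractor plus a classifier, with the shared
#' training settings. `baseline_spec()` builds the named comparison
#' configurations.
#'
#' @param features one of `"tsne"`, `"pca"`, `"ica"`, `"raw"`, `"cwt"`.
#' @param classifier one of `"lstm"`, `"deep_lstm"`, `"svm"`, `"bp"`,
#'   `"cnn"`.
#' @param dims embedding/component count (default 5).
#' @param embed_mode `"transductive"` (one unsupervised embedding over
#'   all trials; default) or `"inductive"` (per-fold embedding of the
#'   train+validation rows, out-of-sample placement of test rows).
#' @param tsne list of [run_tsne()] settings used when
#'   `features = "tsne"`.
#' @param lstm_hidden LSTM hidden units (default 80).
#' @param dropout dropout rate after the LSTM (default 0.2).
#' @param deep_hidden front-end hidden units for `deep_lstm`
#'   (default 120).
#' @param raw_downsample sample-axis decimation for `features = "raw"`
#'   (default 10).
#' @param svm,bp,cnn method-specific settings lists.
#' @param train_cfg a [train_config()].
#' @param seed integer seed (feature extraction and training derive
#'   their streams from it).
#' @return a `pipeline_spec`.
#' @export
pipeline_spec <- function(features = c("tsne", "pca", "ica", "raw", "cwt"),
                          classifier = c("lstm", "deep_lstm", "svm", "bp",
                                         "cnn"),
                          dims = 5,
                          embed_mode = c("transductive", "inductive"),
                          tsne = list(), lstm_hidden = 80, dropout = 0.2,
                          deep_hidden = 120, raw_downsample = 10,
                          svm = list(), bp = list(), cnn = list(),
                          train_cfg = train_config(), seed = 1) {
  features <- match.arg(features)
  classifier <- match.arg(classifier)
  embed_mode <- match.arg(embed_mode)
  tsne <- modifyList(list(perplexity = 30, iterations = 300,
                          learning_rate = 100, exaggeration = 4,
                          exaggeration_iter = 50), tsne)
  svm <- modifyList(list(gamma = NULL, cost = 1), svm)
  bp <- modifyList(list(hidden = c(20, 10), output = "softmax2"), bp)
  cnn <- modifyList(list(n_filters = 20, kernel_size = 5,
                         n_scales = 32, time_downsample = 20), cnn)
  structure(list(features = features, classifier = classifier, dims = dims,
                 embed_mode = embed_mode, tsne = tsne,
                 lstm_hidden = lstm_hidden, dropout = dropout,
                 deep_hidden = deep_hidden, raw_downsample = raw_downsample,
                 svm = svm, bp = bp, cnn = cnn, train_cfg = train_cfg,
                 seed = as.integer(seed)),
            class = "pipeline_spec")
}

#' @param method a named comparison configuration: `"recurrent_tsne"`,
#'   `"recurrent_pca"`, `"recurrent_ica"`, `"deep_lstm"`, `"tsne_svm"`,
#'   `"tsne_bp"` or `"cwt_cnn"`.
#' @param ... overrides passed on to [pipeline_spec()].
#' @rdname pipeline_spec
#' @export
baseline_spec <- function(method = c("recurrent_tsne", "recurrent_pca",
                                     "recurrent_ica", "deep_lstm",
                                     "tsne_svm", "tsne_bp", "cwt_cnn"),
                          ...) {
  method <- match.arg(method)
  args <- switch(method,
    recurrent_tsne = list(features = "tsne", classifier = "lstm"),
    recurrent_pca = list(features = "pca", classifier = "lstm"),
    recurrent_ica = list(features = "ica", classifier = "lstm"),
    deep_lstm = list(features = "raw", classifier = "deep_lstm"),
    tsne_svm = list(features = "tsne", classifier = "svm"),
    tsne_bp = list(features = "tsne", classifier = "bp"),
    cwt_cnn = list(features = "cwt", classifier = "cnn"))
  spec <- do.call(pipeline_spec, modifyList(args, list(...)))
  spec$method <- method
  spec
}

#' @export
print.pipeline_spec <- function(x, ...) {
  cat(sprintf("<pipeline_spec> %s features -> %s classifier (dims %d, %s)\n",
              x$features, x$classifier, x$dims, x$embed_mode))
  invisible(x)
}

# ---- feature extraction shared by evaluate_pipeline / compare_methods ----

# Per-(trial, channel) feature matrix for sequence classifiers, or
# per-trial inputs for flat/image classifiers. Transductive: computed once
# on all trials.
extract_features <- function(spec, epochs) {
  dp <- build_datapoints(epochs)
  switch(spec$features,
    tsne = {
      emb <- run_tsne(dp$X, dims = spec$dims,
                      perplexity = spec$tsne$perplexity,
                      iterations = spec$tsne$iterations,
                      learning_rate = spec$tsne$learning_rate,
                      exaggeration = spec$tsne$exaggeration,
                      exaggeration_iter = spec$tsne$exaggeration_iter,
                      seed = derive_seed(spec$seed, "tsne"))
      Y <- emb$Y
      attr(Y, "row_index") <- dp$row_index
      Y
    },
    pca = {
      Y <- pca_features(dp, k = spec$dims)
      attr(Y, "row_index") <- dp$row_index
      Y
    },
    ica = {
      Y <- ica_features(dp, k = spec$dims,
                        seed = derive_seed(spec$seed, "ica"))
      attr(Y, "row_index") <- dp$row_index
      Y
    },
    raw = NULL,   # handled directly from epochs
    cwt = NULL)
}

# key used to share feature computations between methods on the same data
feature_key <- function(spec) {
  paste(spec$features, spec$dims, spec$embed_mode,
        paste(unlist(spec$tsne), collapse = ","), spec$seed, sep = "|")
}

# n x steps x features raw sequences (channels as steps, decimated samples
# as features) for the deep LSTM front-end.
raw_sequences <- function(epochs, downsample) {
  d <- dim(epochs$data)
  keep <- seq(1, d[3], by = downsample)
  arr <- epochs$data[, , keep, drop = FALSE]
  structure(list(sequences = arr, labels = epochs$labels,
                 orientation = "channels_as_steps",
                 channel_names = epochs$channel_names),
            class = "feature_sequences")
}

cwt_images <- function(epochs, cnn_opts) {
  d <- dim(epochs$data)
  lapply(seq_len(d[1]), function(t)
    unclass(cwt_image(matrix(epochs$data[t, , ], d[2], d[3]),
                      sampling_rate = epochs$sampling_rate,
                      n_scales = cnn_opts$n_scales,
                      time_downsample = cnn_opts$time_downsample)))
}

# mean embedding over channels -> one dims-vector per trial (flat input
# for svm/bp, the "five-dimensional data" those methods classify)
trial_mean_features <- function(feat, n_trials, n_channels) {
  ri <- attr(feat, "row_index")
  out <- matrix(0, n_trials, ncol(feat))
  for (t in seq_len(n_trials))
    out[t, ] <- colMeans(feat[ri$row[ri$trial == t], , drop = FALSE])
  out
}

# ---- fold evaluation ----

run_fold <- function(spec, epochs, feat, fold, fold_seed) {
  labs <- epochs$labels
  train <- fold$train; val <- fold$validation; test <- fold$test
  if (length(unique(labs[train])) < 2)
    return(NULL)
  tc <- spec$train_cfg
  tc$seed <- fold_seed
  if (spec$classifier %in% c("lstm", "deep_lstm")) {
    if (spec$classifier == "deep_lstm") {
      seqs <- raw_sequences(epochs, spec$raw_downsample)
      cfg <- network_config(
        layer_lstm(spec$deep_hidden, "sequence_to_sequence"),
        layer_dropout(spec$dropout),
        layer_lstm(spec$lstm_hidden, "sequence_to_label"),
        layer_dropout(spec$dropout),
        layer_dense(2))
    } else {
      seqs <- assemble_sequences(feat, epochs)
      cfg <- network_config(layer_lstm(spec$lstm_hidden, "sequence_to_label"),
                            layer_dropout(spec$dropout),
                            layer_dense(2))
    }
    take <- function(idx) seqs$sequences[idx, , , drop = FALSE]
    fit <- lstm_train(cfg, take(train), labels = labs[train],
                      train_cfg = tc, validation = take(val),
                      validation_labels = labs[val])
    val_acc <- utils::tail(fit$history$val_acc[!is.na(fit$history$val_acc)], 1)
    pred <- predict(fit, take(test))$labels
    list(val_acc = val_acc, test_acc = mean(pred == labs[test]),
         history = fit$history)
  } else if (spec$classifier %in% c("svm", "bp")) {
    d <- dim(epochs$data)
    flat <- trial_mean_features(feat, d[1], d[2])
    if (spec$classifier == "svm") {
      valp <- svm_rbf(flat[train, , drop = FALSE], labs[train],
                      flat[val, , drop = FALSE], gamma = spec$svm$gamma,
                      cost = spec$svm$cost)
      testp <- svm_rbf(flat[train, , drop = FALSE], labs[train],
                       flat[test, , drop = FALSE], gamma = spec$svm$gamma,
                       cost = spec$svm$cost)
      list(val_acc = mean(valp == labs[val]),
           test_acc = mean(testp == labs[test]), history = NULL)
    } else {
      res_v <- bp_classifier(flat[train, , drop = FALSE], labs[train],
                             flat[val, , drop = FALSE],
                             hidden = spec$bp$hidden,
                             output = spec$bp$output, train_cfg = tc)
      res_t <- bp_classifier(flat[train, , drop = FALSE], labs[train],
                             flat[test, , drop = FALSE],
                             hidden = spec$bp$hidden,
                             output = spec$bp$output, train_cfg = tc)
      list(val_acc = mean(res_v$labels == labs[val]),
           test_acc = mean(res_t$labels == labs[test]), history = NULL)
    }
  } else {   # cnn
    imgs <- feat   # precomputed list of images
    res_v <- cnn_classifier(imgs[train], labs[train], imgs[val],
                            train_cfg = tc, n_filters = spec$cnn$n_filters,
                            kernel_size = spec$cnn$kernel_size)
    res_t <- cnn_classifier(imgs[train], labs[train], imgs[test],
                            train_cfg = tc, n_filters = spec$cnn$n_filters,
                            kernel_size = spec$cnn$kernel_size)
    list(val_acc = mean(res_v$labels == labs[val]),
         test_acc = mean(res_t$labels == labs[test]), history = NULL)
  }
}

#' Evaluate a decoding pipeline under a cross-validation plan
#'
#' Per fold: feature extraction (shared transductively across folds when
#' the extractor is unsupervised; per-fold with out-of-sample placement
#' in inductive mode), classifier training on the training split with
#' monitoring on the validation split, and scoring on the test split.
#' Folds whose training split loses a class (e.g., after artifact
#' rejection) are flagged invalid and excluded with a warning.
#'
#' @param spec a [pipeline_spec()] or [baseline_spec()].
#' @param epochs a labeled [epoch_set] (already preprocessed; see
#'   [preprocess_epochs()]).
#' @param plan a [make_splits()] plan consistent with `epochs`.
#' @param features optional precomputed feature matrix (with
#'   `row_index`), to share one embedding across several pipelines.
#' @return a `fold_report`: list with `folds` (data.frame: fold,
#'   val_acc, test_acc), `mean_val`, `sd_val` (population SD over the
#'   valid folds), `mean_test`, `spec`.
#' @export
evaluate_pipeline <- function(spec, epochs, plan, features = NULL) {
  stopifnot(inherits(spec, "pipeline_spec"), inherits(plan, "cv_plan"))
  if (is.null(epochs$labels)) stop2("labeled epochs required")
  if (plan$n_trials != dim(epochs$data)[1])
    stop2("plan was built for n = %d but epochs have %d trials",
          plan$n_trials, dim(epochs$data)[1])
  feat <- features
  if (is.null(feat)) {
    if (spec$features == "cwt") feat <- cwt_images(epochs, spec$cnn)
    else if (!(spec$features == "tsne" && spec$embed_mode == "inductive"))
      feat <- extract_features(spec, epochs)
  }
  rows <- vector("list", plan$k)
  for (i in seq_len(plan$k)) {
    fold <- plan$folds[[i]]
    fi <- feat
    if (spec$embed_mode == "inductive" && spec$features == "tsne") {
      dp <- build_datapoints(epochs)
      fi <- embed_trials(dp, dims = spec$dims, mode = "inductive",
                         train_trials = sort(c(fold$train, fold$validation)),
                         perplexity = spec$tsne$perplexity,
                         iterations = spec$tsne$iterations,
                         learning_rate = spec$tsne$learning_rate,
                         exaggeration = spec$tsne$exaggeration,
                         exaggeration_iter = spec$tsne$exaggeration_iter,
                         seed = derive_seed(spec$seed, paste0("tsne", i)))
    }
    res <- run_fold(spec, epochs, fi, fold,
                    fold_seed = derive_seed(spec$seed, paste0("fold", i)))
    if (is.null(res)) {
      warning(sprintf("fold %d invalid (single-class training split); excluded", i))
      next
    }
    rows[[i]] <- data.frame(fold = i, val_acc = res$val_acc,
                            test_acc = res$test_acc)
  }
  folds <- do.call(rbind, rows)
  if (is.null(folds) || nrow(folds) == 0)
    stop2("no valid folds")
  structure(list(folds = folds,
                 mean_val = mean(folds$val_acc),
                 sd_val = sqrt(mean((folds$val_acc - mean(folds$val_acc))^2)),
                 mean_test = mean(folds$test_acc),
                 spec = spec),
            class = "fold_report")
}

#' @export
print.fold_report <- function(x, ...) {
  cat(sprintf("<fold_report> %d folds: validation %.3f +/- %.3f, test %.3f\n",
              nrow(x$folds), x$mean_val, x$sd_val, x$mean_test))
  invisible(x)
}

#' Compare decoding methods on identical folds
#'
#' Evaluates every pipeline on the same cross-validation plan (paired
#' comparison) and tabulates mean validation accuracy, its population
#' standard deviation and mean test accuracy, sorted by mean validation
#' accuracy. Feature extraction is shared between methods with an
#' identical extractor signature. A method failing on every fold is
#' reported as failed; the others are unaffected.
#'
#' @param specs list of [pipeline_spec()]/[baseline_spec()] objects,
#'   optionally named.
#' @param epochs a labeled [epoch_set].
#' @param plan a [make_splits()] plan.
#' @return a `comparison_report` data.frame.
#' @export
compare_methods <- function(specs, epochs, plan) {
  if (inherits(specs, "pipeline_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1)
  nms <- names(specs) %||% rep("", length(specs))
  cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_along(specs), function(i) {
    spec <- specs[[i]]
    nm <- if (nzchar(nms[i])) nms[i] else spec$method %||%
      paste(spec$features, spec$classifier, sep = "_")
    feat <- NULL
    if (!(spec$features == "tsne" && spec$embed_mode == "inductive")) {
      key <- feature_key(spec)
      if (!exists(key, envir = cache, inherits = FALSE)) {
        val <- if (spec$features == "cwt") cwt_images(epochs, spec$cnn)
          else extract_features(spec, epochs)
        # NULL result (raw features) cached as a sentinel
        assign(key, val %||% structure(list(), class = "raw_sentinel"),
               envir = cache)
      }
      feat <- get(key, envir = cache)
      if (inherits(feat, "raw_sentinel")) feat <- NULL
    }
    rep_ <- tryCatch(evaluate_pipeline(spec, epochs, plan, features = feat),
                     error = function(e) e)
    if (inherits(rep_, "error"))
      data.frame(method = nm, mean_val = NA_real_, sd_val = NA_real_,
                 mean_test = NA_real_, status = conditionMessage(rep_))
    else
      data.frame(method = nm, mean_val = rep_$mean_val, sd_val = rep_$sd_val,
                 mean_test = rep_$mean_test, status = "ok")
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_val, na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Method comparison (sorted by mean validation accuracy)\n")
  df <- as.data.frame(x)
  df$mean_val <- sprintf("%.3f", df$mean_val)
  df$sd_val <- sprintf("%.3f", df$sd_val)
  df$mean_test <- sprintf("%.3f", df$mean_test)
  print(df, row.names = FALSE)
  invisible(x)
}
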