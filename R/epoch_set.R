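#' Construct an epoched EEG data set
#'
#' An `epoch_set` is the package's central container: a 3-axis array of
#' single-trial EEG (trial x channel x sample, in microvolts) together with
#' per-trial behavioral labels, channel names, the sampling rate and the
#' epoch window relative to stimulus onset.
#'
#' @param data numeric array, trials x channels x samples, in microvolts.
#' @param labels optional per-trial label, coerced to a factor with levels
#'   `c("accept", "reject")` when those values are used; `NULL` for
#'   unlabeled data.
#' @param channel_names character vector naming the channel axis
#'   (10-20/10-10 electrode labels); must be unique.
#' @param sampling_rate sampling frequency in Hz.
#' @param epoch_window length-2 numeric, `(start_ms, end_ms)` relative to
#'   stimulus onset. The sample count must equal
#'   `round((end_ms - start_ms)/1000 * sampling_rate)`.
#' @param subject_id opaque subject identifier (single string).
#' @param subjects optional per-trial subject identifier, used by
#'   subject-level cross-validation on pooled data.
#'
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels = NULL, channel_names = NULL,
                      sampling_rate = 1000, epoch_window = c(-200, 800),
                      subject_id = "S01", subjects = NULL) {
  if (length(dim(data)) != 3)
    stop2("`data` must be a 3-axis array (trial x channel x sample)")
  n_tr <- dim(data)[1]; n_ch <- dim(data)[2]; n_sa <- dim(data)[3]
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(n_ch))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != n_ch)
    stop2("channel_names length (%d) does not match channel axis (%d)",
          length(channel_names), n_ch)
  if (anyDuplicated(channel_names))
    stop2("duplicate channel names: %s",
          paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (length(epoch_window) != 2 || epoch_window[2] <= epoch_window[1])
    stop2("epoch_window must be (start_ms, end_ms) with end > start")
  expected <- round(diff(epoch_window) / 1000 * sampling_rate)
  if (n_sa != expected)
    stop2("sample count %d inconsistent with window/rate (expected %d)",
          n_sa, expected)
  if (!is.null(labels)) {
    if (length(labels) != n_tr)
      stop2("labels length (%d) does not match trial count (%d)",
            length(labels), n_tr)
    labels <- as_decision_labels(labels)
  }
  if (!is.null(subjects) && length(subjects) != n_tr)
    stop2("subjects length must match trial count")
  structure(list(
    data = data, labels = labels, channel_names = channel_names,
    sampling_rate = sampling_rate, epoch_window = as.numeric(epoch_window),
    subject_id = as.character(subject_id),
    subjects = if (is.null(subjects)) NULL else as.character(subjects)
  ), class = "epoch_set")
}

as_decision_labels <- function(labels) {
  lab <- as.character(labels)
  bad <- setdiff(unique(lab), c("accept", "reject"))
  if (length(bad) > 0)
    stop2("unknown label value(s): %s (expected 'accept'/'reject')",
          paste(bad, collapse = ", "))
  factor(lab, levels = c("accept", "reject"))
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples\n",
              d[1], d[2], d[3]))
  cat(sprintf("  window %g..%g ms @ %g Hz, subject %s\n",
              x$epoch_window[1], x$epoch_window[2], x$sampling_rate,
              x$subject_id))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  } else cat("  unlabeled\n")
  invisible(x)
}

#' Number of trials, channels and samples of an epoch set
#' @param epochs an `epoch_set`.
#' @return integer vector `c(trials, channels, samples)`.
#' @export
epoch_dim <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  dim(epochs$data)
}

#' Time axis of an epoch set in milliseconds
#' @param epochs an `epoch_set`.
#' @return numeric vector of sample times (ms relative to stimulus onset),
#'   one per sample, at the left edge of each sampling interval.
#' @export
epoch_times <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- dim(epochs$data)[3]
  epochs$epoch_window[1] + (seq_len(n) - 1) * 1000 / epochs$sampling_rate
}

# Subset trials, keeping metadata aligned.
subset_trials <- function(epochs, idx) {
  stopifnot(inherits(epochs, "epoch_set"))
  epoch_set(epochs$data[idx, , , drop = FALSE],
            labels = if (is.null(epochs$labels)) NULL else epochs$labels[idx],
            channel_names = epochs$channel_names,
            sampling_rate = epochs$sampling_rate,
            epoch_window = epochs$epoch_window,
            subject_id = epochs$subject_id,
            subjects = if (is.null(epochs$subjects)) NULL else epochs$subjects[idx])
}
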