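#' Regress ocular activity out of the EEG channels
#'
#' Removes electrooculogram (EOG) contamination by per-trial ordinary least
#' squares: for every EEG channel, the projection of its time series onto
#' the span of the EOG channel time series (within the same trial) is
#' subtracted. The EOG channels are removed from the output. This is a
#' generic linear regression correction in the same family as the
#' vendor-software regression procedures used in ERP practice.
#'
#' @param epochs an [epoch_set] whose montage includes the EOG channels.
#' @param eog_channels character vector of EOG channel names.
#' @return an [epoch_set] without the EOG channels, residualized.
#' @export
correct_eog <- function(epochs, eog_channels) {
  stopifnot(inherits(epochs, "epoch_set"))
  miss <- setdiff(eog_channels, epochs$channel_names)
  if (length(miss) > 0)
    stop2("EOG channel(s) not present: %s", paste(miss, collapse = ", "))
  eog_idx <- match(eog_channels, epochs$channel_names)
  eeg_idx <- setdiff(seq_along(epochs$channel_names), eog_idx)
  d <- dim(epochs$data)
  out <- array(0, dim = c(d[1], length(eeg_idx), d[3]))
  for (t in seq_len(d[1])) {
    G <- t(matrix(epochs$data[t, eog_idx, , drop = FALSE],
                  nrow = length(eog_idx)))          # samples x n_eog
    E <- t(matrix(epochs$data[t, eeg_idx, , drop = FALSE],
                  nrow = length(eeg_idx)))          # samples x n_eeg
    beta <- qr.coef(qr(G), E)                       # least-squares fit
    beta[is.na(beta)] <- 0                          # rank-deficient EOG
    out[t, , ] <- t(E - G %*% beta)
  }
  epoch_set(out, labels = epochs$labels,
            channel_names = epochs$channel_names[eeg_idx],
            sampling_rate = epochs$sampling_rate,
            epoch_window = epochs$epoch_window,
            subject_id = epochs$subject_id, subjects = epochs$subjects)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the
#' pre-stimulus baseline window from every sample. Idempotent.
#'
#' @param epochs an [epoch_set].
#' @param baseline_window_ms `(start_ms, end_ms)` window, which must lie
#'   inside the epoch window; default is the full pre-stimulus period.
#' @return a baseline-corrected [epoch_set].
#' @export
baseline_correct <- function(epochs, baseline_window_ms = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(baseline_window_ms))
    baseline_window_ms <- c(epochs$epoch_window[1], 0)
  w <- baseline_window_ms
  if (w[1] < epochs$epoch_window[1] || w[2] > epochs$epoch_window[2] ||
      w[2] <= w[1])
    stop2("baseline window [%g, %g] not inside epoch window [%g, %g]",
          w[1], w[2], epochs$epoch_window[1], epochs$epoch_window[2])
  tms <- epoch_times(epochs)
  sel <- which(tms >= w[1] & tms < w[2])
  if (length(sel) == 0) stop2("baseline window contains no samples")
  out <- epochs
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  out$data <- epochs$data - array(base, dim = dim(epochs$data))
  out
}

#' Zero-phase low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and backward over the
#' sample axis so that the net result has zero phase shift (no latency
#' distortion of ERP components). The default is a 2nd-order design run
#' forward-backward, whose combined magnitude response rolls off at
#' 24 dB/octave. Epoch edges are protected by odd-reflection padding.
#'
#' @param epochs an [epoch_set].
#' @param cutoff_hz -3 dB cutoff per pass (default 30 Hz).
#' @param order filter order of the single-pass design; the effective
#'   roll-off of the zero-phase result is `12 * order` dB/octave.
#' @return a filtered [epoch_set].
#' @export
lowpass_filter <- function(epochs, cutoff_hz = 30, order = 2) {
  stopifnot(inherits(epochs, "epoch_set"))
  nyq <- epochs$sampling_rate / 2
  if (cutoff_hz >= nyq)
    stop2("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff_hz, nyq)
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  out <- epochs
  d <- dim(epochs$data)
  for (t in seq_len(d[1]))
    for (c in seq_len(d[2]))
      out$data[t, c, ] <- filtfilt_padded(bf$b, bf$a, epochs$data[t, c, ])
  out
}

# Forward-backward filtering with odd-reflection padding at both ends
# (standard zero-phase practice; suppresses edge transients). The pad is
# long enough for the start-up transient of a low-order IIR filter to decay
# below double precision before the retained segment begins.
filtfilt_padded <- function(b, a, x) {
  n <- length(x)
  padlen <- min(300, n - 1)
  pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  xp <- c(pre, x, post)
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(padlen + 1):(padlen + n)]
}

#' Reject trials exceeding an amplitude criterion
#'
#' A trial is rejected when its peak-to-peak deflection exceeds the
#' `+/- threshold_uv` amplitude window on any channel. Two readings of the
#' criterion are offered: `"window"` (default) rejects a trial if any
#' sample on any channel falls outside `[-threshold, +threshold]`;
#' `"range"` rejects if any channel's `max - min` exceeds `threshold`.
#' Surviving trials keep their original relative order; sample values are
#' never altered.
#'
#' @param epochs an [epoch_set].
#' @param threshold_uv amplitude criterion in microvolts (default 80).
#' @param mode `"window"` or `"range"`; see above.
#' @return a list with elements `epochs` (the retained trials) and
#'   `report`, a `rejection_report` with `kept_indices`, a `rejected`
#'   data.frame (trial, reason) and `per_condition_counts`.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 80,
                             mode = c("window", "range")) {
  stopifnot(inherits(epochs, "epoch_set"), threshold_uv > 0)
  mode <- match.arg(mode)
  d <- dim(epochs$data)
  bad <- vapply(seq_len(d[1]), function(t) {
    m <- matrix(epochs$data[t, , ], nrow = d[2])
    if (mode == "window") any(abs(m) > threshold_uv)
    else any(apply(m, 1, function(r) max(r) - min(r)) > threshold_uv)
  }, logical(1))
  kept <- which(!bad)
  report <- structure(list(
    kept_indices = kept,
    rejected = data.frame(trial = which(bad),
                          reason = rep("amplitude", sum(bad)),
                          stringsAsFactors = FALSE),
    per_condition_counts = if (is.null(epochs$labels)) NULL
      else table(epochs$labels[kept]),
    threshold_uv = threshold_uv, mode = mode
  ), class = "rejection_report")
  list(epochs = subset_trials(epochs, kept), report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report> kept %d, rejected %d (threshold %g uV, %s)\n",
              length(x$kept_indices), nrow(x$rejected), x$threshold_uv, x$mode))
  invisible(x)
}

#' Retain conditions with enough clean sweeps
#'
#' A condition (label class, per subject when per-trial subjects are
#' recorded) is retained only when strictly more than `min_sweeps` of its
#' trials survived earlier cleaning; otherwise all its trials are dropped.
#'
#' @param epochs a labeled [epoch_set].
#' @param min_sweeps retention threshold (default 30; strict `>`).
#' @return an [epoch_set] containing only the retained conditions.
#' @export
enforce_min_sweeps <- function(epochs, min_sweeps = 30) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(epochs$labels))
    stop2("enforce_min_sweeps needs a labeled epoch_set")
  grp <- as.character(epochs$labels)
  if (!is.null(epochs$subjects))
    grp <- paste(epochs$subjects, grp, sep = "\r")
  counts <- table(grp)
  keep_groups <- names(counts)[counts > min_sweeps]
  subset_trials(epochs, which(grp %in% keep_groups))
}

#' Standard preprocessing chain
#'
#' Runs the fixed recording-analysis sequence: EOG regression (when EOG
#' channels are given), baseline correction, zero-phase low-pass
#' filtering, amplitude rejection and sweep-count gating (when labels are
#' present).
#'
#' @param epochs an [epoch_set].
#' @param eog_channels optional EOG channel names.
#' @param baseline_window_ms baseline window (default: pre-stimulus part).
#' @param cutoff_hz low-pass cutoff (default 30 Hz).
#' @param threshold_uv rejection criterion (default 80 microvolts).
#' @param min_sweeps sweep-count gate (default 30); `NULL` to skip.
#' @return list with `epochs` (clean set) and `report` (rejection report).
#' @export
preprocess_epochs <- function(epochs, eog_channels = NULL,
                              baseline_window_ms = NULL, cutoff_hz = 30,
                              threshold_uv = 80, min_sweeps = 30) {
  if (!is.null(eog_channels))
    epochs <- correct_eog(epochs, eog_channels)
  epochs <- baseline_correct(epochs, baseline_window_ms)
  epochs <- lowpass_filter(epochs, cutoff_hz)
  rej <- reject_artifacts(epochs, threshold_uv)
  out <- rej$epochs
  if (!is.null(min_sweeps) && !is.null(out$labels))
    out <- enforce_min_sweeps(out, min_sweeps)
  list(epochs = out, report = rej$report)
}
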