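#' Configuration for the synthetic two-condition ERP generator
#'
#' Describes a two-class single-trial EEG experiment: every trial is
#' background activity (1/f-shaped noise + a 10 Hz oscillation with
#' random phase + broadband white noise), and trials of the "accept"
#' condition additionally carry a late positive deflection — a
#' Gaussian-windowed bump centered at `latency_ms` with full width at
#' half maximum `width_ms`, scaled per channel by `topography`. Ocular-
#' like artifacts (slow large-amplitude frontal deflections) are injected
#' with probability `artifact_rate` per trial.
#'
#' Default channel names follow the built-in montage presets so that
#' channel-subset experiments work out of the box; the default topography
#' places the effect on eight centro-parietal channels (weight 1 on Cz
#' and Pz, 0.8 on C3/C4/P3/P4, 0.5 on Fz/Oz), the effect family the
#' decision-ERP literature implicates. Defaults make no claim of
#' biological fidelity and every field is configurable.
#'
#' @param n_trials_per_class trials per condition (default 400).
#' @param n_channels channel count (default 16; names from the smallest
#'   montage preset that covers it).
#' @param sampling_rate Hz (default 1000).
#' @param epoch_window ms relative to stimulus onset (default
#'   `c(-200, 800)`).
#' @param amplitude_uv peak amplitude of the class effect (default 8).
#' @param latency_ms center of the effect (default 500).
#' @param width_ms full width at half maximum (default 200; the Gaussian
#'   sd is `width_ms / 2.355`).
#' @param topography per-channel effect weights (length `n_channels`).
#' @param one_over_f_scale RMS amplitude of the 1/f background, microvolts
#'   (default 3).
#' @param white_scale_uv white-noise sd, microvolts (default 1).
#' @param alpha_amplitude_uv amplitude of the 10 Hz oscillation (default
#'   1.5).
#' @param artifact_rate per-trial artifact probability (default 0.05).
#' @param artifact_amplitude_uv artifact peak amplitude (default 120,
#'   above the standard rejection window).
#' @param seed integer seed.
#' @return a `synth_config`.
#' @export
synth_config <- function(n_trials_per_class = 400, n_channels = 16,
                         sampling_rate = 1000, epoch_window = c(-200, 800),
                         amplitude_uv = 8, latency_ms = 500, width_ms = 200,
                         topography = NULL, one_over_f_scale = 3,
                         white_scale_uv = 1, alpha_amplitude_uv = 1.5,
                         artifact_rate = 0.05, artifact_amplitude_uv = 120,
                         seed = 1) {
  stopifnot(artifact_rate >= 0, artifact_rate <= 1,
            one_over_f_scale >= 0, white_scale_uv >= 0,
            alpha_amplitude_uv >= 0, width_ms > 0)
  channel_names <- default_channels(n_channels)
  if (is.null(topography))
    topography <- default_topography(channel_names)
  if (length(topography) != n_channels)
    stop2("topography length (%d) must equal n_channels (%d)",
          length(topography), n_channels)
  structure(list(n_trials_per_class = n_trials_per_class,
                 n_channels = n_channels, channel_names = channel_names,
                 sampling_rate = sampling_rate, epoch_window = epoch_window,
                 amplitude_uv = amplitude_uv, latency_ms = latency_ms,
                 width_ms = width_ms, topography = topography,
                 one_over_f_scale = one_over_f_scale,
                 white_scale_uv = white_scale_uv,
                 alpha_amplitude_uv = alpha_amplitude_uv,
                 artifact_rate = artifact_rate,
                 artifact_amplitude_uv = artifact_amplitude_uv,
                 seed = as.integer(seed)),
            class = "synth_config")
}

default_channels <- function(n) {
  pool <- .montage_presets$active60
  if (n <= length(pool)) pool[seq_len(n)]
  else c(pool, paste0("X", seq_len(n - length(pool))))
}

default_topography <- function(channel_names) {
  w <- numeric(length(channel_names))
  names(w) <- channel_names
  assign_w <- function(chs, val) {
    hit <- intersect(chs, channel_names)
    w[hit] <<- val
  }
  assign_w(c("Cz", "Pz"), 1)
  assign_w(c("C3", "C4", "P3", "P4"), 0.8)
  assign_w(c("Fz", "Oz"), 0.5)
  if (all(w == 0)) w[seq_len(min(8, length(w)))] <- 1
  unname(w)
}

#' Generate synthetic two-condition ERP epochs
#'
#' @param config a [synth_config()].
#' @return list with `epochs` (a labeled [epoch_set]) and `truth`, a
#'   `ground_truth` data.frame with per-trial class, artifact flag and
#'   realized component amplitude. Byte-identical output for a fixed
#'   seed.
#' @examples
#' g <- generate_epochs(synth_config(n_trials_per_class = 5,
#'                                   n_channels = 4, seed = 7))
#' g$epochs
#' @export
generate_epochs <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate
  n_sa <- round(diff(config$epoch_window) / 1000 * fs)
  n_ch <- config$n_channels
  n_per <- config$n_trials_per_class
  n_tr <- 2 * n_per
  tms <- config$epoch_window[1] + (seq_len(n_sa) - 1) * 1000 / fs
  sd_ms <- config$width_ms / 2.355
  bump <- config$amplitude_uv *
    exp(-(tms - config$latency_ms)^2 / (2 * sd_ms^2))
  labels <- rep(c("accept", "reject"), each = n_per)
  frontal <- which(config$channel_names %in%
                     c("Fp1", "Fp2", "Fz", "F7", "F8", "AF7", "AF8"))
  if (length(frontal) == 0) frontal <- seq_len(min(2, n_ch))
  data <- array(0, dim = c(n_tr, n_ch, n_sa))
  with_seed(config$seed, {
    artifact <- runif(n_tr) < config$artifact_rate
    slow <- sin(2 * pi * 1.5 * (tms - tms[1]) / 1000)  # ~1.5 Hz sway
    for (t in seq_len(n_tr)) {
      for (c in seq_len(n_ch)) {
        x <- one_over_f_noise(n_sa, config$one_over_f_scale)
        x <- x + config$alpha_amplitude_uv *
          sin(2 * pi * 10 * (tms - tms[1]) / 1000 + runif(1, 0, 2 * pi))
        x <- x + rnorm(n_sa, sd = config$white_scale_uv)
        if (labels[t] == "accept")
          x <- x + config$topography[c] * bump
        data[t, c, ] <- x
      }
      if (artifact[t]) {
        sgn <- sample(c(-1, 1), 1)
        for (c in frontal)
          data[t, c, ] <- data[t, c, ] +
            sgn * config$artifact_amplitude_uv * slow
      }
    }
  })
  truth <- structure(data.frame(
    trial = seq_len(n_tr), class = labels, artifact = artifact,
    amplitude = ifelse(labels == "accept", config$amplitude_uv, 0)
  ), class = c("ground_truth", "data.frame"))
  attr(truth, "config") <- config
  list(epochs = epoch_set(data, labels = labels,
                          channel_names = config$channel_names,
                          sampling_rate = fs,
                          epoch_window = config$epoch_window,
                          subject_id = "synthetic"),
       truth = truth)
}

# 1/f-shaped noise: white Gaussian spectrum shaped by 1/sqrt(f) amplitude
# (power ~ 1/f), DC bin zeroed, scaled to the requested RMS.
one_over_f_noise <- function(n, rms) {
  if (rms == 0) return(numeric(n))
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))                # avoid division by zero at DC
  shaped <- W / sqrt(f)
  shaped[1] <- 0
  x <- Re(fft(shaped, inverse = TRUE) / n)
  x * rms / sqrt(mean(x^2))
}

#' Summarize generated epochs against their ground truth
#'
#' @param epochs the generated [epoch_set].
#' @param truth the matching `ground_truth`.
#' @return data.frame with one row per class: trial count, empirical mean
#'   amplitude at the component latency on the strongest-topography
#'   channel, and artifact count. Empty input yields an empty table.
#' @export
summarize_truth <- function(epochs, truth) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (nrow(truth) != dim(epochs$data)[1])
    stop2("truth (%d rows) misaligned with epochs (%d trials)",
          nrow(truth), dim(epochs$data)[1])
  if (nrow(truth) == 0)
    return(data.frame(class = character(), n = integer(),
                      mean_peak_uv = numeric(), artifacts = integer()))
  cfg <- attr(truth, "config")
  tms <- epoch_times(epochs)
  peak_sample <- which.min(abs(tms - (cfg$latency_ms %||% 500)))
  peak_channel <- which.max(cfg$topography %||%
                              rep(1, dim(epochs$data)[2]))
  out <- do.call(rbind, lapply(split(truth, truth$class), function(tt) {
    data.frame(class = tt$class[1], n = nrow(tt),
               mean_peak_uv = mean(epochs$data[tt$trial, peak_channel,
                                               peak_sample]),
               artifacts = sum(tt$artifact))
  }))
  rownames(out) <- NULL
  out
}
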