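test_that("EOG regression removes collinear activity and spares orthogonal EEG", {
  n_sa <- 200
  eog <- sin(seq_len(n_sa) / 5)
  # EEG = 2 * EOG exactly -> residual is zero
  d <- array(0, dim = c(1, 2, n_sa))
  d[1, 1, ] <- 2 * eog
  d[1, 2, ] <- eog
  ep <- epoch_set(d, channel_names = c("Cz", "VEOG"),
                  sampling_rate = 1000, epoch_window = c(0, n_sa))
  out <- correct_eog(ep, "VEOG")
  expect_equal(out$channel_names, "Cz")
  expect_lt(max(abs(out$data)), 1e-10)

  # orthogonal EEG is untouched
  eeg <- cos(seq_len(n_sa) / 5)
  eeg <- eeg - eog * sum(eeg * eog) / sum(eog^2)
  d[1, 1, ] <- eeg
  ep2 <- epoch_set(d, channel_names = c("Cz", "VEOG"),
                   sampling_rate = 1000, epoch_window = c(0, n_sa))
  out2 <- correct_eog(ep2, "VEOG")
  expect_equal(out2$data[1, 1, ], eeg, tolerance = 1e-10)

  expect_error(correct_eog(ep, "HEOG"), "not present")
})

test_that("EOG residuals are uncorrelated with the regressors", {
  ep <- toy_epochs(n_trials = 3, n_channels = 4, n_samples = 300)
  # mix some EOG into every channel
  withr::with_seed(9, {
    for (t in 1:3) {
      eog <- rnorm(300)
      ep$data[t, 4, ] <- eog
      for (c in 1:3) ep$data[t, c, ] <- ep$data[t, c, ] + runif(1, -2, 2) * eog
    }
  })
  out <- correct_eog(ep, "ch4")
  for (t in 1:3)
    for (c in 1:3)
      expect_lt(abs(sum(out$data[t, c, ] * ep$data[t, 4, ])), 1e-8)
})

test_that("baseline correction zeroes the baseline mean and is idempotent", {
  ep <- toy_epochs(n_trials = 4, n_channels = 2, n_samples = 500,
                   sampling_rate = 1000)
  ep$epoch_window <- c(-200, 300)
  bc <- baseline_correct(ep, c(-200, 0))
  tms <- epoch_times(bc)
  sel <- tms < 0
  for (t in 1:4)
    for (c in 1:2)
      expect_lt(abs(mean(bc$data[t, c, sel])), 1e-12)
  # constant trace maps to zero
  flat <- epoch_set(array(5, dim = c(1, 1, 500)), sampling_rate = 1000,
                    epoch_window = c(-200, 300))
  expect_equal(max(abs(baseline_correct(flat, c(-200, 0))$data)), 0)
  # idempotent
  bc2 <- baseline_correct(bc, c(-200, 0))
  expect_equal(bc2$data, bc$data, tolerance = 1e-12)
  expect_error(baseline_correct(ep, c(-500, 0)), "not inside")
})

test_that("zero-phase low-pass has unit DC gain, preserves pulse latency, and matches the analytic response", {
  fs <- 1000
  dc <- epoch_set(array(7, dim = c(1, 1, 1000)), sampling_rate = fs,
                  epoch_window = c(0, 1000))
  expect_lt(max(abs(lowpass_filter(dc, 30)$data - 7)), 1e-9)

  # symmetric pulse: peak sample must not move (zero phase)
  x <- exp(-((1:1000) - 500)^2 / (2 * 40^2))
  pulse <- epoch_set(array(x, dim = c(1, 1, 1000)), sampling_rate = fs,
                     epoch_window = c(0, 1000))
  f <- lowpass_filter(pulse, 30)
  expect_equal(which.max(f$data[1, 1, ]), which.max(x))

  # 50 Hz tone vs the squared 2nd-order Butterworth magnitude
  tt <- seq_len(2000) / fs
  tone <- epoch_set(array(sin(2 * pi * 50 * tt), dim = c(1, 1, 2000)),
                    sampling_rate = fs, epoch_window = c(0, 2000))
  ft <- lowpass_filter(tone, 30)
  mid <- 500:1500
  att <- sqrt(mean(ft$data[1, 1, mid]^2)) / sqrt(mean(tone$data[1, 1, mid]^2))
  expect_equal(att, 1 / (1 + (50 / 30)^4), tolerance = 0.05)

  expect_error(lowpass_filter(dc, 600), "Nyquist")
})

test_that("filtering commutes with channel reordering", {
  ep <- toy_epochs(n_trials = 2, n_channels = 3, n_samples = 200)
  f1 <- lowpass_filter(ep, 30)
  swapped <- select_channels(ep, montage(c("ch3", "ch1", "ch2")))
  f2 <- lowpass_filter(swapped, 30)
  expect_equal(f2$data[, 2, ], f1$data[, 1, ])
  expect_equal(f2$data[, 1, ], f1$data[, 3, ])
})

test_that("amplitude rejection matches an exhaustive scan and keeps values intact", {
  ep <- toy_epochs(n_trials = 20, n_channels = 3, n_samples = 80, sd = 40)
  res <- reject_artifacts(ep, 80)
  brute <- which(vapply(1:20, function(t)
    !any(abs(ep$data[t, , ]) > 80), logical(1)))
  expect_equal(res$report$kept_indices, brute)
  expect_equal(res$epochs$data, ep$data[brute, , , drop = FALSE])

  # boundary cases forced by the decided rule
  lo <- array(79, dim = c(1, 1, 10))
  hi <- array(c(rep(0, 9), 81), dim = c(1, 1, 10))
  mk <- function(a) epoch_set(a, sampling_rate = 1000, epoch_window = c(0, 10))
  expect_length(reject_artifacts(mk(lo), 80)$report$kept_indices, 1)
  expect_length(reject_artifacts(mk(hi), 80)$report$kept_indices, 0)

  # range mode: max - min criterion
  swing <- array(rep(c(-45, 45), 5), dim = c(1, 1, 10))
  expect_length(reject_artifacts(mk(swing), 80, mode = "range")$report$kept_indices, 0)
  expect_length(reject_artifacts(mk(swing), 80, mode = "window")$report$kept_indices, 1)
})

test_that("sweep-count gate is strict at the threshold", {
  mk <- function(n_acc, n_rej) {
    d <- array(0, dim = c(n_acc + n_rej, 1, 10))
    epoch_set(d, labels = rep(c("accept", "reject"), c(n_acc, n_rej)),
              sampling_rate = 1000, epoch_window = c(0, 10))
  }
  kept <- enforce_min_sweeps(mk(31, 40), 30)
  expect_equal(as.integer(table(kept$labels)), c(31, 40))
  kept2 <- enforce_min_sweeps(mk(30, 40), 30)      # 30 is not "more than 30"
  expect_equal(sum(kept2$labels == "accept"), 0)
  expect_equal(sum(kept2$labels == "reject"), 40)
  kept3 <- enforce_min_sweeps(mk(40, 12), 30)
  expect_equal(dim(kept3$data)[1], 40)
  expect_true(all(kept3$labels == "accept"))
  unl <- epoch_set(array(0, dim = c(2, 1, 10)), sampling_rate = 1000,
                   epoch_window = c(0, 10))
  expect_error(enforce_min_sweeps(unl, 30), "labeled")
})

test_that("the preprocessing chain runs end to end in the fixed order", {
  g <- generate_epochs(synth_config(n_trials_per_class = 40, n_channels = 4,
                                    artifact_rate = 0.3, seed = 8))
  res <- preprocess_epochs(g$epochs, min_sweeps = NULL)
  expect_lt(dim(res$epochs$data)[1], dim(g$epochs$data)[1])
  expect_true(all(abs(res$epochs$data) <= 80))
  # baseline was removed before filtering; filtering can reintroduce only
  # a small residual in the baseline-window mean
  tms <- epoch_times(res$epochs)
  base <- apply(res$epochs$data[, , tms < 0, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(base)), 1)
})
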