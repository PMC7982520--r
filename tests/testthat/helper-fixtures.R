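# Small in-code fixtures shared across test files.

toy_epochs <- function(n_trials = 6, n_channels = 3, n_samples = 100,
                       sampling_rate = 1000, labeled = TRUE, seed = 42,
                       sd = 1) {
  withr::with_seed(seed, {
    data <- array(rnorm(n_trials * n_channels * n_samples, sd = sd),
                  dim = c(n_trials, n_channels, n_samples))
    epoch_set(data,
              labels = if (labeled)
                rep(c("accept", "reject"), length.out = n_trials) else NULL,
              channel_names = paste0("ch", seq_len(n_channels)),
              sampling_rate = sampling_rate,
              epoch_window = c(0, n_samples / sampling_rate * 1000))
  })
}

# Central finite differences of the network loss for every parameter;
# returns the maximum relative deviation from the analytic gradients.
max_grad_rel_err <- function(config, params, x, y, eps = 1e-6) {
  lg <- loss_and_gradients(config, params, x, y)
  maxrel <- 0
  for (li in seq_along(params)) {
    for (nm in names(params[[li]])) {
      q <- params[[li]][[nm]]
      if (!is.numeric(q) || nm %in% c("hidden", "input_features")) next
      for (ii in seq_along(q)) {
        pp <- params; pp[[li]][[nm]][ii] <- q[ii] + eps
        pm <- params; pm[[li]][[nm]][ii] <- q[ii] - eps
        fd <- (loss_and_gradients(config, pp, x, y)$loss -
                 loss_and_gradients(config, pm, x, y)$loss) / (2 * eps)
        g <- lg$grads[[li]][[nm]][ii]
        maxrel <- max(maxrel, abs(g - fd) / max(abs(fd), 1e-8))
      }
    }
  }
  maxrel
}

# Finite differences of the t-SNE cost with respect to the embedding.
fd_embedding_gradient <- function(P, Y, mode = "joint", eps = 1e-6) {
  Pm <- if (inherits(P, "affinity_matrix")) P$P else P
  fd <- matrix(0, nrow(Y), ncol(Y))
  for (i in seq_len(nrow(Y))) {
    for (j in seq_len(ncol(Y))) {
      Yp <- Y; Yp[i, j] <- Y[i, j] + eps
      Ym <- Y; Ym[i, j] <- Y[i, j] - eps
      fd[i, j] <- (kl_cost(Pm, low_dim_affinities(Yp, mode)$P) -
                     kl_cost(Pm, low_dim_affinities(Ym, mode)$P)) / (2 * eps)
    }
  }
  fd
}

# Sequences whose per-step features are constant at +m for one class and
# -m for the other: a threshold on the feature mean separates perfectly.
separable_sequences <- function(n = 40, steps = 4, features = 3, m = 1,
                                seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(c("accept", "reject"), each = n / 2)
    arr <- array(rnorm(n * steps * features, sd = 0.2),
                 dim = c(n, steps, features))
    arr[lab == "accept", , ] <- arr[lab == "accept", , ] + m
    arr[lab == "reject", , ] <- arr[lab == "reject", , ] - m
    list(x = arr, labels = factor(lab, c("accept", "reject")))
  })
}
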