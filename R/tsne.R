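#' Perplexity-calibrated conditional affinities
#'
#' Converts high-dimensional Euclidean distances between datapoints into
#' conditional probabilities: `p[j|i]` is a Gaussian similarity centered on
#' datapoint `i`, with a per-point bandwidth `sigma_i` found by bisection so
#' that the Shannon perplexity `2^H` of each row equals the requested
#' target. The self-affinity `p[i|i]` is 0 and each row sums to 1.
#'
#' @param X numeric matrix, one datapoint per row (n x m).
#' @param perplexity target perplexity. Automatically clamped to
#'   `(n - 1) / 3` for small n (never below 2), the usual safeguard for
#'   sparse trial counts.
#' @param tol bisection tolerance on `log(perplexity)`.
#' @param max_iter maximum bisection steps per row.
#' @return an `affinity_matrix`: list with `P` (n x n), `sigmas`,
#'   `perplexity` (the value actually used) and `mode = "conditional"`.
#' @export
conditional_affinities <- function(X, perplexity = 30, tol = 1e-7,
                                   max_iter = 200) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop2("need at least 2 datapoints")
  if (any(!is.finite(X))) stop2("X contains non-finite values")
  perplexity <- min(perplexity, max((n - 1) / 3, min(2, n - 1)))
  perplexity <- max(perplexity, 1.01)
  D2 <- sq_dists(X)
  res <- cpp_cond_affinities(D2, perplexity, tol, as.integer(max_iter))
  affinity_matrix(res$P, sigmas = res$sigmas, perplexity = perplexity,
                  mode = "conditional")
}

affinity_matrix <- function(P, sigmas = NULL, perplexity = NA,
                            mode = c("conditional", "joint")) {
  mode <- match.arg(mode)
  structure(list(P = P, sigmas = sigmas, perplexity = perplexity,
                 mode = mode), class = "affinity_matrix")
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("<affinity_matrix> %d x %d, mode %s, perplexity %.3g\n",
              nrow(x$P), ncol(x$P), x$mode, x$perplexity))
  invisible(x)
}

# Pairwise squared Euclidean distances via the Gram-matrix identity;
# clipped at zero to absorb round-off.
sq_dists <- function(X) {
  r <- rowSums(X * X)
  D2 <- outer(r, r, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  D2
}

#' Symmetrize conditional affinities into a joint distribution
#'
#' Forms the symmetric joint affinities
#' `p_ij = (p[j|i] + p[i|j]) / (2n)`, which sum to one over all pairs.
#'
#' @param P_cond a conditional-mode `affinity_matrix`.
#' @return a joint-mode `affinity_matrix`.
#' @export
symmetrize <- function(P_cond) {
  stopifnot(inherits(P_cond, "affinity_matrix"))
  if (P_cond$mode != "conditional")
    stop2("symmetrize expects a conditional-mode affinity matrix")
  n <- nrow(P_cond$P)
  affinity_matrix((P_cond$P + t(P_cond$P)) / (2 * n),
                  sigmas = P_cond$sigmas, perplexity = P_cond$perplexity,
                  mode = "joint")
}

#' Low-dimensional Student-t affinities
#'
#' Computes the heavy-tailed similarities of the embedding coordinates,
#' `q proportional to (1 + ||d_i - d_j||^2)^-1` with zero diagonal.
#' Joint mode normalizes over all pairs; conditional mode normalizes each
#' row. Entries are floored at `1e-12` so that the KL cost stays finite
#' for very distant pairs.
#'
#' @param Y n x d coordinate matrix.
#' @param mode `"joint"` (default) or `"conditional"`.
#' @return an `affinity_matrix` in the requested mode.
#' @export
low_dim_affinities <- function(Y, mode = c("joint", "conditional")) {
  mode <- match.arg(mode)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 2) stop2("need at least 2 points")
  W <- 1 / (1 + sq_dists(Y))
  diag(W) <- 0
  Q <- if (mode == "joint") W / sum(W) else W / rowSums(W)
  Q <- pmax(Q, 1e-12)
  diag(Q) <- 0
  affinity_matrix(Q, mode = mode)
}

#' Kullback-Leibler mismatch between affinity matrices
#'
#' `C = sum_i sum_j p log(p / q)` with the convention
#' `0 * log(0 / q) = 0`. This is the t-SNE cost when `P` holds the
#' high-dimensional and `Q` the low-dimensional affinities.
#'
#' @param P,Q `affinity_matrix` objects (or plain matrices) of matching
#'   shape and mode.
#' @return a non-negative scalar.
#' @export
kl_cost <- function(P, Q) {
  Pm <- if (inherits(P, "affinity_matrix")) P$P else as.matrix(P)
  Qm <- if (inherits(Q, "affinity_matrix")) Q$P else as.matrix(Q)
  if (!all(dim(Pm) == dim(Qm)))
    stop2("P and Q have different shapes")
  if (inherits(P, "affinity_matrix") && inherits(Q, "affinity_matrix") &&
      P$mode != Q$mode)
    stop2("P and Q are in different modes ('%s' vs '%s')", P$mode, Q$mode)
  pos <- Pm > 0
  sum(Pm[pos] * log(Pm[pos] / pmax(Qm[pos], 1e-12)))
}

#' Gradient of the t-SNE cost with respect to the embedding
#'
#' For the default symmetric joint objective the gradient is
#' `dC/dd_i = 4 sum_j (p_ij - q_ij) (d_i - d_j) (1 + ||d_i - d_j||^2)^-1`.
#' For the conditional objective (row-normalized Q) the analytic gradient
#' is `2 sum_j (p[j|i] + p[i|j] - q[j|i] - q[i|j]) w_ij (d_i - d_j)`; both
#' are verified against finite differences of [kl_cost()].
#'
#' @param P an `affinity_matrix` in the mode matching `mode`.
#' @param Y n x d embedding coordinates.
#' @param mode cost formulation, `"joint"` (default) or `"conditional"`.
#' @return n x d gradient matrix.
#' @export
kl_gradient <- function(P, Y, mode = c("joint", "conditional")) {
  mode <- match.arg(mode)
  Pm <- if (inherits(P, "affinity_matrix")) P$P else as.matrix(P)
  Y <- as.matrix(Y)
  if (nrow(Pm) != nrow(Y)) stop2("P and Y have inconsistent sizes")
  if (inherits(P, "affinity_matrix") && P$mode != mode)
    stop2("P is in mode '%s' but the '%s' cost was requested", P$mode, mode)
  W <- 1 / (1 + sq_dists(Y))
  diag(W) <- 0
  if (mode == "joint") {
    Q <- W / sum(W)
    M <- 4 * (Pm - Q) * W
  } else {
    Q <- W / rowSums(W)
    M <- 2 * (Pm + t(Pm) - Q - t(Q)) * W
  }
  rowSums(M) * Y - M %*% Y
}

#' Run t-SNE by momentum gradient descent
#'
#' Embeds the rows of `X` into `dims` dimensions by minimizing the
#' Kullback-Leibler divergence between perplexity-calibrated Gaussian
#' affinities in the input space and Student-t affinities in the
#' embedding. Optimization is plain gradient descent with momentum from a
#' small random initialization, with early exaggeration of the input
#' affinities during the first iterations. Fully deterministic given
#' `seed`.
#'
#' @param X datapoint matrix (n rows) or a `datapoint_matrix` from
#'   [build_datapoints()].
#' @param dims embedding dimensionality (default 5).
#' @param perplexity target perplexity (default 30, clamped for small n).
#' @param iterations gradient-descent iterations (default 1000).
#' @param learning_rate step size (default 100).
#' @param momentum two momentum coefficients: before and after
#'   `momentum_switch` (defaults 0.5 then 0.8 after iteration 250).
#' @param momentum_switch iteration at which momentum switches.
#' @param exaggeration early-exaggeration factor for the input affinities
#'   (default 4) applied for `exaggeration_iter` iterations (default 50);
#'   set `exaggeration = 1` to disable.
#' @param exaggeration_iter duration of early exaggeration.
#' @param seed integer seed for the random initialization.
#' @param mode cost formulation; `"joint"` (the symmetric t-SNE objective,
#'   default) or `"conditional"` (row-normalized Q, kept for completeness).
#' @return a `tsne_embedding`: list with `Y` (n x dims), `cost_trace`
#'   (KL cost per iteration of the optimized objective), `sigmas`,
#'   `seed` and `hyperparams`.
#' @examples
#' X <- matrix(rnorm(40 * 10), 40)
#' emb <- run_tsne(X, dims = 2, perplexity = 10, iterations = 100, seed = 1)
#' dim(emb$Y)
#' @export
run_tsne <- function(X, dims = 5, perplexity = 30, iterations = 1000,
                     learning_rate = 100, momentum = c(0.5, 0.8),
                     momentum_switch = 250, exaggeration = 4,
                     exaggeration_iter = 50, seed = 1,
                     mode = c("joint", "conditional")) {
  mode <- match.arg(mode)
  if (inherits(X, "datapoint_matrix")) X <- X$X
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop2("X contains non-finite values")
  n <- nrow(X)
  if (n < 4) stop2("need at least 4 datapoints")
  Pc <- conditional_affinities(X, perplexity)
  P <- if (mode == "joint") symmetrize(Pc)$P else Pc$P
  Y <- with_seed(seed, matrix(rnorm(n * dims, sd = 1e-2), n, dims))
  V <- matrix(0, n, dims)
  cost_trace <- numeric(iterations)
  p_logp <- function(M) { pos <- M > 0; sum(M[pos] * log(M[pos])) }
  plogp_plain <- if (mode == "joint") p_logp(P) else NA
  plogp_ex <- if (mode == "joint" && exaggeration != 1)
    p_logp(P * exaggeration) else plogp_plain
  for (it in seq_len(iterations)) {
    exag <- exaggeration != 1 && it <= exaggeration_iter
    Pit <- if (exag) P * exaggeration else P
    if (mode == "joint") {
      gc <- cpp_joint_grad(Pit, Y, if (exag) plogp_ex else plogp_plain)
      grad <- gc$grad
      cost_trace[it] <- gc$cost
    } else {
      grad <- kl_gradient(Pit, Y, mode = "conditional")
      cost_trace[it] <- kl_cost(Pit, low_dim_affinities(Y, "conditional")$P)
    }
    mu <- if (it <= momentum_switch) momentum[1] else momentum[2]
    V <- mu * V - learning_rate * grad
    Y <- Y + V
    Y <- sweep(Y, 2, colMeans(Y))    # keep the embedding centered
  }
  structure(list(
    Y = Y, cost_trace = cost_trace, sigmas = Pc$sigmas, seed = seed,
    hyperparams = list(dims = dims, perplexity = Pc$perplexity,
                       iterations = iterations,
                       learning_rate = learning_rate, momentum = momentum,
                       momentum_switch = momentum_switch,
                       exaggeration = exaggeration,
                       exaggeration_iter = exaggeration_iter, mode = mode)
  ), class = "tsne_embedding")
}

#' @export
print.tsne_embedding <- function(x, ...) {
  h <- x$hyperparams
  cat(sprintf(paste0("<tsne_embedding> %d points in %d dims ",
                     "(perplexity %.3g, %d iterations, seed %d)\n"),
              nrow(x$Y), ncol(x$Y), h$perplexity, h$iterations, x$seed))
  cat(sprintf("  final KL cost %.4f\n", x$cost_trace[length(x$cost_trace)]))
  invisible(x)
}

#' @export
plot.tsne_embedding <- function(x, ...) {
  graphics::plot(seq_along(x$cost_trace), x$cost_trace, type = "l",
                 xlab = "iteration", ylab = "KL cost",
                 main = "t-SNE optimization", ...)
  invisible(x)
}
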