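test_that("conditional affinities hit the target perplexity with zero diagonal", {
  withr::with_seed(1, X <- matrix(rnorm(40 * 12), 40))
  P <- conditional_affinities(X, perplexity = 10)
  expect_equal(max(abs(diag(P$P))), 0)
  expect_equal(rowSums(P$P), rep(1, 40), tolerance = 1e-10)
  expect_true(all(P$P >= 0))
  # entropy recomputation oracle: 2^H per row equals the target
  H <- apply(P$P, 1, function(r) { r <- r[r > 0]; -sum(r * log2(r)) })
  expect_equal(2^H, rep(10, 40), tolerance = 1e-4)
  expect_true(all(P$sigmas > 0))
})

test_that("three mutually equidistant points split affinity 0.5/0.5", {
  X <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  P <- conditional_affinities(X, perplexity = 2)
  off <- P$P[row(P$P) != col(P$P)]
  expect_equal(off, rep(0.5, 6), tolerance = 1e-8)
})

test_that("degenerate duplicate-row geometry never yields non-finite affinities", {
  X <- matrix(1, 6, 4)           # all points identical
  P <- conditional_affinities(X, perplexity = 2)
  expect_true(all(is.finite(P$P)))
  expect_equal(rowSums(P$P), rep(1, 6), tolerance = 1e-10)
})

test_that("symmetrization yields a joint distribution", {
  withr::with_seed(2, X <- matrix(rnorm(20 * 6), 20))
  Pc <- conditional_affinities(X, 5)
  Pj <- symmetrize(Pc)
  expect_identical(Pj$P, t(Pj$P))
  expect_equal(sum(Pj$P), 1, tolerance = 1e-12)
  expect_equal(Pj$P, (Pc$P + t(Pc$P)) / (2 * 20), tolerance = 1e-15)
  expect_error(symmetrize(Pj), "conditional")
  # symmetric conditional input is a fixed point up to the 1/n scale
  S <- (Pc$P + t(Pc$P)) / 2
  S <- S / rowSums(S)
  if (max(abs(S - t(S))) < 1e-12)
    expect_equal(symmetrize(affinity_matrix(S, mode = "conditional"))$P,
                 S / 20, tolerance = 1e-12)
})

test_that("low-dimensional Student-t affinities match a double-loop oracle", {
  withr::with_seed(3, Y <- matrix(rnorm(12 * 3), 12))
  Q <- low_dim_affinities(Y)$P
  n <- 12
  W <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j)
    W[i, j] <- 1 / (1 + sum((Y[i, ] - Y[j, ])^2))
  expect_equal(Q, pmax(W / sum(W), 1e-12) * (diag(n) == 0), tolerance = 1e-12)
  # n = 2: joint normalization forces 0.5 on both off-diagonals
  Q2 <- low_dim_affinities(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))$P
  expect_equal(Q2[1, 2], 0.5)
  expect_equal(Q2[2, 1], 0.5)
  # coincident points attain the kernel maximum before normalization
  Y3 <- rbind(c(0, 0), c(0, 0), c(5, 5))
  W3 <- 1 / (1 + as.matrix(dist(Y3))^2)
  expect_equal(max(W3[row(W3) != col(W3)]), 1)
})

test_that("the KL cost is zero at P == Q, non-negative, and matches a double loop", {
  withr::with_seed(4, {
    X <- matrix(rnorm(15 * 5), 15)
    Y <- matrix(rnorm(15 * 2), 15)
  })
  P <- symmetrize(conditional_affinities(X, 4))
  Q <- low_dim_affinities(Y)
  expect_equal(kl_cost(P, P), 0)
  expect_gte(kl_cost(P, Q), 0)
  ref <- 0
  for (i in 1:15) for (j in 1:15)
    if (P$P[i, j] > 0) ref <- ref + P$P[i, j] * log(P$P[i, j] / Q$P[i, j])
  expect_equal(kl_cost(P, Q), ref, tolerance = 1e-12)
  expect_error(kl_cost(P$P, Q$P[1:10, 1:10]), "shapes")
})

test_that("the gradient matches finite differences in both cost modes", {
  withr::with_seed(5, {
    X <- matrix(rnorm(20 * 6), 20)
    Y <- matrix(rnorm(20 * 3), 20)
  })
  Pj <- symmetrize(conditional_affinities(X, 5))
  g <- kl_gradient(Pj, Y)
  fd <- fd_embedding_gradient(Pj, Y, "joint")
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
  # translation invariance: column sums vanish
  expect_lt(max(abs(colSums(g))), 1e-10)
  # compiled path agrees with the R path
  gc_ <- erpdecode:::cpp_joint_grad(Pj$P, Y)
  expect_equal(gc_$grad, g, tolerance = 1e-12)
  expect_equal(gc_$cost, kl_cost(Pj, low_dim_affinities(Y)), tolerance = 1e-12)

  Pc <- conditional_affinities(X, 5)
  gcond <- kl_gradient(Pc, Y, mode = "conditional")
  fdc <- fd_embedding_gradient(Pc$P, Y, "conditional")
  expect_lt(max(abs(gcond - fdc)) / max(abs(fdc)), 1e-4)
})

test_that("the gradient vanishes where Q equals P", {
  # a configuration with all pairwise distances equal makes Q uniform;
  # pairing it with a uniform P puts the cost at its minimum
  Y <- diag(4) * sqrt(2)                     # equidistant in 4 dims
  P <- matrix(1 / 12, 4, 4); diag(P) <- 0
  g <- kl_gradient(affinity_matrix(P, mode = "joint"), Y)
  expect_lt(max(abs(g)), 1e-8)
})

test_that("run_tsne honors dimensionality, determinism and permutation equivariance", {
  withr::with_seed(6, X <- matrix(rnorm(30 * 10), 30))
  e1 <- run_tsne(X, dims = 5, perplexity = 8, iterations = 60, seed = 11)
  expect_equal(ncol(e1$Y), 5)
  expect_length(e1$cost_trace, 60)
  expect_true(all(e1$cost_trace >= 0))
  e2 <- run_tsne(X, dims = 5, perplexity = 8, iterations = 60, seed = 11)
  expect_identical(e1$Y, e2$Y)             # bitwise determinism
  expect_error(run_tsne(matrix(c(NA, 1, 2, 3), 2)), "non-finite")
  expect_error(run_tsne(X[1:3, ]), "at least 4")
})

test_that("well-separated clusters stay separated in the embedding", {
  withr::with_seed(7, {
    X <- rbind(matrix(rnorm(30 * 8, mean = 0), 30),
               matrix(rnorm(30 * 8, mean = 8), 30))
  })
  emb <- run_tsne(X, dims = 2, perplexity = 10, iterations = 250, seed = 3)
  Y <- emb$Y
  c1 <- colMeans(Y[1:30, ]); c2 <- colMeans(Y[31:60, ])
  within <- mean(c(sqrt(rowSums(sweep(Y[1:30, ], 2, c1)^2)),
                   sqrt(rowSums(sweep(Y[31:60, ], 2, c2)^2))))
  between <- sqrt(sum((c1 - c2)^2))
  expect_gt(between, within)
})

test_that("with exaggeration off and a small step the cost settles monotonically", {
  fails <- 0
  for (s in 1:3) {
    withr::with_seed(s, X <- matrix(rnorm(25 * 6), 25))
    emb <- run_tsne(X, dims = 2, perplexity = 6, iterations = 150,
                    learning_rate = 1, exaggeration = 1,
                    momentum = c(0.3, 0.3), seed = s)
    tail_costs <- emb$cost_trace[-(1:10)]
    if (any(diff(tail_costs) > 1e-8)) fails <- fails + 1
  }
  expect_lte(fails, 0)
})

test_that("embedding is equivariant to datapoint permutation of the affinities", {
  withr::with_seed(8, X <- matrix(rnorm(16 * 5), 16))
  perm <- sample(16)
  P1 <- conditional_affinities(X, 4)$P
  P2 <- conditional_affinities(X[perm, ], 4)$P
  expect_equal(P2, P1[perm, perm], tolerance = 1e-12)
})
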