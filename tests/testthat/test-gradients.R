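# Connectivity, sparsification, affinity, and the two decompositions.

test_that("connectivity matrix is the Pearson correlation of vertex columns", {
  # perfect anticorrelation
  x <- cbind(a = c(1, 2, 3, 4), b = -c(1, 2, 3, 4))
  C <- compute_connectivity(x)
  expect_equal(C[1, 2], -1)
  # affine invariance
  x <- cbind(c(1, 2, 3, 5), 2 * c(1, 2, 3, 5) + 3)
  expect_equal(compute_connectivity(x)[1, 2], 1)
  # hand-computed Pearson: (1,2,3,4) vs (1,3,2,4) -> 0.8
  x <- cbind(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(compute_connectivity(x)[1, 2], 0.8)
  # symmetric, unit diagonal, bounded
  set.seed(7)
  C <- compute_connectivity(matrix(rnorm(200), 20, 10))
  expect_equal(unclass(C), t(unclass(C)))
  expect_equal(diag(C), rep(1, 10))
  expect_true(all(C >= -1 & C <= 1))
})

test_that("constant vertex columns error by default and can be dropped", {
  x <- cbind(rnorm(10), rep(2, 10), rnorm(10))
  expect_error(compute_connectivity(x), "constant time series at vertex \\(0-based\\) 1")
  expect_warning(C <- compute_connectivity(x, on_constant = "drop"), "dropping")
  expect_equal(dim(C), c(2L, 2L))
  expect_equal(attr(C, "vertices"), c(0L, 2L))
})

test_that("sparsification keeps exactly the top ceil((1-s)*V) entries per row", {
  # top-1 at the conventional 0.9 threshold
  row <- c(0.9, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05, 0.0, -0.1, -0.2)
  M <- rbind(row, row)
  S <- sparsify_rows(M, 0.9)
  expect_equal(S[1, ], c(0.9, rep(0, 9)), ignore_attr = TRUE)
  # sparsity 0 retains everything
  set.seed(1)
  A <- matrix(rnorm(36), 6, 6)
  expect_equal(sparsify_rows(A, 0), A, ignore_attr = TRUE)
  # top-2 of (4,3,2,1) at sparsity 0.5
  expect_equal(sparsify_rows(rbind(c(4, 3, 2, 1)), 0.5),
               rbind(c(4, 3, 0, 0)), ignore_attr = TRUE)
  # exact retention count on random matrices, with and without ties
  for (seed in 1:5) {
    set.seed(seed)
    V <- 37
    A <- matrix(rnorm(V * V), V, V)
    s <- runif(1, 0, 0.95)
    kept <- rowSums(sparsify_rows(A, s) != 0)
    expect_true(all(kept == ceiling((1 - s) * V)))
  }
})

test_that("sparsification tie-break keeps the lowest vertex index", {
  M <- rbind(c(0.5, 0.9, 0.9, 0.9, 0.1))
  S <- sparsify_rows(M, 0.5) # keep ceil(0.5*5) = 3: the 0.9 at cols 2,3,4
  expect_equal(which(S[1, ] != 0), c(2L, 3L, 4L))
  S1 <- sparsify_rows(M, 0.7) # keep 2: ties at 0.9 -> lowest indices 2,3
  expect_equal(which(S1[1, ] != 0), c(2L, 3L))
})

test_that("magnitude ranking can retain strong negative connections", {
  M <- rbind(c(-0.9, 0.5, 0.1, 0.05))
  expect_equal(which(sparsify_rows(M, 0.5, rank_by = "value")[1, ] != 0),
               c(2L, 3L))
  expect_equal(which(sparsify_rows(M, 0.5, rank_by = "magnitude")[1, ] != 0),
               c(1L, 2L))
})

test_that("cosine affinity matches hand-computed values and flags zero rows", {
  M <- rbind(c(1, 1, 0), c(1, 1, 0))
  expect_equal(cosine_affinity(M)[1, 2], 1)
  M <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(cosine_affinity(M)[1, 2], 0)
  M <- rbind(c(1, 1, 0), c(1, 0, 1)) # 1 / (sqrt(2) * sqrt(2))
  expect_equal(cosine_affinity(M)[1, 2], 0.5)
  M <- rbind(c(1, 1, 0), c(0, 0, 0))
  expect_error(cosine_affinity(M), "degenerate vertex.*1")
})

test_that("affinity invariants hold on synthetic scans across seeds", {
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(60 * 40), 60, 40)
    A <- cosine_affinity(sparsify_rows(compute_connectivity(X), 0.8))
    expect_lt(max(abs(A - t(A))), 1e-10)
    expect_equal(diag(A), rep(1, 40))
    expect_true(all(A >= -1 & A <= 1))
  }
})

test_that("PCA gradients match a dense SVD oracle up to component sign", {
  for (seed in 1:10) {
    A <- random_affinity(60, seed)
    k <- 4
    gs <- pca_gradients(A, k)
    # oracle: direct SVD of the column-centred affinity
    Ac <- scale(unclass(A), center = TRUE, scale = FALSE)
    sv <- svd(Ac)
    oracle_scores <- Ac %*% sv$v[, seq_len(k)]
    expect_lt(signflip_maxdiff(gs$scores, oracle_scores), 1e-8)
    expect_equal(gs$explained_variance,
                 (sv$d^2 / sum(sv$d^2))[seq_len(k)], tolerance = 1e-10)
    # score columns mutually orthogonal
    G <- crossprod(gs$scores)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-6)
  }
})

test_that("rank-1 affinity puts all explained variance on the first component", {
  v <- seq_len(8)
  A <- outer(v, v) + 5 # rank 1 after centring removes nothing rank-wise
  gs <- pca_gradients(A, 3)
  expect_equal(gs$explained_variance[1], 1)
  expect_equal(gs$explained_variance[2:3], c(0, 0))
})

test_that("PCA scores are equivariant under vertex permutation and invariant
           to a constant offset", {
  A <- random_affinity(40, 99)
  gs <- pca_gradients(A, 3)
  set.seed(1); p <- sample(40)
  gs_p <- pca_gradients(unclass(A)[p, p], 3)
  unperm <- gs_p$scores[order(p), ]
  expect_lt(signflip_maxdiff(gs$scores, unperm), 1e-8)
  gs_off <- pca_gradients(unclass(A) + 0.37, 3)
  expect_lt(signflip_maxdiff(gs$scores, gs_off$scores), 1e-8)
})

test_that("diffusion embedding separates a two-block affinity", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1
  A[4:6, 4:6] <- 1
  gs <- diffusion_gradients(A, k = 2, alpha = 0.5, diffusion_time = 1)
  g1 <- gs$scores[, 1]
  expect_lt(max(abs(g1[1:3] - g1[1])), 1e-10)
  expect_lt(max(abs(g1[4:6] - g1[4])), 1e-10)
  expect_lt(g1[1] * g1[4], 0) # opposite signs across blocks
})

test_that("diffusion embedding matches a dense random-walk oracle at alpha 0", {
  for (seed in 1:10) {
    V <- 50
    A <- random_affinity(V, seed + 100)
    k <- 3
    gs <- diffusion_gradients(A, k, alpha = 0, diffusion_time = 1)
    # oracle: dense eigendecomposition of the plain random-walk operator
    W <- pmax(unclass(A), 0)
    P <- W / rowSums(W)
    e <- eigen(P)
    expect_lt(max(abs(Im(e$values))), 1e-10)
    ord <- order(Re(e$values), decreasing = TRUE)
    lam <- Re(e$values)[ord]
    vec <- Re(e$vectors)[, ord]
    d1 <- rowSums(W)
    oracle <- sapply(2:(k + 1), function(j) {
      v <- vec[, j]
      v <- v / sqrt(sum(d1 * v^2) / sum(d1)) # unit degree-weighted RMS
      v * lam[j]
    })
    expect_lt(signflip_maxdiff(gs$scores, oracle), 1e-8)
  }
})

test_that("complete-graph affinity is flagged degenerate", {
  A <- matrix(1, 8, 8)
  gs <- diffusion_gradients(A, 3)
  expect_true(gs$degenerate)
  expect_lt(max(apply(gs$scores, 2, sd)), 1e-12)
})

test_that("disconnected affinity graphs are rejected", {
  A <- diag(0, 4)
  A[1:2, 1:2] <- 1
  A[3, 4] <- A[4, 3] <- -0.5 # negative edge clips to zero -> zero rows
  expect_error(diffusion_gradients(A, 2), "disconnected")
})

test_that("explained variance is a non-increasing fraction vector", {
  for (seed in c(3, 11)) {
    A <- random_affinity(30, seed)
    for (gs in list(pca_gradients(A, 5), diffusion_gradients(A, 5))) {
      ev <- gs$explained_variance
      expect_true(all(diff(ev) <= 1e-12))
      expect_true(all(ev >= 0 & ev <= 1))
      expect_lte(sum(ev), 1 + 1e-12)
    }
  }
})
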