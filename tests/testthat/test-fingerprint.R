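# Similarity matrices, winner-take-all identification, permutation null,
# within/between ratios, repeated-measures ANOVA, Bonferroni.

make_sets <- function(vecs) {
  lapply(vecs, function(v) matrix(v, ncol = 1))
}

test_that("similarity matrix is the Pearson correlation of score vectors", {
  ref <- make_sets(list(c(1, 2, 3), c(3, 2, 1)))
  S <- similarity_matrix(ref, ref, 1)
  expect_equal(unclass(S), rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)
  # a negated target vector shows up as a -1 diagonal entry
  tar <- make_sets(list(-c(1, 2, 3), c(3, 2, 1)))
  S2 <- similarity_matrix(ref, tar, 1)
  expect_equal(S2[1, 1], -1)
  expect_equal(S2[2, 2], 1)
})

test_that("similarity is invariant to positive affine rescaling of one subject", {
  set.seed(20)
  ref <- make_sets(replicate(4, rnorm(30), simplify = FALSE))
  tar <- make_sets(replicate(4, rnorm(30), simplify = FALSE))
  S <- similarity_matrix(ref, tar, 1)
  tar2 <- tar
  tar2[[2]] <- tar2[[2]] * 5.5 + 2
  S2 <- similarity_matrix(ref, tar2, 1)
  expect_equal(unclass(S), unclass(S2), tolerance = 1e-12)
})

test_that("constant score vectors within the mask are rejected by name", {
  ref <- make_sets(list(c(1, 2, 3, 4), rep(2, 4)))
  expect_error(similarity_matrix(ref, ref, 1), "constant.*subject\\(s\\) 2")
  expect_error(
    similarity_matrix(make_sets(list(1:4, 4:1)),
                      make_sets(list(1:4, 4:1)), 1, vertex_mask = 1:2),
    "at least 3"
  )
})

test_that("winner-take-all identification counts correct self-matches", {
  S <- structure(rbind(c(0.9, 0.2), c(0.1, 0.8)), class = "similarity_matrix")
  expect_equal(identification(S)$accuracy, 1)
  S <- structure(rbind(c(0.1, 0.9), c(0.8, 0.2)), class = "similarity_matrix")
  expect_equal(identification(S)$accuracy, 0)
  S <- structure(rbind(c(0.9, 0.2, 0.1),
                       c(0.3, 0.5, 0.6),
                       c(0.2, 0.4, 0.7)), class = "similarity_matrix")
  res <- identification(S)
  expect_equal(res$accuracy, 2 / 3)
  expect_equal(res$predicted, c(1L, 3L, 3L))
})

test_that("identification is invariant to strictly increasing transforms and
           flags exact ties", {
  set.seed(21)
  S <- matrix(runif(49, -1, 1), 7, 7)
  a1 <- identification(S)
  a2 <- identification(tanh(3 * S)) # strictly increasing
  expect_equal(a1$predicted, a2$predicted)
  expect_equal(a1$accuracy, a2$accuracy)
  St <- rbind(c(0.5, 0.5), c(0.1, 0.2))
  res <- identification(St)
  expect_true(res$ties)
  expect_equal(res$predicted[1], 1L) # lowest index wins
})

test_that("exhaustive permutation null for N = 3 identity predictions", {
  S <- diag(3) * 0.5 + 0.1
  res <- permutation_null(S, method = "exhaustive")
  expect_equal(sort(res$null_accuracies, decreasing = TRUE),
               c(1, 1/3, 1/3, 1/3, 0, 0))
  expect_equal(mean(res$null_accuracies), 1/3)
  # independent enumeration oracle for the null mean (fixed-point counts)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  oracle <- vapply(perms, function(p) mean(seq_len(3) == p), numeric(1))
  expect_equal(sort(res$null_accuracies), sort(oracle))
})

test_that("sampled permutation null has mean 1/N within Monte-Carlo error", {
  set.seed(1)
  S <- matrix(runif(100), 10, 10)
  diag(S) <- 1 # perfect identification
  res <- permutation_null(S, n_perm = 2000, seed = 7)
  se <- sd(res$null_accuracies) / sqrt(2000)
  expect_lt(abs(mean(res$null_accuracies) - 1 / 10), 3 * se)
  expect_gt(res$p_raw, 0)
  expect_lte(res$p_raw, 1)
})

test_that("observed accuracy 0 yields p = 1 and the add-one formula holds", {
  S <- rbind(c(0.1, 0.9), c(0.8, 0.2)) # anti-diagonal, accuracy 0
  res <- permutation_null(S, n_perm = 50, seed = 3)
  expect_equal(res$p_raw, 1)
  expect_equal(res$p_literal, 1)
  # add-one smoothing: p_raw = (1 + k) / (n_perm + 1)
  S2 <- diag(5) + matrix(runif(25, 0, 0.1), 5, 5)
  res2 <- permutation_null(S2, n_perm = 200, seed = 4)
  k <- sum(res2$null_accuracies >= res2$accuracy)
  expect_equal(res2$p_raw, (1 + k) / 201)
  expect_equal(res2$p_literal, k / 200)
})

test_that("permutation p-values are reproducible under the same seed", {
  S <- matrix(runif(64), 8, 8)
  r1 <- permutation_null(S, n_perm = 100, seed = 11)
  r2 <- permutation_null(S, n_perm = 100, seed = 11)
  expect_identical(r1$null_accuracies, r2$null_accuracies)
})

test_that("within/between summary and per-subject ratios", {
  S <- structure(rbind(c(0.8, 0.4), c(0.2, 0.6)), class = "similarity_matrix")
  wb <- within_between_ratios(S)
  expect_equal(wb$within, 0.7)
  expect_equal(wb$between, 0.3)
  expect_equal(wb$per_subject$ratio[1], 0.8 / 0.3)
  # uniform matrix: every ratio 1
  Su <- matrix(0.5, 4, 4)
  expect_true(all(within_between_ratios(Su)$per_subject$ratio == 1))
  # diagonal 1, off-diagonal 0.5: ratios all 2
  Sd <- matrix(0.5, 5, 5); diag(Sd) <- 1
  expect_true(all(within_between_ratios(Sd)$per_subject$ratio == 2))
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 4), 1)
  expect_equal(bonferroni(0.001, 6), 0.006)
  expect_error(bonferroni(0, 2), "\\(0, 1\\]")
  expect_error(bonferroni(1.2, 2), "\\(0, 1\\]")
})

test_that("repeated-measures ANOVA matches a definitional SS oracle", {
  set.seed(31)
  for (rep in 1:3) {
    d <- expand.grid(subject = paste0("s", 1:6),
                     gradient = c("G1", "G2", "G3"),
                     interval = c("short", "long"))
    d$ratio <- 1 + 0.3 * (d$gradient == "G3") + rnorm(nrow(d), sd = 0.2)
    res <- rm_anova(d)
    oracle <- rm_anova_oracle(d)
    expect_equal(res$F_gradient$F, oracle$F_gradient, tolerance = 1e-8)
    expect_equal(res$F_interval$F, oracle$F_interval, tolerance = 1e-8)
    expect_equal(res$F_interaction$F, oracle$F_interaction, tolerance = 1e-8)
  }
})

test_that("ANOVA degrees of freedom follow the within-subject partitioning", {
  d <- expand.grid(subject = paste0("s", 1:30),
                   gradient = c("G1", "G2", "G3"),
                   interval = c("short", "long"))
  set.seed(32)
  d$ratio <- rnorm(nrow(d), mean = 1.2, sd = 0.1)
  res <- rm_anova(d)
  expect_equal(c(res$F_gradient$df1, res$F_gradient$df2), c(2, 58))
  expect_equal(c(res$F_interval$df1, res$F_interval$df2), c(1, 29))
  expect_equal(c(res$F_interaction$df1, res$F_interaction$df2), c(2, 58))
  expect_equal(nrow(res$posthoc), 3)
})

test_that("degenerate and constructed-effect ANOVA cases behave as defined", {
  d <- expand.grid(subject = paste0("s", 1:5),
                   gradient = c("G1", "G2"), interval = c("a", "b"))
  d$ratio <- 2
  res <- rm_anova(d)
  expect_true(res$degenerate)
  expect_equal(res$F_gradient$F, 0)
  # gradient-3 shifted by +0.5, no noise: gradient effect dominates, time nil
  d2 <- expand.grid(subject = paste0("s", 1:6),
                    gradient = c("G1", "G2", "G3"),
                    interval = c("short", "long"))
  base <- rnorm(6, sd = 0.2)[as.integer(factor(d2$subject))]
  d2$ratio <- 1 + base + 0.5 * (d2$gradient == "G3")
  res2 <- rm_anova(d2)
  expect_true(res2$F_gradient$F > 1e10 || is.infinite(res2$F_gradient$F))
  expect_equal(res2$F_interval$F, 0)
  # missing cell is an error, not an imputation
  expect_error(rm_anova(d2[-1, ]), "balanced")
})
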