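# Shared fixtures and independent oracles for the test suite.

# Random symmetric affinity-like matrix: cosine similarities of random
# sparse-ish profile rows, guaranteed valid input for both decompositions.
random_affinity <- function(V, seed) {
  set.seed(seed)
  M <- matrix(stats::rnorm(V * V), V, V)
  M[M < 0.3] <- 0
  M <- M + 0.1 # avoid all-zero rows
  cosine_affinity(M)
}

fnorm_test <- function(x) sqrt(sum(x^2))

# Random orthogonal k x k matrix via QR of a seeded Gaussian.
random_orthogonal <- function(k, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
}

# Match two score matrices up to per-column sign; returns max abs difference.
signflip_maxdiff <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  d <- vapply(seq_len(ncol(a)), function(c) {
    min(max(abs(a[, c] - b[, c])), max(abs(a[, c] + b[, c])))
  }, numeric(1))
  max(d)
}

# Definitional sums-of-squares oracle for the two-factor within-subject
# ANOVA: every effect tested against its interaction with subject.
rm_anova_oracle <- function(d) {
  d$subject <- factor(d$subject); d$gradient <- factor(d$gradient)
  d$interval <- factor(d$interval)
  y <- d$ratio
  grand <- mean(y)
  cell <- function(...) tapply(y, lapply(list(...), function(f) d[[f]]), mean)
  m_a <- cell("gradient"); m_b <- cell("interval"); m_s <- cell("subject")
  m_as <- cell("gradient", "subject"); m_bs <- cell("interval", "subject")
  m_ab <- cell("gradient", "interval")
  a <- nlevels(d$gradient); b <- nlevels(d$interval); s <- nlevels(d$subject)
  SS_A <- b * s * sum((m_a - grand)^2)
  SS_B <- a * s * sum((m_b - grand)^2)
  SS_AB <- s * sum(sweep(sweep(m_ab, 1, m_a), 2, m_b) + grand)^0 * 0 +
    s * sum((m_ab - outer(m_a, rep(1, b)) - outer(rep(1, a), m_b) + grand)^2)
  SS_AS <- b * sum((m_as - outer(m_a, rep(1, s)) - outer(rep(1, a), m_s) + grand)^2)
  SS_BS <- a * sum((m_bs - outer(m_b, rep(1, s)) - outer(rep(1, b), m_s) + grand)^2)
  # three-way residual: y - fitted additive+pairwise
  res2 <- 0
  for (i in seq_len(nrow(d))) {
    ai <- d$gradient[i]; bi <- d$interval[i]; si <- d$subject[i]
    fit <- m_ab[ai, bi] + m_as[ai, si] + m_bs[bi, si] -
      m_a[ai] - m_b[bi] - m_s[si] + grand
    res2 <- res2 + (y[i] - fit)^2
  }
  F_A <- (SS_A / (a - 1)) / (SS_AS / ((a - 1) * (s - 1)))
  F_B <- (SS_B / (b - 1)) / (SS_BS / ((b - 1) * (s - 1)))
  F_AB <- (SS_AB / ((a - 1) * (b - 1))) / (res2 / ((a - 1) * (b - 1) * (s - 1)))
  list(F_gradient = unname(F_A), F_interval = unname(F_B),
       F_interaction = unname(F_AB))
}

# Exact signed-rank distribution by enumerating all 2^n sign patterns;
# returns the two-sided p for observed statistic v (same convention as
# stats::wilcox.test exact: 2 * min(P(V <= v), P(V >= v)), capped at 1).
signed_rank_oracle <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  p_le <- mean(vs <= v_obs)
  p_ge <- mean(vs >= v_obs)
  list(statistic = v_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Closed-form first-order partial correlation r_xy.z.
partial_cor_oracle <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Full study-scale run (30 subjects x 3 sessions, V = 1000, T = 300), computed
# once and shared by the acceptance checks that look at different facets of
# the same experiment.
study_run_cache <- new.env(parent = emptyenv())
default_study_run <- function() {
  if (is.null(study_run_cache$res)) {
    ds <- simulate_dataset(synth_config(seed = 1L))
    cfg <- analysis_config(seed = 1L)
    study_run_cache$res <- run_pipeline(cfg, ds)
  }
  study_run_cache$res
}

# Small end-to-end dataset + pipeline result, computed once per test run and
# cached (several test files inspect different facets of the same run).
small_run_cache <- new.env(parent = emptyenv())
small_pipeline_run <- function() {
  if (is.null(small_run_cache$res)) {
    sc <- synth_config(n_subjects = 6L, n_vertices = 150L,
                       n_timepoints = 120L, seed = 42L)
    ds <- simulate_dataset(sc)
    cfg <- analysis_config(n_permutations = 100L, seed = 42L)
    small_run_cache$dataset <- ds
    small_run_cache$res <- run_pipeline(cfg, ds)
  }
  list(dataset = small_run_cache$dataset, res = small_run_cache$res)
}
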