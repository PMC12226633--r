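# Connectivity-gradient computation: correlation -> row-wise sparsification ->
# cosine affinity -> decomposition (PCA or diffusion-map embedding).

#' Pearson connectivity matrix from a time-series scan
#'
#' Computes the vertex-by-vertex Pearson correlation matrix of a T x V
#' time-series matrix (rows = timepoints, columns = vertices).
#'
#' @param x numeric T x V matrix, T >= 2.
#' @param on_constant what to do with zero-variance (constant) columns:
#'   `"error"` (default) aborts naming the offending vertices; `"drop"`
#'   removes them with a warning, shrinking V.
#' @return A V x V symmetric correlation matrix with unit diagonal, of class
#'   `connectivity_matrix`. When columns are dropped the retained vertex
#'   indices are recorded in the `"vertices"` attribute.
#' @export
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' C <- compute_connectivity(x)
#' all.equal(diag(C), rep(1, 4), check.attributes = FALSE)
compute_connectivity <- function(x, on_constant = c("error", "drop")) {
  on_constant <- match.arg(on_constant)
  check_matrix(x, "time-series")
  if (nrow(x) < 2L) gfp_stop("need at least 2 timepoints, got ", nrow(x))
  sds <- apply(x, 2L, stats::sd)
  constant <- which(sds == 0)
  vertices <- seq_len(ncol(x))
  if (length(constant) > 0L) {
    if (on_constant == "error") {
      gfp_stop(
        "constant time series at vertex (0-based) ",
        paste(constant - 1L, collapse = ", ")
      )
    }
    warning(
      "dropping ", length(constant), " constant vertex column(s): ",
      paste(constant - 1L, collapse = ", ")
    )
    x <- x[, -constant, drop = FALSE]
    vertices <- vertices[-constant]
  }
  C <- stats::cor(x)
  # enforce exact symmetry and unit diagonal against floating-point jitter
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C[C > 1] <- 1
  C[C < -1] <- -1
  structure(C, class = c("connectivity_matrix", class(C)),
            vertices = vertices - 1L)
}

#' Row-wise sparsification of a connectivity matrix
#'
#' For each row independently, retains the `ceiling((1 - sparsity) * V)`
#' strongest entries and zeroes the rest. With the default `rank_by =
#' "value"`, "strongest" means largest signed value (so at the usual 0.9
#' threshold negative correlations survive only when fewer than 10% of a
#' row's entries are positive); `rank_by = "magnitude"` ranks by absolute
#' value instead. Ties at the cutoff are broken deterministically in favour
#' of the lowest vertex index. The output is generally not symmetric.
#'
#' @param C numeric V x V matrix (typically a [compute_connectivity()] result).
#' @param sparsity fraction in `[0, 1)` of entries to drop per row; the
#'   conventional default 0.9 keeps the top 10%.
#' @param rank_by `"value"` (default) or `"magnitude"`.
#' @return A V x V matrix with exactly `ceiling((1 - sparsity) * V)` non-zeroed
#'   positions per row (retained entries keep their signed values).
#' @export
sparsify_rows <- function(C, sparsity = 0.9, rank_by = c("value", "magnitude")) {
  rank_by <- match.arg(rank_by)
  check_matrix(C, "connectivity")
  if (!is.numeric(sparsity) || length(sparsity) != 1L ||
      sparsity < 0 || sparsity >= 1) {
    gfp_stop("sparsity must lie in [0, 1), got ", sparsity)
  }
  V <- ncol(C)
  m <- as.integer(ceiling((1 - sparsity) * V))
  out <- matrix(0, nrow(C), V, dimnames = dimnames(C))
  for (i in seq_len(nrow(C))) {
    row <- C[i, ]
    key <- if (rank_by == "magnitude") abs(row) else row
    # radix order is stable: ties keep ascending index, i.e. lowest index wins
    keep <- order(key, decreasing = TRUE, method = "radix")[seq_len(m)]
    out[i, keep] <- row[keep]
  }
  out
}

#' Cosine affinity between sparsified connectivity profiles
#'
#' Entry (i, j) is the cosine of the angle between rows i and j of the
#' sparsified connectivity matrix. The result is symmetric with unit diagonal
#' and entries in `[-1, 1]`.
#'
#' @param M numeric V x V matrix of sparsified connectivity rows.
#' @return A V x V `affinity_matrix`.
#' @export
cosine_affinity <- function(M) {
  check_matrix(M, "sparsified connectivity")
  norms <- sqrt(rowSums(M^2))
  zero <- which(norms == 0)
  if (length(zero) > 0L) {
    gfp_stop(
      "degenerate vertex with all-zero connectivity profile at (0-based) ",
      paste(zero - 1L, collapse = ", ")
    )
  }
  A <- tcrossprod(M / norms)
  A <- (A + t(A)) / 2
  A[A > 1] <- 1
  A[A < -1] <- -1
  diag(A) <- 1
  structure(A, class = c("affinity_matrix", class(A)))
}

# Fix component signs deterministically: the element of largest magnitude in
# each column is made positive (first index wins on exact ties).
fix_signs <- function(scores) {
  for (c in seq_len(ncol(scores))) {
    j <- which.max(abs(scores[, c]))
    if (scores[j, c] < 0) scores[, c] <- -scores[, c]
  }
  scores
}

new_gradient_set <- function(scores, explained_variance, embedding,
                             aligned = FALSE, degenerate = FALSE) {
  structure(
    list(
      scores = unname(scores),
      explained_variance = as.numeric(explained_variance),
      embedding = embedding,
      aligned = aligned,
      degenerate = degenerate
    ),
    class = "gradient_set"
  )
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf(
    "<gradient_set> %d vertices x %d components (%s%s)\n",
    nrow(x$scores), ncol(x$scores), x$embedding,
    if (x$aligned) ", aligned" else ""
  ))
  cat("explained variance:",
      paste(sprintf("%.3f", x$explained_variance), collapse = " "), "\n")
  invisible(x)
}

#' Principal-component gradients of an affinity matrix
#'
#' Columns of the affinity matrix are mean-centred and the rows projected onto
#' the top-k right singular vectors; the projections are the per-vertex
#' gradient coefficient scores. Explained variance fractions are singular
#' values squared over their total across the full spectrum.
#'
#' @param A V x V affinity matrix (signed affinities are used as-is).
#' @param k number of components to extract (default 5).
#' @return A `gradient_set` with `scores` (V x k), `explained_variance`
#'   (length-k fractions), `embedding = "pca"`. Component signs follow the
#'   convention that each column's largest-magnitude element is positive;
#'   downstream alignment supersedes this.
#' @export
pca_gradients <- function(A, k = 5L) {
  check_matrix(A, "affinity")
  V <- ncol(A)
  if (!is_count(k) || k > V) gfp_stop("k must be a positive integer <= V")
  k <- as.integer(k)
  Ac <- scale(A, center = TRUE, scale = FALSE)
  # eigen of the Gram matrix: eigenvalues are squared singular values of Ac
  e <- eigen(crossprod(Ac), symmetric = TRUE)
  evals <- pmax(e$values, 0)
  total <- sum(evals)
  scores <- Ac %*% e$vectors[, seq_len(k), drop = FALSE]
  ev <- if (total > 0) evals[seq_len(k)] / total else rep(0, k)
  degenerate <- total == 0
  new_gradient_set(fix_signs(scores), ev, "pca", degenerate = degenerate)
}

#' Diffusion-map gradients of an affinity matrix
#'
#' Builds a Markov operator from the (non-negative part of the) affinity
#' matrix with anisotropic alpha-normalisation and takes its leading
#' non-trivial eigenvectors as gradients. Negative affinities are clipped to
#' zero, as a transition kernel must be non-negative. With
#' `diffusion_time = 0` eigenvectors are scaled by `lambda / (1 - lambda)`
#' (the multi-scale convention); with `diffusion_time = t > 0` by `lambda^t`.
#'
#' @param A V x V symmetric affinity matrix.
#' @param k number of non-trivial components (default 5).
#' @param alpha anisotropic diffusion parameter in `[0, 1]`; 0.5 (default)
#'   approximates the Fokker-Planck diffusion, 0 the classical random walk.
#' @param diffusion_time non-negative scale parameter; 0 selects the
#'   multi-scale `lambda / (1 - lambda)` weighting.
#' @return A `gradient_set` with `embedding = "diffusion"`. Explained-variance
#'   fractions are eigenvalue magnitudes normalised over the retained
#'   spectrum. A flat affinity graph whose non-trivial spectrum vanishes is
#'   flagged `degenerate = TRUE` (all scores constant).
#' @export
diffusion_gradients <- function(A, k = 5L, alpha = 0.5, diffusion_time = 0) {
  check_matrix(A, "affinity")
  V <- ncol(A)
  if (!is_count(k) || k > V - 1L) {
    gfp_stop("k must be a positive integer <= V - 1")
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    gfp_stop("alpha must lie in [0, 1]")
  }
  if (!is.numeric(diffusion_time) || diffusion_time < 0) {
    gfp_stop("diffusion_time must be non-negative")
  }
  if (max(abs(A - t(A))) > 1e-10) gfp_stop("affinity must be symmetric")
  k <- as.integer(k)
  W <- pmax(unclass(A), 0)
  d <- rowSums(W)
  if (any(d == 0)) {
    gfp_stop(
      "disconnected affinity graph: zero row after clipping at (0-based) ",
      paste(which(d == 0) - 1L, collapse = ", ")
    )
  }
  # anisotropic normalisation W' = D^-alpha W D^-alpha
  da <- d^(-alpha)
  W1 <- W * outer(da, da)
  d1 <- rowSums(W1)
  # P = D1^-1 W1 is similar to the symmetric M = D1^-1/2 W1 D1^-1/2,
  # so its spectrum is real and computed stably from M.
  s <- 1 / sqrt(d1)
  M <- W1 * outer(s, s)
  # The trivial eigenpair is known exactly: M %*% sqrt(d1) = sqrt(d1) with
  # eigenvalue 1. Deflating it before the decomposition keeps the non-trivial
  # eigenvectors orthogonal to the stationary direction even when the leading
  # eigenvalue is (near-)degenerate, e.g. for strongly block-structured
  # affinities.
  u <- sqrt(d1) / sqrt(sum(d1))
  e <- eigen(M - outer(u, u), symmetric = TRUE)
  # guard against the deflated (eigenvalue 0) trivial direction re-entering
  keep <- which(abs(crossprod(e$vectors, u)) < 0.99)[seq_len(k)]
  # eigenvectors of P: psi = D1^-1/2 v, scaled to unit d1-weighted RMS
  psi <- (e$vectors[, keep, drop = FALSE] * s) * sqrt(sum(d1))
  lam_k <- e$values[keep]
  scaling <- if (diffusion_time == 0) {
    ifelse(abs(1 - lam_k) < 1e-14, 0, lam_k / (1 - lam_k))
  } else {
    lam_k^diffusion_time
  }
  scores <- sweep(psi, 2L, scaling, `*`)
  denom <- sum(abs(lam_k))
  ev <- if (denom > 0) abs(lam_k) / denom else rep(0, k)
  degenerate <- all(apply(scores, 2L, stats::sd) < 1e-12)
  new_gradient_set(fix_signs(scores), ev, "diffusion", degenerate = degenerate)
}

#' Compute gradients for one scan
#'
#' Convenience wrapper chaining [compute_connectivity()], [sparsify_rows()],
#' [cosine_affinity()] and the chosen decomposition.
#'
#' @param x T x V time-series matrix, or a precomputed `connectivity_matrix`.
#' @param sparsity row-wise sparsity fraction (default 0.9).
#' @param n_components components to extract (default 5).
#' @param embedding `"pca"` (default) or `"diffusion"`.
#' @param alpha,diffusion_time passed to [diffusion_gradients()].
#' @param zero_diagonal if `TRUE`, zero the connectivity diagonal before
#'   sparsification so self-correlation does not consume a retained slot;
#'   default `FALSE` keeps the diagonal in play.
#' @param rank_by passed to [sparsify_rows()].
#' @return A `gradient_set`.
#' @export
scan_gradients <- function(x, sparsity = 0.9, n_components = 5L,
                           embedding = c("pca", "diffusion"), alpha = 0.5,
                           diffusion_time = 0, zero_diagonal = FALSE,
                           rank_by = "value") {
  embedding <- match.arg(embedding)
  C <- if (inherits(x, "connectivity_matrix")) x else compute_connectivity(x)
  if (zero_diagonal) diag(C) <- 0
  S <- sparsify_rows(C, sparsity, rank_by = rank_by)
  A <- cosine_affinity(S)
  if (embedding == "pca") {
    pca_gradients(A, n_components)
  } else {
    diffusion_gradients(A, n_components, alpha = alpha,
                        diffusion_time = diffusion_time)
  }
}
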