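# Connectome fingerprinting: pairwise spatial similarity, winner-take-all
# identification, permutation significance, within/between ratios, and the
# repeated-measures ANOVA on the ratio.

extract_score_matrix <- function(sets, gradient_index) {
  mats <- lapply(sets, function(s) {
    sc <- if (inherits(s, "gradient_set")) s$scores else s
    sc[, gradient_index, drop = FALSE]
  })
  do.call(cbind, mats) # V x N, one column per subject
}

#' Between-subject spatial similarity matrix for one gradient
#'
#' Entry (i, j) is the Pearson correlation between target-session subject i's
#' and reference-session subject j's gradient score vector, optionally
#' restricted to a vertex mask (e.g. one network's vertices).
#'
#' @param ref_sets,target_sets lists of per-subject `gradient_set`s for the
#'   reference and target sessions, in the same subject order.
#' @param gradient_index which component to compare (default 1).
#' @param vertex_mask optional integer vector of 1-based vertex indices (or a
#'   logical V-vector) restricting the correlation; must keep >= 3 vertices.
#' @param session_pair optional length-2 character `(reference, target)`
#'   labels, carried as metadata.
#' @return A `similarity_matrix`: N x N numeric matrix (rows = target
#'   subjects, columns = reference subjects) with attributes `gradient_index`,
#'   `session_pair` and `vertex_mask`.
#' @export
similarity_matrix <- function(ref_sets, target_sets, gradient_index = 1L,
                              vertex_mask = NULL, session_pair = NULL) {
  if (length(ref_sets) != length(target_sets)) {
    gfp_stop("reference and target sessions must cover the same subjects")
  }
  N <- length(ref_sets)
  if (N < 2L) gfp_stop("need at least 2 subjects")
  refM <- extract_score_matrix(ref_sets, gradient_index)
  tarM <- extract_score_matrix(target_sets, gradient_index)
  if (!is.null(vertex_mask)) {
    if (is.logical(vertex_mask)) vertex_mask <- which(vertex_mask)
    if (length(vertex_mask) < 3L) {
      gfp_stop("vertex mask must keep at least 3 vertices")
    }
    refM <- refM[vertex_mask, , drop = FALSE]
    tarM <- tarM[vertex_mask, , drop = FALSE]
  }
  degenerate <- c(which(apply(refM, 2L, stats::sd) == 0),
                  which(apply(tarM, 2L, stats::sd) == 0))
  if (length(degenerate) > 0L) {
    gfp_stop(
      "constant gradient score vector (Pearson undefined) for subject(s) ",
      paste(sort(unique(degenerate)), collapse = ", ")
    )
  }
  S <- stats::cor(tarM, refM) # rows = target subjects, cols = reference
  S[S > 1] <- 1
  S[S < -1] <- -1
  structure(S,
    class = c("similarity_matrix", class(S)),
    gradient_index = gradient_index,
    session_pair = session_pair,
    vertex_mask = vertex_mask
  )
}

#' Winner-take-all subject identification
#'
#' Each target-session subject is assigned the reference-session subject with
#' the highest spatial similarity; accuracy is the fraction of correct
#' self-matches. Exact ties at the maximum break to the lowest column index
#' and are flagged.
#'
#' @param S an N x N `similarity_matrix` (rows = target, columns = reference).
#' @return An `identification_result`: list with `accuracy`, `predicted`
#'   (per-row argmax), `n_correct`, `n`, `ties` (logical), plus null/p fields
#'   filled in by [permutation_null()].
#' @export
identification <- function(S) {
  check_matrix(unclass(S), "similarity matrix")
  N <- nrow(S)
  if (N < 2L || ncol(S) != N) gfp_stop("similarity matrix must be N x N, N >= 2")
  predicted <- apply(S, 1L, which.max) # which.max breaks ties to lowest index
  ties <- any(apply(S, 1L, function(r) sum(r == max(r)) > 1L))
  n_correct <- sum(predicted == seq_len(N))
  structure(
    list(
      accuracy = n_correct / N,
      predicted = as.integer(predicted),
      n_correct = as.integer(n_correct),
      n = as.integer(N),
      ties = ties,
      null_accuracies = NULL,
      p_raw = NA_real_,
      p_literal = NA_real_,
      p_bonferroni = NA_real_
    ),
    class = "identification_result"
  )
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("<identification_result> accuracy %d/%d = %.3f", x$n_correct,
              x$n, x$accuracy))
  if (!is.na(x$p_raw)) cat(sprintf(", p = %.4g", x$p_raw))
  cat("\n")
  invisible(x)
}

#' Permutation null distribution for identification accuracy
#'
#' Holds the winner-take-all predictions fixed and permutes the subject
#' labels: for each permuted labelling, the null accuracy is the fraction of
#' rows whose fixed argmax matches the permuted identity. The p-value uses
#' add-one smoothing, `p = (1 + #\{null >= observed\}) / (n_perm + 1)`, so it
#' is never zero; the literal proportion `#\{null >= observed\} / n_perm` is
#' also reported. "At least as extreme" is `>=`.
#'
#' @param S an N x N `similarity_matrix`.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param method `"sample"` (default) draws `n_perm` uniform permutations;
#'   `"exhaustive"` enumerates all N! permutations (N <= 7) and ignores
#'   `n_perm` and `seed`.
#' @return The `identification_result` for `S` with `null_accuracies`,
#'   `p_raw`, `p_literal` filled in (`p_bonferroni` is left for the caller,
#'   who knows the comparison count; see [bonferroni()]).
#' @export
permutation_null <- function(S, n_perm = 1000L, seed = 1L,
                             method = c("sample", "exhaustive")) {
  method <- match.arg(method)
  res <- identification(S)
  N <- res$n
  pred <- res$predicted
  if (method == "exhaustive") {
    if (N > 7L) gfp_stop("exhaustive enumeration is limited to N <= 7")
    perms <- all_permutations(N)
    null_acc <- vapply(perms, function(p) mean(pred == p), numeric(1))
    # exhaustive null: p is the exact proportion at least as extreme
    p_literal <- mean(null_acc >= res$accuracy)
    p_raw <- p_literal
  } else {
    if (!is_count(n_perm)) gfp_stop("n_perm must be a positive integer")
    rng <- local({
      set.seed(seed)
      replicate(n_perm, mean(pred == sample.int(N)))
    })
    null_acc <- rng
    k <- sum(null_acc >= res$accuracy)
    p_raw <- (1 + k) / (n_perm + 1)
    p_literal <- k / n_perm
  }
  res$null_accuracies <- null_acc
  res$p_raw <- p_raw
  res$p_literal <- p_literal
  res
}

# All permutations of 1..n as a list (n small).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[idx]] <- append(p, n, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}

#' Bonferroni adjustment
#'
#' @param p numeric vector of raw p-values in `(0, 1]`.
#' @param m number of comparisons (default `length(p)`).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    gfp_stop("p-values must lie in (0, 1]")
  }
  if (!is_count(m)) gfp_stop("m must be a positive integer")
  pmin(1, p * m)
}

#' Within- and between-subject similarity summary and per-subject ratios
#'
#' The matrix-level summary averages the diagonal (within-subject test-retest
#' similarity) and all off-diagonal entries (between-subject similarity). The
#' per-subject ratio divides a subject's diagonal entry by the mean of the
#' off-diagonal entries in that subject's row and column; a ratio above 1
#' marks individual uniqueness.
#'
#' @param S an N x N `similarity_matrix`.
#' @return List with `within` (mean diagonal), `between` (mean off-diagonal),
#'   `ratio` (`within/between`), and `per_subject`, a data frame of
#'   `(subject, within_r, between_r, ratio)`.
#' @export
within_between_ratios <- function(S) {
  check_matrix(unclass(S), "similarity matrix")
  N <- nrow(S)
  if (N < 2L) gfp_stop("need at least 2 subjects")
  diag_vals <- diag(S)
  off <- unclass(S)
  diag(off) <- NA
  between_all <- mean(off, na.rm = TRUE)
  per <- vapply(seq_len(N), function(i) {
    vals <- c(off[i, ], off[, i])
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  if (any(per == 0)) {
    gfp_stop(
      "between-subject mean is 0 for subject(s) ",
      paste(which(per == 0), collapse = ", "), "; ratio undefined"
    )
  }
  list(
    within = mean(diag_vals),
    between = between_all,
    ratio = mean(diag_vals) / between_all,
    per_subject = data.frame(
      subject = seq_len(N),
      within_r = diag_vals,
      between_r = per,
      ratio = diag_vals / per
    )
  )
}

#' Repeated-measures ANOVA on within/between ratios
#'
#' Classical two-factor within-subject ANOVA of the per-subject ratio with
#' gradient and time interval as repeated factors: each effect is tested
#' against its effect-by-subject interaction mean square (the `aov`
#' `Error(subject/(gradient * interval))` stratification). Post-hoc paired
#' comparisons between gradient levels (averaged over intervals within
#' subject) are Bonferroni-adjusted.
#'
#' @param ratios data frame with columns `subject`, `gradient`, `interval`,
#'   `ratio`; must be complete and balanced (every subject x gradient x
#'   interval cell present exactly once).
#' @return An `anova_result`: list with `F_gradient`, `F_interval`,
#'   `F_interaction` (each a list of `F`, `df1`, `df2`, `p`), `posthoc` data
#'   frame (`pair`, `mean_difference`, `se`, `p_raw`, `p_bonferroni`), and
#'   `degenerate` flag (TRUE when the response has no variance at all, in
#'   which case F values are reported as 0).
#' @export
rm_anova <- function(ratios) {
  req <- c("subject", "gradient", "interval", "ratio")
  if (!all(req %in% names(ratios))) {
    gfp_stop("ratios must have columns ", paste(req, collapse = ", "))
  }
  d <- data.frame(
    subject = factor(ratios$subject),
    gradient = factor(ratios$gradient),
    interval = factor(ratios$interval),
    ratio = as.numeric(ratios$ratio)
  )
  counts <- table(d$subject, d$gradient, d$interval)
  if (any(counts != 1L)) {
    gfp_stop("design must be complete and balanced: every subject x gradient",
             " x interval cell exactly once (no imputation)")
  }
  degenerate <- stats::var(d$ratio) == 0
  if (degenerate) {
    zero <- list(F = 0, df1 = NA_integer_, df2 = NA_integer_, p = NA_real_)
    return(structure(
      list(F_gradient = zero, F_interval = zero, F_interaction = zero,
           posthoc = NULL, degenerate = TRUE),
      class = "anova_result"
    ))
  }
  fit <- stats::aov(
    ratio ~ gradient * interval + Error(subject / (gradient * interval)),
    data = d
  )
  sm <- summary(fit)
  total_ss <- sum((d$ratio - mean(d$ratio))^2)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1L]]
    row <- trimws(rownames(tab)) == term
    Fv <- tab[row, "F value"]
    # an effect whose sum of squares is numerically nil (relative to the
    # total) is a true null: report F = 0 rather than 0/0 round-off noise;
    # a genuine effect with zero error variance keeps F = Inf
    if (tab[row, "Sum Sq"] < 1e-12 * total_ss) Fv <- 0
    list(
      F = if (is.nan(Fv)) 0 else Fv,
      df1 = tab[row, "Df"],
      df2 = tab[trimws(rownames(tab)) == "Residuals", "Df"],
      p = tab[row, "Pr(>F)"]
    )
  }
  F_gradient <- pull("Error: subject:gradient", "gradient")
  F_interval <- pull("Error: subject:interval", "interval")
  F_interaction <- pull("Error: subject:gradient:interval", "gradient:interval")

  # post-hoc: paired comparisons between gradient levels on the per-subject
  # means over intervals
  means <- stats::aggregate(ratio ~ subject + gradient, data = d, FUN = mean)
  levs <- levels(d$gradient)
  pairs <- utils::combn(levs, 2L, simplify = FALSE)
  posthoc <- do.call(rbind, lapply(pairs, function(pr) {
    a <- means$ratio[means$gradient == pr[1L]][order(means$subject[means$gradient == pr[1L]])]
    b <- means$ratio[means$gradient == pr[2L]][order(means$subject[means$gradient == pr[2L]])]
    diffs <- a - b
    se <- stats::sd(diffs) / sqrt(length(diffs))
    p <- if (se < 1e-12 * max(1, abs(mean(diffs)))) {
      # no variability in the paired differences: p degenerates
      if (abs(mean(diffs)) < 1e-12) 1 else NA_real_
    } else {
      stats::t.test(diffs)$p.value
    }
    data.frame(
      pair = paste(pr, collapse = " vs "),
      mean_difference = mean(diffs),
      se = se,
      p_raw = p,
      stringsAsFactors = FALSE
    )
  }))
  posthoc$p_bonferroni <- pmin(1, posthoc$p_raw * length(pairs))
  structure(
    list(F_gradient = F_gradient, F_interval = F_interval,
         F_interaction = F_interaction, posthoc = posthoc,
         degenerate = FALSE),
    class = "anova_result"
  )
}
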