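# Per-network fingerprinting, heteromodal vs unimodal comparison, gradient
# dispersion, dispersion-accuracy partial correlation, and multi-gradient
# concatenation.

#' Per-network winner-take-all identification
#'
#' Restricts the similarity computation to each included network's vertices
#' and runs identification separately, quantifying how much individual
#' signature each network carries. Excluded networks are skipped.
#'
#' @param ref_sets,target_sets per-subject `gradient_set` lists (same order).
#' @param parc a `parcellation`.
#' @param gradient_index which component to fingerprint.
#' @return Named list of `identification_result`, one per included network.
#' @export
network_identification <- function(ref_sets, target_sets, parc,
                                   gradient_index = 1L) {
  stopifnot(inherits(parc, "parcellation"))
  nets <- included_networks(parc)
  small <- nets[vapply(nets, function(n) length(network_mask(parc, n)) < 3L,
                       logical(1))]
  if (length(small) > 0L) {
    gfp_stop("network(s) with fewer than 3 vertices: ",
             paste(small, collapse = ", "))
  }
  out <- lapply(nets, function(n) {
    S <- similarity_matrix(ref_sets, target_sets, gradient_index,
                           vertex_mask = network_mask(parc, n))
    identification(S)
  })
  stats::setNames(out, nets)
}

#' Dispersion of gradient scores within a network
#'
#' Dispersion is the unbiased sample variance (denominator n - 1) of the
#' gradient coefficient scores of a network's vertices on one component. High
#' dispersion means the network spreads broadly along the gradient
#' (integration); low dispersion means a tight, segregated score range.
#'
#' @param set a `gradient_set` (or V x k matrix).
#' @param parc a `parcellation`.
#' @param network network name (must be included, >= 2 vertices).
#' @param gradient_index component index.
#' @return The sample variance (unitless squared score units).
#' @export
network_dispersion <- function(set, parc, network, gradient_index = 1L) {
  scores <- if (inherits(set, "gradient_set")) set$scores else set
  mask <- network_mask(parc, network)
  if (!parc$networks$included[parc$networks$name == network]) {
    gfp_stop("network ", network, " is excluded from analysis")
  }
  if (length(mask) < 2L) gfp_stop("network ", network, " has < 2 vertices")
  stats::var(scores[mask, gradient_index])
}

#' Paired signed-rank comparison of heteromodal vs unimodal accuracy
#'
#' For each gradient, compares class-mean identification accuracies of
#' heteromodal and unimodal networks with a Wilcoxon signed-rank test, paired
#' across the interval conditions (default) or pooled across all
#' gradient-by-interval conditions in a single test. Zero differences are
#' dropped (classical Wilcoxon rule); if all differences are zero the test is
#' degenerate and reported with p = 1. P-values are Bonferroni-adjusted over
#' the gradients tested.
#'
#' @param records data frame with columns `network`, `class` (`"heteromodal"`
#'   or `"unimodal"`), `gradient_index`, `interval`, `accuracy` (one row per
#'   network x gradient x interval).
#' @param pairing `"interval"` (default; one test per gradient, pairs are the
#'   interval conditions) or `"pooled"` (one test, pairs are all gradient x
#'   interval conditions).
#' @param alternative passed to [stats::wilcox.test()]; default `"two.sided"`.
#' @return Data frame of `stat_result` rows: `gradient_index` (NA for
#'   pooled), `statistic` (V, sum of positive-difference ranks), `p_raw`,
#'   `p_bonferroni`, `n` (non-zero pairs), `method`.
#' @export
class_comparison <- function(records, pairing = c("interval", "pooled"),
                             alternative = "two.sided") {
  pairing <- match.arg(pairing)
  req <- c("network", "class", "gradient_index", "interval", "accuracy")
  if (!all(req %in% names(records))) {
    gfp_stop("records must have columns ", paste(req, collapse = ", "))
  }
  if (!all(c("heteromodal", "unimodal") %in% records$class)) {
    gfp_stop("both heteromodal and unimodal networks are required")
  }
  class_means <- function(sub) {
    het <- stats::aggregate(accuracy ~ interval,
                            data = sub[sub$class == "heteromodal", ], FUN = mean)
    uni <- stats::aggregate(accuracy ~ interval,
                            data = sub[sub$class == "unimodal", ], FUN = mean)
    merge(het, uni, by = "interval", suffixes = c("_het", "_uni"))
  }
  run_one <- function(x, y, gradient_index) {
    res <- paired_signed_rank(x, y, alternative = alternative)
    data.frame(
      gradient_index = gradient_index,
      statistic = res$statistic,
      p_raw = res$p,
      n = res$n,
      method = "Wilcoxon signed-rank",
      stringsAsFactors = FALSE
    )
  }
  if (pairing == "pooled") {
    cm <- do.call(rbind, lapply(split(records, records$gradient_index),
                                class_means))
    out <- run_one(cm$accuracy_het, cm$accuracy_uni, NA_integer_)
    out$p_bonferroni <- pmin(1, out$p_raw)
    return(out)
  }
  grads <- sort(unique(records$gradient_index))
  out <- do.call(rbind, lapply(grads, function(g) {
    cm <- class_means(records[records$gradient_index == g, ])
    run_one(cm$accuracy_het, cm$accuracy_uni, g)
  }))
  out$p_bonferroni <- pmin(1, out$p_raw * length(grads))
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Thin wrapper over [stats::wilcox.test()] that applies the classical
#' zero-difference rule explicitly: zero differences are dropped before
#' ranking, and if none remain the comparison is degenerate with `p = 1` and
#' statistic 0.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `statistic` (V), `p`, `n` (non-zero pairs), `degenerate`.
#' @export
paired_signed_rank <- function(x, y, alternative = "two.sided") {
  if (length(x) != length(y)) gfp_stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) {
    return(list(statistic = 0, p = 1, n = 0L, degenerate = TRUE))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(d, alternative = alternative, exact = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value, n = length(d),
       degenerate = FALSE)
}

#' Partial correlation between network dispersion and identification accuracy
#'
#' Residualises both percent accuracy and mean dispersion on the network
#' vertex count by least squares and correlates the residuals, testing
#' whether broader spread along a gradient predicts a more identifiable
#' network beyond sheer network size. The p-value comes from the t
#' distribution with n - 3 degrees of freedom.
#'
#' @param records data frame with one row per point (typically network x
#'   gradient for one interval): columns `accuracy` (fraction or percent;
#'   correlation is scale-invariant so either works, percent is conventional),
#'   `dispersion`, `vertex_count`. At least 5 rows.
#' @param m_comparisons Bonferroni multiplier (default 4: two time intervals
#'   by two parcellation schemes).
#' @return A `stat_result` list: `statistic` (partial r), `p_raw`,
#'   `p_bonferroni`, `df`, `n`, `method`.
#' @export
dispersion_accuracy_partial <- function(records, m_comparisons = 4L) {
  req <- c("accuracy", "dispersion", "vertex_count")
  if (!all(req %in% names(records))) {
    gfp_stop("records must have columns ", paste(req, collapse = ", "))
  }
  n <- nrow(records)
  if (n < 5L) gfp_stop("need at least 5 records, got ", n)
  acc <- as.numeric(records$accuracy) * 100 # percent, cosmetic
  disp <- as.numeric(records$dispersion)
  vc <- as.numeric(records$vertex_count)
  rx <- stats::resid(stats::lm(acc ~ vc))
  ry <- stats::resid(stats::lm(disp ~ vc))
  if (stats::sd(rx) < 1e-10 * max(1, stats::sd(acc)) ||
      stats::sd(ry) < 1e-10 * max(1, stats::sd(disp))) {
    gfp_stop("zero variance after residualising on vertex count")
  }
  r <- stats::cor(rx, ry)
  df <- n - 3L
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(
    statistic = r,
    p_raw = p,
    p_bonferroni = min(1, p * m_comparisons),
    df = df,
    n = n,
    method = "partial Pearson correlation (residualised on vertex count)"
  )
}

#' Stack the first k gradients into one fingerprint vector per subject
#'
#' Concatenates components 1..`k_used` vertex-major into a single length
#' `V * k_used` vector per subject, pooling the spatial information of
#' several gradients into one fingerprint.
#'
#' @param sets list of per-subject `gradient_set`s.
#' @param k_used number of leading components to stack (>= 1).
#' @return List of numeric vectors, one per subject.
#' @export
concatenate_gradients <- function(sets, k_used) {
  if (!is_count(k_used)) gfp_stop("k_used must be a positive integer")
  lapply(sets, function(s) {
    sc <- if (inherits(s, "gradient_set")) s$scores else s
    if (k_used > ncol(sc)) gfp_stop("k_used exceeds available components")
    as.vector(sc[, seq_len(k_used), drop = FALSE])
  })
}

#' Similarity matrix over concatenated multi-gradient fingerprints
#'
#' @param ref_sets,target_sets per-subject `gradient_set` lists.
#' @param k_used number of leading components concatenated per subject.
#' @return A `similarity_matrix` over the stacked vectors (rows = target
#'   subjects), with `gradient_index` attribute `"concat"`.
#' @export
concatenated_similarity <- function(ref_sets, target_sets, k_used) {
  refV <- do.call(cbind, concatenate_gradients(ref_sets, k_used))
  tarV <- do.call(cbind, concatenate_gradients(target_sets, k_used))
  S <- stats::cor(tarV, refV)
  S[S > 1] <- 1
  S[S < -1] <- -1
  structure(S,
    class = c("similarity_matrix", class(S)),
    gradient_index = "concat",
    session_pair = NULL,
    vertex_mask = NULL
  )
}
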