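# Multi-subject multi-session synthetic connectome generator with known
# ground truth: a group gradient template with network block structure,
# subject-specific signatures concentrated in configurable networks, session
# noise, and low-rank latent time series.

#' Specify one synthetic network
#'
#' @param name network name.
#' @param class `"heteromodal"` (higher-order associative) or `"unimodal"`
#'   (primary sensory/motor).
#' @param fraction proportion of vertices assigned to this network.
#' @param centers length-k vector: mean gradient score per component.
#' @param dispersion length-k non-negative vector: within-network score
#'   standard deviation per component (scalars are recycled).
#' @param signature_strength non-negative scalar scaling the subject-specific
#'   gradient perturbation within this network; 0 means the network carries
#'   no individual signature.
#' @return A `network_spec`.
#' @export
network_spec <- function(name, class = c("heteromodal", "unimodal"),
                         fraction, centers, dispersion,
                         signature_strength = 1) {
  class <- match.arg(class)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    gfp_stop("fraction must lie in (0, 1]")
  }
  k <- length(centers)
  dispersion <- rep_len(dispersion, k)
  if (any(dispersion < 0)) gfp_stop("dispersion must be non-negative")
  if (signature_strength < 0) gfp_stop("signature_strength must be >= 0")
  structure(
    list(name = name, class = class, fraction = fraction,
         centers = as.numeric(centers), dispersion = as.numeric(dispersion),
         signature_strength = signature_strength),
    class = "network_spec"
  )
}

#' Default six-network layout
#'
#' A canonical cortical layout with four heteromodal networks (default-mode,
#' frontoparietal, dorsal-attention, ventral-attention) and two unimodal ones
#' (somatomotor, visual). Centres place the default-mode network at one end
#' of the principal gradient and the somatomotor/visual networks at the
#' other; the second component separates visual from somatomotor and the
#' third tracks task-positive vs default-mode. Heteromodal networks get
#' higher within-network dispersion and stronger subject signatures, so the
#' generated data carry individual uniqueness predominantly in heteromodal
#' cortex.
#'
#' @param k number of components (>= 3; components beyond 3 get zero centres
#'   and a small common dispersion).
#' @return List of `network_spec`s with fractions summing to 1.
#' @export
default_network_specs <- function(k = 5L) {
  stopifnot(k >= 3L)
  pad <- function(v) c(v, rep(0, k - 3L))
  disp <- function(s) c(rep(s, 3L), rep(0.3, k - 3L))
  list(
    network_spec("DMN", "heteromodal", 0.24, pad(c( 1.2,  0.1, -0.8)), disp(0.7), 1.5),
    network_spec("FPN", "heteromodal", 0.15, pad(c( 0.6,  0.0,  0.8)), disp(0.7), 1.5),
    network_spec("DAN", "heteromodal", 0.15, pad(c(-0.2,  0.3,  0.6)), disp(0.7), 1.2),
    network_spec("VAN", "heteromodal", 0.13, pad(c( 0.1,  0.4,  0.2)), disp(0.7), 1.2),
    network_spec("SMN", "unimodal",    0.18, pad(c(-1.0, -1.0,  0.0)), disp(0.35), 0.5),
    network_spec("VN",  "unimodal",    0.15, pad(c(-1.0,  1.0, -0.1)), disp(0.35), 0.5)
  )
}

#' Network layout where subject signature tracks dispersion
#'
#' Six networks whose within-network dispersion spans a wide range and whose
#' subject signature strength is exactly proportional to that dispersion
#' (constant of proportionality 1). Designed for parameter-recovery
#' experiments on the dispersion-accuracy association: networks with low
#' dispersion sit near the absolute session-noise floor, networks with high
#' dispersion rise well above it, giving the accuracy-dispersion point cloud
#' genuine dynamic range. Vertex fractions are deliberately unequal so the
#' vertex-count covariate is non-degenerate.
#'
#' @param k number of components.
#' @return List of `network_spec`s.
#' @export
dispersion_linked_specs <- function(k = 5L) {
  disps <- c(0.9, 0.75, 0.55, 0.4, 0.25, 0.15)
  fracs <- c(0.24, 0.13, 0.20, 0.11, 0.17, 0.15)
  classes <- c("heteromodal", "heteromodal", "heteromodal", "heteromodal",
               "unimodal", "unimodal")
  centers <- list(c(1.2, 0.1, -0.8), c(0.6, 0, 0.8), c(-0.2, 0.3, 0.6),
                  c(0.1, 0.4, 0.2), c(-1, -1, 0), c(-1, 1, -0.1))
  names <- c("N1", "N2", "N3", "N4", "N5", "N6")
  lapply(seq_along(names), function(i) {
    network_spec(names[i], classes[i], fracs[i],
                 c(centers[[i]], rep(0, k - 3L)),
                 c(rep(disps[i], 3L), rep(min(disps[i], 0.3), k - 3L)),
                 signature_strength = disps[i])
  })
}

#' Synthetic study configuration
#'
#' Defaults emulate a 30-subject, 3-session test-retest study (sessions
#' labelled day1/day3/day30 for the short and long retest intervals) at desk
#' scale: 1000 vertices, 300 timepoints, 5 latent components.
#'
#' @param n_subjects number of subjects (default 30).
#' @param n_sessions number of sessions (default 3).
#' @param n_vertices vertex count V (default 1000).
#' @param n_timepoints timepoints T per scan (default 300); must exceed
#'   `n_components`.
#' @param n_components latent components k (default 5).
#' @param network_specs list of `network_spec`s with fractions summing to 1.
#' @param sigma_subject scale of the stable subject-specific gradient
#'   perturbation (score units; multiplied per-vertex by the owning network's
#'   `signature_strength`). Default 0.5.
#' @param sigma_session scale of the session-to-session gradient wobble
#'   (default 0.1).
#' @param sigma_observation timepoint noise standard deviation added on top
#'   of the latent signal (default 1).
#' @param session_labels optional character vector of session names.
#' @param seed master seed; all generator randomness derives from it via
#'   named substreams.
#' @return A validated `synth_config`.
#' @export
synth_config <- function(n_subjects = 30L, n_sessions = 3L,
                         n_vertices = 1000L, n_timepoints = 300L,
                         n_components = 5L,
                         network_specs = default_network_specs(n_components),
                         sigma_subject = 0.5, sigma_session = 0.1,
                         sigma_observation = 1,
                         session_labels = NULL, seed = 1L) {
  for (nm in c("n_subjects", "n_sessions", "n_vertices", "n_timepoints",
               "n_components")) {
    if (!is_count(get(nm))) gfp_stop(nm, " must be a positive integer")
  }
  if (n_timepoints <= n_components) {
    gfp_stop("n_timepoints must exceed n_components for a full-rank latent ",
             "covariance")
  }
  sig <- c(sigma_subject, sigma_session, sigma_observation)
  if (any(!is.finite(sig)) || any(sig < 0)) {
    gfp_stop("all sigma parameters must be finite and >= 0")
  }
  fr <- vapply(network_specs, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9) {
    gfp_stop("network fractions must sum to 1, got ", sum(fr))
  }
  if (is.null(session_labels)) {
    session_labels <- if (n_sessions == 3L) {
      c("day1", "day3", "day30")
    } else {
      paste0("ses", seq_len(n_sessions))
    }
  }
  if (length(session_labels) != n_sessions ||
      anyDuplicated(session_labels) > 0L) {
    gfp_stop("session_labels must be ", n_sessions, " unique labels")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_sessions = as.integer(n_sessions),
         n_vertices = as.integer(n_vertices),
         n_timepoints = as.integer(n_timepoints),
         n_components = as.integer(n_components),
         network_specs = network_specs,
         sigma_subject = sigma_subject, sigma_session = sigma_session,
         sigma_observation = sigma_observation,
         session_labels = session_labels, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Block parcellation from network specs
#'
#' Assigns contiguous vertex blocks to networks in layout order: each network
#' gets `round(fraction * V)` vertices, with any rounding remainder absorbed
#' by the last network.
#'
#' @param V vertex count.
#' @param specs list of `network_spec`s (fractions summing to 1 within 1e-9).
#' @return A `parcellation`.
#' @export
build_parcellation <- function(V, specs) {
  if (!is_count(V)) gfp_stop("V must be a positive integer")
  fr <- vapply(specs, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9) {
    gfp_stop("network fractions must sum to 1, got ", sum(fr))
  }
  if (V < length(specs)) gfp_stop("V smaller than the number of networks")
  counts <- round(fr * V)
  counts[length(counts)] <- V - sum(counts[-length(counts)])
  if (any(counts < 1)) gfp_stop("a network received no vertices at V = ", V)
  labels <- rep(vapply(specs, `[[`, character(1), "name"), counts)
  classes <- stats::setNames(vapply(specs, `[[`, character(1), "class"),
                             vapply(specs, `[[`, character(1), "name"))
  parcellation(labels, classes)
}

#' Group gradient template from network specs
#'
#' Draws each vertex's score on component c as `centers[n, c] +
#' dispersion[n, c] * N(0, 1)` for its network n, then orthogonalises the
#' columns (Gram-Schmidt, preserving the leading column's direction) and
#' scales each column to unit standard deviation so scores live on the O(1)
#' scale the generator sigmas assume. Ground-truth per-network variances are
#' recorded from the raw draw, before orthogonalisation.
#'
#' @param parc a `parcellation` (typically from [build_parcellation()]).
#' @param specs the `network_spec` list that produced `parc`.
#' @param k number of components (<= V).
#' @param seed integer seed for the template substream.
#' @return A `template_gradients` with an extra `ground_truth` field: a data
#'   frame of per-network, per-component raw-draw variances.
#' @export
build_template <- function(parc, specs, k, seed = 1L) {
  stopifnot(inherits(parc, "parcellation"))
  V <- length(parc$labels)
  if (!is_count(k) || k > V) gfp_stop("k must be a positive integer <= V")
  names <- vapply(specs, `[[`, character(1), "name")
  if (!all(parc$networks$name %in% names)) {
    gfp_stop("specs must cover every network in the parcellation")
  }
  set.seed(substream_seed(seed, "template"))
  raw <- matrix(0, V, k)
  gt <- list()
  for (sp in specs) {
    mask <- which(parc$labels == sp$name)
    for (c in seq_len(k)) {
      raw[mask, c] <- sp$centers[c] + sp$dispersion[c] * stats::rnorm(length(mask))
    }
    gt[[sp$name]] <- data.frame(
      network = sp$name, component = seq_len(k),
      variance = vapply(seq_len(k), function(c) stats::var(raw[mask, c]),
                        numeric(1))
    )
  }
  # Gram-Schmidt without renormalising inside the sweep, then unit-sd scaling
  # (column scaling preserves orthogonality)
  orth <- raw
  for (c in seq_len(k)) {
    if (c > 1L) {
      prev <- orth[, seq_len(c - 1L), drop = FALSE]
      orth[, c] <- orth[, c] - prev %*% (crossprod(prev, orth[, c]) /
                                           colSums(prev^2))
    }
  }
  # scale each component to unit standard deviation; a component whose
  # residual is (numerically) constant carries no spatial structure and is
  # left unscaled rather than amplified out of round-off dust
  sds <- apply(orth, 2L, stats::sd)
  raw_sds <- apply(raw, 2L, stats::sd)
  for (c in seq_len(k)) {
    if (sds[c] > 1e-9 * max(raw_sds[c], 1e-12)) {
      orth[, c] <- orth[, c] / sds[c]
    }
  }
  tpl <- template_gradients(orth, provenance = sprintf(
    "synthetic template (V=%d, k=%d, seed=%d)", V, k, seed))
  tpl$ground_truth <- do.call(rbind, gt)
  rownames(tpl$ground_truth) <- NULL
  tpl
}

#' Simulate a multi-subject multi-session study
#'
#' For each subject i, a stable latent gradient matrix `G_i = template +
#' sigma_subject * E_i` is drawn, with the standard-normal perturbation
#' `E_i` scaled per-vertex by the owning network's `signature_strength` (so
#' individual uniqueness concentrates where the layout says it should). Each
#' session adds isotropic wobble: `G_is = G_i + sigma_session * E_is`.
#' The scan's time series is low-rank plus noise: `X_is = S_is %*% t(G_is) +
#' sigma_observation * noise`, where `S_is` is a T x k matrix of independent
#' unit-variance latent signals (no temporal autocorrelation: the analysis
#' depends only on spatial correlation structure).
#'
#' @param config a `synth_config`.
#' @return A `study_dataset`: list with `subjects`, `sessions`, `scans`
#'   (named `"<subject>.<session>"`, each a T x V matrix), `parcellation`,
#'   `template` (a `template_gradients`), `ground_truth` (list with
#'   `subject_gradients` and `session_gradients`), `config` and `metadata`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  V <- config$n_vertices
  Tt <- config$n_timepoints
  k <- config$n_components
  parc <- build_parcellation(V, config$network_specs)
  tpl <- build_template(parc, config$network_specs, k, seed = config$seed)
  strengths <- stats::setNames(
    vapply(config$network_specs, `[[`, numeric(1), "signature_strength"),
    vapply(config$network_specs, `[[`, character(1), "name")
  )
  vertex_strength <- unname(strengths[parc$labels])
  subjects <- sprintf("sub%02d", seq_len(config$n_subjects))
  sessions <- config$session_labels
  scans <- list()
  subject_gradients <- list()
  session_gradients <- list()
  set.seed(substream_seed(config$seed, "simulation"))
  for (i in seq_along(subjects)) {
    Ei <- matrix(stats::rnorm(V * k), V, k) * vertex_strength
    Gi <- tpl$scores + config$sigma_subject * Ei
    subject_gradients[[subjects[i]]] <- Gi
    for (s in seq_along(sessions)) {
      Gis <- Gi + config$sigma_session * matrix(stats::rnorm(V * k), V, k)
      # latent signals, exactly whitened within the scan (empirical mean 0,
      # identity covariance) so a scan's correlation matrix is a deterministic
      # function of its latent gradients
      Sis <- matrix(stats::rnorm(Tt * k), Tt, k)
      Sis <- scale(Sis, center = TRUE, scale = FALSE)
      Sis <- Sis %*% backsolve(chol(stats::cov(Sis)), diag(k))
      X <- Sis %*% t(Gis) +
        config$sigma_observation * matrix(stats::rnorm(Tt * V), Tt, V)
      key <- paste(subjects[i], sessions[s], sep = ".")
      scans[[key]] <- X
      session_gradients[[key]] <- Gis
    }
  }
  structure(
    list(
      subjects = subjects,
      sessions = sessions,
      scans = scans,
      parcellation = parc,
      template = tpl,
      ground_truth = list(subject_gradients = subject_gradients,
                          session_gradients = session_gradients),
      config = config,
      metadata = list(generator = "gradfp synthetic connectome generator",
                      seed = config$seed)
    ),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "<study_dataset> %d subjects x %d sessions, V = %d, T = %d\n",
    length(x$subjects), length(x$sessions), x$config$n_vertices,
    x$config$n_timepoints
  ))
  invisible(x)
}

#' Fetch one scan from a study dataset
#'
#' @param dataset a `study_dataset`.
#' @param subject subject identifier.
#' @param session session label.
#' @return The T x V time-series matrix.
#' @export
get_scan <- function(dataset, subject, session) {
  key <- paste(subject, session, sep = ".")
  if (!key %in% names(dataset$scans)) {
    gfp_stop("no scan for subject ", subject, ", session ", session)
  }
  dataset$scans[[key]]
}
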