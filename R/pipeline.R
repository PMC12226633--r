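# End-to-end orchestration: gradients -> alignment -> similarity ->
# identification -> network analyses -> dispersion statistics.

interval_label <- function(pair_index, n_pairs, pair) {
  if (n_pairs == 2L) c("short", "long")[pair_index]
  else paste(pair, collapse = "-")
}

#' Compute and align gradient sets for every scan of a dataset
#'
#' @param dataset a `study_dataset`.
#' @param config an `analysis_config`.
#' @param template a `template_gradients` (defaults to the dataset's own).
#' @return Named list (by `"<subject>.<session>"`) of aligned `gradient_set`s.
#' @export
dataset_gradients <- function(dataset, config = analysis_config(),
                              template = dataset$template) {
  stopifnot(inherits(dataset, "study_dataset"))
  sets <- lapply(dataset$scans, function(X) {
    scan_gradients(
      X,
      sparsity = config$sparsity,
      n_components = config$n_components,
      embedding = config$embedding,
      alpha = config$diffusion_alpha,
      diffusion_time = config$diffusion_time,
      zero_diagonal = config$zero_diagonal,
      rank_by = config$rank_by
    )
  })
  tpl_scores <- template$scores[, seq_len(config$n_components), drop = FALSE]
  aligned <- iterative_template_align(
    sets, template_gradients(tpl_scores, "pipeline template"),
    n_iter = config$n_procrustes_iter
  )
  stats::setNames(aligned$aligned, names(dataset$scans))
}

session_sets <- function(sets, subjects, session) {
  lapply(subjects, function(s) sets[[paste(s, session, sep = ".")]])
}

#' Run the full gradient-fingerprinting pipeline
#'
#' Stages: per-scan connectivity gradients, iterative Procrustes alignment to
#' the template, per-gradient similarity matrices and winner-take-all
#' identification with a permutation null for every configured session pair,
#' within/between ratios and their repeated-measures ANOVA, per-network
#' identification and dispersion, the heteromodal-vs-unimodal comparison,
#' and the dispersion-accuracy partial correlation per interval. All
#' stochastic steps derive their seeds from `config$seed` via named
#' substreams, so a rerun with the same config and seed reproduces every
#' number exactly.
#'
#' @param config an `analysis_config`.
#' @param dataset a `study_dataset` (e.g. from [simulate_dataset()] or
#'   assembled from files).
#' @param parc a `parcellation`; defaults to the dataset's own.
#' @param template a `template_gradients`; defaults to the dataset's own.
#' @param aligned_sets optionally, precomputed aligned gradient sets (from
#'   [dataset_gradients()]) to skip the decomposition stage.
#' @return A `pipeline_result` list: `fingerprints` (per pair x gradient:
#'   similarity matrix, identification with permutation p, ratio summary),
#'   `ratio_table`, `anova`, `network_records`, `network_identification`,
#'   `class_comparison`, `dispersion_partial` (per interval), `concat`
#'   (multi-gradient fingerprinting per pair), `config_hash`, `seed`.
#' @export
run_pipeline <- function(config, dataset, parc = dataset$parcellation,
                         template = dataset$template,
                         aligned_sets = NULL) {
  stopifnot(inherits(config, "analysis_config"),
            inherits(dataset, "study_dataset"))
  V <- ncol(dataset$scans[[1L]])
  if (length(parc$labels) != V) {
    gfp_stop("parcellation covers ", length(parc$labels),
             " vertices but scans have ", V)
  }
  if (nrow(template$scores) != V) {
    gfp_stop("template covers ", nrow(template$scores),
             " vertices but scans have ", V)
  }
  pairs <- config$session_pairs
  for (p in pairs) {
    if (!all(p %in% dataset$sessions)) {
      gfp_stop("session pair references unknown label: ",
               paste(setdiff(p, dataset$sessions), collapse = ", "))
    }
  }
  if (is.null(aligned_sets)) {
    aligned_sets <- dataset_gradients(dataset, config, template)
  }
  subjects <- dataset$subjects
  grads <- config$gradients_used
  m_tests <- length(pairs) * length(grads)

  fingerprints <- list()
  ratio_rows <- list()
  network_records <- list()
  net_id <- list()
  for (pi in seq_along(pairs)) {
    pair <- pairs[[pi]]
    label <- interval_label(pi, length(pairs), pair)
    ref_sets <- session_sets(aligned_sets, subjects, pair[1L])
    tar_sets <- session_sets(aligned_sets, subjects, pair[2L])
    for (g in grads) {
      S <- similarity_matrix(ref_sets, tar_sets, g, session_pair = pair)
      idr <- permutation_null(
        S, n_perm = config$n_permutations,
        seed = substream_seed(config$seed,
                              paste("permutation", label, g))
      )
      idr$p_bonferroni <- bonferroni(idr$p_raw, m_tests)
      wb <- within_between_ratios(S)
      key <- sprintf("%s.G%d", label, g)
      fingerprints[[key]] <- list(
        session_pair = pair, interval = label, gradient_index = g,
        similarity = S, identification = idr, ratios = wb
      )
      ratio_rows[[key]] <- data.frame(
        subject = subjects,
        gradient = paste0("G", g),
        interval = label,
        ratio = wb$per_subject$ratio,
        within_r = wb$per_subject$within_r,
        between_r = wb$per_subject$between_r,
        stringsAsFactors = FALSE
      )
      # per-network identification and dispersion
      nid <- network_identification(ref_sets, tar_sets, parc, g)
      net_id[[key]] <- nid
      for (nname in names(nid)) {
        mask_sets <- c(ref_sets, tar_sets)
        disp <- mean(vapply(mask_sets, function(s) {
          network_dispersion(s, parc, nname, g)
        }, numeric(1)))
        cls <- parc$networks$class[parc$networks$name == nname]
        network_records[[paste(key, nname)]] <- data.frame(
          network = nname, class = cls, gradient_index = g,
          interval = label, accuracy = nid[[nname]]$accuracy,
          dispersion = disp,
          vertex_count = length(network_mask(parc, nname)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  ratio_table <- do.call(rbind, ratio_rows)
  rownames(ratio_table) <- NULL
  records <- do.call(rbind, network_records)
  rownames(records) <- NULL

  anova_res <- if (length(grads) >= 2L && length(pairs) >= 2L) {
    rm_anova(ratio_table)
  } else {
    NULL
  }
  cls_cmp <- if (all(c("heteromodal", "unimodal") %in% records$class)) {
    class_comparison(records)
  } else {
    NULL
  }
  partials <- lapply(split(records, records$interval), function(sub) {
    if (nrow(sub) < 5L) return(NULL)
    # degenerate point clouds (e.g. every network at ceiling accuracy)
    # leave the association undefined rather than failing the whole run
    tryCatch(dispersion_accuracy_partial(sub), gradfp_error = function(e) NULL)
  })

  concat <- list()
  for (pi in seq_along(pairs)) {
    pair <- pairs[[pi]]
    label <- interval_label(pi, length(pairs), pair)
    ref_sets <- session_sets(aligned_sets, subjects, pair[1L])
    tar_sets <- session_sets(aligned_sets, subjects, pair[2L])
    S <- concatenated_similarity(ref_sets, tar_sets, max(grads))
    concat[[label]] <- identification(S)
  }

  structure(
    list(
      fingerprints = fingerprints,
      ratio_table = ratio_table,
      anova = anova_res,
      network_records = records,
      network_identification = net_id,
      class_comparison = cls_cmp,
      dispersion_partial = partials,
      concat = concat,
      aligned_sets = aligned_sets,
      config = config,
      config_hash = config_hash(config),
      seed = config$seed
    ),
    class = "pipeline_result"
  )
}

#' Write a pipeline result bundle to disk
#'
#' Emits per-pair, per-gradient similarity matrices (TSV), the ratio table
#' (TSV), network records (TSV) and a JSON summary of every statistic, each
#' tagged with the configuration hash and seed. Deterministic: rerunning the
#' pipeline with the same config and seed yields byte-identical files.
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(result$fingerprints)) {
    fp <- result$fingerprints[[key]]
    write_matrix(unclass(fp$similarity),
                 file.path(out_dir, sprintf("similarity_%s.tsv", key)))
  }
  utils::write.table(result$ratio_table,
                     file.path(out_dir, "ratio_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$network_records,
                     file.path(out_dir, "network_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    config_hash = result$config_hash,
    seed = result$seed,
    identification = lapply(result$fingerprints, function(fp) {
      list(
        interval = fp$interval,
        gradient = fp$gradient_index,
        accuracy = fp$identification$accuracy,
        p_raw = fp$identification$p_raw,
        p_literal = fp$identification$p_literal,
        p_bonferroni = fp$identification$p_bonferroni,
        within = fp$ratios$within,
        between = fp$ratios$between,
        ratio = fp$ratios$ratio
      )
    }),
    anova = if (!is.null(result$anova)) {
      list(
        F_gradient = result$anova$F_gradient,
        F_interval = result$anova$F_interval,
        F_interaction = result$anova$F_interaction,
        degenerate = result$anova$degenerate
      )
    },
    class_comparison = result$class_comparison,
    dispersion_partial = lapply(result$dispersion_partial, function(p) {
      if (is.null(p)) NULL else p[c("statistic", "p_raw", "p_bonferroni", "n")]
    }),
    concat_accuracy = lapply(result$concat, `[[`, "accuracy")
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}

#' Write a study dataset (scans, parcellation, template, ground truth)
#'
#' @param dataset a `study_dataset`.
#' @param out_dir output directory.
#' @param layout matrix layout for scans, `"dense_tsv"` or `"binary"`.
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(dataset, out_dir, layout = "binary") {
  stopifnot(inherits(dataset, "study_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (layout == "binary") "bin" else "tsv"
  for (key in names(dataset$scans)) {
    write_matrix(dataset$scans[[key]],
                 file.path(out_dir, sprintf("scan_%s.%s", key, ext)), layout)
  }
  write_parcellation(dataset$parcellation, file.path(out_dir, "parcellation.tsv"))
  write_matrix(dataset$template$scores, file.path(out_dir, "template.tsv"))
  jsonlite::write_json(
    list(subjects = dataset$subjects, sessions = dataset$sessions,
         seed = dataset$config$seed, layout = layout,
         metadata = dataset$metadata),
    file.path(out_dir, "dataset.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}

#' Load a study dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return A `study_dataset` (without generator ground truth).
#' @export
load_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  layout <- meta$layout
  ext <- if (layout == "binary") "bin" else "tsv"
  scans <- list()
  for (sub in meta$subjects) {
    for (ses in meta$sessions) {
      key <- paste(sub, ses, sep = ".")
      scans[[key]] <- load_matrix(
        file.path(dir, sprintf("scan_%s.%s", key, ext)), layout)
    }
  }
  V <- ncol(scans[[1L]])
  if (any(vapply(scans, ncol, integer(1)) != V)) {
    gfp_stop("scans disagree on vertex count")
  }
  structure(
    list(
      subjects = meta$subjects,
      sessions = meta$sessions,
      scans = scans,
      parcellation = load_parcellation(file.path(dir, "parcellation.tsv")),
      template = template_gradients(
        load_matrix(file.path(dir, "template.tsv")),
        provenance = paste0("loaded from ", dir)
      ),
      ground_truth = NULL,
      config = list(n_vertices = V, n_timepoints = nrow(scans[[1L]]),
                    seed = meta$seed),
      metadata = meta$metadata
    ),
    class = "study_dataset"
  )
}
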