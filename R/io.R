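# File formats: tab-delimited matrices, a shape-prefixed little-endian binary
# matrix container, parcellation label tables, YAML analysis configuration.
# All formats are plain, language-agnostic and diffable (text) or documented
# byte-exact (binary).

#' Write a numeric matrix
#'
#' Text layout (`dense_tsv`): tab-delimited, no header, row-major, full
#' `%.17g` precision (round-trips within 1e-12). Binary layout: the bytes
#' `GFPB`, an int32 format version (1), int32 nrow, int32 ncol, then the
#' doubles row-major — all little-endian; round-trips bit-exact.
#'
#' @param x numeric matrix.
#' @param path output file path.
#' @param layout `"dense_tsv"` (default) or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, layout = c("dense_tsv", "binary")) {
  layout <- match.arg(layout)
  if (!is.matrix(x) || !is.numeric(x)) gfp_stop("x must be a numeric matrix")
  if (layout == "dense_tsv") {
    lines <- apply(x, 1L, function(row) {
      paste(sprintf("%.17g", row), collapse = "\t")
    })
    writeLines(lines, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("GFPB"), con)
    writeBin(c(1L, nrow(x), ncol(x)), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(x)), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a numeric matrix written by [write_matrix()]
#'
#' @param path input file path.
#' @param layout `"dense_tsv"` (default) or `"binary"`.
#' @return The numeric matrix.
#' @export
load_matrix <- function(path, layout = c("dense_tsv", "binary")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) gfp_stop("file not found: ", path)
  if (layout == "binary") {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- rawToChar(readBin(con, "raw", 4L))
    if (magic != "GFPB") gfp_stop("not a gradfp binary matrix: ", path)
    hdr <- readBin(con, "integer", 3L, size = 4L, endian = "little")
    if (hdr[1L] != 1L) gfp_stop("unsupported binary format version ", hdr[1L])
    vals <- readBin(con, "numeric", hdr[2L] * hdr[3L], size = 8L,
                    endian = "little")
    if (length(vals) != hdr[2L] * hdr[3L]) {
      gfp_stop("truncated binary matrix: expected ", hdr[2L] * hdr[3L],
               " values, got ", length(vals))
    }
    return(matrix(vals, hdr[2L], hdr[3L], byrow = TRUE))
  }
  lines <- readLines(path)
  if (length(lines) == 0L) gfp_stop("empty matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    gfp_stop("ragged matrix file: row ", bad, " has ", widths[bad],
             " fields, expected ", widths[1L])
  }
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) {
    flat <- which(is.na(vals))[1L]
    row <- ceiling(flat / widths[1L])
    col <- flat - (row - 1L) * widths[1L]
    gfp_stop("non-numeric cell at row ", row, ", column ", col, ": '",
             unlist(fields)[flat], "'")
  }
  if (any(!is.finite(vals))) gfp_stop("matrix contains non-finite values")
  matrix(vals, length(lines), widths[1L], byrow = TRUE)
}

#' Write a parcellation label table
#'
#' Tab-delimited with a header `vertex  network  class`; vertex indices are
#' 0-based.
#'
#' @param parc a `parcellation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  cls <- stats::setNames(
    ifelse(parc$networks$included, parc$networks$class, "excluded"),
    parc$networks$name
  )
  df <- data.frame(
    vertex = seq_along(parc$labels) - 1L,
    network = parc$labels,
    class = unname(cls[parc$labels])
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a parcellation label table
#'
#' Expects a delimited table with columns vertex index (0-based), network
#' name, and optionally a class token in `{heteromodal, unimodal, excluded}`
#' (missing class defaults to heteromodal). Vertices must cover 0..V-1
#' exactly once. A header row is detected automatically.
#'
#' @param path label table path.
#' @return A `parcellation`.
#' @export
load_parcellation <- function(path) {
  if (!file.exists(path)) gfp_stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  header <- is.na(suppressWarnings(as.numeric(first[1L])))
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) gfp_stop("parcellation table needs >= 2 columns")
  names(df)[1:2] <- c("vertex", "network")
  if (ncol(df) >= 3L) names(df)[3L] <- "class"
  if (anyDuplicated(df$vertex) > 0L) {
    gfp_stop("duplicate vertex index: ",
             df$vertex[anyDuplicated(df$vertex)])
  }
  expected <- seq(0L, max(df$vertex))
  missing <- setdiff(expected, df$vertex)
  if (length(missing) > 0L || min(df$vertex) != 0L) {
    gfp_stop("vertex indices must cover 0..V-1; missing index ",
             paste(utils::head(missing, 5L), collapse = ", "))
  }
  df <- df[order(df$vertex), ]
  classes <- NULL
  if ("class" %in% names(df)) {
    cls_by_net <- tapply(df$class, df$network, function(x) unique(x))
    if (any(lengths(cls_by_net) > 1L)) {
      gfp_stop("conflicting class tokens within network(s): ",
               paste(names(cls_by_net)[lengths(cls_by_net) > 1L],
                     collapse = ", "))
    }
    classes <- vapply(cls_by_net, `[[`, character(1), 1L)
  }
  parcellation(df$network, classes)
}

# ---- analysis configuration ------------------------------------------------

config_schema <- function() {
  list(
    sparsity = 0.9, n_components = 5L, gradients_used = 1:3,
    embedding = "pca", diffusion_alpha = 0.5, diffusion_time = 0,
    n_procrustes_iter = 10L, n_permutations = 1000L, alpha_level = 0.05,
    seed = 1L, session_pairs = list(c("day1", "day3"), c("day1", "day30")),
    rank_by = "value", zero_diagonal = FALSE
  )
}

#' Build an analysis configuration
#'
#' Conventional defaults: 0.9 sparsity (keep the top 10% of connections per
#' vertex), 5 extracted components with the first 3 analysed, PCA embedding,
#' 10 Procrustes iterations, 1000 permutations, alpha 0.05, and the
#' day1-day3 (short) / day1-day30 (long) session pairs.
#'
#' @param ... named overrides of any schema field (unknown names are an
#'   error).
#' @return A validated `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- config_schema()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    gfp_stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$sparsity) || cfg$sparsity < 0 || cfg$sparsity >= 1) {
    gfp_stop("sparsity must lie in [0, 1)")
  }
  if (!is_count(cfg$n_components)) gfp_stop("n_components must be a positive integer")
  if (!all(cfg$gradients_used %in% seq_len(cfg$n_components))) {
    gfp_stop("gradients_used must be a subset of 1..n_components")
  }
  if (!cfg$embedding %in% c("pca", "diffusion")) {
    gfp_stop("embedding must be 'pca' or 'diffusion'")
  }
  if (cfg$diffusion_alpha < 0 || cfg$diffusion_alpha > 1) {
    gfp_stop("diffusion_alpha must lie in [0, 1]")
  }
  if (!is_count(cfg$n_procrustes_iter)) gfp_stop("n_procrustes_iter must be a positive integer")
  if (!is_count(cfg$n_permutations)) gfp_stop("n_permutations must be >= 1")
  if (!is.numeric(cfg$alpha_level) || cfg$alpha_level <= 0 || cfg$alpha_level >= 1) {
    gfp_stop("alpha_level must lie in (0, 1)")
  }
  if (!cfg$rank_by %in% c("value", "magnitude")) {
    gfp_stop("rank_by must be 'value' or 'magnitude'")
  }
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are an error (fail fast rather than silently ignoring a
#' typo).
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) gfp_stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$session_pairs)) {
    raw$session_pairs <- lapply(raw$session_pairs, function(p) {
      if (length(p) != 2L) gfp_stop("each session pair must have 2 labels")
      as.character(unlist(p))
    })
  }
  if (!is.null(raw$gradients_used)) {
    raw$gradients_used <- as.integer(unlist(raw$gradients_used))
  }
  do.call(analysis_config, raw)
}

#' Write an analysis configuration to YAML
#'
#' @param cfg an `analysis_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Configuration fingerprint used to tag every emitted result.
config_hash <- function(cfg) {
  fnv1a_hash(paste(
    vapply(unclass(cfg), function(v) paste(format(v, digits = 17), collapse = ","),
           character(1)),
    collapse = ";"
  ))
}
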