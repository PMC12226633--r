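# Vertex -> network parcellation with heteromodal/unimodal class labels.

#' Construct a parcellation
#'
#' @param labels character V-vector assigning each vertex (0-based order) a
#'   network name.
#' @param classes named character vector mapping network name to class, one of
#'   `"heteromodal"`, `"unimodal"`, `"excluded"`. Networks marked `"excluded"`
#'   are carried in metadata but masked from every analysis (the convention
#'   used for, e.g., a low-SNR limbic network). Networks not named default to
#'   `"heteromodal"`.
#' @return A `parcellation`: list with `labels` and a `networks` data frame
#'   (`name`, `class`, `vertex_count`, `included`).
#' @export
parcellation <- function(labels, classes = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0L) gfp_stop("labels must be non-empty")
  nets <- unique(labels)
  cls <- stats::setNames(rep("heteromodal", length(nets)), nets)
  if (!is.null(classes)) {
    bad <- setdiff(classes, c("heteromodal", "unimodal", "excluded"))
    if (length(bad) > 0L) {
      gfp_stop("unknown class token(s): ", paste(bad, collapse = ", "))
    }
    unknown <- setdiff(names(classes), nets)
    if (length(unknown) > 0L) {
      gfp_stop("class given for unknown network(s): ",
               paste(unknown, collapse = ", "))
    }
    cls[names(classes)] <- classes
  }
  counts <- table(labels)[nets]
  structure(
    list(
      labels = labels,
      networks = data.frame(
        name = nets,
        class = ifelse(cls == "excluded", NA_character_, unname(cls)),
        vertex_count = as.integer(counts),
        included = unname(cls) != "excluded",
        stringsAsFactors = FALSE
      )
    ),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d vertices, %d networks (%d included)\n",
              length(x$labels), nrow(x$networks), sum(x$networks$included)))
  print(x$networks, row.names = FALSE)
  invisible(x)
}

#' Vertex mask (1-based indices) for one network
#'
#' @param parc a `parcellation`.
#' @param network network name.
#' @return Integer vector of 1-based vertex indices belonging to `network`.
#' @export
network_mask <- function(parc, network) {
  stopifnot(inherits(parc, "parcellation"))
  if (!network %in% parc$networks$name) {
    gfp_stop("unknown network: ", network)
  }
  which(parc$labels == network)
}

#' Names of networks included in analyses
#'
#' @param parc a `parcellation`.
#' @return Character vector of included (non-excluded) network names.
#' @export
included_networks <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  parc$networks$name[parc$networks$included]
}
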