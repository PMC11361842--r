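# DatasetBundle: screen + feature tables + network views re-indexed to one
# shared ordered gene universe.

#' Assemble a dataset bundle
#'
#' Aligns a labeled (or unlabeled) screen, any number of feature tables and
#' any number of network views onto a single ordered gene universe — by
#' default the screen's. Genes missing from a feature table receive NA rows
#' (imputed at training time); genes missing from a network view are
#' isolated nodes, never dropped.
#'
#' @param screen An `sl_screen`.
#' @param features List of `feature_table` objects.
#' @param networks List of `network_view` objects.
#' @param universe Optional explicit gene universe; defaults to the
#'   screen's.
#' @param connectivity Optional `connectivity_vector` (derived later if
#'   absent).
#' @return A `dataset_bundle`.
#' @export
dataset_bundle <- function(screen, features = list(), networks = list(),
                           universe = NULL, connectivity = NULL) {
  stopifnot(inherits(screen, "sl_screen"))
  universe <- sort(universe %||% screen$gene_universe)
  if (!all(screen$gene_universe %in% universe)) {
    stop("universe must cover every screen gene", call. = FALSE)
  }
  features <- lapply(features, function(ft) {
    stopifnot(inherits(ft, "feature_table"))
    ft$values <- reindex_features(ft$values, universe)
    ft
  })
  networks <- lapply(networks, function(nv) {
    stopifnot(inherits(nv, "network_view"))
    keep <- nv$edges$gene_a %in% universe & nv$edges$gene_b %in% universe
    out <- network_view(nv$name, nv$edges[keep, , drop = FALSE])
    out$node_set <- universe
    out
  })
  screen$gene_universe <- universe
  structure(list(screen = screen, features = features, networks = networks,
                 universe = universe, connectivity = connectivity),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf(
    "<dataset_bundle> %d genes | screen '%s' (%d pairs) | %d feature tables | %d network views\n",
    length(x$universe), x$screen$cell_line, nrow(x$screen$records),
    length(x$features), length(x$networks)))
  invisible(x)
}

# Stack feature tables of one scope into a single genes x features matrix
# (NULL when the bundle carries no table of that scope).
scope_matrix <- function(bundle, scope) {
  tabs <- Filter(function(ft) ft$scope == scope, bundle$features)
  if (!length(tabs)) return(NULL)
  mats <- lapply(tabs, function(ft) {
    m <- ft$values
    colnames(m) <- paste(ft$name, colnames(m), sep = ".")
    m
  })
  do.call(cbind, mats)
}

#' Write a bundle to a directory of TSV files
#'
#' Emits `screen.tsv`, one `features_<name>.tsv` per table (with a
#' `features_<name>.meta.tsv` sidecar holding scope and modality), and one
#' `network_<name>.tsv` per view, all in the package's TSV dialects.
#' Serialization is deterministic: identical bundles produce byte-identical
#' directories.
#'
#' @param bundle A `dataset_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_screen(bundle$screen, file.path(dir, "screen.tsv"))
  for (ft in bundle$features) {
    stem <- file.path(dir, paste0("features_", ft$name))
    write_feature_table(ft, paste0(stem, ".tsv"))
    meta <- data.frame(name = ft$name, scope = ft$scope,
                       modality = ft$modality, stringsAsFactors = FALSE)
    utils::write.table(meta, paste0(stem, ".meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (nv in bundle$networks) {
    write_network(nv, file.path(dir, paste0("network_", nv$name, ".tsv")))
  }
  writeLines(bundle$universe, file.path(dir, "universe.txt"))
  invisible(dir)
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @param cell_line Cell line identifier for the screen.
#' @return A `dataset_bundle`.
#' @export
load_bundle <- function(dir, cell_line = "unknown") {
  screen <- load_screen(file.path(dir, "screen.tsv"), cell_line)
  metas <- sort(list.files(dir, pattern = "^features_.*\\.meta\\.tsv$",
                           full.names = TRUE))
  features <- lapply(metas, function(mp) {
    meta <- utils::read.table(mp, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    load_feature_table(sub("\\.meta\\.tsv$", ".tsv", mp),
                       scope = meta$scope, modality = meta$modality,
                       name = meta$name)
  })
  nets <- sort(list.files(dir, pattern = "^network_.*\\.tsv$",
                          full.names = TRUE))
  networks <- lapply(nets, function(np) {
    load_network(np, name = sub("^network_(.*)\\.tsv$", "\\1", basename(np)))
  })
  universe_path <- file.path(dir, "universe.txt")
  universe <- if (file.exists(universe_path)) readLines(universe_path)
  dataset_bundle(screen, features, networks, universe = universe)
}
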