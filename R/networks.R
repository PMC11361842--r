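# Biological network views: undirected edge lists plus cell-specific
# filtering and screen-leakage removal.

NETWORK_NAMES <- c("ppi_physical", "ppi_genetic", "pathway", "other")

#' Construct a network view
#'
#' An undirected, self-loop-free edge list over gene symbols. Edges are
#' canonicalized to unordered pairs and deduplicated; `node_set` always
#' contains every endpoint and may list additional isolated genes.
#'
#' @param name View name: `"ppi_physical"`, `"ppi_genetic"`, `"pathway"`
#'   or `"other"`.
#' @param edges data.frame with columns `gene_a`, `gene_b`.
#' @param node_set Optional character vector of nodes; extended to cover
#'   all endpoints.
#' @return A `network_view`.
#' @export
network_view <- function(name, edges, node_set = NULL) {
  name <- match.arg(name, NETWORK_NAMES)
  if (nrow(edges)) {
    cp <- canonical_pairs(edges$gene_a, edges$gene_b)
    edges <- cp[!duplicated(cp$key), c("gene_a", "gene_b"), drop = FALSE]
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        stringsAsFactors = FALSE)
  }
  node_set <- sort(unique(c(node_set, edges$gene_a, edges$gene_b)))
  structure(list(name = name, edges = edges, node_set = node_set),
            class = "network_view")
}

#' @export
print.network_view <- function(x, ...) {
  cat(sprintf("<network_view> '%s': %d edges over %d nodes\n",
              x$name, nrow(x$edges), length(x$node_set)))
  invisible(x)
}

#' Read a network view from an undirected edge list
#'
#' TSV with header columns `gene_a`, `gene_b`.
#'
#' @param path Path to the edge-list TSV.
#' @param name View name (see [network_view()]).
#' @return A `network_view`.
#' @export
load_network <- function(path, name = "other") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (!all(c("gene_a", "gene_b") %in% names(df))) {
    stop("network file must have columns gene_a and gene_b", call. = FALSE)
  }
  network_view(name, df[, c("gene_a", "gene_b")])
}

#' Write a network edge list
#' @param network A `network_view`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Restrict a network view to genes expressed in a cell line
#'
#' Drops nodes outside `expressed_genes` and every edge touching a dropped
#' node, mirroring the preprocessing that makes population-level networks
#' specific to the modeled cell line.
#'
#' @param network A `network_view`.
#' @param expressed_genes Non-empty character vector of retained genes.
#' @return The filtered `network_view` (with a warning if it comes out
#'   empty).
#' @export
filter_network_to_cell <- function(network, expressed_genes) {
  stopifnot(inherits(network, "network_view"))
  if (!length(expressed_genes)) {
    stop("expressed_genes must be nonempty", call. = FALSE)
  }
  nodes <- intersect(network$node_set, expressed_genes)
  keep <- network$edges$gene_a %in% nodes & network$edges$gene_b %in% nodes
  edges <- network$edges[keep, , drop = FALSE]
  if (!length(nodes)) {
    warning(sprintf("network '%s' is empty after cell-specific filtering",
                    network$name), call. = FALSE)
  }
  out <- network_view(network$name, edges, node_set = nodes)
  out$node_set <- nodes  # may be empty; network_view() sorts nonempty sets
  out
}

#' Genes expressed in a cell line
#'
#' Convenience rule for [filter_network_to_cell()]: a gene counts as
#' expressed when its expression value is strictly positive (log-scale
#' profiles put non-expressed genes at or below zero). With several
#' expression features, the gene's maximum is used.
#'
#' @param expression A `feature_table` with modality `"expression"`.
#' @param threshold Expression value that must be strictly exceeded.
#' @return Character vector of expressed gene symbols.
#' @export
expressed_genes <- function(expression, threshold = 0) {
  stopifnot(inherits(expression, "feature_table"))
  if (expression$modality != "expression") {
    stop("expressed_genes expects an expression feature table", call. = FALSE)
  }
  v <- expression$values
  mx <- apply(v, 1, function(x) if (all(is.na(x))) -Inf else max(x, na.rm = TRUE))
  rownames(v)[mx > threshold]
}

#' Remove screen pairs from a network view
#'
#' Deletes from the view every unordered pair that appears in the screen's
#' records, so a genetic-interaction network cannot leak the supervision
#' pairs into the model input.
#'
#' @param network A `network_view`.
#' @param screen An `sl_screen`.
#' @return The `network_view` without screen pairs (idempotent).
#' @export
remove_leakage_edges <- function(network, screen) {
  stopifnot(inherits(network, "network_view"), inherits(screen, "sl_screen"))
  if (!nrow(network$edges)) return(network)
  screen_keys <- paste(screen$records$gene_a, screen$records$gene_b, sep = "|")
  edge_keys <- paste(network$edges$gene_a, network$edges$gene_b, sep = "|")
  out <- network
  out$edges <- network$edges[!edge_keys %in% screen_keys, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

#' Symmetric-normalized adjacency with self-connections
#'
#' Builds the dense matrix D^(-1/2) (A + I) D^(-1/2) over an ordered gene
#' universe, the propagation operator of the graph encoder. Genes of the
#' universe absent from the view are isolated nodes: their row reduces to
#' the self-connection, so message passing propagates their own features
#' only.
#'
#' @param network A `network_view`.
#' @param universe Ordered character vector of genes defining row/column
#'   order.
#' @return A dense numeric `length(universe)` square matrix.
#' @export
normalized_adjacency <- function(network, universe) {
  n <- length(universe)
  A <- matrix(0, n, n, dimnames = list(universe, universe))
  e <- network$edges
  keep <- e$gene_a %in% universe & e$gene_b %in% universe
  e <- e[keep, , drop = FALSE]
  if (nrow(e)) {
    ia <- match(e$gene_a, universe)
    ib <- match(e$gene_b, universe)
    A[cbind(ia, ib)] <- 1
    A[cbind(ib, ia)] <- 1
  }
  diag(A) <- diag(A) + 1
  d <- rowSums(A)
  dinv <- 1 / sqrt(d)
  A * tcrossprod(dinv)
}
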