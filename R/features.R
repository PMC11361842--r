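# Gene feature tables (omics blocks) and the impute/standardize policy.

FEATURE_SCOPES <- c("population", "cell_specific")
FEATURE_MODALITIES <- c("expression", "essentiality", "cnv", "mutation", "other")

#' Construct a feature table
#'
#' A genes x features numeric matrix carrying one omics modality at one
#' scope (population-level profiles across cell lines, or profiles specific
#' to the modeled cell line). Mutation-modality tables must hold
#' non-negative integer mutation counts.
#'
#' @param values Numeric matrix with rownames = gene symbols and colnames =
#'   feature names.
#' @param scope `"population"` or `"cell_specific"`.
#' @param modality One of `"expression"`, `"essentiality"`, `"cnv"`,
#'   `"mutation"`, `"other"`.
#' @param name Optional display name; defaults to `scope.modality`.
#' @return A `feature_table`.
#' @export
feature_table <- function(values, scope, modality, name = NULL) {
  scope <- match.arg(scope, FEATURE_SCOPES)
  modality <- match.arg(modality, FEATURE_MODALITIES)
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (modality == "mutation") {
    v <- values[!is.na(values)]
    if (any(v < 0) || any(v != round(v))) {
      stop("mutation feature tables must contain non-negative integer counts",
           call. = FALSE)
    }
  }
  structure(list(values = values, scope = scope, modality = modality,
                 name = name %||% paste(scope, modality, sep = ".")),
            class = "feature_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> '%s' (%s, %s): %d genes x %d features\n",
              x$name, x$scope, x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a feature table
#'
#' TSV with header; first column `gene`, remaining columns named features.
#'
#' @param path Path to the TSV.
#' @inheritParams feature_table
#' @return A `feature_table`.
#' @export
load_feature_table <- function(path, scope, modality, name = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  if (names(df)[1] != "gene") {
    stop("feature table must have 'gene' as its first column", call. = FALSE)
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene
  feature_table(values, scope = scope, modality = modality, name = name)
}

#' Write a feature table
#' @param table A `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(gene = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Reindex a feature matrix to a gene universe; genes without a row get NA
# (imputed later by prepare_feature_matrix).
reindex_features <- function(values, universe) {
  out <- matrix(NA_real_, nrow = length(universe), ncol = ncol(values),
                dimnames = list(universe, colnames(values)))
  shared <- intersect(universe, rownames(values))
  out[shared, ] <- values[shared, , drop = FALSE]
  out
}

#' Impute and standardize a feature matrix with training-set statistics
#'
#' Missing values are imputed with the per-feature median over observed
#' genes, then each feature is centered and scaled using mean and standard
#' deviation computed over `train_genes` only, so no statistic of held-out
#' genes leaks into preprocessing. Zero-variance features are centered and
#' left on their original scale.
#'
#' @param values Numeric genes x features matrix (rownames = genes), may
#'   contain NA.
#' @param train_genes Genes whose rows define the standardization
#'   statistics.
#' @return List with `values` (imputed, standardized matrix), `center` and
#'   `scale` (per-feature statistics used).
#' @export
prepare_feature_matrix <- function(values, train_genes) {
  stopifnot(length(train_genes) > 0, all(train_genes %in% rownames(values)))
  for (j in seq_len(ncol(values))) {
    col <- values[, j]
    if (anyNA(col)) {
      med <- stats::median(col, na.rm = TRUE)
      if (is.na(med)) med <- 0
      col[is.na(col)] <- med
      values[, j] <- col
    }
  }
  tr <- values[train_genes, , drop = FALSE]
  center <- colMeans(tr)
  scale <- apply(tr, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  values <- sweep(values, 2, center, "-")
  values <- sweep(values, 2, scale, "/")
  list(values = values, center = center, scale = scale)
}
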