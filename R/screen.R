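# Core screen container and label/connectivity derivations.

#' Canonicalize unordered gene pairs
#'
#' Pairs are stored as (min, max) under lexicographic gene-symbol order so
#' that every downstream operation is invariant to the order in which the
#' two genes of a pair are written.
#'
#' @param gene_a,gene_b Character vectors of gene symbols (recycled to a
#'   common length).
#' @return A data.frame with columns `gene_a`, `gene_b` (canonical order)
#'   and `key`, the `"a|b"` string key of the unordered pair.
#' @export
canonical_pairs <- function(gene_a, gene_b) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  if (any(gene_a == gene_b)) {
    stop("self-pairs are not allowed (gene_a == gene_b)", call. = FALSE)
  }
  a <- pmin(gene_a, gene_b)
  b <- pmax(gene_a, gene_b)
  data.frame(gene_a = a, gene_b = b, key = paste(a, b, sep = "|"),
             stringsAsFactors = FALSE)
}

new_sl_screen <- function(records, cell_line, gene_universe) {
  stopifnot(is.data.frame(records),
            all(c("gene_a", "gene_b", "gi_score") %in% names(records)))
  if (!"sl_label" %in% names(records)) records$sl_label <- NA_integer_
  structure(
    list(records = records,
         cell_line = as.character(cell_line),
         gene_universe = gene_universe),
    class = "sl_screen")
}

#' @export
print.sl_screen <- function(x, ...) {
  n_sl <- sum(x$records$sl_label == 1L, na.rm = TRUE)
  labeled <- !anyNA(x$records$sl_label)
  cat(sprintf("<sl_screen> cell line '%s': %d pairs over %d genes%s\n",
              x$cell_line, nrow(x$records), length(x$gene_universe),
              if (labeled) sprintf(", %d SL (%.2f%%)",
                                   n_sl, 100 * n_sl / nrow(x$records))
              else " (unlabeled)"))
  invisible(x)
}

#' Read a double-knockout screen table
#'
#' Reads a tab- or comma-separated table with header columns `gene_a`,
#' `gene_b`, `gi_score` (optionally `sl_label`) holding one genetic
#' interaction (GI) score per gene pair in one cell line. Pairs are
#' deduplicated on the unordered pair; a duplicate with a conflicting
#' `gi_score` is an integrity error.
#'
#' @param path Path to the screen file.
#' @param cell_line Identifier of the screened cell line.
#' @return An `sl_screen` object with canonicalized, deduplicated records
#'   and `gene_universe` equal to the sorted union of endpoint symbols.
#' @export
load_screen <- function(path, cell_line) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  required <- c("gene_a", "gene_b", "gi_score")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("screen file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  has_label <- "sl_label" %in% names(df)
  screen_from_records(df$gene_a, df$gene_b, as.numeric(df$gi_score),
                      sl_label = if (has_label) as.integer(df$sl_label),
                      cell_line = cell_line)
}

#' Build a screen from in-memory pair records
#'
#' @param gene_a,gene_b Gene symbols per record.
#' @param gi_score Numeric GI score per record.
#' @param sl_label Optional binary labels.
#' @param cell_line Cell line identifier.
#' @return An `sl_screen`.
#' @export
screen_from_records <- function(gene_a, gene_b, gi_score, sl_label = NULL,
                                cell_line = "unknown") {
  cp <- canonical_pairs(gene_a, gene_b)
  rec <- data.frame(gene_a = cp$gene_a, gene_b = cp$gene_b,
                    gi_score = as.numeric(gi_score),
                    stringsAsFactors = FALSE)
  if (!is.null(sl_label)) rec$sl_label <- as.integer(sl_label)
  dup <- duplicated(cp$key)
  if (any(dup)) {
    # collapse exact duplicates; conflicting scores are an integrity error
    split_scores <- split(rec$gi_score, cp$key)
    conflict <- vapply(split_scores, function(s) diff(range(s)) > 0, logical(1))
    if (any(conflict)) {
      stop("conflicting gi_score for duplicated pair(s): ",
           paste(utils::head(names(split_scores)[conflict], 5), collapse = ", "),
           call. = FALSE)
    }
    rec <- rec[!dup, , drop = FALSE]
  }
  rec <- rec[order(rec$gene_a, rec$gene_b), , drop = FALSE]
  rownames(rec) <- NULL
  universe <- sort(unique(c(rec$gene_a, rec$gene_b)))
  new_sl_screen(rec, cell_line, universe)
}

#' Write a screen table
#'
#' Emits the tab-separated dialect read by [load_screen()], rows sorted by
#' canonical pair, so identical screens serialize bit-identically.
#'
#' @param screen An `sl_screen`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen <- function(screen, path) {
  rec <- screen$records
  rec <- rec[order(rec$gene_a, rec$gene_b), , drop = FALSE]
  if (all(is.na(rec$sl_label))) rec$sl_label <- NULL
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Label screen pairs as SL by GI-score threshold
#'
#' A pair is labeled synthetic lethal when its genetic-interaction score is
#' strictly below the threshold (default -3); a score exactly at the
#' threshold is non-SL.
#'
#' @param screen An `sl_screen` with `gi_score` present for every record.
#' @param threshold GI-score cutoff; scores strictly below it are SL.
#' @return The screen with `sl_label` set to 0/1 for every record.
#' @export
label_pairs <- function(screen, threshold = -3) {
  stopifnot(inherits(screen, "sl_screen"))
  if (anyNA(screen$records$gi_score)) {
    stop("gi_score must be present for all records before labeling",
         call. = FALSE)
  }
  screen$records$sl_label <- as.integer(screen$records$gi_score < threshold)
  screen
}

#' Per-gene SL connectivity
#'
#' SL connectivity of a gene is its number of SL partners: the count of
#' labeled-SL pairs that contain the gene. Genes of the universe with no SL
#' partner get 0. The sum of connectivities always equals twice the number
#' of SL pairs counted.
#'
#' @param screen A labeled `sl_screen`.
#' @param restrict_to_pairs Optional data.frame with columns
#'   `gene_a`/`gene_b` (any order); only labeled pairs in this set are
#'   counted. Used to compute split-local connectivity targets.
#' @return A `connectivity_vector`: named integer vector over
#'   `screen$gene_universe`.
#' @export
compute_connectivity <- function(screen, restrict_to_pairs = NULL) {
  stopifnot(inherits(screen, "sl_screen"))
  rec <- screen$records
  if (anyNA(rec$sl_label)) {
    stop("screen must be labeled (see label_pairs) before computing connectivity",
         call. = FALSE)
  }
  if (!is.null(restrict_to_pairs)) {
    keep_keys <- canonical_pairs(restrict_to_pairs$gene_a,
                                 restrict_to_pairs$gene_b)$key
    rec <- rec[paste(rec$gene_a, rec$gene_b, sep = "|") %in% keep_keys, ,
               drop = FALSE]
  }
  sl <- rec[rec$sl_label == 1L, , drop = FALSE]
  counts <- table(factor(c(sl$gene_a, sl$gene_b),
                         levels = screen$gene_universe))
  connectivity_vector(stats::setNames(as.integer(counts),
                                      screen$gene_universe))
}

#' Construct a connectivity vector
#'
#' @param counts Named non-negative integer vector (names = gene symbols).
#' @return A `connectivity_vector`.
#' @export
connectivity_vector <- function(counts) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  structure(as.integer(counts), names = names(counts),
            class = "connectivity_vector")
}

#' @export
print.connectivity_vector <- function(x, ...) {
  cat(sprintf("<connectivity_vector> %d genes, %d SL pair endpoints (max %d)\n",
              length(x), sum(x), if (length(x)) max(x) else 0L))
  invisible(x)
}
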