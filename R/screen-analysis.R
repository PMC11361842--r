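# Double-knockout screen analytics: SL rates, two-screen enrichment
# comparison, pathway-pair stratified reports, hub genes, and
# predicted-vs-validated connectivity correlation.

#' SL rate of a validated screen
#'
#' Fraction of validated SL pairs among all validated pairs.
#'
#' @param validated_sl,validated_non_sl Non-negative integer counts.
#' @return `validated_sl / (validated_sl + validated_non_sl)`.
#' @export
sl_rate <- function(validated_sl, validated_non_sl) {
  stopifnot(validated_sl >= 0, validated_non_sl >= 0)
  total <- validated_sl + validated_non_sl
  if (total == 0) stop("sl_rate undefined for zero total", call. = FALSE)
  validated_sl / total
}

#' Chi-square comparison of two screens' SL fractions
#'
#' Pearson chi-square on a 2x2 table (rows = screens, columns = SL /
#' non-SL), 1 degree of freedom, without continuity correction by default
#' (the motivating comparisons have large counts); Yates correction is
#' available by flag.
#'
#' @param table 2x2 non-negative integer matrix.
#' @param correct Apply Yates continuity correction.
#' @return List with `statistic` and `p_value`.
#' @export
compare_screens_chi2 <- function(table, correct = FALSE) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-square statistic undefined: a row or column total is zero",
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Pathway-pair stratified prediction report
#'
#' Groups validated pairs by the unordered pair of their genes' pathways
#' and reports, per occupied stratum and in a Total row: predicted SL /
#' non-SL call counts, validated SL / non-SL counts, precision and recall
#' of the binary calls, AUC-ROC / AUPR / Precision@10 of the probabilities,
#' and the validated SL ratio. Metrics undefined within a stratum (single
#' class, no positives, zero denominators) are reported as NA.
#'
#' @param screen An `sl_screen` whose `sl_label` holds the validated
#'   labels.
#' @param predictions data.frame with columns `gene_a`, `gene_b`,
#'   `probability` and optionally `call` (binary predicted-SL calls; if
#'   absent, `probability >= call_threshold` is used).
#' @param pathway_map data.frame with columns `gene`, `pathway`; a gene
#'   annotated to several pathways takes its first mapping in file order
#'   (with a warning).
#' @param call_threshold Probability cutoff for derived calls.
#' @return A data.frame of `StratifiedRow`s, Total row last.
#' @export
stratified_report <- function(screen, predictions, pathway_map,
                              call_threshold = 0.5) {
  stopifnot(inherits(screen, "sl_screen"))
  if (anyNA(screen$records$sl_label)) {
    stop("screen must carry validated sl_label values", call. = FALSE)
  }
  if (anyDuplicated(pathway_map$gene)) {
    warning("gene(s) annotated to multiple pathways; keeping first mapping",
            call. = FALSE)
    pathway_map <- pathway_map[!duplicated(pathway_map$gene), , drop = FALSE]
  }
  path_of <- stats::setNames(pathway_map$pathway, pathway_map$gene)
  rec <- screen$records
  cp <- canonical_pairs(predictions$gene_a, predictions$gene_b)
  pred_key <- cp$key
  rec_key <- paste(rec$gene_a, rec$gene_b, sep = "|")
  hit <- match(rec_key, pred_key)
  if (anyNA(hit)) {
    stop("predictions missing for ", sum(is.na(hit)), " screen pair(s)",
         call. = FALSE)
  }
  prob <- predictions$probability[hit]
  call <- if ("call" %in% names(predictions)) {
    as.integer(predictions$call[hit])
  } else {
    as.integer(prob >= call_threshold)
  }
  unmapped <- setdiff(unique(c(rec$gene_a, rec$gene_b)), names(path_of))
  if (length(unmapped)) {
    stop("gene(s) missing from pathway map: ",
         paste(utils::head(unmapped, 10), collapse = ", "), call. = FALSE)
  }
  pa <- as.character(path_of[rec$gene_a])
  pb <- as.character(path_of[rec$gene_b])
  stratum <- paste(pmin(pa, pb), pmax(pa, pb), sep = "/")
  one_stratum <- function(idx, name) {
    lab <- rec$sl_label[idx]
    p <- prob[idx]
    cl <- call[idx]
    tp <- sum(cl == 1L & lab == 1L)
    v_sl <- sum(lab == 1L)
    v_non <- sum(lab == 0L)
    safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    tie_key <- paste(rec$gene_a[idx], rec$gene_b[idx], sep = "|")
    data.frame(
      pathway_pair = name,
      predicted_sl = sum(cl == 1L),
      predicted_non_sl = sum(cl == 0L),
      validated_sl = v_sl,
      validated_non_sl = v_non,
      precision = if (sum(cl == 1L) > 0) tp / sum(cl == 1L) else NA_real_,
      recall = if (v_sl > 0) tp / v_sl else NA_real_,
      auc_roc = safe(auc_roc(lab, p)),
      aupr = safe(aupr(lab, p)),
      precision_at_10 = safe(precision_at_k(lab, p, 10, tie_key)),
      sl_ratio = if (v_sl + v_non > 0) v_sl / (v_sl + v_non) else NA_real_,
      stringsAsFactors = FALSE)
  }
  strata <- sort(unique(stratum))
  rows <- lapply(strata, function(s) one_stratum(which(stratum == s), s))
  rows <- c(rows, list(one_stratum(seq_len(nrow(rec)), "Total")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hub genes of an SL network
#'
#' Genes ranked by SL connectivity, descending, ties broken alphabetically
#' for determinism; the top `top_n` are retained.
#'
#' @param connectivity A `connectivity_vector`.
#' @param top_n Number of hub genes to keep.
#' @return A `hub_report` with the full ranking and the `top` gene set.
#' @export
hub_genes <- function(connectivity, top_n = 10) {
  stopifnot(inherits(connectivity, "connectivity_vector"), top_n >= 1)
  if (all(connectivity == 0)) {
    warning("all connectivities are zero; hub ranking is alphabetical",
            call. = FALSE)
  }
  ord <- order(-as.integer(connectivity), names(connectivity))
  ranked <- names(connectivity)[ord]
  top_n <- min(top_n, length(ranked))
  structure(list(ranked = ranked, top = ranked[seq_len(top_n)],
                 top_n = as.integer(top_n),
                 connectivity = connectivity),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("<hub_report> top %d: %s\n", x$top_n,
              paste(x$top, collapse = ", ")))
  invisible(x)
}

#' Overlap between two hub reports
#'
#' @param a,b `hub_report` objects.
#' @return Integer size of the intersection of the two top sets
#'   (symmetric).
#' @export
hub_overlap <- function(a, b) {
  stopifnot(inherits(a, "hub_report"), inherits(b, "hub_report"))
  length(intersect(a$top, b$top))
}

#' Correlation of predicted and validated SL connectivity
#'
#' Pearson correlation over a gene subset, with the two-sided p-value from
#' the t distribution.
#'
#' @param predicted,validated `connectivity_vector`s (or named numeric
#'   vectors) defined on `gene_subset`.
#' @param gene_subset Genes to correlate over (at least 3).
#' @return List with `pearson_r` and `p_value`.
#' @export
connectivity_correlation <- function(predicted, validated,
                                     gene_subset = intersect(names(predicted),
                                                             names(validated))) {
  if (length(gene_subset) < 3) {
    stop("need at least 3 genes to correlate", call. = FALSE)
  }
  x <- as.numeric(predicted[gene_subset])
  y <- as.numeric(validated[gene_subset])
  if (anyNA(x) || anyNA(y)) {
    stop("both vectors must be defined on gene_subset", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in a connectivity vector",
         call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value)
}
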