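# Threshold-free ranking metrics for imbalanced pair classification.

check_binary <- function(labels) {
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  labels
}

#' Area under the ROC curve
#'
#' Computed from the Mann-Whitney rank statistic, so it equals the
#' probability that a random positive outscores a random negative plus half
#' the tie probability. Invariant under any strictly monotone transform of
#' the scores.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores (higher = more likely positive).
#' @return AUC-ROC in \[0,1\].
#' @export
auc_roc <- function(labels, scores) {
  labels <- check_binary(labels)
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("auc_roc requires both classes present", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise convention: tied scores are grouped, precision is evaluated at
#' each recall change and the area is the recall-weighted sum of those
#' precisions (no trapezoidal interpolation, which overestimates PR areas).
#' With all scores tied the result is the positive prevalence.
#'
#' @inheritParams auc_roc
#' @return AUPR in \[0,1\].
#' @export
aupr <- function(labels, scores) {
  labels <- check_binary(labels)
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0) stop("aupr requires at least one positive", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # group tied scores: cumulative counts at each distinct-score boundary
  boundary <- c(sc[-1] != sc[-length(sc)], TRUE)
  cum_tp <- cumsum(lab)[boundary]
  cum_n <- seq_along(lab)[boundary]
  precision <- cum_tp / cum_n
  recall <- cum_tp / n_pos
  d_recall <- diff(c(0, recall))
  sum(d_recall * precision)
}

#' Precision among the top k% of predictions
#'
#' Takes the `ceiling(k_percent/100 * N)` highest-scored items (stable sort
#' with an optional deterministic secondary key for ties) and returns the
#' fraction of positives among them. At `k_percent = 100` this is the
#' prevalence.
#'
#' @inheritParams auc_roc
#' @param k_percent Percentage of the list to keep, in (0, 100\].
#' @param tie_key Optional vector (e.g. lexicographic gene-pair keys) used
#'   as a deterministic secondary sort key among tied scores; defaults to
#'   input order.
#' @return Precision in \[0,1\].
#' @export
precision_at_k <- function(labels, scores, k_percent = 10, tie_key = NULL) {
  labels <- check_binary(labels)
  stopifnot(length(labels) == length(scores),
            k_percent > 0, k_percent <= 100)
  m <- ceiling(k_percent / 100 * length(labels))
  ord <- if (is.null(tie_key)) {
    order(-scores, seq_along(scores))
  } else {
    order(-scores, tie_key)
  }
  mean(labels[ord][seq_len(m)])
}
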