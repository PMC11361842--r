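# Train/validation/test splits, including the nonoverlap (gene-disjoint)
# setting used to measure generalization to unseen genes.

new_split_spec <- function(mode, train_genes, test_genes, train_pairs,
                           val_pairs, test_pairs, seed, n_discarded = 0L) {
  structure(list(mode = mode, train_genes = train_genes,
                 test_genes = test_genes, train_pairs = train_pairs,
                 val_pairs = val_pairs, test_pairs = test_pairs,
                 seed = seed, n_discarded = as.integer(n_discarded)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf(
    "<split_spec> %s: %d train / %d test genes; %d train + %d val + %d test pairs (%d discarded)\n",
    x$mode, length(x$train_genes), length(x$test_genes),
    nrow(x$train_pairs), nrow(x$val_pairs), nrow(x$test_pairs),
    x$n_discarded))
  invisible(x)
}

split_pair_frame <- function(screen) {
  screen$records[, c("gene_a", "gene_b", "sl_label"), drop = FALSE]
}

#' Nonoverlap (gene-disjoint) train/test split
#'
#' Partitions the gene universe uniformly at random into a training and a
#' test side with no shared genes. Test pairs are the screen pairs with
#' both endpoints among test genes; training-side pairs have both endpoints
#' among training genes; cross pairs (one endpoint on each side) are
#' discarded so that no test gene influences training. A random
#' `val_pair_fraction` of the training-side pairs is set aside as internal
#' validation pairs.
#'
#' @param bundle A labeled `dataset_bundle`.
#' @param test_gene_fraction Fraction of genes assigned to the test side.
#' @param val_pair_fraction Fraction of training-side pairs held out as
#'   validation pairs.
#' @param seed Split seed.
#' @return A `split_spec` with `mode = "nonoverlap"`.
#' @export
split_nonoverlap <- function(bundle, test_gene_fraction = 0.2,
                             val_pair_fraction = 0.2, seed = 0) {
  stopifnot(inherits(bundle, "dataset_bundle"),
            test_gene_fraction > 0, test_gene_fraction < 1,
            val_pair_fraction > 0, val_pair_fraction < 1)
  universe <- bundle$universe
  pairs <- split_pair_frame(bundle$screen)
  withr_seed(seed, {
    n_test <- max(1L, round(test_gene_fraction * length(universe)))
    test_genes <- sort(sample(universe, n_test))
    train_genes <- setdiff(universe, test_genes)
    in_test_a <- pairs$gene_a %in% test_genes
    in_test_b <- pairs$gene_b %in% test_genes
    test_pairs <- pairs[in_test_a & in_test_b, , drop = FALSE]
    train_side <- pairs[!in_test_a & !in_test_b, , drop = FALSE]
    n_discarded <- nrow(pairs) - nrow(test_pairs) - nrow(train_side)
    if (!nrow(test_pairs)) {
      stop("nonoverlap split produced no test pairs; increase test_gene_fraction",
           call. = FALSE)
    }
    n_val <- round(val_pair_fraction * nrow(train_side))
    val_idx <- sample(nrow(train_side), n_val)
    val_pairs <- train_side[val_idx, , drop = FALSE]
    train_pairs <- train_side[setdiff(seq_len(nrow(train_side)), val_idx), ,
                              drop = FALSE]
  })
  rownames(test_pairs) <- rownames(val_pairs) <- rownames(train_pairs) <- NULL
  new_split_spec("nonoverlap", train_genes, test_genes, train_pairs,
                 val_pairs, test_pairs, seed, n_discarded)
}

#' Overlap (pair-level) train/test split
#'
#' Splits screen pairs uniformly at random regardless of gene membership;
#' genes may appear on both sides and no pair is discarded.
#'
#' @param bundle A labeled `dataset_bundle`.
#' @param test_pair_fraction Fraction of pairs assigned to the test set.
#' @param val_pair_fraction Fraction of the remaining pairs held out as
#'   validation pairs.
#' @param seed Split seed.
#' @return A `split_spec` with `mode = "overlap"`; `train_genes` is the
#'   full universe (genes are shared by construction).
#' @export
split_overlap <- function(bundle, test_pair_fraction = 0.2,
                          val_pair_fraction = 0.2, seed = 0) {
  stopifnot(inherits(bundle, "dataset_bundle"),
            test_pair_fraction > 0, test_pair_fraction < 1,
            val_pair_fraction > 0, val_pair_fraction < 1)
  pairs <- split_pair_frame(bundle$screen)
  withr_seed(seed, {
    n_test <- round(test_pair_fraction * nrow(pairs))
    test_idx <- sample(nrow(pairs), n_test)
    rest <- setdiff(seq_len(nrow(pairs)), test_idx)
    n_val <- round(val_pair_fraction * length(rest))
    val_idx <- sample(rest, n_val)
    train_idx <- setdiff(rest, val_idx)
  })
  if (!length(test_idx)) {
    stop("overlap split produced no test pairs; increase test_pair_fraction",
         call. = FALSE)
  }
  test_pairs <- pairs[test_idx, , drop = FALSE]
  val_pairs <- pairs[val_idx, , drop = FALSE]
  train_pairs <- pairs[train_idx, , drop = FALSE]
  rownames(test_pairs) <- rownames(val_pairs) <- rownames(train_pairs) <- NULL
  new_split_spec("overlap", bundle$universe, bundle$universe, train_pairs,
                 val_pairs, test_pairs, seed, 0L)
}
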