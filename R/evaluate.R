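# End-to-end two-step runs, repeated-split aggregation, and the ablation
# harness.

#' Run the two-step pipeline on one split
#'
#' Trains the connectivity model on the split's training side, predicts
#' per-gene connectivities, fits the logistic pair classifier on
#' training-side pairs using those *predicted* connectivities, and scores
#' the test pairs.
#'
#' @param bundle A labeled `dataset_bundle`.
#' @param split A `split_spec`.
#' @param config A `model_config`.
#' @param weighting Class weighting for the pair classifier.
#' @param feature_set Pair feature set (see [pair_features()]).
#' @param feature_transform Per-feature transform for the classifier;
#'   `"log1p"` by default because connectivity counts are heavy-tailed.
#' @return List with `model`, `classifier`, `connectivity_pred` (all
#'   genes), `test` (data.frame of test pairs with `sl_label` and `score`)
#'   and the split.
#' @export
run_two_step <- function(bundle, split, config = model_config(),
                         weighting = "balanced",
                         feature_set = c("min", "max", "product"),
                         feature_transform = "log1p") {
  model <- train_connectivity_model(bundle, split, config)
  chat <- predict_connectivity(bundle, model)
  train_side <- rbind(split$train_pairs, split$val_pairs)
  feats <- pair_features(chat[train_side$gene_a], chat[train_side$gene_b],
                         feature_set = feature_set)
  classifier <- fit_sl_classifier(feats, train_side$sl_label,
                                  weighting = weighting,
                                  feature_transform = feature_transform)
  test <- split$test_pairs
  test$score <- predict_sl(classifier, test, chat)
  list(model = model, classifier = classifier, connectivity_pred = chat,
       test = test, split = split)
}

metric_row <- function(labels, scores, k_percent, tie_key = NULL) {
  data.frame(aupr = aupr(labels, scores),
             auc_roc = auc_roc(labels, scores),
             precision_at_k = precision_at_k(labels, scores, k_percent,
                                             tie_key))
}

new_metrics_report <- function(per_run, k_percent, mode, single_run_flag) {
  metrics <- c("aupr", "auc_roc", "precision_at_k")
  agg_mean <- colMeans(per_run[, metrics, drop = FALSE])
  agg_sd <- if (nrow(per_run) > 1) {
    apply(per_run[, metrics, drop = FALSE], 2, stats::sd)
  } else {
    stats::setNames(rep(0, length(metrics)), metrics)
  }
  structure(list(per_run = per_run, mean = agg_mean, sd = agg_sd,
                 n_runs = nrow(per_run), k_percent = k_percent, mode = mode,
                 single_run = single_run_flag,
                 aupr_convention = "stepwise precision at each recall change, ties grouped"),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s evaluation, %d run(s)%s\n", x$mode,
              x$n_runs, if (x$single_run) " [single run: sd is 0 by definition]" else ""))
  for (m in names(x$mean)) {
    label <- if (m == "precision_at_k") sprintf("Precision@%g%%", x$k_percent) else toupper(m)
    cat(sprintf("  %-14s %.3f ± %.3f\n", label, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Repeated-split evaluation of the two-step pipeline
#'
#' For run i (seed `run_seeds[i]`, default 0..n_runs-1) the bundle is
#' split, both steps are trained on the training side, test pairs are
#' scored, and AUPR / AUC-ROC / Precision@k are computed. Aggregates are
#' the arithmetic mean and the (n-1)-denominator standard deviation over
#' runs.
#'
#' @param bundle A labeled `dataset_bundle`.
#' @param model_config A `model_config`; run i trains with seed
#'   `model_config$seed + run_seeds[i]`.
#' @param n_runs Number of repeated splits.
#' @param mode `"nonoverlap"` or `"overlap"`.
#' @param test_fraction,val_fraction Split fractions (genes for
#'   nonoverlap, pairs for overlap).
#' @param k_percent k for Precision@k.
#' @param run_seeds Optional explicit split seeds.
#' @return A `metrics_report`.
#' @export
repeated_evaluation <- function(bundle, model_config = model_config(),
                                n_runs = 10,
                                mode = c("nonoverlap", "overlap"),
                                test_fraction = 0.2, val_fraction = 0.2,
                                k_percent = 10, run_seeds = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_runs >= 1)
  run_seeds <- run_seeds %||% (seq_len(n_runs) - 1L)
  stopifnot(length(run_seeds) == n_runs)
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    split <- if (mode == "nonoverlap") {
      split_nonoverlap(bundle, test_fraction, val_fraction,
                       seed = run_seeds[i])
    } else {
      split_overlap(bundle, test_fraction, val_fraction,
                    seed = run_seeds[i])
    }
    cfg <- model_config
    cfg$seed <- model_config$seed + as.integer(run_seeds[i])
    res <- run_two_step(bundle, split, cfg)
    tie_key <- paste(res$test$gene_a, res$test$gene_b, sep = "|")
    row <- metric_row(res$test$sl_label, res$test$score, k_percent, tie_key)
    rows[[i]] <- cbind(data.frame(run = i, seed = run_seeds[i]), row)
  }
  per_run <- do.call(rbind, rows)
  new_metrics_report(per_run, k_percent, mode, single_run_flag = n_runs == 1)
}

#' Ablation specification
#'
#' Declares which input sources stay real; every disabled source is
#' replaced by a shape-matched random stand-in (standard-Normal feature
#' matrices; equal-size uniform random edge sets for network views), the
#' random-features control. With all three source flags off, the run is
#' the all-random control row. `single_feature` keeps exactly one named
#' source (a view name or a feature-table name) real and randomizes the
#' rest. `use_transformer = FALSE` bypasses the transformer stage
#' (graph-encoder-only model).
#'
#' @param use_network_features,use_population_omics,use_cell_specific_omics
#'   Logical flags.
#' @param use_transformer Logical flag.
#' @param single_feature Optional name of the single source kept real.
#' @return An `ablation_spec`.
#' @export
ablation_spec <- function(use_network_features = TRUE,
                          use_population_omics = TRUE,
                          use_cell_specific_omics = TRUE,
                          use_transformer = TRUE,
                          single_feature = NULL) {
  structure(list(use_network_features = isTRUE(use_network_features),
                 use_population_omics = isTRUE(use_population_omics),
                 use_cell_specific_omics = isTRUE(use_cell_specific_omics),
                 use_transformer = isTRUE(use_transformer),
                 single_feature = single_feature),
            class = "ablation_spec")
}

# Random stand-ins, seeded per run for reproducibility.
randomize_feature_table <- function(ft) {
  v <- ft$values
  r <- matrix(stats::rnorm(length(v)), nrow(v), ncol(v), dimnames = dimnames(v))
  if (ft$modality == "mutation") {
    # keep the modality invariant: non-negative integer counts
    r <- matrix(stats::rpois(length(v), lambda = 1), nrow(v), ncol(v),
                dimnames = dimnames(v))
    ft$modality <- "other"  # contents are random, no longer real mutations
  }
  ft$values <- r
  ft
}

randomize_network_view <- function(nv, universe) {
  n_edges <- nrow(nv$edges)
  n <- length(universe)
  max_edges <- n * (n - 1) / 2
  n_edges <- min(n_edges, max_edges)
  keys <- character(0)
  while (length(keys) < n_edges) {
    need <- n_edges - length(keys)
    ia <- sample.int(n, need, replace = TRUE)
    ib <- sample.int(n, need, replace = TRUE)
    ok <- ia != ib
    a <- pmin(universe[ia[ok]], universe[ib[ok]])
    b <- pmax(universe[ia[ok]], universe[ib[ok]])
    keys <- unique(c(keys, paste(a, b, sep = "|")))
  }
  keys <- keys[seq_len(n_edges)]
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- network_view(nv$name,
                      data.frame(gene_a = vapply(parts, `[`, "", 1),
                                 gene_b = vapply(parts, `[`, "", 2),
                                 stringsAsFactors = FALSE))
  out$node_set <- universe
  out
}

apply_ablation <- function(bundle, spec, seed) {
  withr_seed(seed, {
    single <- spec$single_feature
    keep_ft <- function(ft) {
      if (!is.null(single)) return(ft$name == single || ft$modality == single)
      (ft$scope == "population" && spec$use_population_omics) ||
        (ft$scope == "cell_specific" && spec$use_cell_specific_omics)
    }
    keep_nv <- function(nv) {
      if (!is.null(single)) return(nv$name == single)
      spec$use_network_features
    }
    features <- lapply(bundle$features, function(ft) {
      if (keep_ft(ft)) ft else randomize_feature_table(ft)
    })
    networks <- lapply(bundle$networks, function(nv) {
      if (keep_nv(nv)) nv else randomize_network_view(nv, bundle$universe)
    })
  })
  out <- bundle
  out$features <- features
  out$networks <- networks
  out
}

#' Ablation run
#'
#' Repeated evaluation of the pipeline with disabled input sources replaced
#' by random stand-ins, reproducing the ablation-table protocol: each run
#' rebuilds the randomized bundle under that run's seed, so the random
#' controls vary across runs like any other stochastic component.
#'
#' @param bundle A labeled `dataset_bundle`.
#' @param spec An `ablation_spec`.
#' @param model_config A `model_config`.
#' @param n_runs Number of repeated splits.
#' @param ... Passed to [repeated_evaluation()].
#' @return A `metrics_report`.
#' @export
ablation_run <- function(bundle, spec, model_config = model_config(),
                         n_runs = 10, ...) {
  stopifnot(inherits(spec, "ablation_spec"))
  cfg <- model_config
  cfg$use_transformer <- spec$use_transformer
  dots <- list(...)
  mode <- dots$mode %||% "nonoverlap"
  test_fraction <- dots$test_fraction %||% 0.2
  val_fraction <- dots$val_fraction %||% 0.2
  k_percent <- dots$k_percent %||% 10
  run_seeds <- dots$run_seeds %||% (seq_len(n_runs) - 1L)
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    abl_bundle <- apply_ablation(bundle, spec, seed = run_seeds[i] + 7919L)
    split <- if (mode == "nonoverlap") {
      split_nonoverlap(abl_bundle, test_fraction, val_fraction,
                       seed = run_seeds[i])
    } else {
      split_overlap(abl_bundle, test_fraction, val_fraction,
                    seed = run_seeds[i])
    }
    run_cfg <- cfg
    run_cfg$seed <- cfg$seed + as.integer(run_seeds[i])
    res <- run_two_step(abl_bundle, split, run_cfg)
    tie_key <- paste(res$test$gene_a, res$test$gene_b, sep = "|")
    rows[[i]] <- cbind(data.frame(run = i, seed = run_seeds[i]),
                       metric_row(res$test$sl_label, res$test$score,
                                  k_percent, tie_key))
  }
  per_run <- do.call(rbind, rows)
  new_metrics_report(per_run, k_percent, mode, single_run_flag = n_runs == 1)
}
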