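# Synthetic benchmark generator: scale-free SL graph, GI scores,
# connectivity-coupled omics features, and correlated network views.

#' Simulation configuration
#'
#' Defines the statistical conditions of a synthetic benchmark: a
#' preferential-attachment SL graph over `n_genes`, Gaussian GI scores
#' around class means `gi_mean_sl` / `gi_mean_non_sl`, omics features whose
#' variance is split between standardized log-connectivity signal and
#' independent noise, and network views obtained by randomly rewiring the
#' SL graph.
#'
#' @param n_genes Number of genes.
#' @param attachment_m Preferential-attachment edges added per new node
#'   (must satisfy `1 <= attachment_m < n_genes`).
#' @param feature_signal Fraction in \[0,1\] of each feature's construction
#'   weight on standardized log1p-connectivity (the rest is N(0,1) noise).
#' @param n_features_per_block Features per omics block.
#' @param network_rewire_prob Per-edge probability in \[0,1\] that a view
#'   edge is replaced by a uniform random non-edge.
#' @param gi_noise_sd Standard deviation of GI scores around their class
#'   mean (>= 0).
#' @param gi_mean_sl,gi_mean_non_sl GI-score class means; chosen so the -3
#'   labeling threshold separates the classes.
#' @param seed Master seed; every component derives its own sub-stream from
#'   it, so the whole benchmark is a pure function of the configuration.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_genes = 500, attachment_m = 2, feature_signal = 0.7,
                       n_features_per_block = 8, network_rewire_prob = 0.2,
                       gi_noise_sd = 1, gi_mean_sl = -5, gi_mean_non_sl = 0,
                       seed = 0) {
  stopifnot(n_genes >= 3, attachment_m >= 1, attachment_m < n_genes,
            feature_signal >= 0, feature_signal <= 1,
            network_rewire_prob >= 0, network_rewire_prob <= 1,
            gi_noise_sd >= 0, n_features_per_block >= 1)
  structure(list(n_genes = as.integer(n_genes),
                 attachment_m = as.integer(attachment_m),
                 feature_signal = feature_signal,
                 n_features_per_block = as.integer(n_features_per_block),
                 network_rewire_prob = network_rewire_prob,
                 gi_noise_sd = gi_noise_sd,
                 gi_mean_sl = gi_mean_sl,
                 gi_mean_non_sl = gi_mean_non_sl,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic per-component sub-seed below 2^31.
sub_seed <- function(seed, component) {
  offsets <- c(graph = 11L, gi = 23L, features = 37L, networks = 53L)
  (abs(seed) * 2654435761) %% 1000000007 + offsets[[component]]
}

sim_gene_names <- function(n) sprintf("g%05d", seq_len(n))

#' Simulate a scale-free SL graph by preferential attachment
#'
#' Grows a Barabasi-Albert-type graph: starting from `attachment_m` seed
#' nodes, each new node attaches to `attachment_m` distinct existing nodes
#' with probability proportional to their current degree (uniformly while
#' all degrees are zero). The result has exactly
#' `attachment_m * (n_genes - attachment_m)` edges and a heavy-tailed
#' degree distribution (exponent near 3 for large graphs), matching the
#' scale-free connectivity pattern observed in real SL networks.
#'
#' @param config A `sim_config`.
#' @return A `sim_truth`: `true_sl_pairs` (canonical pair data.frame),
#'   `true_connectivity` (degree = number of SL partners) and the echoed
#'   config.
#' @export
simulate_sl_graph <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  m <- config$attachment_m
  genes <- sim_gene_names(n)
  edges_a <- integer(m * (n - m))
  edges_b <- integer(m * (n - m))
  deg <- integer(n)
  k <- 0L
  withr_seed(sub_seed(config$seed, "graph"), {
    for (i in seq.int(m + 1L, n)) {
      w <- deg[seq_len(i - 1L)]
      if (sum(w) == 0) w <- rep(1, i - 1L)
      targets <- sample.int(i - 1L, m, prob = w)
      for (t in targets) {
        k <- k + 1L
        edges_a[k] <- t
        edges_b[k] <- i
        deg[t] <- deg[t] + 1L
        deg[i] <- deg[i] + 1L
      }
    }
  })
  pairs <- canonical_pairs(genes[edges_a], genes[edges_b])
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b),
                 c("gene_a", "gene_b"), drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(true_sl_pairs = pairs,
                 true_connectivity = connectivity_vector(
                   stats::setNames(deg, genes)),
                 config = config),
            class = "sim_truth")
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d genes, %d true SL pairs (max connectivity %d)\n",
              x$config$n_genes, nrow(x$true_sl_pairs),
              max(x$true_connectivity)))
  invisible(x)
}

#' Simulate GI scores for every gene pair
#'
#' Every unordered pair of simulated genes receives a Gaussian GI score:
#' true SL pairs around `gi_mean_sl` (default -5), non-SL pairs around
#' `gi_mean_non_sl` (default 0), both with `gi_noise_sd`. Labeling the
#' resulting screen at the -3 threshold recovers the true SL set with an
#' error rate set by the per-class Gaussian tail beyond the threshold.
#'
#' @param truth A `sim_truth` from [simulate_sl_graph()].
#' @param config The `sim_config` (defaults to the one echoed in `truth`).
#' @return An unlabeled `sl_screen` covering all pairs.
#' @export
simulate_gi_scores <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  genes <- names(truth$true_connectivity)
  n <- length(genes)
  idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  a <- genes[idx[, 1]]
  b <- genes[idx[, 2]]
  key <- paste(pmin(a, b), pmax(a, b), sep = "|")
  true_keys <- paste(truth$true_sl_pairs$gene_a, truth$true_sl_pairs$gene_b,
                     sep = "|")
  is_sl <- key %in% true_keys
  mu <- ifelse(is_sl, config$gi_mean_sl, config$gi_mean_non_sl)
  scores <- withr_seed(sub_seed(config$seed, "gi"),
                       stats::rnorm(length(mu), mean = mu,
                                    sd = config$gi_noise_sd))
  screen_from_records(a, b, scores, cell_line = "simulated")
}

#' Simulate omics feature tables coupled to SL connectivity
#'
#' Each feature of gene g is built as
#' `feature_signal * z(g) + (1 - feature_signal) * e`, where `z` is the
#' standardized log1p true connectivity and `e` is independent N(0,1)
#' noise, so at signal s the population feature/connectivity correlation is
#' `s / sqrt(s^2 + (1 - s)^2)`. Two tables are produced: a continuous
#' population-scope expression block and a cell-specific mutation block
#' whose entries are Poisson counts with rate `exp(min(raw, 3))` — sparse
#' non-negative integers, as mutation profiles are.
#'
#' @inheritParams simulate_gi_scores
#' @return List of two `feature_table` objects.
#' @export
simulate_features <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  genes <- names(truth$true_connectivity)
  n <- length(genes)
  p <- config$n_features_per_block
  s <- config$feature_signal
  z <- as.numeric(scale(log1p(as.numeric(truth$true_connectivity))))
  if (anyNA(z)) z <- rep(0, n)  # degenerate constant connectivity
  withr_seed(sub_seed(config$seed, "features"), {
    expr_raw <- s * z + (1 - s) * matrix(stats::rnorm(n * p), n, p)
    mut_raw <- s * z + (1 - s) * matrix(stats::rnorm(n * p), n, p)
    mut <- matrix(stats::rpois(n * p, lambda = exp(pmin(mut_raw, 3))), n, p)
  })
  dimnames(expr_raw) <- list(genes, sprintf("expr_%02d", seq_len(p)))
  dimnames(mut) <- list(genes, sprintf("mut_%02d", seq_len(p)))
  list(feature_table(expr_raw, "population", "expression"),
       feature_table(mut, "cell_specific", "mutation"))
}

#' Simulate correlated biological network views
#'
#' Each view starts as a copy of the true SL graph; every edge is then
#' independently replaced, with probability `network_rewire_prob`, by a
#' uniformly drawn non-edge. Edge count is preserved exactly; at rewire 0 a
#' view equals the SL graph, at rewire 1 it is an unrelated random graph of
#' the same size. Views are mutually independent given the truth.
#'
#' @inheritParams simulate_gi_scores
#' @param view_names Names of the generated views.
#' @return List of `network_view` objects.
#' @export
simulate_network_views <- function(truth, config = truth$config,
                                   view_names = c("ppi_physical",
                                                  "ppi_genetic", "pathway")) {
  stopifnot(inherits(truth, "sim_truth"))
  genes <- names(truth$true_connectivity)
  base_keys <- paste(truth$true_sl_pairs$gene_a, truth$true_sl_pairs$gene_b,
                     sep = "|")
  withr_seed(sub_seed(config$seed, "networks"), {
    lapply(view_names, function(nm) {
      keys <- base_keys
      rewire <- stats::runif(length(keys)) < config$network_rewire_prob
      keyset <- new.env(hash = TRUE, parent = emptyenv())
      for (k in keys) assign(k, TRUE, envir = keyset)
      for (i in which(rewire)) {
        repeat {
          cand <- sort(genes[sample.int(length(genes), 2)])
          ck <- paste(cand[1], cand[2], sep = "|")
          if (!exists(ck, envir = keyset, inherits = FALSE)) {
            rm(list = keys[i], envir = keyset)
            assign(ck, TRUE, envir = keyset)
            keys[i] <- ck
            break
          }
        }
      }
      parts <- strsplit(keys, "|", fixed = TRUE)
      edges <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                          gene_b = vapply(parts, `[`, "", 2),
                          stringsAsFactors = FALSE)
      nv <- network_view(nm, edges)
      nv$node_set <- genes
      nv
    })
  })
}

#' Compose a ready-to-train synthetic benchmark
#'
#' Runs the four simulators under one master seed and assembles their
#' output into a labeled `dataset_bundle` (complete-pair screen labeled at
#' the -3 threshold, two feature tables, three network views) plus the
#' generating `sim_truth`.
#'
#' @param config A `sim_config`.
#' @return List with elements `bundle` and `truth`.
#' @export
make_benchmark <- function(config = sim_config()) {
  truth <- simulate_sl_graph(config)
  screen <- label_pairs(simulate_gi_scores(truth, config), threshold = -3)
  features <- simulate_features(truth, config)
  networks <- simulate_network_views(truth, config)
  bundle <- dataset_bundle(screen, features, networks)
  bundle$connectivity <- compute_connectivity(screen)
  list(bundle = bundle, truth = truth)
}

#' Write a benchmark (bundle + truth) as TSV files
#'
#' Adds `truth_pairs.tsv` and `truth_connectivity.tsv` next to the files
#' written by [write_bundle()].
#'
#' @param benchmark Output of [make_benchmark()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  write_bundle(benchmark$bundle, dir)
  utils::write.table(benchmark$truth$true_sl_pairs,
                     file.path(dir, "truth_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  conn <- data.frame(gene = names(benchmark$truth$true_connectivity),
                     connectivity = as.integer(benchmark$truth$true_connectivity),
                     stringsAsFactors = FALSE)
  utils::write.table(conn, file.path(dir, "truth_connectivity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
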