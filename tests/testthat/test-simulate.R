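# Synthetic benchmark generator: scale-free graph, GI scores, features,
# network views, and the composed benchmark.

test_that("preferential attachment yields the exact edge-count identity", {
  truth <- simulate_sl_graph(sim_config(n_genes = 100, attachment_m = 2,
                                        seed = 0))
  expect_equal(nrow(truth$true_sl_pairs), 2 * (100 - 2))
  expect_equal(sum(truth$true_connectivity), 2 * nrow(truth$true_sl_pairs))

  truth3 <- simulate_sl_graph(sim_config(n_genes = 50, attachment_m = 3,
                                         seed = 1))
  expect_equal(nrow(truth3$true_sl_pairs), 3 * (50 - 3))

  # determinism
  truth2 <- simulate_sl_graph(sim_config(n_genes = 100, attachment_m = 2,
                                         seed = 0))
  expect_identical(truth$true_sl_pairs, truth2$true_sl_pairs)
})

test_that("generated degree distribution is heavy-tailed with exponent near 3", {
  truth <- simulate_sl_graph(sim_config(n_genes = 2000, attachment_m = 2,
                                        seed = 0))
  deg <- as.integer(truth$true_connectivity)
  # scale-free signature: max degree far above the median
  expect_gt(max(deg), 10 * stats::median(deg))
  # tail exponent from the complementary CDF of the degree histogram:
  # P(D >= d) ~ d^-(alpha-1); regress log survival on log degree over the
  # tail d >= 4
  ds <- sort(unique(deg[deg >= 4]))
  surv <- vapply(ds, function(d) mean(deg >= d), numeric(1))
  fit <- stats::lm(log(surv) ~ log(ds))
  alpha <- 1 - unname(stats::coef(fit)[2])
  expect_gt(alpha, 2.3)
  expect_lt(alpha, 3.7)
})

test_that("GI scores recover the truth at the labeling threshold", {
  cfg0 <- sim_config(n_genes = 60, gi_noise_sd = 0, seed = 3)
  truth <- simulate_sl_graph(cfg0)
  screen <- label_pairs(simulate_gi_scores(truth, cfg0))
  sl <- screen$records[screen$records$sl_label == 1L, ]
  expect_setequal(paste(sl$gene_a, sl$gene_b),
                  paste(truth$true_sl_pairs$gene_a,
                        truth$true_sl_pairs$gene_b))
  # full screen invariants
  n <- cfg0$n_genes
  expect_equal(nrow(screen$records), n * (n - 1) / 2)
  expect_equal(length(screen$gene_universe), n)
})

test_that("labeling error rates match the per-class Gaussian tails", {
  # class means -5 (SL) and 0 (non-SL), threshold -3, sd 1:
  # SL flips with prob pnorm(-2), non-SL with prob pnorm(-3)
  cfg <- sim_config(n_genes = 150, gi_noise_sd = 1, seed = 7)
  truth <- simulate_sl_graph(cfg)
  screen <- label_pairs(simulate_gi_scores(truth, cfg))
  keys <- paste(screen$records$gene_a, screen$records$gene_b, sep = "|")
  true_keys <- paste(truth$true_sl_pairs$gene_a, truth$true_sl_pairs$gene_b,
                     sep = "|")
  is_true_sl <- keys %in% true_keys
  lab <- screen$records$sl_label
  flip_sl <- mean(lab[is_true_sl] == 0L)
  flip_non <- mean(lab[!is_true_sl] == 1L)
  n_sl <- sum(is_true_sl); n_non <- sum(!is_true_sl)
  p_sl <- stats::pnorm(-2); p_non <- stats::pnorm(-3)
  expect_lt(abs(flip_sl - p_sl), 3 * sqrt(p_sl * (1 - p_sl) / n_sl))
  expect_lt(abs(flip_non - p_non), 3 * sqrt(p_non * (1 - p_non) / n_non))
})

test_that("feature/connectivity coupling follows the signal-to-noise formula", {
  # population correlation = s / sqrt(s^2 + (1-s)^2)
  z_of <- function(truth) as.numeric(scale(log1p(as.numeric(truth$true_connectivity))))

  cfg1 <- sim_config(n_genes = 2000, feature_signal = 1, seed = 5)
  truth1 <- simulate_sl_graph(cfg1)
  f1 <- simulate_features(truth1, cfg1)
  expect_equal(unname(stats::cor(f1[[1]]$values[, 1], z_of(truth1))), 1,
               tolerance = 1e-10)

  cfg0 <- sim_config(n_genes = 2000, feature_signal = 0, seed = 5)
  f0 <- simulate_features(truth1, cfg0)
  expect_lt(abs(stats::cor(f0[[1]]$values[, 1], z_of(truth1))), 0.1)

  cfg5 <- sim_config(n_genes = 2000, feature_signal = 0.5, seed = 5)
  f5 <- simulate_features(truth1, cfg5)
  rho <- 0.5 / sqrt(0.5^2 + 0.5^2)
  cors <- stats::cor(f5[[1]]$values, z_of(truth1))
  se <- (1 - rho^2) / sqrt(2000)
  expect_lt(abs(mean(cors) - rho), 3 * se)

  # mutation block is sparse non-negative integers
  mut <- f5[[2]]$values
  expect_true(all(mut >= 0) && all(mut == round(mut)))
})

test_that("network views preserve edge count and interpolate between copy and noise", {
  cfg <- sim_config(n_genes = 1000, network_rewire_prob = 0, seed = 2)
  truth <- simulate_sl_graph(cfg)
  v0 <- simulate_network_views(truth, cfg)
  true_keys <- paste(truth$true_sl_pairs$gene_a, truth$true_sl_pairs$gene_b,
                     sep = "|")
  for (v in v0) {
    expect_identical(paste(v$edges$gene_a, v$edges$gene_b, sep = "|"),
                     true_keys)
  }
  cfg1 <- sim_config(n_genes = 1000, network_rewire_prob = 1, seed = 2)
  v1 <- simulate_network_views(truth, cfg1)
  for (v in v1) {
    expect_equal(nrow(v$edges), length(true_keys))  # conservation
    keys <- paste(v$edges$gene_a, v$edges$gene_b, sep = "|")
    jaccard <- length(intersect(keys, true_keys)) /
      length(union(keys, true_keys))
    expect_lt(jaccard, 0.05)
  }
})

test_that("the composed benchmark is consistent and byte-deterministic", {
  cfg <- sim_config(n_genes = 80, seed = 11)
  bm <- make_benchmark(cfg)
  expect_equal(length(bm$bundle$universe), 80)
  expect_equal(nrow(bm$bundle$screen$records), 80 * 79 / 2)
  expect_length(bm$bundle$features, 2)
  expect_length(bm$bundle$networks, 3)
  expect_equal(sum(bm$bundle$connectivity),
               2L * sum(bm$bundle$screen$records$sl_label))

  bm2 <- make_benchmark(cfg)
  expect_identical(serialize(bm, NULL, version = 3),
                   serialize(bm2, NULL, version = 3))

  # serialized TSVs are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_benchmark(bm, d1); write_benchmark(bm2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }

  # noiseless pipeline consistency: labeled connectivity equals the truth
  cfg0 <- sim_config(n_genes = 60, gi_noise_sd = 0, seed = 4)
  bm0 <- make_benchmark(cfg0)
  expect_equal(as.integer(bm0$bundle$connectivity),
               as.integer(bm0$truth$true_connectivity))
})

test_that("a written bundle directory loads back equivalent", {
  bm <- small_benchmark(n = 30)
  d <- withr::local_tempdir()
  write_bundle(bm$bundle, d)
  b2 <- load_bundle(d, cell_line = bm$bundle$screen$cell_line)
  expect_equal(b2$universe, bm$bundle$universe)
  expect_equal(b2$screen$records, bm$bundle$screen$records,
               tolerance = 1e-10)
  expect_length(b2$features, length(bm$bundle$features))
  names1 <- vapply(bm$bundle$features, `[[`, "", "name")
  names2 <- vapply(b2$features, `[[`, "", "name")
  expect_setequal(names2, names1)
  for (ft in bm$bundle$features) {
    ft2 <- b2$features[[match(ft$name, names2)]]
    expect_equal(ft2$values, ft$values, tolerance = 1e-10)
    expect_equal(ft2$scope, ft$scope)
  }
  nm <- function(nets) sort(vapply(nets, `[[`, "", "name"))
  expect_equal(nm(b2$networks), nm(bm$bundle$networks))
})
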