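# Double-knockout screen analytics.

test_that("sl_rate reproduces the published screen fractions", {
  expect_equal(round(sl_rate(462, 525), 3), 0.468)
  expect_equal(sl_rate(88, 1137), 88 / 1225)
  expect_equal(round(100 * sl_rate(88, 1137), 1), 7.2)
  expect_equal(sl_rate(0, 10), 0)
  expect_error(sl_rate(0, 0), "zero total")
  # scale invariance
  expect_equal(sl_rate(6, 4), sl_rate(60, 40))
})

test_that("chi-square screen comparison matches the closed 2x2 formula", {
  tab <- matrix(c(88, 1137, 462, 525), 2, 2, byrow = TRUE)
  res <- compare_screens_chi2(tab)
  # independent closed-form oracle: n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  a <- 88; b <- 1137; c <- 462; d <- 525; n <- a + b + c + d
  oracle <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(res$statistic, oracle, tolerance = 1e-10)
  expect_lt(res$p_value, 1e-4)

  # identical proportions -> statistic 0, p 1
  res0 <- compare_screens_chi2(matrix(c(10, 90, 10, 90), 2, 2, byrow = TRUE))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # row/column swaps leave the statistic unchanged
  expect_equal(compare_screens_chi2(tab[2:1, ])$statistic, res$statistic)
  expect_equal(compare_screens_chi2(tab[, 2:1])$statistic, res$statistic)

  expect_error(compare_screens_chi2(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)),
               "undefined")
})

make_stratified_fixture <- function() {
  # two pathways, three strata with known counts
  genes <- sprintf("G%02d", 1:10)
  pathway_map <- data.frame(gene = genes,
                            pathway = rep(c("Apoptosis", "Mitotic"), each = 5))
  idx <- utils::combn(10, 2)
  gene_a <- genes[idx[1, ]]
  gene_b <- genes[idx[2, ]]
  withr_seed(8, {
    lab <- rbinom(ncol(idx), 1, 0.4)
    prob <- stats::runif(ncol(idx))
  })
  screen <- screen_from_records(gene_a, gene_b,
                                gi_score = ifelse(lab == 1, -5, 0),
                                sl_label = lab)
  predictions <- data.frame(gene_a = gene_a, gene_b = gene_b,
                            probability = prob)
  list(screen = screen, predictions = predictions, pathway_map = pathway_map)
}

test_that("stratified report groups by unordered pathway pair and conserves totals", {
  fx <- make_stratified_fixture()
  rep <- stratified_report(fx$screen, fx$predictions, fx$pathway_map)
  expect_equal(rep$pathway_pair,
               c("Apoptosis/Apoptosis", "Apoptosis/Mitotic",
                 "Mitotic/Mitotic", "Total"))
  total <- rep[rep$pathway_pair == "Total", ]
  strata <- rep[rep$pathway_pair != "Total", ]
  for (col in c("predicted_sl", "predicted_non_sl", "validated_sl",
                "validated_non_sl")) {
    expect_equal(total[[col]], sum(strata[[col]]))
  }
  expect_equal(rep$sl_ratio,
               rep$validated_sl / (rep$validated_sl + rep$validated_non_sl))
  # counts per stratum match a direct cross-tab
  expect_equal(strata$validated_sl + strata$validated_non_sl,
               c(choose(5, 2), 25, choose(5, 2)))
})

test_that("stratified report mirrors published-style count arithmetic", {
  # a stratum with 67 SL / 33 non-SL validates at ratio 0.670; a single
  # all-negative pair yields ratio 0 with undefined recall
  genes <- c(sprintf("M%03d", 1:101), "A1", "A2")
  pathway_map <- data.frame(gene = genes,
                            pathway = c(rep("Mitotic", 101), "Autosis",
                                        "Autosis"))
  ga <- c(rep("M101", 100), "A1")
  gb <- c(sprintf("M%03d", 1:100), "A2")
  lab <- c(rep(1L, 67), rep(0L, 33), 0L)
  call <- c(rep(1L, 50), rep(0L, 50), 1L)
  screen <- screen_from_records(ga, gb, ifelse(lab == 1, -5, 0), lab)
  key_in <- paste(ga, gb, sep = "|")
  predictions <- data.frame(gene_a = ga, gene_b = gb,
                            probability = ifelse(call == 1, 0.9, 0.1),
                            call = call)
  rep <- stratified_report(screen, predictions, pathway_map)
  mm <- rep[rep$pathway_pair == "Mitotic/Mitotic", ]
  expect_equal(mm$validated_sl, 67)
  expect_equal(round(mm$sl_ratio, 3), 0.670)
  aa <- rep[rep$pathway_pair == "Autosis/Autosis", ]
  expect_equal(aa$sl_ratio, 0)
  expect_true(is.na(aa$recall))   # no validated SL in the stratum
  expect_true(is.na(aa$auc_roc))  # single class
})

test_that("stratified report validates pathway and prediction coverage", {
  fx <- make_stratified_fixture()
  expect_error(stratified_report(fx$screen, fx$predictions,
                                 fx$pathway_map[-1, ]),
               "missing from pathway map")
  expect_error(stratified_report(fx$screen, fx$predictions[-1, ],
                                 fx$pathway_map),
               "predictions missing")
  dup_map <- rbind(fx$pathway_map,
                   data.frame(gene = "G01", pathway = "Mitotic"))
  expect_warning(stratified_report(fx$screen, fx$predictions, dup_map),
                 "multiple pathways")
})

test_that("hub ranking, tie policy and overlap behave as specified", {
  conn_a <- connectivity_vector(c(A = 5L, B = 3L, C = 3L, D = 0L, E = 9L))
  hub_a <- hub_genes(conn_a, top_n = 3)
  expect_equal(hub_a$top, c("E", "A", "B"))  # tie B/C broken alphabetically
  conn_b <- connectivity_vector(c(A = 1L, B = 7L, C = 2L, D = 5L, E = 0L))
  hub_b <- hub_genes(conn_b, top_n = 3)
  expect_equal(hub_overlap(hub_a, hub_b), hub_overlap(hub_b, hub_a))
  expect_equal(hub_overlap(hub_a, hub_a), 3)
  expect_warning(h0 <- hub_genes(connectivity_vector(c(X = 0L, Y = 0L, Z = 0L)),
                                 top_n = 2), "alphabetical")
  expect_equal(h0$top, c("X", "Y"))
  # two top-10 lists sharing exactly 6 symbols report overlap 6
  ca <- connectivity_vector(stats::setNames(c(20:11, rep(1L, 10)),
                                            sprintf("S%02d", 1:20)))
  cb <- connectivity_vector(stats::setNames(
    c(20:15, rep(1L, 10), 14:11), sprintf("S%02d", c(1:16, 21:24))))
  expect_equal(hub_overlap(hub_genes(ca, 10), hub_genes(cb, 10)), 6)
})

test_that("connectivity correlation matches the definition oracle", {
  p <- c(A = 1, B = 2, C = 3)
  expect_equal(connectivity_correlation(p, 2 * p)$pearson_r, 1)
  expect_equal(connectivity_correlation(p, -p + 10)$pearson_r, -1)
  res <- connectivity_correlation(c(A = 1, B = 2, C = 3),
                                  c(A = 2, B = 1, C = 3))
  # direct covariance-formula oracle
  x <- c(1, 2, 3); y <- c(2, 1, 3)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$pearson_r, oracle)
  expect_equal(oracle, 0.5)
  expect_error(connectivity_correlation(c(A = 1, B = 1, C = 1), p),
               "zero variance")
  expect_error(connectivity_correlation(p[1:2], p[1:2]), "at least 3")
})
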