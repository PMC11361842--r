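# Encoder internals: independent oracles for message passing and
# attention, exact gradients, and permutation equivariance.

make_toy_state <- function(n = 6, fp = 3, fc = 2, n_views = 2, seed = 42,
                           n_transformer_layers = 2) {
  cfg <- model_config(embed_dim = 4, n_graph_layers = 2,
                      n_attention_heads = 2,
                      n_transformer_layers = n_transformer_layers,
                      dropout_encoder = 0, dropout_predictor = 0, seed = 1)
  withr_seed(seed, {
    params <- slconnect:::init_net_params(cfg, fp, fc, n_views)
    Xp <- matrix(stats::rnorm(n * fp), n)
    Xc <- matrix(stats::rnorm(n * fc), n)
    A <- matrix(stats::runif(n * n) < 0.4, n, n)
    A <- 1 * (A | t(A)); diag(A) <- 0
  })
  Araw <- A; diag(Araw) <- diag(Araw) + 1
  d <- rowSums(Araw)
  An <- Araw * tcrossprod(1 / sqrt(d))
  list(cfg = cfg, params = params,
       inputs = list(Xp = Xp, Xc = Xc, A_list = list(An, diag(n))))
}

test_that("one message-passing layer equals the dense normalized-adjacency product", {
  # 3-node path A-B-C, hand-normalized adjacency with self-connections
  A <- matrix(c(0, 1, 0,
                1, 0, 1,
                0, 1, 0), 3, 3, byrow = TRUE)
  Araw <- A; diag(Araw) <- 1
  d <- rowSums(Araw)
  An <- Araw * tcrossprod(1 / sqrt(d))
  # independent oracle: explicit per-entry computation
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    oracle[i, j] <- Araw[i, j] / sqrt(d[i] * d[j])
  }
  expect_equal(An, oracle, tolerance = 1e-12)

  cfg <- model_config(embed_dim = 4, n_graph_layers = 1,
                      n_attention_heads = 2, seed = 1)
  withr_seed(9, {
    params <- slconnect:::init_net_params(cfg, 1, 1, 1)
    H <- matrix(stats::rnorm(12), 3, 4)
  })
  out <- slconnect:::fw_graph(params, H, list(An), 1)$out
  expected <- pmax(An %*% H %*% params$GW_1_1 +
                     rep(params$Gb_1_1, each = 3), 0)
  expected <- pmax(cbind(expected) %*% params$Gf + rep(params$Gfb, each = 3), 0)
  expect_equal(out, expected, tolerance = 1e-10)
})

test_that("graph encoding with no edges depends only on each gene's own embedding", {
  st <- make_toy_state(n_views = 1)
  n <- 6
  st$inputs$A_list <- list(diag(n))  # edgeless graph: self-connection only
  H <- slconnect:::fw_gene(st$params, st$inputs$Xp, st$inputs$Xc)$out
  out_full <- slconnect:::fw_graph(st$params, H, st$inputs$A_list, 2)$out
  # recompute gene 3 alone: same result row
  out_solo <- slconnect:::fw_graph(st$params, H[3, , drop = FALSE],
                                   list(diag(1)), 2)$out
  expect_equal(out_full[3, ], out_solo[1, ], tolerance = 1e-10)
})

test_that("attention rows are probability vectors and match the softmax oracle", {
  st <- make_toy_state(n_transformer_layers = 1)
  H <- matrix(stats::rnorm(24), 6, 4)
  tr <- slconnect:::fw_transformer(st$params, H, st$cfg)
  for (head in tr$layers[[1]]$heads) {
    expect_true(all(head$A >= 0))
    expect_equal(rowSums(head$A), rep(1, 6), tolerance = 1e-6)
  }
  # direct softmax(QK^T/sqrt(d))V oracle for head 1
  Wq <- st$params$Wq_1; Wk <- st$params$Wk_1; Wv <- st$params$Wv_1
  Q <- (H %*% Wq)[, 1:2]; K <- (H %*% Wk)[, 1:2]; V <- (H %*% Wv)[, 1:2]
  S <- Q %*% t(K) / sqrt(2)
  A_or <- exp(S) / rowSums(exp(S))
  expect_equal(tr$layers[[1]]$heads[[1]]$A, A_or, tolerance = 1e-10)
  O_or <- A_or %*% V
  expect_equal((tr$layers[[1]]$O)[, 1:2], O_or, tolerance = 1e-10)
})

test_that("single-token attention is the identity distribution", {
  st <- make_toy_state(n_transformer_layers = 1)
  H <- matrix(stats::rnorm(4), 1, 4)
  tr <- slconnect:::fw_transformer(st$params, H, st$cfg)
  for (head in tr$layers[[1]]$heads) {
    expect_equal(head$A, matrix(1, 1, 1))
  }
  # deterministic: repeated calls identical
  tr2 <- slconnect:::fw_transformer(st$params, H, st$cfg)
  expect_identical(tr$out, tr2$out)
})

test_that("analytic gradients match finite differences through the full stack", {
  st <- make_toy_state()
  n <- 6
  withr_seed(7, {
    t_target <- stats::rnorm(n)
    w <- as.numeric(stats::runif(n) < 0.7)
  })
  w[1] <- 1  # ensure nonempty fit set
  lossfn <- function(p) {
    pred <- slconnect:::forward_net(p, st$inputs, st$cfg)$pred
    sum(w * (pred - t_target)^2) / sum(w)
  }
  ones <- matrix(1, n, 4)
  fwd <- slconnect:::forward_net(st$params, st$inputs, st$cfg,
                                 masks = list(enc0 = ones, enc1 = ones,
                                              pred = ones))
  dy <- 2 * w * (fwd$pred - t_target) / sum(w)
  grads <- slconnect:::backward_net(fwd$cache, st$params, dy, st$cfg)
  eps <- 1e-5
  withr_seed(3, {
    for (nm in names(st$params)) {
      for (i in sample(length(st$params[[nm]]),
                       min(3, length(st$params[[nm]])))) {
        p_hi <- st$params; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
        p_lo <- st$params; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
        num <- (lossfn(p_hi) - lossfn(p_lo)) / (2 * eps)
        expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                     label = sprintf("grad %s[%d]", nm, i))
      }
    }
  })
})

test_that("the whole network is permutation-equivariant", {
  st <- make_toy_state()
  n <- 6
  pred <- slconnect:::forward_net(st$params, st$inputs, st$cfg)$pred
  withr_seed(5, perm <- sample(n))
  inputs_p <- list(Xp = st$inputs$Xp[perm, , drop = FALSE],
                   Xc = st$inputs$Xc[perm, , drop = FALSE],
                   A_list = lapply(st$inputs$A_list,
                                   function(A) A[perm, perm]))
  pred_p <- slconnect:::forward_net(st$params, inputs_p, st$cfg)$pred
  expect_equal(pred_p, pred[perm], tolerance = 1e-10)
})
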