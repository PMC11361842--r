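# Dense neural-network primitives: forward/backward passes written directly
# in matrix algebra, plus Adam. Gradients are exact (verified against finite
# differences in the test suite), full-batch over genes.

glorot <- function(fin, fout) {
  r <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -r, r), fin, fout)
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

lin_fw <- function(X, W, b) add_bias(X %*% W, b)

# returns list(dX, dW, db)
lin_bw <- function(X, W, dZ) {
  list(dX = dZ %*% t(W), dW = crossprod(X, dZ), db = colSums(dZ))
}

relu <- function(Z) pmax(Z, 0)
relu_bw <- function(Z, dH) dH * (Z > 0)

# Inverted dropout mask; p = 0 gives the all-ones mask.
dropout_mask <- function(n, d, p) {
  if (p <= 0) return(matrix(1, n, d))
  matrix((stats::runif(n * d) >= p) / (1 - p), n, d)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# dS from dA given A = softmax_rows(S)
softmax_rows_bw <- function(A, dA) A * (dA - rowSums(dA * A))

LN_EPS <- 1e-5

layernorm_fw <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(out = add_bias(xhat * rep(g, each = nrow(X)), b),
       xhat = xhat, inv = inv)
}

layernorm_bw <- function(cache, g, dY) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dxhat <- dY * rep(g, each = n)
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dX <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

# ---- parameter initialisation --------------------------------------------

init_net_params <- function(config, n_pop, n_cell, n_views) {
  d <- config$embed_dim
  L <- config$n_graph_layers
  Tt <- config$n_transformer_layers
  ff <- config$ff_mult * d
  hd <- config$head_hidden
  p <- list(
    Wp = glorot(n_pop, d), bp = numeric(d),
    Wc = glorot(n_cell, d), bc = numeric(d),
    Wg = glorot(2 * d, d), bg = numeric(d))
  if (n_views > 0) {
    for (v in seq_len(n_views)) {
      for (l in seq_len(L)) {
        p[[sprintf("GW_%d_%d", v, l)]] <- glorot(d, d)
        p[[sprintf("Gb_%d_%d", v, l)]] <- numeric(d)
      }
    }
    p$Gf <- glorot(n_views * d, d)
    p$Gfb <- numeric(d)
  }
  if (isTRUE(config$use_transformer)) {
    for (t in seq_len(Tt)) {
      p[[sprintf("Wq_%d", t)]] <- glorot(d, d)
      p[[sprintf("Wk_%d", t)]] <- glorot(d, d)
      p[[sprintf("Wv_%d", t)]] <- glorot(d, d)
      p[[sprintf("Wo_%d", t)]] <- glorot(d, d)
      p[[sprintf("bo_%d", t)]] <- numeric(d)
      p[[sprintf("ln1g_%d", t)]] <- rep(1, d)
      p[[sprintf("ln1b_%d", t)]] <- numeric(d)
      p[[sprintf("F1_%d", t)]] <- glorot(d, ff)
      p[[sprintf("F1b_%d", t)]] <- numeric(ff)
      p[[sprintf("F2_%d", t)]] <- glorot(ff, d)
      p[[sprintf("F2b_%d", t)]] <- numeric(d)
      p[[sprintf("ln2g_%d", t)]] <- rep(1, d)
      p[[sprintf("ln2b_%d", t)]] <- numeric(d)
    }
  }
  p$M1 <- glorot(d, hd); p$M1b <- numeric(hd)
  p$M2 <- glorot(hd, 1); p$M2b <- numeric(1)
  p
}

zero_like <- function(params) lapply(params, function(x) x * 0)

# ---- stage forwards -------------------------------------------------------

fw_gene <- function(params, Xp, Xc) {
  Zp <- lin_fw(Xp, params$Wp, params$bp); Hp <- relu(Zp)
  Zc <- lin_fw(Xc, params$Wc, params$bc); Hc <- relu(Zc)
  Cg <- cbind(Hp, Hc)
  Zg <- lin_fw(Cg, params$Wg, params$bg); H0 <- relu(Zg)
  list(out = H0, Xp = Xp, Xc = Xc, Zp = Zp, Hp = Hp, Zc = Zc, Hc = Hc,
       Cg = Cg, Zg = Zg)
}

bw_gene <- function(cache, params, dH0, grads) {
  dZg <- relu_bw(cache$Zg, dH0)
  lg <- lin_bw(cache$Cg, params$Wg, dZg)
  grads$Wg <- grads$Wg + lg$dW; grads$bg <- grads$bg + lg$db
  d <- ncol(cache$Hp)
  dHp <- lg$dX[, seq_len(d), drop = FALSE]
  dHc <- lg$dX[, d + seq_len(d), drop = FALSE]
  dZp <- relu_bw(cache$Zp, dHp)
  lp <- lin_bw(cache$Xp, params$Wp, dZp)
  grads$Wp <- grads$Wp + lp$dW; grads$bp <- grads$bp + lp$db
  dZc <- relu_bw(cache$Zc, dHc)
  lc <- lin_bw(cache$Xc, params$Wc, dZc)
  grads$Wc <- grads$Wc + lc$dW; grads$bc <- grads$bc + lc$db
  grads
}

fw_graph <- function(params, H, A_list, n_layers) {
  V <- length(A_list)
  if (V == 0) return(list(out = H, passthrough = TRUE))
  views <- vector("list", V)
  for (v in seq_len(V)) {
    layers <- vector("list", n_layers)
    Hv <- H
    for (l in seq_len(n_layers)) {
      P <- A_list[[v]] %*% Hv
      Z <- lin_fw(P, params[[sprintf("GW_%d_%d", v, l)]],
                  params[[sprintf("Gb_%d_%d", v, l)]])
      layers[[l]] <- list(Hin = Hv, P = P, Z = Z)
      Hv <- relu(Z)
    }
    views[[v]] <- list(layers = layers, out = Hv)
  }
  Cc <- do.call(cbind, lapply(views, `[[`, "out"))
  Zf <- lin_fw(Cc, params$Gf, params$Gfb)
  H1 <- relu(Zf)
  list(out = H1, passthrough = FALSE, views = views, Cc = Cc, Zf = Zf,
       A_list = A_list, n_layers = n_layers)
}

bw_graph <- function(cache, params, dH1, grads) {
  if (isTRUE(cache$passthrough)) return(list(grads = grads, dH = dH1))
  dZf <- relu_bw(cache$Zf, dH1)
  lf <- lin_bw(cache$Cc, params$Gf, dZf)
  grads$Gf <- grads$Gf + lf$dW; grads$Gfb <- grads$Gfb + lf$db
  V <- length(cache$views)
  d <- ncol(cache$views[[1]]$out)
  dH <- 0
  for (v in seq_len(V)) {
    dHv <- lf$dX[, (v - 1) * d + seq_len(d), drop = FALSE]
    for (l in rev(seq_len(cache$n_layers))) {
      lay <- cache$views[[v]]$layers[[l]]
      dZ <- relu_bw(lay$Z, dHv)
      lb <- lin_bw(lay$P, params[[sprintf("GW_%d_%d", v, l)]], dZ)
      gw <- sprintf("GW_%d_%d", v, l); gb <- sprintf("Gb_%d_%d", v, l)
      grads[[gw]] <- grads[[gw]] + lb$dW
      grads[[gb]] <- grads[[gb]] + lb$db
      # propagation operator is symmetric, so its transpose is itself
      dHv <- cache$A_list[[v]] %*% lb$dX
    }
    dH <- dH + dHv
  }
  list(grads = grads, dH = dH)
}

fw_transformer <- function(params, H, config) {
  Tt <- config$n_transformer_layers
  h <- config$n_attention_heads
  d <- ncol(H)
  dh <- d %/% h
  layers <- vector("list", Tt)
  Tcur <- H
  for (t in seq_len(Tt)) {
    Q <- Tcur %*% params[[sprintf("Wq_%d", t)]]
    K <- Tcur %*% params[[sprintf("Wk_%d", t)]]
    Vm <- Tcur %*% params[[sprintf("Wv_%d", t)]]
    heads <- vector("list", h)
    O <- matrix(0, nrow(H), d)
    for (i in seq_len(h)) {
      idx <- (i - 1) * dh + seq_len(dh)
      Qh <- Q[, idx, drop = FALSE]
      Kh <- K[, idx, drop = FALSE]
      Vh <- Vm[, idx, drop = FALSE]
      S <- tcrossprod(Qh, Kh) / sqrt(dh)
      A <- softmax_rows(S)
      O[, idx] <- A %*% Vh
      heads[[i]] <- list(Qh = Qh, Kh = Kh, Vh = Vh, A = A)
    }
    Z <- lin_fw(O, params[[sprintf("Wo_%d", t)]], params[[sprintf("bo_%d", t)]])
    R1 <- Tcur + Z
    ln1 <- layernorm_fw(R1, params[[sprintf("ln1g_%d", t)]],
                        params[[sprintf("ln1b_%d", t)]])
    L1 <- ln1$out
    ZF1 <- lin_fw(L1, params[[sprintf("F1_%d", t)]],
                  params[[sprintf("F1b_%d", t)]])
    HF <- relu(ZF1)
    ZF2 <- lin_fw(HF, params[[sprintf("F2_%d", t)]],
                  params[[sprintf("F2b_%d", t)]])
    R2 <- L1 + ZF2
    ln2 <- layernorm_fw(R2, params[[sprintf("ln2g_%d", t)]],
                        params[[sprintf("ln2b_%d", t)]])
    layers[[t]] <- list(Tin = Tcur, heads = heads, O = O, ln1 = ln1,
                        L1 = L1, ZF1 = ZF1, HF = HF)
    Tcur <- ln2$out
    layers[[t]]$ln2 <- ln2
  }
  list(out = Tcur, layers = layers, dh = dh, h = h)
}

bw_transformer <- function(cache, params, dT, grads) {
  h <- cache$h
  dh <- cache$dh
  for (t in rev(seq_along(cache$layers))) {
    lay <- cache$layers[[t]]
    l2 <- layernorm_bw(lay$ln2, params[[sprintf("ln2g_%d", t)]], dT)
    grads[[sprintf("ln2g_%d", t)]] <- grads[[sprintf("ln2g_%d", t)]] + l2$dg
    grads[[sprintf("ln2b_%d", t)]] <- grads[[sprintf("ln2b_%d", t)]] + l2$db
    dR2 <- l2$dX
    dL1 <- dR2
    lf2 <- lin_bw(lay$HF, params[[sprintf("F2_%d", t)]], dR2)
    grads[[sprintf("F2_%d", t)]] <- grads[[sprintf("F2_%d", t)]] + lf2$dW
    grads[[sprintf("F2b_%d", t)]] <- grads[[sprintf("F2b_%d", t)]] + lf2$db
    dZF1 <- relu_bw(lay$ZF1, lf2$dX)
    lf1 <- lin_bw(lay$L1, params[[sprintf("F1_%d", t)]], dZF1)
    grads[[sprintf("F1_%d", t)]] <- grads[[sprintf("F1_%d", t)]] + lf1$dW
    grads[[sprintf("F1b_%d", t)]] <- grads[[sprintf("F1b_%d", t)]] + lf1$db
    dL1 <- dL1 + lf1$dX
    l1 <- layernorm_bw(lay$ln1, params[[sprintf("ln1g_%d", t)]], dL1)
    grads[[sprintf("ln1g_%d", t)]] <- grads[[sprintf("ln1g_%d", t)]] + l1$dg
    grads[[sprintf("ln1b_%d", t)]] <- grads[[sprintf("ln1b_%d", t)]] + l1$db
    dR1 <- l1$dX
    dTin <- dR1
    lo <- lin_bw(lay$O, params[[sprintf("Wo_%d", t)]], dR1)
    grads[[sprintf("Wo_%d", t)]] <- grads[[sprintf("Wo_%d", t)]] + lo$dW
    grads[[sprintf("bo_%d", t)]] <- grads[[sprintf("bo_%d", t)]] + lo$db
    dO <- lo$dX
    n <- nrow(dO)
    d <- ncol(dO)
    dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
    for (i in seq_len(h)) {
      idx <- (i - 1) * dh + seq_len(dh)
      hd <- lay$heads[[i]]
      dOh <- dO[, idx, drop = FALSE]
      dA <- tcrossprod(dOh, hd$Vh)
      dV[, idx] <- crossprod(hd$A, dOh)
      dS <- softmax_rows_bw(hd$A, dA)
      dQ[, idx] <- (dS %*% hd$Kh) / sqrt(dh)
      dK[, idx] <- (crossprod(dS, hd$Qh)) / sqrt(dh)
    }
    for (nm in c("Wq", "Wk", "Wv")) {
      dX <- switch(nm, Wq = dQ, Wk = dK, Wv = dV)
      key <- sprintf("%s_%d", nm, t)
      grads[[key]] <- grads[[key]] + crossprod(lay$Tin, dX)
      dTin <- dTin + dX %*% t(params[[key]])
    }
    dT <- dTin
  }
  list(grads = grads, dH = dT)
}

fw_head <- function(params, H) {
  Z1 <- lin_fw(H, params$M1, params$M1b)
  H1 <- relu(Z1)
  Z2 <- lin_fw(H1, params$M2, params$M2b)
  list(out = Z2[, 1], H = H, Z1 = Z1, H1 = H1)
}

bw_head <- function(cache, params, dy, grads) {
  dZ2 <- matrix(dy, ncol = 1)
  l2 <- lin_bw(cache$H1, params$M2, dZ2)
  grads$M2 <- grads$M2 + l2$dW; grads$M2b <- grads$M2b + l2$db
  dZ1 <- relu_bw(cache$Z1, l2$dX)
  l1 <- lin_bw(cache$H, params$M1, dZ1)
  grads$M1 <- grads$M1 + l1$dW; grads$M1b <- grads$M1b + l1$db
  list(grads = grads, dH = l1$dX)
}

# ---- composed network -----------------------------------------------------

# inputs: list(Xp, Xc, A_list); masks: list(enc0, enc1, pred) or NULL (eval)
forward_net <- function(params, inputs, config, masks = NULL) {
  eval_mode <- is.null(masks)
  n <- nrow(inputs$Xp)
  one <- function(m) if (eval_mode) 1 else m
  g <- fw_gene(params, inputs$Xp, inputs$Xc)
  D0 <- g$out * one(masks$enc0)
  gr <- fw_graph(params, D0, inputs$A_list, config$n_graph_layers)
  D1 <- gr$out * one(masks$enc1)
  if (isTRUE(config$use_transformer)) {
    tr <- fw_transformer(params, D1, config)
    Ht <- tr$out
  } else {
    tr <- NULL
    Ht <- D1
  }
  Dh <- Ht * one(masks$pred)
  hd <- fw_head(params, Dh)
  list(pred = hd$out,
       cache = list(gene = g, graph = gr, transf = tr, head = hd,
                    masks = masks, eval_mode = eval_mode))
}

backward_net <- function(cache, params, dy, config) {
  grads <- zero_like(params)
  one <- function(m) if (cache$eval_mode) 1 else m
  hb <- bw_head(cache$head, params, dy, grads)
  grads <- hb$grads
  dHt <- hb$dH * one(cache$masks$pred)
  if (!is.null(cache$transf)) {
    tb <- bw_transformer(cache$transf, params, dHt, grads)
    grads <- tb$grads
    dD1 <- tb$dH
  } else {
    dD1 <- dHt
  }
  dH1 <- dD1 * one(cache$masks$enc1)
  gb <- bw_graph(cache$graph, params, dH1, grads)
  grads <- gb$grads
  dD0 <- gb$dH * one(cache$masks$enc0)
  bw_gene(cache$gene, params, dD0, grads)
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
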