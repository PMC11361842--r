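# Step 1 of the two-step method: the connectivity regression model
# (gene encoder -> multiview graph encoder -> transformer encoder -> MLP
# head) and its training loop.

#' Connectivity-model configuration
#'
#' Hyperparameters of the step-1 connectivity regressor. The optimization
#' defaults (Adam at learning rate 5e-5, encoder/predictor dropouts of
#' 0.5/0.7, up to 1000 epochs with 200-epoch early-stopping patience)
#' follow the published training protocol; architectural sizes are
#' desk-scale defaults and fully configurable.
#'
#' @param embed_dim Embedding width; must be divisible by
#'   `n_attention_heads`.
#' @param n_graph_layers Message-passing rounds per network view.
#' @param n_attention_heads Attention heads per transformer layer.
#' @param n_transformer_layers Transformer layers.
#' @param dropout_encoder Dropout rate applied after the gene and graph
#'   encoder stages (training only).
#' @param dropout_predictor Dropout rate applied between the final encoder
#'   output and the MLP head (training only).
#' @param learning_rate Adam learning rate.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without internal-validation
#'   improvement before training stops.
#' @param target_transform `"log1p"` (regress log1p connectivity; counts
#'   recovered by expm1) or `"identity"`.
#' @param use_transformer If `FALSE` the transformer stage is bypassed
#'   (graph-encoder-only ablation).
#' @param ff_mult Transformer feed-forward width as a multiple of
#'   `embed_dim`.
#' @param head_hidden Hidden width of the MLP head (default `embed_dim`).
#' @param val_gene_fraction Fraction of training genes held out as the
#'   internal early-stopping monitor.
#' @param seed Seed controlling initialization, dropout and the internal
#'   monitor split; identical configurations train identically.
#' @return A `model_config`.
#' @export
model_config <- function(embed_dim = 64, n_graph_layers = 2,
                         n_attention_heads = 4, n_transformer_layers = 1,
                         dropout_encoder = 0.5, dropout_predictor = 0.7,
                         learning_rate = 5e-5, max_epochs = 1000,
                         early_stop_patience = 200,
                         target_transform = c("log1p", "identity"),
                         use_transformer = TRUE, ff_mult = 2,
                         head_hidden = NULL, val_gene_fraction = 0.2,
                         seed = 1) {
  target_transform <- match.arg(target_transform)
  if (embed_dim %% n_attention_heads != 0) {
    stop("embed_dim must be divisible by n_attention_heads", call. = FALSE)
  }
  stopifnot(dropout_encoder >= 0, dropout_encoder < 1,
            dropout_predictor >= 0, dropout_predictor < 1,
            learning_rate > 0, max_epochs >= 1, early_stop_patience >= 1,
            val_gene_fraction > 0, val_gene_fraction < 1)
  structure(list(embed_dim = as.integer(embed_dim),
                 n_graph_layers = as.integer(n_graph_layers),
                 n_attention_heads = as.integer(n_attention_heads),
                 n_transformer_layers = as.integer(n_transformer_layers),
                 dropout_encoder = dropout_encoder,
                 dropout_predictor = dropout_predictor,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 target_transform = target_transform,
                 use_transformer = isTRUE(use_transformer),
                 ff_mult = as.integer(ff_mult),
                 head_hidden = as.integer(head_hidden %||% embed_dim),
                 val_gene_fraction = val_gene_fraction,
                 seed = as.integer(seed)),
            class = "model_config")
}

new_gene_embeddings <- function(genes, matrix, stage) {
  structure(list(genes = genes, matrix = matrix, stage = stage),
            class = "gene_embeddings")
}

#' @export
print.gene_embeddings <- function(x, ...) {
  cat(sprintf("<gene_embeddings> %d genes x %d dims (stage: %s)\n",
              length(x$genes), ncol(x$matrix), x$stage))
  invisible(x)
}

# Build standardized model inputs for a bundle. scalers = NULL computes
# statistics over train_genes; a stored scaler reapplies training-time
# statistics at prediction time.
build_model_inputs <- function(bundle, train_genes = bundle$universe,
                               scalers = NULL) {
  n <- length(bundle$universe)
  sc_out <- list()
  mk <- function(scope) {
    m <- scope_matrix(bundle, scope)
    if (is.null(m)) {
      warning(sprintf(
        "bundle has no %s-scope features; that branch reduces to a learned constant",
        scope), call. = FALSE)
      return(matrix(numeric(0), nrow = n, ncol = 0,
                    dimnames = list(bundle$universe, NULL)))
    }
    if (is.null(scalers)) {
      prep <- prepare_feature_matrix(m, train_genes)
      sc_out[[scope]] <<- list(center = prep$center, scale = prep$scale)
      prep$values
    } else {
      sc <- scalers[[scope]]
      for (j in seq_len(ncol(m))) {
        col <- m[, j]
        if (anyNA(col)) {
          med <- stats::median(col, na.rm = TRUE)
          col[is.na(col)] <- if (is.na(med)) 0 else med
          m[, j] <- col
        }
      }
      sweep(sweep(m, 2, sc$center, "-"), 2, sc$scale, "/")
    }
  }
  Xp <- mk("population")
  Xc <- mk("cell_specific")
  if (!length(bundle$networks)) {
    warning("bundle has no network views; graph encoder is an identity pass-through",
            call. = FALSE)
  }
  A_list <- lapply(bundle$networks, normalized_adjacency, bundle$universe)
  list(Xp = Xp, Xc = Xc, A_list = A_list,
       scalers = scalers %||% sc_out)
}

# Resolve (model | config) + bundle into params/inputs for the stage API.
resolve_stage_state <- function(bundle, model) {
  if (inherits(model, "trained_connectivity_model")) {
    inputs <- build_model_inputs(bundle, scalers = model$scalers)
    list(params = model$params, config = model$config, inputs = inputs)
  } else if (inherits(model, "model_config")) {
    inputs <- build_model_inputs(bundle)
    params <- withr_seed(model$seed,
                         init_net_params(model, ncol(inputs$Xp),
                                         ncol(inputs$Xc),
                                         length(inputs$A_list)))
    list(params = params, config = model, inputs = inputs)
  } else {
    stop("model must be a trained_connectivity_model or a model_config",
         call. = FALSE)
  }
}

#' Gene encoder stage
#'
#' Encodes population-scope and cell-specific omics features through two
#' parallel feed-forward branches and fuses them (concatenation + linear
#' projection) into one embedding per gene. If a scope is absent from the
#' bundle, its branch degenerates to a learned constant vector (with a
#' warning).
#'
#' @param bundle A `dataset_bundle`.
#' @param model A `trained_connectivity_model` (uses its learned weights
#'   and training-time feature scaling) or a `model_config` (fresh seeded
#'   weights; standardization over all genes).
#' @return `gene_embeddings` at stage `"gene_encoded"`.
#' @export
encode_genes <- function(bundle, model) {
  st <- resolve_stage_state(bundle, model)
  H <- fw_gene(st$params, st$inputs$Xp, st$inputs$Xc)$out
  rownames(H) <- bundle$universe
  new_gene_embeddings(bundle$universe, H, "gene_encoded")
}

#' Multiview graph encoder stage
#'
#' Propagates gene embeddings over each network view with
#' symmetric-normalized neighbor averaging (self-connections included) and
#' learned per-layer linear maps, then fuses the per-view outputs.
#' Isolated genes propagate only their own features. An empty view list is
#' an identity pass-through with a warning.
#'
#' @param embeddings `gene_embeddings` at stage `"gene_encoded"`.
#' @param networks List of `network_view` objects (re-indexed to the
#'   embedding gene order).
#' @param model A `trained_connectivity_model` or `model_config`.
#' @return `gene_embeddings` at stage `"graph_encoded"`.
#' @export
graph_encode <- function(embeddings, networks, model) {
  stopifnot(inherits(embeddings, "gene_embeddings"))
  if (embeddings$stage != "gene_encoded") {
    stop("graph_encode expects stage 'gene_encoded'", call. = FALSE)
  }
  config <- if (inherits(model, "model_config")) model else model$config
  params <- if (inherits(model, "model_config")) {
    withr_seed(model$seed,
               init_net_params(model, 1L, 1L, length(networks)))
  } else model$params
  if (!length(networks)) {
    warning("no network views: graph encoder is an identity pass-through",
            call. = FALSE)
    out <- embeddings
    out$stage <- "graph_encoded"
    return(out)
  }
  A_list <- lapply(networks, normalized_adjacency, embeddings$genes)
  H <- fw_graph(params, embeddings$matrix, A_list, config$n_graph_layers)$out
  rownames(H) <- embeddings$genes
  new_gene_embeddings(embeddings$genes, H, "graph_encoded")
}

#' Transformer encoder stage
#'
#' Dense multihead self-attention over all gene tokens (no positional
#' encoding: the gene set is unordered), with residual connections, layer
#' normalization and a feed-forward sublayer, extending the encoder from
#' local to global topology.
#'
#' @param embeddings `gene_embeddings` at stage `"graph_encoded"`.
#' @param model A `trained_connectivity_model` or `model_config`.
#' @param return_attention If `TRUE`, attach per-layer/per-head attention
#'   matrices as the `"attention"` attribute.
#' @return `gene_embeddings` at stage `"transformer_encoded"`.
#' @export
transformer_encode <- function(embeddings, model, return_attention = FALSE) {
  stopifnot(inherits(embeddings, "gene_embeddings"))
  if (embeddings$stage != "graph_encoded") {
    stop("transformer_encode expects stage 'graph_encoded'", call. = FALSE)
  }
  config <- if (inherits(model, "model_config")) model else model$config
  params <- if (inherits(model, "model_config")) {
    withr_seed(model$seed, init_net_params(model, 1L, 1L, 0L))
  } else model$params
  tr <- fw_transformer(params, embeddings$matrix, config)
  out <- new_gene_embeddings(embeddings$genes, tr$out, "transformer_encoded")
  rownames(out$matrix) <- embeddings$genes
  if (return_attention) {
    attr(out, "attention") <- lapply(tr$layers, function(l) {
      lapply(l$heads, `[[`, "A")
    })
  }
  out
}

#' Predict per-gene SL connectivity
#'
#' Applies the MLP head to final embeddings (or runs the full encoder stack
#' on a bundle), inverts the target transform and clips at zero, returning
#' predictions on the connectivity-count scale. Evaluation mode: no
#' dropout, bit-identical on repeated calls.
#'
#' @param x `gene_embeddings` at stage `"transformer_encoded"`, or a
#'   `dataset_bundle` (the full pipeline is run).
#' @param model A `trained_connectivity_model`.
#' @return Named numeric vector of non-negative predicted connectivities.
#' @export
predict_connectivity <- function(x, model) {
  stopifnot(inherits(model, "trained_connectivity_model") ||
              inherits(model, "model_config"))
  config <- if (inherits(model, "model_config")) model else model$config
  if (inherits(x, "gene_embeddings")) {
    if (x$stage != "transformer_encoded") {
      stop("predict_connectivity expects stage 'transformer_encoded'",
           call. = FALSE)
    }
    params <- if (inherits(model, "model_config")) {
      withr_seed(model$seed, init_net_params(model, 1L, 1L, 0L))
    } else model$params
    yhat <- fw_head(params, x$matrix)$out
    genes <- x$genes
  } else if (inherits(x, "dataset_bundle")) {
    st <- resolve_stage_state(x, model)
    yhat <- forward_net(st$params, st$inputs, st$config)$pred
    genes <- x$universe
  } else {
    stop("x must be gene_embeddings or a dataset_bundle", call. = FALSE)
  }
  out <- if (config$target_transform == "log1p") expm1(yhat) else yhat
  stats::setNames(pmax(out, 0), genes)
}

#' Train the connectivity regression model
#'
#' Minimizes mean squared error on (transformed) SL connectivity over the
#' split's training genes with full-batch Adam. Connectivity targets are
#' computed from training-side pairs only, so no held-out pair label leaks
#' into step-1 supervision. A seeded fraction of the training genes is held
#' out as an internal monitor for early stopping; the returned model
#' carries the parameters of the epoch with the lowest monitor loss.
#'
#' @param bundle A labeled `dataset_bundle`.
#' @param split A `split_spec` (see [split_nonoverlap()]).
#' @param config A `model_config`.
#' @return A `trained_connectivity_model` with elements `params`, `config`,
#'   `history` (per-epoch train/validation loss), `best_epoch`, `scalers`
#'   and the gene universe.
#' @export
train_connectivity_model <- function(bundle, split, config = model_config()) {
  stopifnot(inherits(bundle, "dataset_bundle"), inherits(split, "split_spec"),
            inherits(config, "model_config"))
  train_genes <- split$train_genes
  if (!length(train_genes)) stop("empty training gene set", call. = FALSE)
  universe <- bundle$universe
  train_side <- rbind(split$train_pairs, split$val_pairs)
  conn <- compute_connectivity(bundle$screen, restrict_to_pairs = train_side)
  y <- as.numeric(conn[universe])
  t_target <- if (config$target_transform == "log1p") log1p(y) else y

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(config$seed)

  inputs <- suppressWarnings(build_model_inputs(bundle, train_genes))
  n <- length(universe)
  n_monitor <- max(1L, floor(config$val_gene_fraction * length(train_genes)))
  if (n_monitor >= length(train_genes)) {
    stop("too few training genes for an internal validation monitor",
         call. = FALSE)
  }
  monitor_genes <- sample(train_genes, n_monitor)
  fit_genes <- setdiff(train_genes, monitor_genes)
  w_fit <- as.numeric(universe %in% fit_genes)
  w_mon <- as.numeric(universe %in% monitor_genes)

  params <- init_net_params(config, ncol(inputs$Xp), ncol(inputs$Xc),
                            length(inputs$A_list))
  state <- adam_init(params)
  d <- config$embed_dim
  best <- list(loss = Inf, epoch = 0L, params = params)
  hist_train <- numeric(config$max_epochs)
  hist_val <- numeric(config$max_epochs)
  n_epochs <- 0L
  masked_mse <- function(pred, w) sum(w * (pred - t_target)^2) / sum(w)

  for (epoch in seq_len(config$max_epochs)) {
    masks <- list(enc0 = dropout_mask(n, d, config$dropout_encoder),
                  enc1 = dropout_mask(n, d, config$dropout_encoder),
                  pred = dropout_mask(n, d, config$dropout_predictor))
    fwd <- forward_net(params, inputs, config, masks)
    train_loss <- masked_mse(fwd$pred, w_fit)
    if (!is.finite(train_loss)) {
      stop(sprintf("training loss diverged (non-finite) at epoch %d", epoch),
           call. = FALSE)
    }
    dy <- 2 * w_fit * (fwd$pred - t_target) / sum(w_fit)
    grads <- backward_net(fwd$cache, params, dy, config)
    upd <- adam_step(params, grads, state, config$learning_rate)
    params <- upd$params
    state <- upd$state
    val_pred <- forward_net(params, inputs, config)$pred
    val_loss <- masked_mse(val_pred, w_mon)
    hist_train[epoch] <- train_loss
    hist_val[epoch] <- val_loss
    n_epochs <- epoch
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, epoch = epoch, params = params)
    } else if (epoch - best$epoch >= config$early_stop_patience) {
      break
    }
  }
  history <- data.frame(epoch = seq_len(n_epochs),
                        train_loss = hist_train[seq_len(n_epochs)],
                        val_loss = hist_val[seq_len(n_epochs)])
  structure(list(params = best$params, config = config, history = history,
                 best_epoch = best$epoch, scalers = inputs$scalers,
                 universe = universe, monitor_genes = monitor_genes),
            class = "trained_connectivity_model")
}

#' @export
print.trained_connectivity_model <- function(x, ...) {
  cat(sprintf(
    "<trained_connectivity_model> %d genes, %d epochs trained, best epoch %d (val MSE %.4g)\n",
    length(x$universe), nrow(x$history), x$best_epoch,
    x$history$val_loss[x$best_epoch]))
  invisible(x)
}
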