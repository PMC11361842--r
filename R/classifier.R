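# Step 2 of the two-step method: logistic regression from a pair's
# (predicted) connectivities to an SL probability.

#' Symmetric pair features from two connectivities
#'
#' Maps the connectivities of a pair's two genes to an order-invariant
#' feature vector. The default set is (min, max, product): min/max keep the
#' asymmetry between the two genes without imposing an order, and the
#' product captures the "both genes are hubs" interaction. `sum` and
#' `absdiff` are available as alternatives.
#'
#' @param c_a,c_b Non-negative connectivities (vectorized).
#' @param feature_set Character subset of
#'   `c("min", "max", "product", "sum", "absdiff")`.
#' @return Numeric matrix, one row per pair, one column per feature.
#' @export
pair_features <- function(c_a, c_b,
                          feature_set = c("min", "max", "product")) {
  if (any(c_a < 0) || any(c_b < 0)) {
    stop("connectivities must be non-negative", call. = FALSE)
  }
  feature_set <- match.arg(feature_set,
                           c("min", "max", "product", "sum", "absdiff"),
                           several.ok = TRUE)
  cols <- list(min = pmin(c_a, c_b), max = pmax(c_a, c_b),
               product = c_a * c_b, sum = c_a + c_b,
               absdiff = abs(c_a - c_b))
  out <- do.call(cbind, cols[feature_set])
  colnames(out) <- feature_set
  out
}

# Exact ridge-penalized weighted logistic regression by Newton iteration.
# The weighted log-likelihood is averaged over total weight, so the fit is
# exactly invariant under row duplication and weight rescaling; the
# intercept is unpenalized. Converges to machine precision.
ridge_logistic <- function(X, y, w, lambda, tol = 1e-12, max_iter = 100) {
  Z <- cbind(1, X)
  p_dim <- ncol(Z)
  pen <- diag(c(0, rep(lambda, p_dim - 1)), p_dim)
  w <- w / sum(w)
  beta <- numeric(p_dim)
  for (iter in seq_len(max_iter)) {
    eta <- as.numeric(Z %*% beta)
    mu <- stats::plogis(eta)
    grad <- crossprod(Z, w * (mu - y)) + pen %*% beta
    s <- pmax(w * mu * (1 - mu), 1e-12)
    H <- crossprod(Z, Z * s) + pen
    step <- solve(H, grad)
    beta <- beta - step
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Fit the SL pair classifier
#'
#' Logistic regression with a light ridge (L2) penalty on standardized
#' pair features, fitted by Newton iteration to machine precision (so the
#' fit is deterministic and exactly invariant under duplication of
#' training rows). With balanced class weighting (the default; SL
#' prevalence in double-knockout screens is typically 0.5-1.5%) each class
#' contributes equally to the weighted log-likelihood.
#'
#' @param features Matrix from [pair_features()], one row per training
#'   pair.
#' @param labels Binary 0/1 SL labels.
#' @param weighting `"balanced"` or `"none"`.
#' @param lambda Ridge penalty (small; stabilizes separable fits).
#' @param feature_transform `"identity"` or `"log1p"`: transform applied
#'   to each feature column before standardization (and, through the
#'   stored classifier, to prediction-time features). Connectivity counts
#'   are heavy-tailed, so the two-step pipeline fits on the log scale.
#' @return An `sl_classifier` with coefficients, intercept and the feature
#'   standardization used.
#' @export
fit_sl_classifier <- function(features, labels, weighting = c("balanced", "none"),
                              lambda = 1e-3,
                              feature_transform = c("identity", "log1p")) {
  weighting <- match.arg(weighting)
  feature_transform <- match.arg(feature_transform)
  labels <- check_binary(labels)
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop(sprintf("cannot fit classifier: no %s examples in training labels",
                 if (n_pos == 0) "positive (SL)" else "negative (non-SL)"),
         call. = FALSE)
  }
  if (feature_transform == "log1p") features <- log1p(features)
  center <- colMeans(features)
  # population (1/n) standard deviation: exactly invariant under row
  # duplication, which the (n-1)-denominator form is not
  scale <- sqrt(colMeans(sweep(features, 2, center, "-")^2))
  scale[!is.finite(scale) | scale == 0] <- 1
  X <- sweep(sweep(features, 2, center, "-"), 2, scale, "/")
  w <- if (weighting == "balanced") {
    ifelse(labels == 1L, length(labels) / (2 * n_pos),
           length(labels) / (2 * n_neg))
  } else {
    rep(1, length(labels))
  }
  beta <- ridge_logistic(X, labels, w, lambda)
  structure(list(coefficients = stats::setNames(beta[-1], colnames(features)),
                 intercept = beta[1],
                 center = center, scale = scale,
                 feature_set = colnames(features),
                 feature_transform = feature_transform,
                 class_weighting = weighting, lambda = lambda),
            class = "sl_classifier")
}

#' @export
print.sl_classifier <- function(x, ...) {
  cat(sprintf("<sl_classifier> logistic on (%s), %s weighting\n",
              paste(x$feature_set, collapse = ", "), x$class_weighting))
  coefs <- c(`(intercept)` = x$intercept, x$coefficients)
  print(round(coefs, 4))
  invisible(x)
}

# Probability from raw (untransformed) features.
classifier_prob <- function(classifier, features) {
  if (identical(classifier$feature_transform, "log1p")) {
    features <- log1p(features)
  }
  X <- sweep(sweep(features, 2, classifier$center, "-"),
             2, classifier$scale, "/")
  eta <- as.numeric(X %*% classifier$coefficients) + classifier$intercept
  stats::plogis(eta)
}

#' Predict SL probabilities for gene pairs
#'
#' Looks up each pair's per-gene predicted connectivities, builds the
#' classifier's symmetric pair features and returns the logistic
#' probability. Exactly invariant to the order of the two genes within a
#' pair.
#'
#' @param classifier An `sl_classifier`.
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param connectivity_pred Named numeric vector of per-gene predicted
#'   connectivities covering every endpoint.
#' @return Numeric vector of SL probabilities in (0,1), one per pair.
#' @export
predict_sl <- function(classifier, pairs, connectivity_pred) {
  stopifnot(inherits(classifier, "sl_classifier"))
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  missing_genes <- setdiff(genes, names(connectivity_pred))
  if (length(missing_genes)) {
    stop("no connectivity prediction for gene(s): ",
         paste(utils::head(missing_genes, 10), collapse = ", "),
         call. = FALSE)
  }
  ca <- connectivity_pred[pairs$gene_a]
  cb <- connectivity_pred[pairs$gene_b]
  feats <- pair_features(ca, cb, feature_set = classifier$feature_set)
  classifier_prob(classifier, feats)
}
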