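# Regressor chain of random forests mapping 2-D embedding coordinates to
# POD principal coefficients: one forest per mode, each consuming the
# embedding features plus the chain's predictions for the upstream modes.

#' @importFrom ranger ranger
NULL

#' Regressor-chain configuration
#'
#' @param trees Trees per forest (default 70).
#' @param depth Maximum tree depth (default 20).
#' @param order Chain order as a permutation of mode indices; `NULL`
#'   means `1..k` (descending singular value).
#' @param seed Integer seed; forest `j` uses `seed + j`.
#' @param upstream `"predicted"` (default) feeds each downstream forest
#'   the chain's own training-set predictions for earlier modes, matching
#'   how the chain is evaluated at prediction time; `"true"` feeds the
#'   true upstream coefficients during fitting.
#' @return A `chain_config` object.
#' @export
chain_config <- function(trees = 70L, depth = 20L, order = NULL, seed = 1L,
                         upstream = c("predicted", "true")) {
  if (trees < 1L) stop("need at least one tree")
  if (depth < 1L) stop("depth must be at least 1")
  structure(list(trees = as.integer(trees), depth = as.integer(depth),
                 order = order, seed = as.integer(seed),
                 upstream = match.arg(upstream)),
            class = "chain_config")
}

.chain_features <- function(coords, preds, j, order) {
  df <- data.frame(tsne_x = coords[, 1], tsne_y = coords[, 2])
  if (j > 1L) {
    for (u in seq_len(j - 1L)) df[[sprintf("chat_m%d", order[u])]] <- preds[[u]]
  }
  df
}

.fit_forest <- function(feats, y, cfg, seed) {
  if (nrow(feats) < 2L || stats::var(y) == 0) {
    # degenerate training set: a forest would return the mean anyway
    structure(list(value = mean(y)), class = "constant_regressor")
  } else {
    ranger::ranger(x = feats, y = y, num.trees = cfg$trees,
                   max.depth = cfg$depth, seed = seed, num.threads = 1L)
  }
}

.predict_forest <- function(fit, feats) {
  if (inherits(fit, "constant_regressor")) rep(fit$value, nrow(feats))
  else stats::predict(fit, data = feats)$predictions
}

#' Fit the coefficient regressor chain
#'
#' Trains `k` random forests in chain order: forest `j` regresses mode
#' `order[j]`'s coefficient on `(tsne_x, tsne_y)` plus the chain
#' predictions for modes `order[1..j-1]`. Deterministic given the seed.
#'
#' @param coords M x 2 embedding coordinates.
#' @param coefficients M x k principal-coefficient matrix.
#' @param cfg A [chain_config()].
#' @return A `coef_chain`: list with `forests`, `order`, `k`, `cfg`, and
#'   `train_ranges` (per-mode coefficient ranges of the training set,
#'   used to normalise prediction RMSE).
#' @export
fit_coefficient_chain <- function(coords, coefficients, cfg = chain_config()) {
  coords <- as.matrix(coords)
  coefficients <- as.matrix(coefficients)
  if (nrow(coords) != nrow(coefficients)) stop("row count mismatch")
  if (ncol(coords) != 2L) stop("coords must be M x 2")
  k <- ncol(coefficients)
  order <- if (is.null(cfg$order)) seq_len(k) else cfg$order
  if (!setequal(order, seq_len(k))) stop("order must permute 1..k")
  forests <- vector("list", k)
  upstream <- vector("list", k)
  for (j in seq_len(k)) {
    feats <- .chain_features(coords, upstream, j, order)
    y <- coefficients[, order[j]]
    forests[[j]] <- .fit_forest(feats, y, cfg, cfg$seed + j)
    upstream[[j]] <- if (cfg$upstream == "predicted")
      .predict_forest(forests[[j]], feats) else y
  }
  structure(
    list(forests = forests, order = order, k = k, cfg = cfg,
         train_ranges = apply(coefficients, 2L, function(x) diff(range(x)))),
    class = "coef_chain")
}

#' @export
print.coef_chain <- function(x, ...) {
  cat(sprintf("<coef_chain> %d mode(s), %d trees x depth %d, upstream = %s\n",
              x$k, x$cfg$trees, x$cfg$depth, x$cfg$upstream))
  invisible(x)
}

#' Predict POD coefficients for embedding coordinates
#'
#' Evaluates the chain in order, threading each forest's prediction into
#' the downstream feature sets. Deterministic.
#'
#' @param chain A fitted `coef_chain`.
#' @param coords Length-2 coordinate or m x 2 matrix.
#' @return Length-k coefficient vector, or m x k matrix.
#' @export
predict_chain <- function(chain, coords) {
  stopifnot(inherits(chain, "coef_chain"))
  single <- !is.matrix(coords)
  if (single) coords <- matrix(coords, nrow = 1L)
  if (ncol(coords) != 2L) stop("coords must have 2 columns")
  preds <- vector("list", chain$k)
  for (j in seq_len(chain$k)) {
    feats <- .chain_features(coords, preds, j, chain$order)
    preds[[j]] <- .predict_forest(chain$forests[[j]], feats)
  }
  out <- matrix(0, nrow(coords), chain$k)
  for (j in seq_len(chain$k)) out[, chain$order[j]] <- preds[[j]]
  if (single) as.vector(out) else out
}

#' Range-normalised RMSE of one mode's coefficient predictions
#'
#' RMSE of the mode-`j` predictions divided by the training-set range of
#' that coefficient, as a percentage. Returns `NA` (with a warning) for a
#' zero range.
#'
#' @param predicted,truth m x k coefficient matrices (or vectors for
#'   `k = 1`).
#' @param j Mode index.
#' @param norm_range Normalising range; defaults to the range of the true
#'   values supplied, but should be the training-set range when scoring a
#'   held-out split.
#' @return RMSE as a percentage of the range.
#' @export
coefficient_rmse_percent <- function(predicted, truth, j = 1L,
                                     norm_range = NULL) {
  predicted <- as.matrix(predicted); truth <- as.matrix(truth)
  if (!all(dim(predicted) == dim(truth))) stop("shape mismatch")
  if (j < 1L || j > ncol(truth)) stop("mode index out of range")
  if (is.null(norm_range)) norm_range <- diff(range(truth[, j]))
  if (norm_range <= 0) {
    warning("zero coefficient range: RMSE% undefined")
    return(NA_real_)
  }
  100 * sqrt(mean((predicted[, j] - truth[, j])^2)) / norm_range
}
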