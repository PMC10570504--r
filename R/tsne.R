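# Exact t-SNE (t-distributed Stochastic Neighbor Embedding).
#
# Dense O(M^2) implementation of the standard algorithm: per-point
# Gaussian bandwidths calibrated to a target perplexity by bisecting the
# Shannon entropy, then gradient descent on the Kullback-Leibler
# divergence between the symmetrised input affinities and the Student-t
# affinities of the low-dimensional map, with early exaggeration,
# momentum switching and adaptive per-coordinate gains. Suitable for the
# ensemble sizes this package works with (hundreds to a few thousand
# cases); deterministic given the seed.

# Conditional affinities P_{j|i} at a fixed perplexity via entropy bisection.
.tsne_affinities <- function(D2, perplexity, tol = 1e-5, max_tries = 50L) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    Di <- D2[i, -i]
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Pi <- exp(-Di * beta)
    for (tries in seq_len(max_tries)) {
      sumP <- sum(Pi)
      if (sumP < .Machine$double.xmin) {
        H <- 0
      } else {
        H <- log(sumP) + beta * sum(Di * Pi) / sumP
      }
      if (abs(H - logU) < tol) break
      if (H > logU) {                      # entropy too high -> sharpen
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
      Pi <- exp(-Di * beta)
    }
    sumP <- sum(Pi)
    P[i, -i] <- if (sumP < .Machine$double.xmin) 1 / (n - 1) else Pi / sumP
  }
  P
}

#' Exact t-SNE embedding
#'
#' @param X Numeric matrix, one row per case.
#' @param dims Output dimensionality (default 2).
#' @param perplexity Target perplexity; must be below the number of rows.
#' @param seed Integer seed for the random map initialisation.
#' @param max_iter Gradient-descent iterations.
#' @param eta Learning rate.
#' @param exaggeration Early-exaggeration factor applied to the input
#'   affinities for the first quarter (capped at 100 iterations) of the
#'   optimisation.
#' @return A `max_iter`-optimised M x `dims` coordinate matrix with
#'   attribute `kl` (final KL divergence).
#' @export
tsne_embed <- function(X, dims = 2L, perplexity = 30, seed = 1L,
                       max_iter = 500L, eta = 200, exaggeration = 12) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 cases")
  if (perplexity >= n) stop("perplexity must be smaller than the number of cases")
  sq <- rowSums(X^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(X), 0)
  P <- .tsne_affinities(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  lying <- min(100L, max_iter %/% 4L)
  mom_switch <- min(250L, max_iter %/% 2L)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  V <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  Pe <- P * exaggeration
  kl <- NA_real_
  for (it in seq_len(max_iter)) {
    if (it == lying + 1L) Pe <- P
    sy <- rowSums(Y^2)
    num <- 1 / (1 + outer(sy, sy, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (Y * rowSums(L) - L %*% Y)
    mom <- if (it < mom_switch) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(V), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    V <- mom * V - eta * gains * grad
    Y <- Y + V
    Y <- sweep(Y, 2L, colMeans(Y))
    if (it == max_iter) kl <- sum(P * log(P / Q))
  }
  attr(Y, "kl") <- kl
  Y
}
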