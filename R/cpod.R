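# Mesh-domain common-base POD: stack per-mesh field vectors into an M x N
# solution matrix, factor by SVD (direct or snapshot path), truncate by
# singular-value energy, project and reconstruct.

#' Assemble the solution matrix for one field
#'
#' Stacks each mesh's field vector as one row of an M x N matrix: rows
#' are meshes (in input order), columns are nodes. The `"pressure"` field
#' takes the volume-node values, `"wss"` the surface-node values. All
#' solutions must come from meshes with identical node count and ordering.
#'
#' @param solutions List of `flow_solution` objects.
#' @param field `"pressure"` or `"wss"`.
#' @return A numeric matrix of class `solution_matrix` with attributes
#'   `field` and `mesh_ids`.
#' @export
assemble_solution_matrix <- function(solutions, field = c("pressure", "wss")) {
  field <- match.arg(field)
  if (length(solutions) < 2L) stop("need at least 2 solutions")
  vecs <- lapply(solutions, `[[`, field)
  n <- lengths(vecs)
  if (length(unique(n)) != 1L)
    stop("inconsistent node counts across solutions (topology error)")
  A <- do.call(rbind, vecs)
  if (anyNA(A)) stop("missing values in solution matrix")
  structure(A, class = c("solution_matrix", class(A)),
            field = field,
            mesh_ids = vapply(solutions, `[[`, "", "mesh_id"))
}

#' Proper orthogonal decomposition of a solution matrix
#'
#' Factors `A = U D V^T` and packages the POD basis: orthonormal spatial
#' modes (rows of `V^T`), the full singular-value spectrum, and the
#' per-mesh principal coefficients (rows of `U D`, so that
#' `coefficients %*% modes` reproduces `A`). Two routes are provided: the
#' direct LAPACK SVD of `A`, and the snapshot method via the M x M
#' correlation matrix `A A^T` — the standard economy when the node count
#' far exceeds the number of meshes. `"auto"` picks the snapshot path when
#' `N > 4 M`. Both routes agree on singular values and coefficients up to
#' numerical precision; modes are made deterministic across backends by a
#' sign convention (the largest-magnitude entry of each mode is
#' non-negative). Modes are retained only down to the relative numerical
#' rank tolerance; the full spectrum is kept for energy accounting.
#'
#' @param A A `solution_matrix` (or plain numeric matrix).
#' @param method `"auto"`, `"svd"` or `"snapshot"`.
#' @param center Subtract the ensemble-mean field before factoring
#'   (off by default: mode 1 then carries the mean pattern).
#' @param rank_tol Relative singular-value cutoff for retained modes.
#' @return A `pod_basis`: list with `modes` (k x N), `sigma` (full
#'   spectrum, non-increasing), `coefficients` (M x k), `k`, `field`,
#'   `mesh_ids`, `center` (the subtracted mean, or NULL), `n_nodes`.
#' @export
pod_decompose <- function(A, method = c("auto", "svd", "snapshot"),
                          center = FALSE, rank_tol = 1e-10) {
  method <- match.arg(method)
  field <- attr(A, "field")
  mesh_ids <- attr(A, "mesh_ids")
  A <- unclass(A)
  attr(A, "field") <- NULL; attr(A, "mesh_ids") <- NULL
  M <- nrow(A); N <- ncol(A)
  mu <- NULL
  if (center) {
    mu <- colMeans(A)
    A <- sweep(A, 2L, mu)
  }
  if (method == "auto") method <- if (N > 4L * M) "snapshot" else "svd"
  if (method == "snapshot") {
    G <- tcrossprod(A)                       # M x M
    eg <- eigen(G, symmetric = TRUE)
    lambda <- pmax(eg$values, 0)
    sigma <- sqrt(lambda)[seq_len(min(M, N))]
    k <- sum(sigma > rank_tol * sigma[1])
    Uk <- eg$vectors[, seq_len(k), drop = FALSE]
    modes <- crossprod(Uk, A) / sigma[seq_len(k)]   # k x N, rows V^T
  } else {
    sv <- svd(A, nu = min(M, N), nv = min(M, N))
    sigma <- sv$d
    k <- sum(sigma > rank_tol * sigma[1])
    modes <- t(sv$v[, seq_len(k), drop = FALSE])
  }
  # sign convention: largest-magnitude entry of each mode non-negative
  for (i in seq_len(k)) {
    j <- which.max(abs(modes[i, ]))
    if (modes[i, j] < 0) modes[i, ] <- -modes[i, ]
  }
  coefficients <- A %*% t(modes)             # rows of U D under the convention
  structure(
    list(modes = modes, sigma = sigma, coefficients = coefficients,
         k = k, field = field, mesh_ids = mesh_ids, center = mu, n_nodes = N),
    class = "pod_basis")
}

#' @export
print.pod_basis <- function(x, ...) {
  cat(sprintf("<pod_basis>%s %d mode(s) x %d nodes, %d mesh(es); energy(k) = %.2f%%\n",
              if (is.null(x$field)) "" else paste0(" [", x$field, "]"),
              x$k, x$n_nodes, nrow(x$coefficients),
              100 * energy_fraction(x, x$k)))
  invisible(x)
}

#' Cumulative singular-value energy fraction
#'
#' The share of the singular-value sum carried by the `k` leading modes,
#' `sum(sigma[1:k]) / sum(sigma)` — the truncation criterion used
#' throughout the pipeline ("information" is the sum of singular values,
#' not of their squares). Non-decreasing in `k` and equal to 1 at full
#' rank. The squared-singular-value (variance) fraction is available via
#' `squared = TRUE` for comparison.
#'
#' @param basis A `pod_basis`.
#' @param k Number of leading modes, `1 <= k <= length(sigma)`.
#' @param squared Use `sigma^2` instead of `sigma`.
#' @return Fraction in `[0, 1]`.
#' @export
energy_fraction <- function(basis, k, squared = FALSE) {
  stopifnot(inherits(basis, "pod_basis"))
  s <- basis$sigma
  if (k < 1 || k > length(s)) stop("k out of range")
  if (squared) s <- s^2
  sum(s[seq_len(k)]) / sum(s)
}

#' Truncate a POD basis
#'
#' Keep either a fixed number of leading modes or the smallest number
#' whose cumulative singular-value energy reaches a threshold. The full
#' singular-value spectrum is preserved for energy accounting.
#'
#' @param basis A `pod_basis`.
#' @param k Number of modes to keep (ignored if `energy` given).
#' @param energy Energy threshold in `(0, 1]`.
#' @return A `pod_basis` with `k` modes and M x k coefficients.
#' @export
pod_truncate <- function(basis, k = NULL, energy = NULL) {
  stopifnot(inherits(basis, "pod_basis"))
  if (!is.null(energy)) {
    if (energy <= 0 || energy > 1) stop("energy threshold must lie in (0, 1]")
    cum <- cumsum(basis$sigma) / sum(basis$sigma)
    k <- which(cum >= energy - 1e-12)[1]
    if (is.na(k)) k <- length(basis$sigma)
    k <- min(k, basis$k)
  }
  if (is.null(k)) stop("give k or energy")
  if (k < 1 || k > basis$k) stop("k out of range")
  basis$modes <- basis$modes[seq_len(k), , drop = FALSE]
  basis$coefficients <- basis$coefficients[, seq_len(k), drop = FALSE]
  basis$k <- k
  basis
}

#' Project a field vector onto the POD modes
#'
#' Principal coefficients of a field: `c = modes %*% f` (inner products
#' with the orthonormal modes, after subtracting the ensemble mean if the
#' basis was centered).
#'
#' @param f Numeric field vector of length `n_nodes`.
#' @param basis A `pod_basis`.
#' @return Numeric vector of `k` coefficients.
#' @export
pod_project <- function(f, basis) {
  stopifnot(inherits(basis, "pod_basis"))
  if (length(f) != basis$n_nodes) stop("field length mismatch")
  if (!is.null(basis$center)) f <- f - basis$center
  as.vector(basis$modes %*% f)
}

#' Reconstruct a field from POD coefficients
#'
#' `f_hat = c %*% modes` (plus the ensemble mean for a centered basis);
#' linear in the coefficients. With a mesh's own (full-rank) coefficients
#' this reproduces its field exactly; with truncated coefficients it is
#' the orthogonal projection onto the retained mode span.
#'
#' @param coefficients Numeric vector of `k` coefficients, or an m x k
#'   matrix (one row per mesh).
#' @param basis A `pod_basis`.
#' @return Field vector of length `n_nodes`, or an m x n_nodes matrix.
#' @export
pod_reconstruct <- function(coefficients, basis) {
  stopifnot(inherits(basis, "pod_basis"))
  if (is.matrix(coefficients)) {
    if (ncol(coefficients) != basis$k) stop("coefficient length mismatch")
    out <- coefficients %*% basis$modes
    if (!is.null(basis$center)) out <- sweep(out, 2L, basis$center, "+")
    return(out)
  }
  if (length(coefficients) != basis$k) stop("coefficient length mismatch")
  out <- as.vector(coefficients %*% basis$modes)
  if (!is.null(basis$center)) out <- out + basis$center
  out
}

#' Write the singular-value spectrum and coefficients as CSV
#'
#' Emits `sigma.csv` (mode, sigma, energy_cum) and `coefficients.csv`
#' (mesh_id plus one column per retained mode) into `dir`.
#'
#' @param basis A `pod_basis`.
#' @param dir Output directory (created if missing).
#' @export
write_pod_csv <- function(basis, dir) {
  stopifnot(inherits(basis, "pod_basis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- basis$sigma
  utils::write.csv(
    data.frame(mode = seq_along(s), sigma = s, energy_cum = cumsum(s) / sum(s)),
    file.path(dir, "sigma.csv"), row.names = FALSE)
  co <- as.data.frame(basis$coefficients)
  names(co) <- sprintf("c%d", seq_len(basis$k))
  ids <- basis$mesh_ids
  if (is.null(ids)) ids <- sprintf("mesh_%d", seq_len(nrow(co)))
  utils::write.csv(cbind(data.frame(mesh_id = ids), co),
                   file.path(dir, "coefficients.csv"), row.names = FALSE)
  invisible(dir)
}
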