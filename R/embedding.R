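# Shape embedding: flatten mesh node coordinates into shape vectors,
# embed the ensemble in 2-D with t-SNE, and place unseen meshes by
# k-nearest-neighbour Gaussian-kernel interpolation in input space.

#' Flatten a geometry into a shape vector
#'
#' Concatenates the surface and volume node coordinates (in the frozen
#' node ordering), centers the mesh at its centroid, and flattens
#' node-major (x, y, z per node) into a length `3*(Ns+Nv)` vector. Shapes
#' are centroid-centered but deliberately not scale-normalised: the
#' radius scale is physically informative for the flow fields.
#'
#' @param geom A `vessel_geometry` built with `nodes = TRUE`.
#' @return Numeric shape vector.
#' @export
shape_vector <- function(geom) {
  stopifnot(inherits(geom, "vessel_geometry"))
  if (is.null(geom$surface)) stop("geometry has no node coordinates")
  pts <- rbind(geom$surface, geom$volume)
  ctr <- colMeans(pts)
  as.vector(t(pts) - ctr)
}

#' Shape matrix of a dataset
#'
#' @param dataset A `vessel_dataset` (all geometries with coordinates).
#' @return M x D matrix, one shape vector per row, rownames = mesh ids.
#' @export
shape_matrix <- function(dataset) {
  X <- t(vapply(dataset, shape_vector, numeric(3L * (dataset[[1]]$n_surface +
                                                       dataset[[1]]$n_volume))))
  rownames(X) <- vapply(dataset, `[[`, "", "mesh_id")
  X
}

#' Embed a shape ensemble in 2-D with t-SNE
#'
#' Runs exact t-SNE on the shape vectors (Euclidean distances between
#' node coordinate vectors) and stores everything needed to place unseen
#' meshes later: the training shapes, their 2-D coordinates, and the
#' out-of-sample interpolation settings.
#'
#' @param shapes M x D shape matrix (see [shape_matrix()]).
#' @param perplexity t-SNE perplexity (< M).
#' @param seed Integer seed; the same seed reproduces identical
#'   coordinates.
#' @param k_nn Neighbour count for out-of-sample placement.
#' @param max_iter t-SNE iterations.
#' @param parent_ids Optional character vector of parent labels, stored
#'   for plotting/diagnostics.
#' @return An `embedding_model`: list with `shapes`, `coords` (M x 2),
#'   `perplexity`, `seed`, `k_nn`, `mesh_ids`, `parent_ids`.
#' @export
embed_dataset <- function(shapes, perplexity = 30, seed = 1L, k_nn = 5L,
                          max_iter = 500L, parent_ids = NULL) {
  shapes <- as.matrix(shapes)
  if (nrow(shapes) < 4L) stop("need at least 4 meshes")
  if (perplexity >= nrow(shapes))
    stop("perplexity must be smaller than the number of meshes")
  coords <- tsne_embed(shapes, dims = 2L, perplexity = perplexity,
                       seed = seed, max_iter = max_iter)
  colnames(coords) <- c("tsne_x", "tsne_y")
  structure(
    list(shapes = shapes, coords = coords, perplexity = perplexity,
         seed = seed, k_nn = as.integer(k_nn),
         mesh_ids = rownames(shapes), parent_ids = parent_ids),
    class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> %d meshes in 2-D, perplexity %.1f, seed %d\n",
              nrow(x$coords), x$perplexity, x$seed))
  invisible(x)
}

#' Place an unseen mesh in the embedding space
#'
#' Deterministic out-of-sample extension: the query's 2-D position is the
#' Gaussian-kernel-weighted average of the embeddings of its `k_nn`
#' nearest training shapes (Euclidean distance in input space), with
#' bandwidth `h` = median of the `k_nn` neighbour distances and weights
#' `w_j = exp(-d_j^2 / (2 h^2))` normalised to sum to one. A query that
#' exactly matches a training shape returns that training coordinate.
#'
#' @param model An `embedding_model`.
#' @param x Shape vector (length must match the training dimension), or a
#'   `vessel_geometry` (flattened via [shape_vector()]).
#' @param k_nn Optional override of the neighbour count.
#' @return Named numeric length-2 coordinate (`tsne_x`, `tsne_y`).
#' @export
out_of_sample_embed <- function(model, x, k_nn = NULL) {
  stopifnot(inherits(model, "embedding_model"))
  if (inherits(x, "vessel_geometry")) x <- shape_vector(x)
  if (length(x) != ncol(model$shapes)) stop("shape vector length mismatch")
  if (is.null(k_nn)) k_nn <- model$k_nn
  k_nn <- min(k_nn, nrow(model$shapes))
  d2 <- rowSums(sweep(model$shapes, 2L, x)^2)
  hit <- which(d2 == 0)
  if (length(hit) > 0)
    return(stats::setNames(model$coords[hit[1L], ], c("tsne_x", "tsne_y")))
  nn <- order(d2)[seq_len(k_nn)]
  dn <- sqrt(d2[nn])
  h <- stats::median(dn)
  w <- exp(-d2[nn] / (2 * h^2))
  w <- w / sum(w)
  stats::setNames(as.vector(w %*% model$coords[nn, , drop = FALSE]),
                  c("tsne_x", "tsne_y"))
}

#' Export an embedding as CSV
#'
#' Columns: `mesh_id`, `parent_id`, `tsne_x`, `tsne_y`.
#' @param model An `embedding_model`.
#' @param path Output file path.
#' @export
write_embedding_csv <- function(model, path) {
  ids <- model$mesh_ids
  if (is.null(ids)) ids <- sprintf("mesh_%d", seq_len(nrow(model$coords)))
  parents <- model$parent_ids
  if (is.null(parents)) parents <- NA_character_
  utils::write.csv(
    data.frame(mesh_id = ids, parent_id = parents,
               tsne_x = model$coords[, 1], tsne_y = model$coords[, 2]),
    path, row.names = FALSE)
  invisible(path)
}
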