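#' Build a kd-tree spatial index over a point cloud
#'
#' The index supports exact k-nearest-neighbour and fixed-radius queries over
#' point positions; kd-tree search is delegated to \pkg{RANN}.
#'
#' @param cloud a `point_cloud`.
#' @return an object of class `spatial_index`.
#' @export
build_index <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  structure(list(positions = cloud$positions, n = n_points(cloud)),
            class = "spatial_index")
}

#' @export
print.spatial_index <- function(x, ...) {
  cat(sprintf("spatial_index (kd-tree) over %d points\n", x$n))
  invisible(x)
}

#' k-nearest-neighbour query
#'
#' @param index a `spatial_index`.
#' @param queries m x 3 matrix (or single 3-vector) of query positions.
#' @param k neighbours per query; must not exceed the indexed point count.
#' @return list with integer matrix `ids` (m x k, indices into the source
#'   cloud, nearest first) and numeric matrix `dists` (Euclidean distances).
#' @export
query_knn <- function(index, queries, k) {
  stopifnot(inherits(index, "spatial_index"))
  queries <- as_query_matrix(queries)
  k <- as.integer(k)
  if (k < 1L || k > index$n) stop("k must be in [1, number of indexed points]")
  res <- RANN::nn2(index$positions, queries, k = k)
  list(ids = res$nn.idx, dists = res$nn.dists)
}

#' Fixed-radius neighbour query
#'
#' Returns, for each query point, all indexed points within `radius`
#' (inclusive), nearest first.
#'
#' @param index a `spatial_index`.
#' @param queries m x 3 matrix or a single 3-vector.
#' @param radius search radius (>= 0).
#' @param max_neighbors cap on neighbours returned per query; defaults to the
#'   full indexed count (exact radius search).
#' @return list of per-query lists, each with `ids` and `dists`.
#' @export
query_radius <- function(index, queries, radius, max_neighbors = NULL) {
  stopifnot(inherits(index, "spatial_index"), radius >= 0)
  queries <- as_query_matrix(queries)
  k <- as.integer(min(max_neighbors %||% index$n, index$n))
  res <- RANN::nn2(index$positions, queries, k = k,
                   searchtype = "radius", radius = radius + 1e-12)
  lapply(seq_len(nrow(queries)), function(i) {
    keep <- res$nn.idx[i, ] > 0L
    list(ids = res$nn.idx[i, keep], dists = res$nn.dists[i, keep])
  })
}

as_query_matrix <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 3)
  q <- as.matrix(q)
  if (ncol(q) != 3L) stop("queries must be 3-vectors")
  storage.mode(q) <- "double"
  q
}
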