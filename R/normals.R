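#' Estimate point normals by local plane fitting
#'
#' Fits a plane to the k-nearest neighbourhood of every point (principal
#' component analysis of the local covariance) and takes the direction of
#' least variance as the normal.  Photogrammetric reconstructions normally
#' carry normals already; this fills the gap for clouds that lack them,
#' e.g. synthetic fixtures or bare XYZ files.
#'
#' Degenerate (collinear) neighbourhoods have no unique plane; such points
#' receive an arbitrary unit vector orthogonal to the dominant direction and
#' are counted in the `degenerate` attribute of the result.
#'
#' @param cloud a `point_cloud` with at least `k` points.
#' @param k neighbourhood size (>= 3); default 16.
#' @param viewpoint optional 3-vector; when given, normals are flipped to
#'   face it (typically the first camera position).
#' @return the cloud with unit `normals` set; attribute `degenerate` holds
#'   the count of degenerate neighbourhoods.
#' @export
estimate_normals <- function(cloud, k = 16, viewpoint = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  k <- as.integer(k)
  if (k < 3L) stop("k must be >= 3")
  n <- n_points(cloud)
  if (n < k) stop(sprintf("cloud has %d points but k = %d", n, k))
  idx <- build_index(cloud)
  nn <- query_knn(idx, cloud$positions, k = k)
  pos <- cloud$positions
  normals <- matrix(0, n, 3)
  degenerate <- 0L
  for (i in seq_len(n)) {
    nbr <- pos[nn$ids[i, ], , drop = FALSE]
    ctr <- colMeans(nbr)
    cen <- sweep(nbr, 2, ctr)
    cv <- crossprod(cen) / nrow(cen)
    eg <- eigen(cv, symmetric = TRUE)
    # eigenvalues descending; normal = least-variance direction
    if (eg$values[2] <= max(eg$values[1], 1e-300) * 1e-9) {
      # collinear: any unit vector orthogonal to the dominant direction
      degenerate <- degenerate + 1L
      d1 <- eg$values[1] > 0
      dom <- if (d1) eg$vectors[, 1] else c(1, 0, 0)
      normals[i, ] <- orthogonal_unit(dom)
    } else {
      normals[i, ] <- eg$vectors[, 3]
    }
  }
  # deterministic sign, then optional viewpoint orientation
  flip <- normals[, 3] < 0 |
    (normals[, 3] == 0 & (normals[, 1] < 0 | (normals[, 1] == 0 & normals[, 2] < 0)))
  normals[flip, ] <- -normals[flip, , drop = FALSE]
  if (!is.null(viewpoint)) {
    stopifnot(length(viewpoint) == 3)
    to_vp <- sweep(-pos, 2, as.numeric(viewpoint), "+")
    flip <- rowSums(normals * to_vp) < 0
    normals[flip, ] <- -normals[flip, , drop = FALSE]
  }
  normals <- normals / sqrt(rowSums(normals^2))
  cloud$normals <- normals
  if (degenerate > 0L) {
    warning(sprintf("%d degenerate (collinear) neighbourhoods", degenerate))
  }
  attr(cloud, "degenerate") <- degenerate
  cloud
}

orthogonal_unit <- function(v) {
  v <- v / sqrt(sum(v^2))
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * v) * v
  u / sqrt(sum(u^2))
}
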