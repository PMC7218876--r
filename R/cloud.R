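#' Attributed point cloud
#'
#' Construct an attributed point cloud: per-point position, optional unit
#' normal, optional RGB colour in `[0, 1]`, and an open-ended set of named
#' per-point scalar attributes (band reflectances, NDVI, cluster labels, ...).
#' This is the container every stage of the pipeline consumes and produces.
#'
#' @param positions numeric n x 3 matrix of point positions (metres, local
#'   scene frame).
#' @param normals optional numeric n x 3 matrix of unit normals.
#' @param colors optional numeric n x 3 matrix of RGB colours in `[0, 1]`.
#' @param attributes named list of numeric vectors of length n (per-point
#'   scalar attributes). `NA` marks a missing value for that point.
#' @return An object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(matrix(runif(30), ncol = 3))
#' n_points(pc)
#' @export
point_cloud <- function(positions, normals = NULL, colors = NULL,
                        attributes = list()) {
  positions <- as_xyz_matrix(positions, "positions")
  n <- nrow(positions)
  if (n < 1L) stop("a point cloud must contain at least one point")
  if (!is.null(normals)) {
    normals <- as_xyz_matrix(normals, "normals")
    if (nrow(normals) != n) stop("normals must have one row per point")
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6 & len > 0)) {
      stop("normals must be unit vectors (|n| = 1 within 1e-6)")
    }
  }
  if (!is.null(colors)) {
    colors <- as_xyz_matrix(colors, "colors")
    if (nrow(colors) != n) stop("colors must have one row per point")
    if (any(colors < -1e-9 | colors > 1 + 1e-9)) {
      stop("colors must lie in [0, 1]; 8-bit inputs are rescaled on read")
    }
  }
  if (length(attributes)) {
    if (is.null(names(attributes)) || any(!nzchar(names(attributes)))) {
      stop("attributes must be a named list")
    }
    for (nm in names(attributes)) {
      if (length(attributes[[nm]]) != n) {
        stop(sprintf("attribute '%s' must have length %d", nm, n))
      }
      attributes[[nm]] <- as.numeric(attributes[[nm]])
    }
  }
  structure(list(positions = positions, normals = normals, colors = colors,
                 attributes = attributes),
            class = "point_cloud")
}

as_xyz_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("%s must be an n x 3 matrix", what))
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$positions)
}

#' Names of per-point scalar attributes present on a cloud
#' @param cloud a `point_cloud`.
#' @return character vector (possibly empty).
#' @export
attribute_schema <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  names(cloud$attributes) %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subset a point cloud by index
#'
#' Keeps positions, normals, colours and all attributes for the selected
#' points, in the order given.
#'
#' @param cloud a `point_cloud`.
#' @param idx integer or logical index vector.
#' @return a `point_cloud`.
#' @export
subset_cloud <- function(cloud, idx) {
  stopifnot(inherits(cloud, "point_cloud"))
  point_cloud(cloud$positions[idx, , drop = FALSE],
              normals = if (!is.null(cloud$normals)) cloud$normals[idx, , drop = FALSE],
              colors = if (!is.null(cloud$colors)) cloud$colors[idx, , drop = FALSE],
              attributes = lapply(cloud$attributes, function(a) a[idx]))
}

#' Attach or replace a per-point attribute
#' @param cloud a `point_cloud`.
#' @param name attribute name.
#' @param values numeric vector, one value per point (`NA` = missing).
#' @return the modified cloud.
#' @export
set_attribute <- function(cloud, name, values) {
  stopifnot(inherits(cloud, "point_cloud"), length(values) == n_points(cloud))
  cloud$attributes[[name]] <- as.numeric(values)
  cloud
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points\n", n_points(x)))
  cat(sprintf("  normals: %s   colors: %s\n",
              if (is.null(x$normals)) "no" else "yes",
              if (is.null(x$colors)) "no" else "yes"))
  sch <- attribute_schema(x)
  if (length(sch)) cat("  attributes:", paste(sch, collapse = ", "), "\n")
  bb <- apply(x$positions, 2, range)
  cat(sprintf("  bbox: [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# Diagonal length of the axis-aligned bounding box; the scale reference used
# for translation magnitudes in registration experiments.
bbox_diagonal <- function(cloud) {
  bb <- apply(cloud$positions, 2, range)
  sqrt(sum((bb[2, ] - bb[1, ])^2))
}
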