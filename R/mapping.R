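#' Bilinearly sample a reflectance image at projected 3-D points
#'
#' Projects world points through the camera and interpolates the reflectance
#' grid at the resulting pixel coordinates.  A sample is missing (`NA`) when
#' the projection falls outside the image or any of the four support pixels
#' carries no value.
#'
#' @param image a `reflectance_image`.
#' @param model a `fisheye_model`.
#' @param pose a `camera_pose`.
#' @param points n x 3 world points (or a 3-vector).
#' @return numeric vector of reflectance samples (`NA` = missing).
#' @export
sample_band <- function(image, model, pose, points) {
  stopifnot(inherits(image, "reflectance_image"))
  px <- fisheye_project(model, world_to_camera(pose, points))
  bilinear_sample(image$grid, px[, 1], px[, 2])
}

# grid[row = y + 1, col = x + 1]; 0-based pixel centres at integers
bilinear_sample <- function(grid, x, y) {
  h <- nrow(grid); w <- ncol(grid)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & !is.na(y) & x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  v00 <- grid[cbind(y0 + 1, x0 + 1)]
  v10 <- grid[cbind(y0 + 1, x1 + 1)]
  v01 <- grid[cbind(y1 + 1, x0 + 1)]
  v11 <- grid[cbind(y1 + 1, x1 + 1)]
  val <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
  out[ok] <- val
  out
}

#' Default per-class reliability weights
#'
#' Flat weights for the three view-angle classes: perpendicular views are
#' fully trusted, oblique views at half weight, indirect views discarded.
#' @return named numeric vector.
#' @export
default_class_weights <- function() {
  c(perpendicular = 1.0, oblique = 0.5, indirect = 0.0)
}

#' Aggregate multi-view samples for one point
#'
#' Per band, the weighted mean over samples using the view-class weights;
#' missing when the total weight is zero (e.g. only indirect views).
#' Invariant to sample order and to a common scaling of the weights.
#'
#' @param samples data frame with columns `band`, `value`, `view_class`
#'   (and optionally `weight`, which overrides the class weight).
#' @param class_weights named weights per view class.
#' @return named numeric vector band -> reflectance, or `NULL` when no band
#'   has positive total weight.
#' @export
aggregate_point <- function(samples, class_weights = default_class_weights()) {
  if (!nrow(samples)) return(NULL)
  w <- if (!is.null(samples$weight)) samples$weight
       else unname(class_weights[samples$view_class])
  keep <- !is.na(samples$value) & w > 0
  if (!any(keep)) return(NULL)
  s <- samples[keep, , drop = FALSE]
  w <- w[keep]
  out <- vapply(split(seq_len(nrow(s)), s$band),
                function(ii) sum(w[ii] * s$value[ii]) / sum(w[ii]), 0)
  out
}

#' Enrich an RGB point cloud with multi-view multispectral reflectance
#'
#' For every capture (camera), computes visibility with occlusion rejection,
#' samples all four calibrated band images at the visible points, weights
#' each sample by its view-angle class, and aggregates across cameras.
#' NDVI is computed from the aggregated NIR and red bands.  Points that do
#' not receive all four bands are kept in the cloud but flagged (attributes
#' `NA`, `n_views = 0` excluded from clustering).
#'
#' @param cloud `point_cloud` with colors and normals.
#' @param captures list of captures, each a list with elements `pose`
#'   (`camera_pose`), `model` (`fisheye_model`) and `images` (named list of
#'   `reflectance_image`s for `green`, `red`, `reg`, `nir`).
#' @param neighbor_radius visibility patch radius; default 5 x the mean
#'   nearest-neighbour spacing estimated from up to 1,000 sampled points.
#' @param normal_angle_max visibility neighbour gate, degrees.
#' @param class_weights view-class weights, see [default_class_weights()].
#' @param depth_tol depth-consistency tolerance (scene units; default
#'   `2 * neighbor_radius`): a sample is rejected when the sampling point
#'   lies more than this behind the nearest visible point projecting into
#'   any of its four support pixels.  Guards against a background point
#'   reading pixels owned by a foreground surface near silhouettes.
#' @return the cloud with attributes `red_refl`, `green_refl`, `reg_refl`,
#'   `nir_refl`, `ndvi`, `n_views`; attribute `coverage` on the object holds
#'   per-band coverage fractions.
#' @export
enrich_cloud <- function(cloud, captures, neighbor_radius = NULL,
                         normal_angle_max = 60,
                         class_weights = default_class_weights(),
                         depth_tol = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(cloud$normals) || is.null(cloud$colors)) {
    stop("enrichment requires a cloud with normals and colors")
  }
  if (!length(captures)) stop("at least one capture is required")
  bands <- c("green", "red", "reg", "nir")
  n <- n_points(cloud)
  idx <- build_index(cloud)
  neighbor_radius <- neighbor_radius %||% default_neighbor_radius(cloud, idx)
  depth_tol <- depth_tol %||% (2 * neighbor_radius)
  wsum <- matrix(0, n, 4, dimnames = list(NULL, bands))
  vsum <- matrix(0, n, 4, dimnames = list(NULL, bands))
  nview <- integer(n)
  for (cap in captures) {
    stopifnot(!is.null(cap$pose), !is.null(cap$model), !is.null(cap$images))
    mask <- visible_points(cloud, cap$pose, cap$model, neighbor_radius,
                           normal_angle_max = normal_angle_max, index = idx)
    vis <- visible_ids(mask)
    if (!length(vis)) next
    depth_ok <- depth_consistent(mask, cloud$positions, vis, cap$pose$center,
                                 cap$model$image_size, depth_tol)
    ang <- view_angle(cap$pose, cloud$positions[vis, , drop = FALSE],
                      cloud$normals[vis, , drop = FALSE])
    w <- unname(class_weights[classify_view(ang)])
    pos_w <- w > 0 & depth_ok
    if (!any(pos_w)) next
    vis <- vis[pos_w]; w <- w[pos_w]
    contributed <- logical(length(vis))
    for (b in bands) {
      img <- cap$images[[b]]
      if (is.null(img)) stop(sprintf("capture lacks band image '%s'", b))
      val <- sample_band(img, cap$model, cap$pose,
                         cloud$positions[vis, , drop = FALSE])
      got <- !is.na(val)
      if (any(got)) {
        vsum[vis[got], b] <- vsum[vis[got], b] + w[got] * val[got]
        wsum[vis[got], b] <- wsum[vis[got], b] + w[got]
        contributed <- contributed | got
      }
    }
    nview[vis[contributed]] <- nview[vis[contributed]] + 1L
  }
  if (!any(wsum > 0)) {
    stop("no point received any sample: check camera poses against the cloud")
  }
  refl <- vsum / wsum  # NaN where weight 0
  refl[!is.finite(refl)] <- NA_real_
  complete <- rowSums(!is.na(refl)) == 4L
  refl[!complete, ] <- NA_real_
  nd <- rep(NA_real_, n)
  nd[complete] <- ndvi(refl[complete, "nir"], refl[complete, "red"])
  cloud <- set_attribute(cloud, "green_refl", refl[, "green"])
  cloud <- set_attribute(cloud, "red_refl", refl[, "red"])
  cloud <- set_attribute(cloud, "reg_refl", refl[, "reg"])
  cloud <- set_attribute(cloud, "nir_refl", refl[, "nir"])
  cloud <- set_attribute(cloud, "ndvi", nd)
  cloud <- set_attribute(cloud, "n_views", ifelse(complete, nview, 0))
  attr(cloud, "coverage") <- c(colMeans(wsum > 0), complete = mean(complete))
  attr(cloud, "neighbor_radius") <- neighbor_radius
  cloud
}

# Depth-consistency test: each visible point's depth is compared with the
# nearest visible depth projecting into each of its four bilinear support
# pixels; a point far behind any support pixel's owner would read foreign
# surface values and is rejected for this camera.
depth_consistent <- function(mask, positions, vis, center, image_size, tol) {
  px <- mask$pixels[vis, , drop = FALSE]
  depth <- sqrt(rowSums(sweep(positions[vis, , drop = FALSE], 2, center)^2))
  w <- image_size[1]; h <- image_size[2]
  xi <- pmin(pmax(round(px[, 1]), 0), w - 1)
  yi <- pmin(pmax(round(px[, 2]), 0), h - 1)
  owner <- matrix(Inf, h, w)
  ord <- order(depth, decreasing = TRUE)  # nearest assigned last wins
  owner[cbind(yi[ord] + 1, xi[ord] + 1)] <- depth[ord]
  x0 <- pmin(pmax(floor(px[, 1]), 0), w - 1)
  y0 <- pmin(pmax(floor(px[, 2]), 0), h - 1)
  x1 <- pmin(x0 + 1, w - 1)
  y1 <- pmin(y0 + 1, h - 1)
  ok <- rep(TRUE, length(vis))
  for (sup in list(cbind(y0, x0), cbind(y0, x1), cbind(y1, x0), cbind(y1, x1))) {
    od <- owner[sup + 1]
    # an unowned support pixel carries no depth evidence; only a strictly
    # nearer owner rejects the sample
    ok <- ok & (!is.finite(od) | depth - od <= tol)
  }
  ok
}

#' Default visibility patch radius: 5 x mean nearest-neighbour spacing
#'
#' Triangle-fan patches only seal a Poisson-sampled surface when every
#' sample's neighbourhood surrounds it; 5 x the mean spacing keeps the
#' registered surface hole-free while staying local.
#' @param cloud a `point_cloud`.
#' @param index optional prebuilt index.
#' @param sample_size points sampled for the estimate (default 1,000).
#' @return radius in scene units.
#' @export
default_neighbor_radius <- function(cloud, index = NULL, sample_size = 1000) {
  n <- n_points(cloud)
  idx <- index %||% build_index(cloud)
  take <- if (n <= sample_size) seq_len(n) else
    round(seq(1, n, length.out = sample_size))
  nn <- query_knn(idx, cloud$positions[take, , drop = FALSE], k = min(2L, n))
  if (n < 2L) return(1)
  5 * mean(nn$dists[, 2])
}

#' Indices of points admitted to clustering after enrichment
#' @param cloud an enriched `point_cloud`.
#' @return integer vector of points with all four bands and NDVI present.
#' @export
enriched_ids <- function(cloud) {
  sch <- attribute_schema(cloud)
  need <- c("green_refl", "red_refl", "reg_refl", "nir_refl", "ndvi")
  if (!all(need %in% sch)) stop("cloud is not enriched")
  ok <- !Reduce(`|`, lapply(cloud$attributes[need], is.na))
  which(ok)
}

#' Image-based coverage check of the projection
#'
#' Marks, on a copy of a band image, every pixel that received at least one
#' projected visible point (rounded pixel coordinates), reproducing the
#' image-based validation of the mapping: projected pixels are painted
#' black (0), background pixels are untouched.
#'
#' @param image a `reflectance_image`.
#' @param mask the camera's `visibility_mask`.
#' @param model,pose the camera.
#' @param cloud the projected `point_cloud`.
#' @return a `reflectance_image` with marked pixels set to 0; attributes
#'   `marked` (logical matrix) and `n_marked`.
#' @export
projection_coverage_image <- function(image, mask, model, pose, cloud) {
  stopifnot(inherits(image, "reflectance_image"),
            inherits(mask, "visibility_mask"))
  vis <- visible_ids(mask)
  marked <- matrix(FALSE, image$height, image$width)
  if (length(vis)) {
    px <- mask$pixels[vis, , drop = FALSE]
    xi <- pmin(pmax(round(px[, 1]), 0), image$width - 1)
    yi <- pmin(pmax(round(px[, 2]), 0), image$height - 1)
    marked[cbind(yi + 1, xi + 1)] <- TRUE
  }
  g <- image$grid
  g[marked] <- 0
  out <- reflectance_image(image$band, g)
  attr(out, "marked") <- marked
  attr(out, "n_marked") <- sum(marked)
  out
}
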