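#' Per-camera visibility with occlusion rejection
#'
#' Classifies every cloud point as visible, occluded or out-of-frustum for
#' one camera.  The procedure follows the four-step surface-based test:
#' (1) frustum filtering; (2) candidates sorted by distance to the camera,
#' nearest first; (3) each accepted point registers a minimal triangulated
#' surface patch — a triangle fan spanned by the point and its radius
#' neighbours (neighbours filtered by normal compatibility); (4) a
#' candidate is occluded iff the ray from the camera to it passes through
#' an already-registered, strictly nearer patch.  Iteration continues until
#' all points are checked.
#'
#' "Strictly nearer" uses a configurable depth bias, so patches never
#' occlude the surface samples they interpolate.  Because the
#' patches are chords between actual surface samples they do not overhang
#' curved silhouettes, which keeps the test close to exact ray casting.
#' Ray-triangle lookups are accelerated by binning projected triangle
#' footprints on the image plane.
#'
#' @param cloud `point_cloud` with normals.
#' @param pose a `camera_pose`.
#' @param model a `fisheye_model`.
#' @param neighbor_radius patch radius in scene units (> 0).
#' @param normal_angle_max neighbour normal-compatibility gate, degrees.
#' @param index optional prebuilt `spatial_index` of the cloud.
#' @param max_patch_neighbors cap on neighbours per patch fan.
#' @param depth_bias "strictly nearer" margin in scene units; defaults to
#'   `0.1 * neighbor_radius`, thick enough that patches never occlude the
#'   samples they interpolate, thin enough not to blind the test to
#'   shallow occlusions near silhouettes.
#' @return an object of class `visibility_mask`: integer status per point
#'   (`0` out-of-frustum, `1` visible, `2` occluded) plus the projected
#'   pixel coordinates.
#' @export
visible_points <- function(cloud, pose, model, neighbor_radius,
                           normal_angle_max = 60, index = NULL,
                           max_patch_neighbors = 24,
                           depth_bias = 0.1 * neighbor_radius) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(cloud$normals)) stop("visibility requires normals")
  if (neighbor_radius <= 0) stop("neighbor_radius must be > 0")
  n <- n_points(cloud)
  pos <- cloud$positions
  nrm <- cloud$normals
  o <- pose$center
  px <- fisheye_project(model, world_to_camera(pose, pos))
  infr <- !is.na(px[, 1]) &
    px[, 1] >= 0 & px[, 1] < model$image_size[1] &
    px[, 2] >= 0 & px[, 2] < model$image_size[2]
  status <- integer(n)  # 0 = out of frustum
  cand <- which(infr)
  if (!length(cand)) return(new_visibility_mask(status, px))
  depth_all <- numeric(n)
  depth_all[cand] <- sqrt(rowSums(sweep(pos[cand, , drop = FALSE], 2, o)^2))
  ord <- cand[order(depth_all[cand])]

  idx <- index %||% build_index(cloud)
  nbrs <- query_radius(idx, pos[ord, , drop = FALSE], neighbor_radius,
                       max_neighbors = min(max_patch_neighbors + 1L, n))
  bias <- depth_bias
  # image-plane bins sized to the median projected patch footprint
  s_px <- max(svd(model$affine)$d)
  r_px <- pmax(1, neighbor_radius / depth_all[ord] * s_px * (2 / pi) * 2)
  cell <- max(2, stats::median(r_px))
  grid <- new.env(parent = emptyenv(), hash = TRUE)

  # growing triangle store
  tcap <- 256L
  v0 <- matrix(0, tcap, 3); v1 <- matrix(0, tcap, 3); v2 <- matrix(0, tcap, 3)
  ntri <- 0L
  add_triangles <- function(center_id, fan_ids) {
    m <- length(fan_ids)
    if (m < 2L) return(invisible())
    # order fan neighbours by azimuth in the center's tangent plane
    nc <- nrm[center_id, ]
    e1 <- orthogonal_unit(nc)
    e2 <- cross3(nc, e1)
    rel <- sweep(pos[fan_ids, , drop = FALSE], 2, pos[center_id, ])
    az <- atan2(rel %*% e2, rel %*% e1)
    fan_ids <- fan_ids[order(az)]
    pairs <- cbind(fan_ids, c(fan_ids[-1], fan_ids[1]))
    if (m == 2L) pairs <- pairs[1, , drop = FALSE]
    k <- nrow(pairs)
    while (ntri + k > tcap) {
      tcap <<- tcap * 2L
      grow <- function(mt) rbind(mt, matrix(0, tcap - nrow(mt), 3))
      v0 <<- grow(v0); v1 <<- grow(v1); v2 <<- grow(v2)
    }
    rows <- ntri + seq_len(k)
    v0[rows, ] <<- matrix(pos[center_id, ], k, 3, byrow = TRUE)
    v1[rows, ] <<- pos[pairs[, 1], , drop = FALSE]
    v2[rows, ] <<- pos[pairs[, 2], , drop = FALSE]
    ntri <<- ntri + k
    # bin each triangle over its projected pixel bbox
    for (r in rows) {
      tp <- px[c(center_id, pairs[r - rows[1] + 1, ]), , drop = FALSE]
      tp <- tp[!is.na(tp[, 1]), , drop = FALSE]
      if (!nrow(tp)) next
      cx <- floor(range(tp[, 1]) / cell); cy <- floor(range(tp[, 2]) / cell)
      for (gx in cx[1]:cx[2]) for (gy in cy[1]:cy[2]) {
        key <- paste0(gx, ",", gy)
        grid[[key]] <- c(grid[[key]], r)
      }
    }
    invisible()
  }

  for (j in seq_along(ord)) {
    i <- ord[j]
    key <- paste0(floor(px[i, 1] / cell), ",", floor(px[i, 2] / cell))
    tri <- grid[[key]]
    occluded <- FALSE
    if (length(tri)) {
      L <- depth_all[i]
      u <- (pos[i, ] - o) / L
      occluded <- any_triangle_hit(o, u, L - bias,
                                   v0[tri, , drop = FALSE],
                                   v1[tri, , drop = FALSE],
                                   v2[tri, , drop = FALSE])
    }
    status[i] <- if (occluded) 2L else 1L
    # every processed point extends the registered surface (occluded points
    # are real surface samples too; dropping them would leave the surface
    # short of silhouettes)
    nb <- setdiff(nbrs[[j]]$ids, i)
    if (length(nb)) {
      cosang <- pmin(pmax(as.numeric(nrm[nb, , drop = FALSE] %*% nrm[i, ]), -1), 1)
      nb <- nb[acos(cosang) * 180 / pi < normal_angle_max]
    }
    add_triangles(i, nb)
  }
  new_visibility_mask(status, px)
}

# vectorised Moller-Trumbore: does the ray o + t*u hit any triangle with
# 0 < t < tmax?
any_triangle_hit <- function(o, u, tmax, a, b, c, eps = 1e-12) {
  e1 <- b - a
  e2 <- c - a
  # h = u x e2 (u constant across rows)
  h1 <- u[2] * e2[, 3] - u[3] * e2[, 2]
  h2 <- u[3] * e2[, 1] - u[1] * e2[, 3]
  h3 <- u[1] * e2[, 2] - u[2] * e2[, 1]
  det <- e1[, 1] * h1 + e1[, 2] * h2 + e1[, 3] * h3
  ok <- abs(det) > eps
  if (!any(ok)) return(FALSE)
  f <- 1 / det
  s1 <- o[1] - a[, 1]; s2 <- o[2] - a[, 2]; s3 <- o[3] - a[, 3]
  uu <- f * (s1 * h1 + s2 * h2 + s3 * h3)
  ok <- ok & uu >= 0 & uu <= 1
  if (!any(ok)) return(FALSE)
  q1 <- s2 * e1[, 3] - s3 * e1[, 2]
  q2 <- s3 * e1[, 1] - s1 * e1[, 3]
  q3 <- s1 * e1[, 2] - s2 * e1[, 1]
  vv <- f * (u[1] * q1 + u[2] * q2 + u[3] * q3)
  ok <- ok & vv >= 0 & uu + vv <= 1
  if (!any(ok)) return(FALSE)
  t <- f * (e2[, 1] * q1 + e2[, 2] * q2 + e2[, 3] * q3)
  any(ok & t > eps & t < tmax)
}

new_visibility_mask <- function(status, px) {
  structure(list(status = status, pixels = px,
                 n_visible = sum(status == 1L),
                 n_occluded = sum(status == 2L),
                 n_out = sum(status == 0L)),
            class = "visibility_mask")
}

#' @export
print.visibility_mask <- function(x, ...) {
  cat(sprintf("visibility_mask: %d visible, %d occluded, %d out of frustum\n",
              x$n_visible, x$n_occluded, x$n_out))
  invisible(x)
}

#' Indices of visible points in a visibility mask
#' @param mask a `visibility_mask`.
#' @return integer vector.
#' @export
visible_ids <- function(mask) which(mask$status == 1L)
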