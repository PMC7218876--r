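#' Camera pose
#'
#' Position and orientation of a camera.  The rotation maps world
#' coordinates to the camera frame, whose convention is +Z along the optical
#' axis into the scene, +X right, +Y down.
#'
#' @param center 3-vector camera position (metres).
#' @param rotation 3 x 3 orthonormal world-to-camera matrix, det = +1.
#' @return an object of class `camera_pose`.
#' @export
camera_pose <- function(center, rotation = diag(3)) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3)
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation must be a 3x3 orthonormal matrix")
  }
  if (det(rotation) < 0) stop("rotation must be proper (det = +1)")
  structure(list(center = center, rotation = rotation), class = "camera_pose")
}

#' Look-at camera pose
#'
#' Convenience constructor: a pose at `center` with the optical axis pointed
#' at `target` and +Y as close to `-up` as the axis allows (image "down").
#'
#' @param center camera position.
#' @param target point the optical axis passes through.
#' @param up world up direction (default +Z).
#' @return a `camera_pose`.
#' @export
look_at_pose <- function(center, target, up = c(0, 0, 1)) {
  z <- as.numeric(target) - as.numeric(center)
  nz <- sqrt(sum(z^2))
  if (nz == 0) stop("target must differ from center")
  z <- z / nz
  x <- cross3(z, as.numeric(up))
  nx <- sqrt(sum(x^2))
  if (nx < 1e-12) x <- cross3(z, c(1, 0, 0)) else x <- x / nx
  x <- x / sqrt(sum(x^2))
  y <- cross3(z, x)
  camera_pose(center, rbind(x, y, z))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Polynomial fisheye camera model
#'
#' Wide-angle distortion model: the normalized off-axis angle
#' `theta = (2/pi) * atan(r_xy / Z)` (so `theta` spans `[0, 1]` over the
#' hemisphere) enters a quartic `rho = theta + p2 theta^2 + p3 theta^3 +
#' p4 theta^4`, and the normalized image point is carried to pixels by a
#' 2 x 2 affine matrix (entries C, D, E, F) plus the principal point.
#'
#' @param p2,p3,p4 polynomial distortion coefficients.
#' @param affine 2 x 2 invertible matrix mapping the normalized image plane
#'   to pixels (includes the focal scaling).
#' @param principal_point `(cx, cy)` in pixels.
#' @param image_size `(width, height)` in pixels.
#' @param theta_max largest accepted normalized angle in `(0, 1]`.
#' @return an object of class `fisheye_model`.
#' @export
fisheye_model <- function(p2 = 0, p3 = 0, p4 = 0, affine,
                          principal_point, image_size, theta_max = 1) {
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(2, 2)))
  if (abs(det(affine)) < 1e-12) stop("affine matrix must be invertible")
  if (theta_max <= 0 || theta_max > 1) stop("theta_max must be in (0, 1]")
  structure(list(p2 = p2, p3 = p3, p4 = p4, affine = affine,
                 principal_point = as.numeric(principal_point),
                 image_size = as.integer(image_size), theta_max = theta_max),
            class = "fisheye_model")
}

#' World-to-camera transform of points
#'
#' @param pose a `camera_pose`.
#' @param points n x 3 matrix or a 3-vector.
#' @return n x 3 matrix of camera-frame coordinates.
#' @export
world_to_camera <- function(pose, points) {
  stopifnot(inherits(pose, "camera_pose"))
  points <- as_query_matrix(points)
  sweep(points, 2, pose$center) %*% t(pose$rotation)
}

fisheye_rho <- function(model, theta) {
  theta + model$p2 * theta^2 + model$p3 * theta^3 + model$p4 * theta^4
}

#' Project camera-frame points through the fisheye model
#'
#' A total function: points behind the camera (`Z <= 0`) or beyond
#' `theta_max` yield `NA` pixel coordinates ("not projectable"); the on-axis
#' point maps to the principal point.
#'
#' @param model a `fisheye_model`.
#' @param cam_points n x 3 matrix (or 3-vector) in the camera frame.
#' @return n x 2 matrix of pixel coordinates `(xd, yd)` (0-based, origin
#'   top-left, pixel centres at integers), `NA` rows where not projectable.
#' @export
fisheye_project <- function(model, cam_points) {
  stopifnot(inherits(model, "fisheye_model"))
  p <- as_query_matrix(cam_points)
  X <- p[, 1]; Y <- p[, 2]; Z <- p[, 3]
  rxy <- sqrt(X^2 + Y^2)
  theta <- (2 / pi) * atan2(rxy, Z)
  ok <- Z > 0 & theta <= model$theta_max
  rho <- fisheye_rho(model, theta)
  scale <- ifelse(rxy > 0, rho / rxy, 0)
  xh <- X * scale
  yh <- Y * scale
  px <- cbind(model$affine[1, 1] * xh + model$affine[1, 2] * yh + model$principal_point[1],
              model$affine[2, 1] * xh + model$affine[2, 2] * yh + model$principal_point[2])
  px[!ok, ] <- NA_real_
  px
}

#' Numerically unproject pixel coordinates to camera-frame rays
#'
#' Inverts the affine map, then solves the quartic `rho(theta) = rho_obs`
#' for `theta` by 1-D root finding, and returns the unit ray in the camera
#' frame.  The inverse of [fisheye_project()] up to ray length.
#'
#' @param model a `fisheye_model`.
#' @param pixels n x 2 matrix (or 2-vector) of `(xd, yd)`.
#' @return n x 3 matrix of unit direction vectors.
#' @export
fisheye_unproject <- function(model, pixels) {
  stopifnot(inherits(model, "fisheye_model"))
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2)
  ainv <- solve(model$affine)
  h <- sweep(as.matrix(pixels), 2, model$principal_point) %*% t(ainv)
  rho <- sqrt(rowSums(h^2))
  rho_max <- fisheye_rho(model, 1)
  out <- matrix(NA_real_, nrow(h), 3)
  for (i in seq_len(nrow(h))) {
    if (rho[i] == 0) { out[i, ] <- c(0, 0, 1); next }
    f <- function(th) fisheye_rho(model, th) - rho[i]
    if (f(1) < 0 || rho[i] > rho_max) next  # outside the modelled field
    th <- stats::uniroot(f, c(0, 1), tol = 1e-14)$root
    ang <- th * pi / 2
    u <- h[i, ] / rho[i]
    out[i, ] <- c(sin(ang) * u, cos(ang))
  }
  out
}

#' Frustum test
#'
#' TRUE iff the world point projects (`Z > 0`, `theta <= theta_max`) and its
#' pixel coordinates fall inside the image, `0 <= xd < width` and
#' `0 <= yd < height`.  Vectorised.
#'
#' @param model a `fisheye_model`.
#' @param pose a `camera_pose`.
#' @param points n x 3 world points.
#' @return logical vector.
#' @export
in_frustum <- function(model, pose, points) {
  px <- fisheye_project(model, world_to_camera(pose, points))
  !is.na(px[, 1]) &
    px[, 1] >= 0 & px[, 1] < model$image_size[1] &
    px[, 2] >= 0 & px[, 2] < model$image_size[2]
}

#' View angle between surface normal and camera direction
#'
#' The angle between a point's normal and the unit vector from the point
#' toward the camera centre; 0 deg means a head-on view of the surface.
#'
#' @param pose a `camera_pose`.
#' @param points n x 3 world points.
#' @param normals n x 3 unit normals.
#' @return angles in degrees, in `[0, 180]`.
#' @export
view_angle <- function(pose, points, normals) {
  points <- as_query_matrix(points)
  normals <- as_query_matrix(normals)
  to_cam <- sweep(-points, 2, pose$center, "+")
  d <- sqrt(rowSums(to_cam^2))
  if (any(d == 0)) stop("point coincides with the camera center")
  cosang <- rowSums(normals * to_cam) / d
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Classify a view angle into reliability classes
#'
#' Perpendicular views (0 to 25 deg) give the most reliable reflectance,
#' oblique views (25 to 60 deg) less so, and indirect views (beyond 60 deg)
#' are unreliable.  Boundaries go to the oblique class.
#'
#' @param angle angle(s) in degrees, in `[0, 180]`.
#' @return character vector: `"perpendicular"`, `"oblique"` or `"indirect"`.
#' @export
classify_view <- function(angle) {
  if (any(angle < 0 | angle > 180, na.rm = TRUE)) {
    stop("view angles must lie in [0, 180] degrees")
  }
  ifelse(angle < 25, "perpendicular",
         ifelse(angle <= 60, "oblique", "indirect"))
}

#' Read per-image pose + fisheye records
#'
#' One YAML/JSON record per image with fields `center` (3), `rotation`
#' (row-major 9 values), `p2 p3 p4`, `C D E F` (affine), `cx cy`,
#' `width height`, optional `theta_max`.
#'
#' @param path YAML or JSON file holding a list of records.
#' @return list of `list(pose =, model =)` pairs.
#' @export
read_camera_file <- function(path) {
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  lapply(recs, function(r) {
    list(pose = camera_pose(unlist(r$center),
                            matrix(unlist(r$rotation), 3, 3, byrow = TRUE)),
         model = fisheye_model(r$p2 %||% 0, r$p3 %||% 0, r$p4 %||% 0,
                               affine = matrix(c(r$C, r$D, r$E, r$F), 2, 2,
                                               byrow = TRUE),
                               principal_point = c(r$cx, r$cy),
                               image_size = c(r$width, r$height),
                               theta_max = r$theta_max %||% 1))
  })
}

#' Write per-image pose + fisheye records
#' @param cameras list of `list(pose =, model =)` pairs.
#' @param path output `.yaml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_camera_file <- function(cameras, path) {
  recs <- lapply(cameras, function(cm) {
    list(center = as.numeric(cm$pose$center),
         rotation = as.numeric(t(cm$pose$rotation)),
         p2 = cm$model$p2, p3 = cm$model$p3, p4 = cm$model$p4,
         C = cm$model$affine[1, 1], D = cm$model$affine[1, 2],
         E = cm$model$affine[2, 1], F = cm$model$affine[2, 2],
         cx = cm$model$principal_point[1], cy = cm$model$principal_point[2],
         width = cm$model$image_size[1], height = cm$model$image_size[2],
         theta_max = cm$model$theta_max)
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(recs, path, precision = 15)
  }
  invisible(path)
}
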