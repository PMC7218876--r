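#' Rigid transform
#'
#' A proper rotation plus translation; applied as `R p + t`.
#'
#' @param rotation 3 x 3 orthonormal matrix, det = +1.
#' @param translation 3-vector (metres).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 || det(rotation) < 0) {
    stop("rotation must be orthonormal with det = +1")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("rigid_transform: rotation %.4g deg, translation (%.4g, %.4g, %.4g)\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation angle of a rotation matrix, in degrees
#' @param R 3 x 3 rotation matrix.
#' @return angle in `[0, 180]`.
#' @export
rotation_angle_deg <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}

#' Apply a rigid transform
#' @param transform a `rigid_transform`.
#' @param x n x 3 matrix of points, or a `point_cloud` (normals rotated too).
#' @return same type as `x`.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "point_cloud")) {
    x$positions <- apply_transform(transform, x$positions)
    if (!is.null(x$normals)) x$normals <- x$normals %*% t(transform$rotation)
    return(x)
  }
  sweep(as_query_matrix(x) %*% t(transform$rotation), 2,
        transform$translation, "+")
}

#' Compose two rigid transforms (`b` first, then `a`)
#' @param a,b `rigid_transform`s.
#' @return the composite transform.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return its inverse.
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$rotation),
                  as.numeric(-t(transform$rotation) %*% transform$translation))
}

#' Serialize / deserialize a rigid transform as a 4 x 4 row-major matrix
#' @param transform a `rigid_transform`.
#' @param path plain-text or `.json` file path.
#' @return `path` (write) or a `rigid_transform` (read).
#' @export
write_transform <- function(transform, path) {
  m <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(matrix = as.numeric(t(m))), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(format(m, digits = 17), path, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    matrix(unlist(jsonlite::read_json(path, simplifyVector = TRUE)$matrix),
           4, 4, byrow = TRUE)
  } else {
    as.matrix(utils::read.table(path))
  }
  dimnames(m) <- NULL
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Match source points to their nearest target points
#'
#' Nearest-neighbour correspondences weighted by distance and normal
#' compatibility: `weight = exp(-d^2 / max_dist^2) * max(0, cos(normal
#' angle))`.  Pairs beyond `max_dist` or whose normals disagree by more than
#' `max_normal_angle` are dropped.
#'
#' @param source,target `point_cloud`s with normals.
#' @param target_index optional prebuilt `spatial_index` of the target.
#' @param max_dist distance gate (> 0; `Inf` disables it).
#' @param max_normal_angle normal-compatibility gate in degrees.
#' @return data frame with columns `source`, `target`, `weight`, `dist`.
#' @export
match_points <- function(source, target, target_index = NULL,
                         max_dist = Inf, max_normal_angle = 180) {
  stopifnot(inherits(source, "point_cloud"), inherits(target, "point_cloud"))
  if (is.null(source$normals) || is.null(target$normals)) {
    stop("both clouds must carry normals")
  }
  if (max_dist <= 0) stop("max_dist must be > 0")
  idx <- target_index %||% build_index(target)
  nn <- query_knn(idx, source$positions, k = 1)
  tgt <- nn$ids[, 1]
  d <- nn$dists[, 1]
  cosang <- rowSums(source$normals * target$normals[tgt, , drop = FALSE])
  cosang <- pmin(pmax(cosang, -1), 1)
  ang <- acos(cosang) * 180 / pi
  keep <- d <= max_dist & ang <= max_normal_angle
  if (!any(keep)) stop("no correspondences: clouds do not overlap under the gates")
  w <- exp(-(d[keep]^2) / max_dist^2) * pmax(0, cosang[keep])
  data.frame(source = which(keep), target = tgt[keep], weight = w,
             dist = d[keep])
}

#' Closed-form weighted rigid fit (orthogonal Procrustes)
#'
#' The weighted least-squares rigid transform taking the source points onto
#' their matched target points: weighted centroids are subtracted, the
#' weighted cross-covariance is decomposed by SVD and the rotation sign is
#' corrected so the result is always a proper rotation.
#'
#' @param corr correspondence data frame from [match_points()].
#' @param source,target the matched `point_cloud`s.
#' @return a `rigid_transform`.
#' @export
fit_transform <- function(corr, source, target) {
  if (nrow(corr) < 3) stop("need at least 3 correspondences")
  w <- corr$weight
  if (sum(w) <= 0) stop("all correspondence weights are zero")
  p <- source$positions[corr$source, , drop = FALSE]
  x <- target$positions[corr$target, , drop = FALSE]
  wp <- colSums(p * w) / sum(w)
  wx <- colSums(x * w) / sum(w)
  pc <- sweep(p, 2, wp)
  xc <- sweep(x, 2, wx)
  H <- crossprod(pc * w, xc)
  sv <- svd(H)
  if (sv$d[2] <= max(sv$d[1], 1e-300) * 1e-12) {
    stop("degenerate correspondence configuration (collinear or coincident)")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- wx - as.numeric(R %*% wp)
  rigid_transform(R, t)
}

icp_objective <- function(corr, src_pos, tgt_pos) {
  res <- tgt_pos[corr$target, , drop = FALSE] - src_pos[corr$source, , drop = FALSE]
  mean(rowSums(res^2))
}

#' Iterative closest point rigid registration
#'
#' Alternates nearest-neighbour matching (distance- and normal-gated,
#' weighted) with the closed-form rigid fit until the mean squared
#' correspondence residual stops decreasing.  Point-to-point metric; the
#' objective sequence over accepted iterations is non-increasing.
#'
#' @param source `point_cloud` to be moved (must have normals).
#' @param target reference `point_cloud` (must have normals).
#' @param max_iter iteration cap (default 50).
#' @param tol stop when the objective decreases by less than this
#'   (default 1e-12).
#' @param max_dist correspondence distance gate; a vector is used as a
#'   per-iteration schedule (last value repeats).
#' @param max_normal_angle normal gate in degrees.
#' @param init optional initial `rigid_transform` (default identity).
#' @return list with `transform` (`rigid_transform`) and `report`
#'   (`iterations`, `final_error`, `rmse`, `converged`).
#' @export
icp <- function(source, target, max_iter = 50, tol = 1e-12,
                max_dist = Inf, max_normal_angle = 90, init = NULL) {
  stopifnot(inherits(source, "point_cloud"), inherits(target, "point_cloud"))
  tf <- init %||% rigid_transform()
  tgt_idx <- build_index(target)
  moved <- apply_transform(tf, source)
  best_obj <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    md <- max_dist[min(iter, length(max_dist))]
    corr <- tryCatch(
      match_points(moved, target, target_index = tgt_idx,
                   max_dist = md, max_normal_angle = max_normal_angle),
      error = function(e) NULL)
    if (is.null(corr) || nrow(corr) < 3) break  # correspondence collapse
    obj <- icp_objective(corr, moved$positions, target$positions)
    if (obj <= tol) {                            # already aligned to tolerance
      best_obj <- obj
      converged <- TRUE
      break
    }
    if (obj > best_obj) break                    # reject non-improving step
    if (best_obj - obj < tol && is.finite(best_obj)) {
      best_obj <- obj
      converged <- TRUE
      break
    }
    best_obj <- obj
    step <- tryCatch(fit_transform(corr, moved, target), error = function(e) NULL)
    if (is.null(step)) break
    tf <- compose_transform(step, tf)
    moved <- apply_transform(tf, source)
  }
  rmse <- alignment_rmse(target, moved, reference_index = tgt_idx)
  list(transform = tf,
       report = list(iterations = iter, final_error = best_obj,
                     rmse = rmse, converged = converged))
}

#' Alignment RMSE between a reference and an aligned cloud
#'
#' Every point of the aligned (multispectral) cloud is paired with its
#' nearest point in the reference (RGB) cloud; the root mean squared 3-D
#' distance over all aligned points is returned, in the input length units.
#'
#' @param reference reference `point_cloud` (P1).
#' @param aligned aligned `point_cloud` (P2); the mean runs over its points.
#' @param reference_index optional prebuilt index of the reference.
#' @return RMSE (>= 0).
#' @export
alignment_rmse <- function(reference, aligned, reference_index = NULL) {
  stopifnot(inherits(reference, "point_cloud"), inherits(aligned, "point_cloud"))
  idx <- reference_index %||% build_index(reference)
  nn <- query_knn(idx, aligned$positions, k = 1)
  sqrt(mean(nn$dists[, 1]^2))
}
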