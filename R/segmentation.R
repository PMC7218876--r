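#' Build a standardized feature matrix from an enriched cloud
#'
#' Assembles the 11-attribute feature vector per point — spatial position
#' (X, Y, Z), visible colour (R, G, B), the four band reflectances and NDVI
#' — and z-scores every selected dimension (mean 0, sd 1).  Raw metres,
#' `[0, 1]` colour and reflectance would otherwise enter one Euclidean
#' metric at incompatible scales.  Zero-variance dimensions pass through as
#' zeros with a warning.  Optional per-dimension weights multiply the
#' standardized columns.
#'
#' @param x an enriched `point_cloud` (no `NA` in selected attributes; use
#'   [enriched_ids()] / [subset_cloud()] first) or a plain numeric matrix.
#' @param dims character vector of dimensions to include; default all 11.
#' @param weights optional named (or positional) per-dimension weights.
#' @return a `feature_matrix`: numeric matrix with attributes `center`,
#'   `scale`, `weights` so raw values are recoverable.
#' @export
standardize <- function(x, dims = NULL, weights = NULL) {
  raw <- if (inherits(x, "point_cloud")) cloud_feature_table(x) else as.matrix(x)
  if (is.null(colnames(raw))) colnames(raw) <- paste0("V", seq_len(ncol(raw)))
  dims <- dims %||% colnames(raw)
  if (!length(dims)) stop("empty dimension selection")
  miss <- setdiff(dims, colnames(raw))
  if (length(miss)) stop(sprintf("unknown dimensions: %s", paste(miss, collapse = ", ")))
  raw <- raw[, dims, drop = FALSE]
  if (any(!is.finite(raw))) {
    stop("selected attributes contain non-finite values; subset to enriched points first")
  }
  ctr <- colMeans(raw)
  sc <- apply(raw, 2, stats::sd)
  zero <- sc == 0 | !is.finite(sc)
  if (any(zero)) {
    warning(sprintf("zero-variance dimensions passed through as 0: %s",
                    paste(dims[zero], collapse = ", ")))
    sc[zero] <- 1
  }
  z <- sweep(sweep(raw, 2, ctr), 2, sc, "/")
  z[, zero] <- 0
  w <- rep(1, ncol(z))
  names(w) <- dims
  if (!is.null(weights)) {
    if (!is.null(names(weights))) w[names(weights)] <- weights
    else w[] <- weights
  }
  z <- sweep(z, 2, w, "*")
  structure(z, center = ctr, scale = sc, weights = w, class = c("feature_matrix", "matrix"))
}

# the 11 clustering attributes in canonical order
cloud_feature_table <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(cloud$colors)) stop("feature table requires colors")
  need <- c("red_refl", "green_refl", "reg_refl", "nir_refl", "ndvi")
  if (!all(need %in% attribute_schema(cloud))) {
    stop("cloud is not enriched (band reflectances / ndvi missing)")
  }
  cbind(x = cloud$positions[, 1], y = cloud$positions[, 2],
        z = cloud$positions[, 3],
        R = cloud$colors[, 1], G = cloud$colors[, 2], B = cloud$colors[, 3],
        red = cloud$attributes$red_refl, green = cloud$attributes$green_refl,
        reg = cloud$attributes$reg_refl, nir = cloud$attributes$nir_refl,
        ndvi = cloud$attributes$ndvi)
}

#' Recover raw-unit values from a feature matrix row or centroid
#' @param features a `feature_matrix`.
#' @param z numeric vector (or matrix) in standardized units.
#' @return values in the original units.
#' @export
unstandardize <- function(features, z) {
  w <- attr(features, "weights"); sc <- attr(features, "scale")
  ctr <- attr(features, "center")
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  sweep(sweep(sweep(z, 2, w, "/"), 2, sc, "*"), 2, ctr, "+")
}

#' Euclidean distance between two feature vectors
#' @param pi,pj numeric vectors of equal dimension.
#' @return `sqrt(sum((pi - pj)^2))`.
#' @export
feature_distance <- function(pi, pj) {
  if (length(pi) != length(pj)) stop("dimension mismatch")
  sqrt(sum((pi - pj)^2))
}

## ---- bisection ----------------------------------------------------------

#' Bisect a member set with 2-means
#'
#' k-means++ initialisation, `n_init` restarts, best within-cluster sum of
#' squares kept; deterministic for a fixed seed.  Returns `NULL`
#' ("unsplittable") when all member rows are identical.
#'
#' @param features a `feature_matrix` (or plain matrix).
#' @param members integer row indices (>= 2 of them).
#' @param seed integer seed controlling initialisation.
#' @param n_init number of restarts (default 10).
#' @return list with `A`, `B` (member id sets), `centroids` (2 x d),
#'   `centroid_distance`, `inertia`; or `NULL` if unsplittable.
#' @export
bisect <- function(features, members, seed = 1, n_init = 10) {
  if (length(members) < 2) stop("need at least 2 members to bisect")
  x <- features[members, , drop = FALSE]
  rng <- apply(x, 2, function(v) diff(range(v)))
  if (all(rng == 0)) return(NULL)
  with_seed(seed, {
    best <- NULL
    for (rep in seq_len(n_init)) {
      ctrs <- kmeanspp_centers(x, 2L)
      if (is.null(ctrs)) next
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = ctrs, iter.max = 100,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(km) || any(km$size == 0)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) return(NULL)
    list(A = members[best$cluster == 1L], B = members[best$cluster == 2L],
         centroids = unname(best$centers),
         centroid_distance = feature_distance(best$centers[1, ], best$centers[2, ]),
         inertia = best$tot.withinss)
  })
}

# k-means++ seeding for k centers
kmeanspp_centers <- function(x, k) {
  m <- nrow(x)
  first <- sample.int(m, 1)
  ctrs <- x[first, , drop = FALSE]
  d2 <- rowSums(sweep(x, 2, ctrs[1, ])^2)
  for (j in seq_len(k - 1)) {
    if (sum(d2) == 0) return(NULL)
    nxt <- sample.int(m, 1, prob = d2)
    ctrs <- rbind(ctrs, x[nxt, ])
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[nxt, ])^2))
  }
  ctrs
}

#' Cluster diameter (maximum intra-cluster pairwise distance)
#'
#' Exact for member sets up to `exact_threshold`; larger sets are reduced by
#' deterministic farthest-point sampling to `exact_threshold` members first,
#' whose exact diameter never exceeds the true value and is at least half of
#' it.
#'
#' @param features a `feature_matrix` (or plain matrix).
#' @param members integer row indices.
#' @param exact_threshold exact-computation cap (default 2,000).
#' @return diameter (>= 0).
#' @export
cluster_diameter <- function(features, members, exact_threshold = 2000) {
  m <- length(members)
  if (m < 2) return(0)
  x <- features[members, , drop = FALSE]
  if (m > exact_threshold) x <- x[fps_sample(x, exact_threshold), , drop = FALSE]
  max(stats::dist(x))
}

# deterministic farthest-point sampling: start at the point farthest from
# the centroid (ties -> lowest index), then greedily add the point farthest
# from the selected set
fps_sample <- function(x, k) {
  m <- nrow(x)
  ctr <- colMeans(x)
  d0 <- rowSums(sweep(x, 2, ctr)^2)
  sel <- integer(k)
  sel[1] <- which.max(d0)
  mind <- rowSums(sweep(x, 2, x[sel[1], ])^2)
  for (j in 2:k) {
    sel[j] <- which.max(mind)
    mind <- pmin(mind, rowSums(sweep(x, 2, x[sel[j], ])^2))
  }
  sel
}

#' Splitting decision for a child cluster
#'
#' A child is recursed into only while it remains heterogeneous: its
#' diameter must be at least the distance between the two sibling centroids
#' produced by the split that created it, and it must hold at least
#' `min_size` members.  A cluster whose diameter falls below the centroid
#' distance is homogeneous and stops.
#'
#' @param diameter the child's diameter.
#' @param sibling_centroid_distance distance between the two sibling
#'   centroids of the parent's split.
#' @param size the child's member count.
#' @param min_size smallest splittable cluster (default 10).
#' @return logical.
#' @export
should_split <- function(diameter, sibling_centroid_distance, size,
                         min_size = 10) {
  diameter >= sibling_centroid_distance & size >= min_size
}

## ---- divisive hierarchy --------------------------------------------------

#' Divisive hierarchical clustering with unknown cluster count
#'
#' Top-down segmentation: all points start in one cluster, every
#' heterogeneous cluster is bisected by 2-means (k-means++, restarts), and
#' recursion into a child continues only while the child's diameter is at
#' least the distance between the sibling centroids of its split
#' ([should_split()]).  The number of leaves — the material clusters — is
#' therefore discovered, not supplied.
#'
#' @param features a `feature_matrix` from [standardize()] (or plain
#'   matrix; rows are points).
#' @param seed integer seed; fixed seed gives identical output.
#' @param n_init 2-means restarts per split (default 10).
#' @param min_size smallest cluster eligible for splitting (default 10).
#' @param max_depth recursion guard (default 32).
#' @param exact_threshold exact-diameter cap, see [cluster_diameter()].
#' @return an object of class `divisive_clustering`: per-point `labels`
#'   (0-based contiguous leaf ids), `k` leaves, and a `nodes` table holding
#'   the binary hierarchy (id, parent, size, diameter, centroid,
#'   split-feature ranking).
#' @export
divisive_cluster <- function(features, seed = 1, n_init = 10, min_size = 10,
                             max_depth = 32, exact_threshold = 2000) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("V", seq_len(ncol(features)))
  }
  n <- nrow(features)
  if (n < 1) stop("empty feature matrix")
  nodes <- list()
  members_of <- list()
  make_node <- function(parent, members, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, parent = parent, depth = depth,
                         size = length(members),
                         diameter = cluster_diameter(features, members,
                                                     exact_threshold),
                         centroid = colMeans(features[members, , drop = FALSE]),
                         children = NULL, split_features = NULL, leaf = TRUE)
    members_of[[id]] <<- members
    id
  }
  root <- make_node(NA_integer_, seq_len(n), 0L)
  queue <- if (n >= 2) root else integer(0)
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    nd <- nodes[[id]]
    sp <- bisect(features, members_of[[id]], seed = seed + nd$id,
                 n_init = n_init)
    if (is.null(sp)) next  # unsplittable: stays a leaf
    a <- make_node(id, sp$A, nd$depth + 1L)
    b <- make_node(id, sp$B, nd$depth + 1L)
    rank <- order(abs(sp$centroids[1, ] - sp$centroids[2, ]), decreasing = TRUE)
    nodes[[id]]$children <- c(a, b)
    nodes[[id]]$leaf <- FALSE
    nodes[[id]]$split_features <- structure(
      abs(sp$centroids[1, ] - sp$centroids[2, ])[rank],
      names = colnames(features)[rank])
    nodes[[id]]$centroid_distance <- sp$centroid_distance
    for (child in c(a, b)) {
      if (nodes[[child]]$depth < max_depth &&
          should_split(nodes[[child]]$diameter, sp$centroid_distance,
                       nodes[[child]]$size, min_size)) {
        queue <- c(queue, child)
      }
    }
  }
  leaf_ids <- Filter(function(i) nodes[[i]]$leaf, seq_along(nodes))
  labels <- integer(n)
  for (li in seq_along(leaf_ids)) {
    labels[members_of[[leaf_ids[li]]]] <- li - 1L
    nodes[[leaf_ids[li]]]$label <- li - 1L
  }
  structure(list(nodes = nodes, labels = labels, k = length(leaf_ids),
                 leaf_ids = leaf_ids, n = n, features_info =
                   list(center = attr(features, "center"),
                        scale = attr(features, "scale"),
                        weights = attr(features, "weights"),
                        dims = colnames(features)),
                 params = list(seed = seed, n_init = n_init,
                               min_size = min_size, max_depth = max_depth,
                               exact_threshold = exact_threshold),
                 leaf_centroids = t(vapply(leaf_ids,
                                           function(i) nodes[[i]]$centroid,
                                           numeric(ncol(features)))),
                 call = match.call()),
            class = "divisive_clustering")
}

#' @export
print.divisive_clustering <- function(x, ...) {
  cat(sprintf("divisive_clustering: %d points, %d material clusters, %d tree nodes\n",
              x$n, x$k, length(x$nodes)))
  sizes <- vapply(x$leaf_ids, function(i) x$nodes[[i]]$size, 0L)
  cat("  leaf sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.divisive_clustering <- function(object, ...) {
  leaves <- lapply(object$leaf_ids, function(i) {
    nd <- object$nodes[[i]]
    parent_sf <- if (!is.na(nd$parent))
      names(object$nodes[[nd$parent]]$split_features)[1:2] else c(NA, NA)
    data.frame(label = nd$label, size = nd$size, diameter = nd$diameter,
               top_split_feature = parent_sf[1],
               second_split_feature = parent_sf[2])
  })
  out <- do.call(rbind, leaves)
  class(out) <- c("summary.divisive_clustering", "data.frame")
  out
}

#' Assign new points to the fitted material clusters
#'
#' New observations are standardized with the training scaling and assigned
#' to the nearest leaf centroid.
#'
#' @param object a `divisive_clustering`.
#' @param newdata matrix of raw feature rows (same dimensions as training).
#' @param ... unused.
#' @return integer labels (0-based).
#' @export
predict.divisive_clustering <- function(object, newdata, ...) {
  fi <- object$features_info
  z <- as.matrix(newdata)
  if (!is.null(fi$center)) {
    z <- sweep(sweep(z, 2, fi$center), 2, fi$scale, "/")
    z <- sweep(z, 2, fi$weights, "*")
  }
  d2 <- outer(rowSums(z^2), rowSums(object$leaf_centroids^2), "+") -
    2 * z %*% t(object$leaf_centroids)
  max.col(-d2, ties.method = "first") - 1L
}

#' Plot the cluster hierarchy
#'
#' Simple base-graphics rendering of the binary split tree; node height is
#' the cluster diameter, leaves are annotated with label and size.
#'
#' @param x a `divisive_clustering`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.divisive_clustering <- function(x, ...) {
  xpos <- numeric(length(x$nodes))
  leaf_seq <- 0
  assign_x <- function(id) {
    nd <- x$nodes[[id]]
    if (nd$leaf) {
      leaf_seq <<- leaf_seq + 1
      xpos[id] <<- leaf_seq
    } else {
      for (ch in nd$children) assign_x(ch)
      xpos[id] <<- mean(xpos[nd$children])
    }
  }
  assign_x(1L)
  hts <- vapply(x$nodes, function(nd) nd$diameter, 0)
  graphics::plot(NA, xlim = c(0.5, x$k + 0.5), ylim = c(0, max(hts) * 1.05),
                 xlab = "material cluster", ylab = "cluster diameter",
                 xaxt = "n", ...)
  for (nd in x$nodes) {
    if (!nd$leaf) {
      ch <- nd$children
      graphics::segments(xpos[ch], hts[ch], xpos[ch], hts[nd$id])
      graphics::segments(xpos[ch[1]], hts[nd$id], xpos[ch[2]], hts[nd$id])
    }
  }
  leaf_x <- xpos[unlist(x$leaf_ids)]
  labs <- vapply(x$leaf_ids, function(i) x$nodes[[i]]$label, 0L)
  graphics::axis(1, at = leaf_x, labels = labs)
  invisible(x)
}

#' Attach cluster labels to a point cloud
#'
#' @param result a `divisive_clustering` fitted on the cloud's admitted
#'   (fully enriched) points.
#' @param cloud the `point_cloud`.
#' @param ids indices of the points the clustering covers; defaults to
#'   [enriched_ids()] for enriched clouds, else all points.
#' @return the cloud with an integer `label` attribute; excluded points get
#'   label -1.
#' @export
label_cloud <- function(result, cloud, ids = NULL) {
  stopifnot(inherits(result, "divisive_clustering"),
            inherits(cloud, "point_cloud"))
  ids <- ids %||% tryCatch(enriched_ids(cloud),
                           error = function(e) seq_len(n_points(cloud)))
  if (length(ids) != result$n) {
    stop(sprintf("clustering covers %d points but %d were admitted",
                 result$n, length(ids)))
  }
  lab <- rep(-1, n_points(cloud))
  lab[ids] <- result$labels
  set_attribute(cloud, "label", lab)
}

#' Export the cluster tree as JSON
#'
#' Per node: id, parent, size, diameter, centroid in raw units, and the
#' per-dimension split ranking for internal nodes.
#'
#' @param result a `divisive_clustering`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
cluster_report_json <- function(result, path) {
  fi <- result$features_info
  raw_centroid <- function(z) {
    if (is.null(fi$center)) return(as.numeric(z))
    as.numeric(z / fi$weights * fi$scale + fi$center)
  }
  nodes <- lapply(result$nodes, function(nd) {
    rec <- list(id = nd$id, parent = if (is.na(nd$parent)) NULL else nd$parent,
                size = nd$size, diameter = nd$diameter, leaf = nd$leaf,
                centroid = as.list(structure(raw_centroid(nd$centroid),
                                             names = fi$dims)))
    if (!is.null(nd$label)) rec$label <- nd$label
    if (!is.null(nd$split_features)) {
      rec$split_features <- as.list(nd$split_features)
      rec$centroid_distance <- nd$centroid_distance
    }
    rec
  })
  jsonlite::write_json(list(k = result$k, n = result$n, nodes = nodes),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Segment an enriched cloud end to end
#'
#' Convenience wrapper: selects the fully enriched points, standardizes the
#' 11-attribute features, runs [divisive_cluster()] and labels the cloud.
#'
#' @param cloud an enriched `point_cloud`.
#' @param dims,weights passed to [standardize()].
#' @param ... passed to [divisive_cluster()].
#' @return list with `cloud` (labelled), `clustering`
#'   (`divisive_clustering`), `ids` (admitted point indices).
#' @export
segment_cloud <- function(cloud, dims = NULL, weights = NULL, ...) {
  ids <- enriched_ids(cloud)
  if (!length(ids)) stop("no fully enriched points to segment")
  fm <- standardize(subset_cloud(cloud, ids), dims = dims, weights = weights)
  cl <- divisive_cluster(fm, ...)
  list(cloud = label_cloud(cl, cloud, ids = ids), clustering = cl, ids = ids)
}
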