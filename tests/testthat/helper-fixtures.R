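# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately written from scratch (plain loops, textbook
# formulas) so they stay independent of the package code paths they check.

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# brute-force k-nearest neighbours: full distance scan, no tree
brute_knn <- function(data, query, k) {
  d <- sqrt(colSums((t(data) - query)^2))
  ord <- order(d)[seq_len(k)]
  list(ids = ord, dists = d[ord])
}

brute_radius <- function(data, query, radius) {
  d <- sqrt(colSums((t(data) - query)^2))
  ids <- which(d <= radius + 1e-12)
  ids[order(d[ids])]
}

# a simple overhead test camera looking straight down at the origin
test_camera <- function(height = 5, scale = 200, size = 480) {
  list(pose = look_at_pose(c(0, 0, height), c(0, 0, 0)),
       model = fisheye_model(affine = diag(c(scale, scale)),
                             principal_point = c(size / 2, size / 2),
                             image_size = c(size, size)))
}

# two parallel planes facing the camera; back plane fully inside the
# front plane's shadow for a camera on the axis
two_plane_scene <- function(n_per_plane = 1000, seed = 3) {
  set.seed(seed)
  front <- cbind(runif(n_per_plane, -1, 1), runif(n_per_plane, -1, 1), 1)
  back <- cbind(runif(n_per_plane, -1, 1), runif(n_per_plane, -1, 1), 0)
  cloud <- point_cloud(rbind(front, back),
                       normals = matrix(c(0, 0, 1), 2 * n_per_plane, 3,
                                        byrow = TRUE))
  list(cloud = cloud, n = n_per_plane,
       occluded_truth = c(rep(FALSE, n_per_plane), rep(TRUE, n_per_plane)))
}

# structured lat-long sphere sampling with its exact triangulation
sphere_grid_fixture <- function(center, radius, nlat = 24) {
  pts <- list()
  ring_ids <- list()
  id <- 0L
  for (i in 0:nlat) {
    th <- pi * i / nlat
    nl <- if (i == 0 || i == nlat) 1L else max(3L, round(2 * nlat * sin(th)))
    ids <- integer(nl)
    for (j in seq_len(nl)) {
      ph <- 2 * pi * (j - 1) / nl + (i %% 2) * pi / nl
      id <- id + 1L
      pts[[id]] <- center + radius * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      ids[j] <- id
    }
    ring_ids[[i + 1]] <- ids
  }
  P <- do.call(rbind, pts)
  azim <- function(ids) atan2(P[ids, 2] - center[2], P[ids, 1] - center[1])
  tris <- list()
  for (i in seq_len(nlat)) {
    a <- ring_ids[[i]]; b <- ring_ids[[i + 1]]
    if (length(a) == 1L && length(b) == 1L) next
    aa <- a[order(azim(a))]; bb <- b[order(azim(b))]
    na <- length(aa); nb <- length(bb)
    ia <- 1L; ib <- 1L
    aza <- sort(azim(a)); azb <- sort(azim(b))
    while (ia < na || ib < nb) {
      nexta <- if (ia < na) aza[ia + 1] else Inf
      nextb <- if (ib < nb) azb[ib + 1] else Inf
      if (nexta <= nextb) {
        tris[[length(tris) + 1]] <- c(aa[ia], aa[ia + 1], bb[min(ib, nb)])
        ia <- ia + 1L
      } else {
        tris[[length(tris) + 1]] <- c(aa[min(ia, na)], bb[ib + 1], bb[ib])
        ib <- ib + 1L
      }
    }
    tris[[length(tris) + 1]] <- c(aa[na], aa[1], bb[nb])
    tris[[length(tris) + 1]] <- c(aa[1], bb[1], bb[nb])
  }
  list(points = P, triangles = do.call(rbind, tris))
}

# textbook ray-triangle test: intersect the ray with the triangle plane,
# then check barycentric coordinates of the hit (independent of the
# package's Moller-Trumbore routine)
oracle_ray_hits_triangles <- function(origin, target, verts, tris,
                                      t_frac_max = 1 - 1e-6) {
  dir <- target - origin
  L <- sqrt(sum(dir^2))
  u <- dir / L
  for (k in seq_len(nrow(tris))) {
    a <- verts[tris[k, 1], ]; b <- verts[tris[k, 2], ]; c <- verts[tris[k, 3], ]
    nrm <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
             (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
             (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
    den <- sum(nrm * u)
    if (abs(den) < 1e-14) next
    t <- sum(nrm * (a - origin)) / den
    if (t <= 1e-9 || t >= L * t_frac_max) next
    h <- origin + t * u
    # barycentric via areas
    v0 <- b - a; v1 <- c - a; v2 <- h - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den2 <- d00 * d11 - d01 * d01
    if (den2 == 0) next
    v <- (d11 * d20 - d01 * d21) / den2
    w <- (d00 * d21 - d01 * d20) / den2
    if (v >= -1e-12 && w >= -1e-12 && v + w <= 1 + 1e-12) return(TRUE)
  }
  FALSE
}

# sphere-in-front-of-plane scene: structured sphere (with exact
# triangulation for the oracle) above a random ground plane
sphere_plane_scene <- function(total = 2000, seed = 3) {
  set.seed(seed)
  ctr <- c(0, 0, 1.5)
  rad <- 0.5
  sg <- sphere_grid_fixture(ctr, rad, nlat = 24)
  ns <- nrow(sg$points)
  np <- total - ns
  plane <- cbind(runif(np, -2, 2), runif(np, -2, 2), 0)
  pos <- rbind(sg$points, plane)
  nrm <- rbind(sweep(sg$points, 2, ctr) / rad,
               matrix(c(0, 0, 1), np, 3, byrow = TRUE))
  list(cloud = point_cloud(pos, normals = nrm),
       sphere = sg, n_sphere = ns, center = ctr, radius = rad)
}

# reference-scene feature matrix built from the generator's ground truth
# (bypasses rendering; used to isolate the clustering stage)
truth_enriched_cloud <- function(scene) {
  cl <- scene$cloud
  tr <- scene$true_reflectance
  cl <- set_attribute(cl, "green_refl", tr[, "green"])
  cl <- set_attribute(cl, "red_refl", tr[, "red"])
  cl <- set_attribute(cl, "reg_refl", tr[, "reg"])
  cl <- set_attribute(cl, "nir_refl", tr[, "nir"])
  set_attribute(cl, "ndvi", ndvi(tr[, "nir"], tr[, "red"]))
}

# small fully-calibrated capture set over the reference scene
small_rendered_scene <- function(seed = 42, points_per_material = 300,
                                 noise = 0.01) {
  sc <- default_reference_scene(seed = seed,
                                points_per_material = points_per_material)
  sc$image_noise_sd <- noise
  scene <- generate_scene(sc)
  captures <- render_views(scene)
  ks <- lapply(simulate_panel_shots(sc), panel_calibration)
  list(scene = scene, captures = calibrate_captures(captures, ks),
       config = sc)
}
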