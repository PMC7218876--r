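test_that("trivial visibility cases", {
  cam <- test_camera()
  single <- point_cloud(matrix(c(0, 0, 1), 1), normals = matrix(c(0, 0, 1), 1))
  m <- visible_points(single, cam$pose, cam$model, neighbor_radius = 0.1)
  expect_equal(m$status, 1L)
  behind <- point_cloud(rbind(c(0, 0, 7), c(0.1, 0, 9)),
                        normals = matrix(c(0, 0, 1), 2, 3, byrow = TRUE))
  mb <- visible_points(behind, cam$pose, cam$model, neighbor_radius = 0.1)
  expect_equal(mb$status, c(0L, 0L))
  expect_equal(mb$n_out, 2L)
})

test_that("back plane is occluded behind the front plane's silhouette", {
  sc <- two_plane_scene(1000)
  cam <- test_camera()
  mask <- visible_points(sc$cloud, cam$pose, cam$model,
                         neighbor_radius = default_neighbor_radius(sc$cloud))
  pred_occ <- mask$status == 2L
  # front fully visible, >= 99% of the shadowed back plane occluded
  expect_equal(sum(pred_occ[seq_len(sc$n)]), 0)
  expect_gte(mean(pred_occ[sc$n + seq_len(sc$n)]), 0.99)
  expect_gte(mean(pred_occ == sc$occluded_truth), 0.99)
})

test_that("occlusion agrees with exact-triangulation ray casting (sphere over plane)", {
  sc <- sphere_plane_scene(2000)
  cam <- test_camera()
  mask <- visible_points(sc$cloud, cam$pose, cam$model,
                         neighbor_radius = default_neighbor_radius(sc$cloud))
  pos <- sc$cloud$positions
  oracle <- vapply(seq_len(nrow(pos)), function(i) {
    oracle_ray_hits_triangles(cam$pose$center, pos[i, ],
                              sc$sphere$points, sc$sphere$triangles)
  }, TRUE)
  expect_gte(mean((mask$status == 2L) == oracle), 0.99)
})

test_that("bilinear sampling: constants, pixel centres and linear ramps", {
  cam <- test_camera(height = 5, scale = 100, size = 64)
  img_const <- reflectance_image("nir", matrix(0.42, 64, 64))
  set.seed(33)
  pts <- cbind(runif(50, -0.5, 0.5), runif(50, -0.5, 0.5), runif(50, 0, 1))
  expect_equal(sample_band(img_const, cam$model, cam$pose, pts),
               rep(0.42, 50))
  # exact pixel centre returns that pixel's value
  g <- matrix(runif(64 * 64), 64, 64)
  img <- reflectance_image("red", g)
  ray <- fisheye_unproject(cam$model, c(20, 31))
  world <- cam$pose$center + 4 * as.numeric(ray %*% cam$pose$rotation)
  expect_equal(sample_band(img, cam$model, cam$pose, matrix(world, 1)),
               g[32, 21], tolerance = 1e-9)
  # linear ramp v = a + b x + c y is reproduced exactly by bilinear weights
  xg <- matrix(rep(0:63, each = 64), 64, 64)   # value = x pixel index
  yg <- t(xg)                                  # value = y pixel index
  ramp <- reflectance_image("green", 0.1 + 0.003 * xg + 0.001 * yg)
  px <- fisheye_project(cam$model, world_to_camera(cam$pose, pts))
  got <- sample_band(ramp, cam$model, cam$pose, pts)
  expect_equal(got, 0.1 + 0.003 * px[, 1] + 0.001 * px[, 2], tolerance = 1e-9)
  # outside the image -> missing
  expect_true(is.na(sample_band(img, cam$model, cam$pose, c(50, 0, 0.2))))
})

test_that("missing support pixels make the sample missing", {
  g <- matrix(1, 8, 8)
  g[4, 5] <- NA
  expect_true(is.na(cloudspectra:::bilinear_sample(g, 3.5, 3.0)))
  expect_equal(cloudspectra:::bilinear_sample(g, 1.5, 1.5), 1)
})

test_that("multi-view aggregation weights by view class", {
  s1 <- data.frame(band = "nir", value = 0.6, view_class = "perpendicular")
  expect_equal(aggregate_point(s1), c(nir = 0.6))
  s2 <- rbind(s1, data.frame(band = "nir", value = 0.2, view_class = "oblique"))
  expect_equal(aggregate_point(s2), c(nir = (1 * 0.6 + 0.5 * 0.2) / 1.5))
  expect_equal(unname(round(aggregate_point(s2), 4)), 0.4667)
  s3 <- data.frame(band = c("nir", "red"), value = c(0.5, 0.1),
                   view_class = "indirect")
  expect_null(aggregate_point(s3))
  # order invariance and weight-scale invariance
  set.seed(34)
  s <- data.frame(band = sample(c("red", "nir"), 12, TRUE),
                  value = runif(12),
                  view_class = sample(c("perpendicular", "oblique"), 12, TRUE))
  a <- aggregate_point(s)
  b <- aggregate_point(s[sample(12), ])
  expect_equal(a, b)
  scaled <- aggregate_point(s, class_weights = 3 * default_class_weights())
  expect_equal(a, scaled)
})

test_that("enrichment with constant band images attaches constants and NDVI", {
  set.seed(35)
  cl <- point_cloud(cbind(runif(200, -0.5, 0.5), runif(200, -0.5, 0.5), 0),
                    normals = matrix(c(0, 0, 1), 200, 3, byrow = TRUE),
                    colors = matrix(0.5, 200, 3))
  cam <- test_camera()
  vals <- c(green = 0.2, red = 0.1, reg = 0.4, nir = 0.7)
  caps <- list(list(pose = cam$pose, model = cam$model,
                    images = lapply(vals, function(v)
                      reflectance_image("x", matrix(v, 480, 480)))))
  names(caps[[1]]$images) <- names(vals)
  enr <- enrich_cloud(cl, caps, neighbor_radius = 0.2)
  ids <- enriched_ids(enr)
  expect_equal(ids, seq_len(200))
  expect_equal(enr$attributes$nir_refl, rep(0.7, 200), tolerance = 1e-12)
  expect_equal(enr$attributes$ndvi, rep((0.7 - 0.1) / (0.7 + 0.1), 200),
               tolerance = 1e-12)
  expect_true(all(enr$attributes$n_views == 1))
})

test_that("a camera looking away from the scene is a pipeline error", {
  cl <- point_cloud(cbind(runif(50), runif(50), 0),
                    normals = matrix(c(0, 0, 1), 50, 3, byrow = TRUE),
                    colors = matrix(0.5, 50, 3))
  away <- look_at_pose(c(0, 0, 5), c(0, 0, 10))  # optical axis away
  m <- fisheye_model(affine = diag(c(100, 100)), principal_point = c(50, 50),
                     image_size = c(100, 100))
  caps <- list(list(pose = away, model = m,
                    images = sapply(c("green", "red", "reg", "nir"),
                                    function(b) reflectance_image(b, matrix(0.3, 100, 100)),
                                    simplify = FALSE)))
  expect_error(enrich_cloud(cl, caps, neighbor_radius = 0.2), "no point received")
})

test_that("rendered reference scene is recovered within tolerance", {
  fx <- small_rendered_scene(seed = 42, points_per_material = 300, noise = 0.01)
  enr <- enrich_cloud(fx$scene$cloud, fx$captures)
  ids <- enriched_ids(enr)
  expect_gt(length(ids), 1000)
  rec <- cbind(enr$attributes$green_refl, enr$attributes$red_refl,
               enr$attributes$reg_refl, enr$attributes$nir_refl)[ids, ]
  tr <- fx$scene$true_reflectance[ids, ]
  expect_lt(median(abs(rec - tr) / tr), 0.02)
})

test_that("coverage image marks exactly the distinct projected pixels", {
  sc <- two_plane_scene(400, seed = 36)
  cam <- test_camera()
  img <- reflectance_image("nir", matrix(0.5, 480, 480))
  mask <- visible_points(sc$cloud, cam$pose, cam$model,
                         neighbor_radius = default_neighbor_radius(sc$cloud))
  cov <- projection_coverage_image(img, mask, cam$model, cam$pose, sc$cloud)
  vis <- visible_ids(mask)
  px <- round(mask$pixels[vis, , drop = FALSE])
  expect_equal(attr(cov, "n_marked"), nrow(unique(px)))
  expect_true(all(cov$grid[attr(cov, "marked")] == 0))
  # empty mask leaves the image untouched
  empty <- cloudspectra:::new_visibility_mask(rep(0L, n_points(sc$cloud)),
                                              mask$pixels)
  cov0 <- projection_coverage_image(img, empty, cam$model, cam$pose, sc$cloud)
  expect_equal(attr(cov0, "n_marked"), 0)
  expect_equal(cov0$grid, img$grid)
})
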