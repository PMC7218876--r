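test_that("standardization gives zero-mean unit-sd weighted columns", {
  set.seed(41)
  x <- cbind(a = rnorm(200, 5, 3), b = runif(200), c = rnorm(200, -2, 0.1))
  fm <- standardize(x)
  expect_equal(unname(colMeans(fm)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(fm, 2, sd)), rep(1, 3), tolerance = 1e-9)
  fm2 <- standardize(x, weights = c(b = 2))
  expect_equal(unname(sd(fm2[, "b"])), 2, tolerance = 1e-9)
  expect_warning(fmc <- standardize(cbind(x, k = 1)), "zero-variance")
  expect_true(all(fmc[, "k"] == 0))
  expect_error(standardize(x, dims = character(0)), "empty")
  expect_error(standardize(x, dims = "zz"), "unknown")
  # raw values recoverable
  expect_equal(unstandardize(fm2, fm2[7, ]), x[7, , drop = FALSE],
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("feature distance is plain Euclidean", {
  expect_equal(feature_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(feature_distance(c(0, 0, 0, 0), c(3, 4, 0, 0)), 5)
  set.seed(42)
  p <- rnorm(11); q <- rnorm(11)
  expect_equal(feature_distance(p, q), feature_distance(q, p))
  expect_error(feature_distance(1:3, 1:4), "mismatch")
})

test_that("bisection separates well-separated blobs and is deterministic", {
  expect_equal(lengths(bisect(rbind(c(0, 0), c(10, 0)), 1:2, seed = 1)[c("A", "B")]),
               c(A = 1L, B = 1L))
  set.seed(43)
  x <- rbind(matrix(rnorm(400), ncol = 2),
             matrix(rnorm(400, mean = 10), ncol = 2))
  sp <- bisect(x, seq_len(400), seed = 7)
  side <- sp$A
  expect_true(setequal(side, 1:200) || setequal(side, 201:400))
  sp2 <- bisect(x, seq_len(400), seed = 7)
  expect_equal(sp$A, sp2$A)
  # all-identical rows are unsplittable
  expect_null(bisect(matrix(1, 30, 4), 1:30, seed = 1))
})

test_that("cluster diameter: exact cases and brute-force agreement", {
  expect_equal(cluster_diameter(matrix(rnorm(5), 1), 1), 0)
  seg <- cbind(seq(0, 3, length.out = 40), 0)
  expect_equal(cluster_diameter(seg, 1:40), 3)
  set.seed(44)
  x <- matrix(rnorm(500 * 5), ncol = 5)
  brute <- max(dist(x))
  expect_equal(cluster_diameter(x, 1:500), brute, tolerance = 1e-12)
  # subsampled estimate is bounded by the exact value and half of it
  approx <- cluster_diameter(x, 1:500, exact_threshold = 50)
  expect_lte(approx, brute + 1e-12)
  expect_gte(approx, brute / 2)
})

test_that("the stop rule compares child diameter with sibling centroid distance", {
  expect_false(should_split(0, 1, 1))          # singleton
  expect_true(should_split(5, 2, 100))         # heterogeneous: recurse
  expect_false(should_split(1, 3, 100))        # diameter below distance: stop
  expect_false(should_split(5, 2, 5, min_size = 10))  # too small to split
})

test_that("divisive clustering recovers blob structure with a strict hierarchy", {
  same <- divisive_cluster(matrix(1, 40, 3), seed = 1)
  expect_equal(same$k, 1)
  expect_true(all(same$labels == 0))

  mx <- simulate_mixture(600, 2, d = 5, seed = 45)
  res <- divisive_cluster(mx$x, seed = 2)
  expect_equal(res$k, 2)
  expect_equal(ari(res$labels, mx$labels), 1)

  mx5 <- simulate_mixture(2000, 5, d = 11, seed = 46)
  res5 <- divisive_cluster(mx5$x, seed = 3)
  expect_equal(res5$k, 5)
  expect_gte(ari(res5$labels, mx5$labels), 0.95)

  # leaves partition the points; binary internal nodes; labels contiguous
  leaf_sizes <- vapply(res5$leaf_ids, function(i) res5$nodes[[i]]$size, 0L)
  expect_equal(sum(leaf_sizes), 2000)
  expect_equal(sort(unique(res5$labels)), 0:4)
  for (nd in res5$nodes) {
    if (!nd$leaf) {
      expect_length(nd$children, 2)
      expect_equal(sum(vapply(nd$children, function(c) res5$nodes[[c]]$size, 0L)),
                   nd$size)
    }
  }
  # every leaf satisfies a stop condition
  for (i in res5$leaf_ids) {
    nd <- res5$nodes[[i]]
    if (is.na(nd$parent)) next
    d_sib <- res5$nodes[[nd$parent]]$centroid_distance
    expect_true(nd$diameter < d_sib || nd$size < 10)
  }
})

test_that("clustering is deterministic under a fixed seed", {
  mx <- simulate_mixture(1000, 4, seed = 47)
  a <- divisive_cluster(mx$x, seed = 11)
  b <- divisive_cluster(mx$x, seed = 11)
  expect_identical(a$labels, b$labels)
  expect_equal(a$leaf_centroids, b$leaf_centroids)
})

test_that("with spatial dimensions disabled the result is rigid-motion invariant", {
  scene <- generate_scene(default_reference_scene(seed = 3,
                                                  points_per_material = 150))
  cl <- truth_enriched_cloud(scene)
  spectral <- c("R", "G", "B", "red", "green", "reg", "nir", "ndvi")
  fm1 <- standardize(cl, dims = spectral)
  moved <- apply_transform(random_rigid_transform(40, 3, seed = 8), cl)
  fm2 <- standardize(moved, dims = spectral)
  r1 <- divisive_cluster(fm1, seed = 5)
  r2 <- divisive_cluster(fm2, seed = 5)
  expect_identical(r1$labels, r2$labels)
})

test_that("six-material reference features give six leaves at high ARI", {
  scene <- generate_scene(default_reference_scene(seed = 1,
                                                  points_per_material = 500))
  cl <- truth_enriched_cloud(scene)
  res <- divisive_cluster(standardize(cl), seed = 3)
  expect_equal(res$k, 6)
  expect_gte(ari(res$labels, cl$attributes$material), 0.95)
})

test_that("labels attach to the cloud and survive a PLY round-trip", {
  mx <- simulate_mixture(300, 3, d = 11, seed = 48)
  res <- divisive_cluster(mx$x, seed = 4)
  cl <- point_cloud(mx$x[, 1:3])
  labeled <- label_cloud(res, cl, ids = seq_len(300))
  expect_setequal(unique(labeled$attributes$label), 0:2)
  f <- withr::local_tempfile(fileext = ".ply")
  write_cloud(labeled, f)
  back <- read_cloud(f)
  expect_equal(back$attributes$label, labeled$attributes$label)
  expect_error(label_cloud(res, subset_cloud(cl, 1:10), ids = 1:10), "covers")
  one <- divisive_cluster(matrix(0, 5, 2), seed = 1)
  expect_true(all(label_cloud(one, point_cloud(matrix(rnorm(15), 5)),
                              ids = 1:5)$attributes$label == 0))
})

test_that("model-object methods: print, summary, predict, report", {
  # raw features: z-scoring an isotropic mixture would drown the three
  # informative dimensions among the noise ones
  mx <- simulate_mixture(800, 3, seed = 49)
  res <- divisive_cluster(mx$x, seed = 6)
  expect_output(print(res), "material clusters")
  sm <- summary(res)
  expect_equal(nrow(sm), res$k)
  expect_true(all(c("label", "size", "diameter") %in% names(sm)))
  pred <- predict(res, mx$x)
  expect_equal(pred, res$labels)  # training points map to their own leaves
  f <- withr::local_tempfile(fileext = ".json")
  cluster_report_json(res, f)
  rep <- jsonlite::read_json(f, simplifyVector = FALSE)
  expect_equal(rep$k, res$k)
  expect_equal(length(rep$nodes), length(res$nodes))
  expect_true(!is.null(rep$nodes[[1]]$split_features))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(res))
})
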