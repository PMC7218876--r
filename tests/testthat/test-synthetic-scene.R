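test_that("a zero-sd plane material reproduces its signature exactly", {
  m <- material_spec("flat", "plane", list(center = c(0, 0, 2), radius = 1),
                     color = c(0.3, 0.6, 0.2),
                     reflectance = c(green = 0.2, red = 0.1, reg = 0.4, nir = 0.5),
                     color_sd = 0, reflectance_sd = 0)
  sc <- scene_config(list(m), points_per_material = 100, seed = 5)
  scene <- generate_scene(sc)
  expect_equal(n_points(scene$cloud), 100)
  expect_true(all(scene$cloud$normals[, 3] == 1))
  expect_equal(unique(scene$true_reflectance[, "nir"]), 0.5)
  expect_equal(unique(scene$cloud$colors[, 2]), 0.6)
  expect_true(all(abs(scene$cloud$positions[, 3] - 2) < 1e-12))
})

test_that("generation is a deterministic function of the seed", {
  a <- generate_scene(default_reference_scene(seed = 7, points_per_material = 50))
  b <- generate_scene(default_reference_scene(seed = 7, points_per_material = 50))
  expect_identical(a$cloud$positions, b$cloud$positions)
  expect_identical(a$true_reflectance, b$true_reflectance)
  c <- generate_scene(default_reference_scene(seed = 8, points_per_material = 50))
  expect_false(identical(a$cloud$positions, c$cloud$positions))
})

test_that("six-material scene has the expected label histogram", {
  scene <- generate_scene(default_reference_scene(seed = 1,
                                                  points_per_material = 120))
  h <- table(scene$cloud$attributes$material)
  expect_equal(unname(c(h)), rep(120L, 6))
  expect_equal(names(h), as.character(0:5))
})

test_that("every geometric primitive samples on its surface with valid normals", {
  specs <- list(
    material_spec("s", "sphere", list(center = c(1, 2, 3), radius = 0.7),
                  color = rep(0.5, 3),
                  reflectance = c(green = .1, red = .1, reg = .1, nir = .1)),
    material_spec("c", "cylinder", list(center = c(0, 0, 0), radius = 0.3,
                                        height = 2),
                  color = rep(0.5, 3),
                  reflectance = c(green = .1, red = .1, reg = .1, nir = .1)),
    material_spec("b", "box", list(center = c(0, 0, 0), dims = c(1, 2, 3)),
                  color = rep(0.5, 3),
                  reflectance = c(green = .1, red = .1, reg = .1, nir = .1)),
    material_spec("g", "blob", list(center = c(5, 5, 5), sd = c(.2, .2, .1)),
                  color = rep(0.5, 3),
                  reflectance = c(green = .1, red = .1, reg = .1, nir = .1)))
  scene <- generate_scene(scene_config(specs, points_per_material = 200, seed = 2))
  pos <- scene$cloud$positions
  lab <- scene$cloud$attributes$material
  expect_true(all(abs(sqrt(rowSums(scene$cloud$normals^2)) - 1) < 1e-9))
  sph <- pos[lab == 0, ]
  expect_true(all(abs(sqrt(rowSums(sweep(sph, 2, c(1, 2, 3))^2)) - 0.7) < 1e-9))
  cyl <- pos[lab == 1, ]
  expect_true(all(abs(sqrt(cyl[, 1]^2 + cyl[, 2]^2) - 0.3) < 1e-9))
  expect_true(all(cyl[, 3] >= 0 & cyl[, 3] <= 2))
  box <- pos[lab == 2, ]
  on_face <- abs(abs(box[, 1]) - 0.5) < 1e-9 | abs(abs(box[, 2]) - 1) < 1e-9 |
    abs(abs(box[, 3]) - 1.5) < 1e-9
  expect_true(all(on_face))
})

test_that("rendered raw pixels equal the closed-form radiometric inversion", {
  m <- material_spec("flat", "plane", list(center = c(0, 0, 0), radius = 1.5),
                     color = c(0.5, 0.5, 0.5),
                     reflectance = c(green = .25, red = .25, reg = .25, nir = 0.35),
                     color_sd = 0, reflectance_sd = 0)
  sc <- scene_config(list(m), points_per_material = 3000,
                     camera_ring = list(count = 1, radius = 0.01, height = 4,
                                        look_at = c(0, 0, 0)),
                     image_noise_sd = 0, seed = 6)
  scene <- generate_scene(sc)
  caps <- render_views(scene)
  raw <- caps[[1]]$raw$nir
  rad <- sc$radiometry
  # independent hand inversion: R -> phi_er -> counts
  phi_ei <- rad$nu / (rad$gain * rad$tau)
  phi_er <- 0.35 * phi_ei * cos(rad$sun_angle * pi / 180) / rad$K_true[["nir"]]
  expected <- (phi_er - rad$C) * rad$A * rad$iso * rad$exposure / rad$f_number^2 + rad$B
  expect_equal(unique(as.numeric(raw[!is.na(raw)])), expected, tolerance = 1e-9)
  # calibrate with the true K and sample anywhere on the plane
  cal <- caps[[1]]$calibrations$nir
  cal$K <- rad$K_true[["nir"]]
  img <- calibrate_image(raw, cal, caps[[1]]$reading)
  got <- sample_band(img, caps[[1]]$model, caps[[1]]$pose,
                     scene$cloud$positions[1:50, ])
  expect_equal(got[!is.na(got)], rep(0.35, sum(!is.na(got))), tolerance = 1e-6)
})

test_that("doubling tau halves the incident flux but leaves recovered R unchanged", {
  rad <- scene_config(list(material_spec("x", "plane",
                                         list(center = c(0, 0, 0), radius = 1),
                                         color = rep(.5, 3),
                                         reflectance = c(green = .2, red = .2,
                                                         reg = .2, nir = .2))),
                      seed = 1)$radiometry
  cal <- band_calibration("nir", exposure = rad$exposure, A = rad$A, B = rad$B,
                          C = rad$C, K = 1.5)
  r1 <- sunshine_reading(rad$nu, rad$gain, rad$tau, 10)
  r2 <- sunshine_reading(rad$nu, rad$gain, 2 * rad$tau, 10)
  expect_equal(incident_irradiance(r2), incident_irradiance(r1) / 2)
  p1 <- reflectance_to_pixel(0.4, cal, r1)
  p2 <- reflectance_to_pixel(0.4, cal, r2)  # re-synthesized under the new tau
  expect_equal(as.numeric(compute_reflectance(p1, cal, r1)), 0.4, tolerance = 1e-12)
  expect_equal(as.numeric(compute_reflectance(p2, cal, r2)), 0.4, tolerance = 1e-12)
})

test_that("packaged reference signatures satisfy the vegetation ordering", {
  sc <- default_reference_scene(seed = 1)
  sigs <- lapply(sc$materials, function(m) m$reflectance)
  names(sigs) <- vapply(sc$materials, function(m) m$name, "")
  nd <- vapply(sigs, function(s) (s[["nir"]] - s[["red"]]) / (s[["nir"]] + s[["red"]]), 0)
  expect_gt(nd[["leaves"]], 0.6)
  expect_lt(nd[["rocks"]], 0.2)
  expect_lt(nd[["ground"]], 0.2)
  expect_identical(default_reference_scene(seed = 4),
                   default_reference_scene(seed = 4))
})

test_that("between-material separation is at least 6 within-material sds", {
  scene <- generate_scene(default_reference_scene(seed = 2,
                                                  points_per_material = 400))
  fm <- standardize(truth_enriched_cloud(scene))
  lab <- scene$cloud$attributes$material
  cent <- t(vapply(0:5, function(g) colMeans(fm[lab == g, , drop = FALSE]),
                   numeric(ncol(fm))))
  # scalar within-material spread: rms per-dimension sd in standardized space
  spread <- vapply(0:5, function(g)
    sqrt(mean(apply(fm[lab == g, , drop = FALSE], 2, var))), 0)
  dmin <- min(dist(cent))
  expect_gte(dmin / max(spread), 6)
})

test_that("perturbation applies the transform exactly and keeps unit normals", {
  scene <- generate_scene(default_reference_scene(seed = 3,
                                                  points_per_material = 60))
  cl <- scene$cloud
  ident <- perturb_cloud(cl, rigid_transform(), noise_sd = 0)
  expect_identical(ident$positions, cl$positions)
  tf <- random_rigid_transform(25, 1, seed = 12)
  moved <- perturb_cloud(cl, tf, noise_sd = 0)
  expect_equal(moved$positions, apply_transform(tf, cl$positions))
  expect_equal(sqrt(rowSums(moved$normals^2)), rep(1, n_points(cl)),
               tolerance = 1e-9)
})

test_that("the analytic occlusion oracle handles each primitive", {
  mats <- default_reference_scene(seed = 1)$materials
  names(mats) <- vapply(mats, function(m) m$name, "")
  o <- c(0, 0, 5)
  # point below the ground disc centre is hidden; above it is not
  expect_true(oracle_occluded(mats["ground"], o, matrix(c(0, 0, -1), 1)))
  expect_false(oracle_occluded(mats["ground"], o, matrix(c(0, 0, 1), 1)))
  # point behind the leaf canopy sphere from this camera
  ctr <- mats$leaves$params$center
  beyond <- ctr + 1.2 * (ctr - o) / sqrt(sum((ctr - o)^2))
  expect_true(oracle_occluded(mats["leaves"], o, matrix(beyond, 1)))
  expect_false(oracle_occluded(mats["leaves"], o, matrix(c(5, 5, 5), 1)))
  # box blocks what lies straight behind it
  bctr <- mats$rocks$params$center
  behind_box <- bctr + 0.8 * (bctr - o) / sqrt(sum((bctr - o)^2))
  expect_true(oracle_occluded(mats["rocks"], o, matrix(behind_box, 1)))
})

test_that("mixture generator puts equidistant centres and balanced sizes", {
  mx <- simulate_mixture(1003, 5, d = 11, separation = 16, seed = 13)
  expect_equal(unname(c(table(mx$labels))), c(201L, 201L, 201L, 200L, 200L))
  cent <- t(vapply(1:5, function(g) colMeans(mx$x[mx$labels == g, ]),
                   numeric(11)))
  pw <- dist(cent)
  expect_equal(as.numeric(pw), rep(16, length(pw)), tolerance = 0.5)
  expect_identical(simulate_mixture(100, 3, seed = 2)$x,
                   simulate_mixture(100, 3, seed = 2)$x)
  expect_error(simulate_mixture(100, 13, d = 11), "simplex")
})
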