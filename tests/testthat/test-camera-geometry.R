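random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

test_that("world-to-camera transform and its inverse compose to identity", {
  pose <- camera_pose(c(1, 2, 3), diag(3))
  expect_equal(as.numeric(world_to_camera(pose, c(1, 2, 3))), c(0, 0, 0))
  pose0 <- camera_pose(c(0, 0, 0), diag(3))
  expect_equal(as.numeric(world_to_camera(pose0, c(4, 5, 6))), c(4, 5, 6))
  set.seed(10)
  for (i in 1:20) {
    pose <- camera_pose(rnorm(3), random_rotation())
    p <- rnorm(3)
    camf <- as.numeric(world_to_camera(pose, p))
    back <- as.numeric(t(pose$rotation) %*% camf + pose$center)
    expect_equal(back, p, tolerance = 1e-9)
  }
})

test_that("fisheye projection matches symbolic substitution", {
  m <- fisheye_model(0.1, -0.2, 0.3, affine = diag(c(7, 7)),
                     principal_point = c(100, 50), image_size = c(200, 100))
  expect_equal(as.numeric(fisheye_project(m, c(0, 0, 1))), c(100, 50))
  # (1, 0, 1) with zero distortion and scaled identity affine:
  # theta = (2/pi) atan(1) = 0.5 exactly
  for (s in c(1, 7, 240)) {
    m0 <- fisheye_model(0, 0, 0, affine = diag(c(s, s)),
                        principal_point = c(10, 20), image_size = c(500, 500))
    expect_equal(as.numeric(fisheye_project(m0, c(1, 0, 1))),
                 c(s * 0.5 + 10, 20), tolerance = 1e-12)
  }
  expect_true(all(is.na(fisheye_project(m, c(0.3, 0.2, -1)))))
  expect_true(all(is.na(fisheye_project(m, c(1, 1, 0)))))  # Z = 0
})

test_that("projection with distortion matches an explicit reimplementation", {
  set.seed(11)
  m <- fisheye_model(0.07, -0.04, 0.02,
                     affine = matrix(c(310, 3, -2, 305), 2, 2, byrow = TRUE),
                     principal_point = c(321.5, 243.25), image_size = c(640, 480))
  pts <- cbind(rnorm(20), rnorm(20), runif(20, 0.5, 4))
  got <- fisheye_project(m, pts)
  for (i in 1:20) {
    X <- pts[i, 1]; Y <- pts[i, 2]; Z <- pts[i, 3]
    th <- (2 / pi) * atan(sqrt(X^2 + Y^2) / Z)
    rho <- th + 0.07 * th^2 - 0.04 * th^3 + 0.02 * th^4
    xh <- rho * X / sqrt(X^2 + Y^2)
    yh <- rho * Y / sqrt(X^2 + Y^2)
    expect_equal(got[i, 1], 310 * xh + 3 * yh + 321.5, tolerance = 1e-10)
    expect_equal(got[i, 2], -2 * xh + 305 * yh + 243.25, tolerance = 1e-10)
  }
})

test_that("unproject then project is the identity to 1e-6 pixels", {
  set.seed(12)
  m <- fisheye_model(0.1, -0.08, 0.05,
                     affine = matrix(c(300, 2, -1, 298), 2, 2, byrow = TRUE),
                     principal_point = c(320, 240), image_size = c(640, 480))
  th <- runif(500, 0.01, 0.95)
  phi <- runif(500, 0, 2 * pi)
  ang <- th * pi / 2
  cam <- cbind(sin(ang) * cos(phi), sin(ang) * sin(phi), cos(ang))
  px <- fisheye_project(m, cam)
  rays <- fisheye_unproject(m, px)
  expect_false(anyNA(rays))
  px2 <- fisheye_project(m, rays)
  expect_lt(max(abs(px2 - px)), 1e-6)
})

test_that("undistorted projection is radially monotone", {
  m <- fisheye_model(0, 0, 0, affine = diag(2), principal_point = c(0, 0),
                     image_size = c(10, 10))
  xs <- seq(0.05, 5, length.out = 40)
  r <- vapply(xs, function(x) fisheye_project(m, c(x, 0, 1))[1, 1], 0)
  expect_true(all(diff(r) > 0))
})

test_that("frustum test equals the composition of its two predicates", {
  set.seed(13)
  cam <- test_camera()
  pts <- cbind(runif(1000, -6, 6), runif(1000, -6, 6), runif(1000, -6, 6))
  got <- in_frustum(cam$model, cam$pose, pts)
  px <- fisheye_project(cam$model, world_to_camera(cam$pose, pts))
  manual <- !is.na(px[, 1]) & px[, 1] >= 0 & px[, 1] < 480 &
    px[, 2] >= 0 & px[, 2] < 480
  expect_equal(got, manual)
  expect_false(in_frustum(cam$model, cam$pose, matrix(cam$pose$center, 1)))
  expect_true(in_frustum(cam$model, cam$pose, c(0, 0, 0)))
})

test_that("view angle measures normal vs point-to-camera direction", {
  pose <- camera_pose(c(0, 0, 5), diag(3))
  expect_equal(view_angle(pose, c(0, 0, 0), c(0, 0, 1)), 0)
  expect_equal(view_angle(pose, c(0, 0, 0), c(1, 0, 0)), 90)
  expect_equal(view_angle(pose, c(0, 0, 0), c(0, 0, -1)), 180)
  expect_error(view_angle(pose, c(0, 0, 5), c(0, 0, 1)), "coincides")
})

test_that("view classes use the printed angle ranges", {
  expect_equal(classify_view(10), "perpendicular")
  expect_equal(classify_view(45), "oblique")
  expect_equal(classify_view(80), "indirect")
  # boundary assignment: both breakpoints go to oblique
  expect_equal(classify_view(c(25, 60)), c("oblique", "oblique"))
  expect_equal(classify_view(24.999), "perpendicular")
  expect_equal(classify_view(60.001), "indirect")
  expect_error(classify_view(-1), "0, 180")
  expect_error(classify_view(181), "0, 180")
  # piecewise constant with exactly two breakpoints
  angs <- seq(0, 180, by = 0.25)
  cls <- classify_view(angs)
  expect_equal(sum(cls[-1] != cls[-length(cls)]), 2)
})

test_that("camera records round-trip through YAML and JSON", {
  set.seed(14)
  cams <- lapply(1:3, function(i) {
    list(pose = camera_pose(rnorm(3), random_rotation()),
         model = fisheye_model(0.01 * i, -0.02, 0.005,
                               affine = matrix(c(200, 1, -1, 199), 2, 2,
                                               byrow = TRUE),
                               principal_point = c(320, 240),
                               image_size = c(640, 480)))
  })
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_camera_file(cams, f)
    back <- read_camera_file(f)
    expect_length(back, 3)
    expect_equal(back[[2]]$pose$rotation, cams[[2]]$pose$rotation,
                 tolerance = 1e-12)
    expect_equal(back[[3]]$model$affine, cams[[3]]$model$affine)
    expect_equal(back[[1]]$model$p2, 0.01)
  }
})
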