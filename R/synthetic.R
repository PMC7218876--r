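#' Material specification for synthetic scenes
#'
#' One natural material: a geometric primitive with placement parameters,
#' a mean spectral signature (visible colour plus reflectance in the four
#' bands) and the within-material standard deviation per channel.
#'
#' @param name material name.
#' @param geometry one of `"plane"` (disc), `"sphere"`, `"cylinder"`,
#'   `"box"`, `"blob"` (Gaussian scatter).
#' @param params named list of placement parameters: `center` (3-vector)
#'   and, depending on geometry, `radius`, `height`, `dims` (box edge
#'   lengths) or `sd` (blob axis sds).
#' @param color mean RGB in `[0, 1]`.
#' @param reflectance named mean reflectances for `green`, `red`, `reg`,
#'   `nir` (>= 0).
#' @param color_sd within-material colour channel sd, absolute (>= 0).
#' @param reflectance_sd within-material reflectance sd as a fraction of the
#'   band mean (>= 0); natural surfaces scatter roughly in proportion to
#'   their brightness.
#' @return an object of class `material_spec`.
#' @export
material_spec <- function(name, geometry, params, color, reflectance,
                          color_sd = 0.01, reflectance_sd = 0.01) {
  geometry <- match.arg(geometry, c("plane", "sphere", "cylinder", "box", "blob"))
  reflectance <- unlist(reflectance)[c("green", "red", "reg", "nir")]
  if (any(is.na(reflectance)) || any(reflectance < 0)) {
    stop("reflectance must give non-negative green/red/reg/nir values")
  }
  if (color_sd < 0 || reflectance_sd < 0) stop("sds must be >= 0")
  if (is.null(params$center)) stop("params$center is required")
  structure(list(name = name, geometry = geometry, params = params,
                 color = as.numeric(color), reflectance = reflectance,
                 color_sd = color_sd, reflectance_sd = reflectance_sd),
            class = "material_spec")
}

#' Synthetic scene configuration
#'
#' Everything needed to generate a labelled cloud and physically consistent
#' multispectral captures: the materials, sampling density, the camera ring,
#' the fisheye model, and the radiometric constants (including the true
#' per-band calibration coefficients the panel stage must recover).
#'
#' @param materials list of `material_spec`s (>= 1).
#' @param points_per_material points sampled per material.
#' @param camera_ring list: `count`, `radius`, `height`, `look_at`.
#' @param fisheye list: `p2, p3, p4, affine, principal_point, image_size`.
#' @param radiometry list: `f_number, iso, exposure, A, B, C, gain, tau, nu,
#'   sun_angle, K_true` (named per band), `panel_reflectance`,
#'   `exposure_levels`.
#' @param image_noise_sd relative (multiplicative) Gaussian pixel noise sd.
#' @param seed integer; fixed seed gives identical outputs.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(materials, points_per_material = 1000,
                         camera_ring = list(count = 8, radius = 5.5,
                                            height = 4, look_at = c(0, 0, 0.4)),
                         fisheye = NULL, radiometry = NULL,
                         image_noise_sd = 0.01, seed = 1) {
  stopifnot(length(materials) >= 1,
            all(vapply(materials, inherits, TRUE, "material_spec")),
            camera_ring$count >= 1)
  fisheye <- fisheye %||% list(p2 = 0.02, p3 = -0.01, p4 = 0.005,
                               affine = matrix(c(80, 0.25, -0.25, 80), 2, 2,
                                               byrow = TRUE),
                               principal_point = c(48, 48),
                               image_size = c(96, 96))
  radiometry <- radiometry %||% list(
    f_number = 2.2, iso = 100, exposure = 0.001, A = 0.8, B = 1000, C = 0,
    gain = 1, tau = 0.01, nu = 80000, sun_angle = 20,
    K_true = c(green = 1.4, red = 1.6, reg = 1.3, nir = 1.2),
    panel_reflectance = 0.5, exposure_levels = c(0.4, 0.7, 1.0))
  structure(list(materials = materials,
                 points_per_material = as.integer(points_per_material),
                 camera_ring = camera_ring, fisheye = fisheye,
                 radiometry = radiometry, image_noise_sd = image_noise_sd,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Packaged six-material reference scene
#'
#' One material per class of the motivating scenario — leaves, wood
#' (trunk), flowers, plants (shrubs), rocks, ground — arranged as compact
#' objects around a central ground patch and observed by a ring of eight
#' fisheye cameras.  Signatures encode the ordinal spectral facts of
#' natural materials: vegetation reflects strongly in red-edge/NIR and
#' weakly in the visible; rocks and ground have flat spectra; flowers pair
#' high red-edge/NIR with a distinctive visible colour.  The leaf signature
#' has NDVI above 0.6; rock and ground NDVI sit below 0.2.
#'
#' @param seed integer seed stored in the config.
#' @param points_per_material default 1667 (about 10,000 points in total).
#' @return a `scene_config`.
#' @export
default_reference_scene <- function(seed = 1, points_per_material = 1667) {
  ring <- function(angle_deg, r = 2.2, z = 0) {
    a <- angle_deg * pi / 180
    c(r * cos(a), r * sin(a), z)
  }
  materials <- list(
    material_spec("ground", "plane",
                  list(center = c(0, 0, 0), radius = 1.0),
                  color = c(0.68, 0.58, 0.42),
                  reflectance = c(green = 0.30, red = 0.36, reg = 0.40, nir = 0.42)),
    material_spec("rocks", "box",
                  list(center = ring(0, z = 0.25), dims = c(0.8, 0.6, 0.5)),
                  color = c(0.42, 0.44, 0.50),
                  reflectance = c(green = 0.18, red = 0.20, reg = 0.21, nir = 0.23)),
    material_spec("wood", "cylinder",
                  list(center = ring(72, z = 0), radius = 0.18, height = 1.4),
                  color = c(0.45, 0.32, 0.22),
                  reflectance = c(green = 0.15, red = 0.18, reg = 0.22, nir = 0.28)),
    material_spec("leaves", "sphere",
                  list(center = ring(144, z = 1.5), radius = 0.55),
                  color = c(0.20, 0.45, 0.18),
                  reflectance = c(green = 0.12, red = 0.05, reg = 0.45, nir = 0.55)),
    material_spec("plants", "sphere",
                  list(center = ring(216, z = 0.35), radius = 0.45),
                  color = c(0.24, 0.34, 0.20),
                  reflectance = c(green = 0.08, red = 0.07, reg = 0.24, nir = 0.30)),
    material_spec("flowers", "sphere",
                  list(center = ring(288, z = 0.30), radius = 0.30),
                  color = c(0.85, 0.35, 0.55),
                  reflectance = c(green = 0.18, red = 0.30, reg = 0.50, nir = 0.52)))
  scene_config(materials, points_per_material = points_per_material, seed = seed)
}

sample_primitive <- function(spec, n) {
  p <- spec$params
  ctr <- p$center
  switch(spec$geometry,
    plane = {
      r <- p$radius * sqrt(stats::runif(n))
      a <- stats::runif(n, 0, 2 * pi)
      pos <- cbind(ctr[1] + r * cos(a), ctr[2] + r * sin(a), ctr[3])
      list(pos = pos, nrm = matrix(c(0, 0, 1), n, 3, byrow = TRUE))
    },
    sphere = {
      u <- matrix(stats::rnorm(3 * n), n, 3)
      u <- u / sqrt(rowSums(u^2))
      list(pos = sweep(u * p$radius, 2, ctr, "+"), nrm = u)
    },
    cylinder = {
      a <- stats::runif(n, 0, 2 * pi)
      z <- stats::runif(n, 0, p$height)
      nrm <- cbind(cos(a), sin(a), 0)
      pos <- cbind(ctr[1] + p$radius * cos(a), ctr[2] + p$radius * sin(a),
                   ctr[3] + z)
      list(pos = pos, nrm = nrm)
    },
    box = {
      d <- p$dims
      areas <- c(d[2] * d[3], d[2] * d[3], d[1] * d[3], d[1] * d[3],
                 d[1] * d[2], d[1] * d[2])
      face <- sample.int(6, n, replace = TRUE, prob = areas)
      u <- stats::runif(n) - 0.5
      v <- stats::runif(n) - 0.5
      pos <- matrix(0, n, 3)
      nrm <- matrix(0, n, 3)
      sgn <- ifelse(face %% 2 == 1, 1, -1)
      ax <- (face + 1) %/% 2  # 1=x, 2=y, 3=z
      for (i in seq_len(n)) {
        o <- switch(ax[i],
                    c(sgn[i] * d[1] / 2, u[i] * d[2], v[i] * d[3]),
                    c(u[i] * d[1], sgn[i] * d[2] / 2, v[i] * d[3]),
                    c(u[i] * d[1], v[i] * d[2], sgn[i] * d[3] / 2))
        pos[i, ] <- ctr + o
        nrm[i, ax[i]] <- sgn[i]
      }
      list(pos = pos, nrm = nrm)
    },
    blob = {
      off <- matrix(stats::rnorm(3 * n), n, 3)
      off <- sweep(off, 2, p$sd, "*")
      len <- sqrt(rowSums(off^2))
      len[len == 0] <- 1
      list(pos = sweep(off, 2, ctr, "+"), nrm = off / len)
    },
    stop(sprintf("invalid primitive '%s'", spec$geometry)))
}

#' Generate a labelled synthetic scene
#'
#' Samples `points_per_material` points on every material primitive with
#' analytic normals, draws per-point colour and true band reflectance from
#' the material signature (Gaussian, truncated to valid ranges), and
#' attaches the ground-truth material label.  Deterministic in the config
#' seed.
#'
#' @param config a `scene_config`.
#' @return list with `cloud` (a `point_cloud` with colors, normals and a
#'   `material` attribute, 0-based), `true_reflectance` (n x 4 matrix,
#'   bands green/red/reg/nir) and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    n <- config$points_per_material
    parts <- lapply(seq_along(config$materials), function(mi) {
      spec <- config$materials[[mi]]
      geo <- sample_primitive(spec, n)
      col <- matrix(stats::rnorm(3 * n, mean = rep(spec$color, each = n),
                                 sd = spec$color_sd), n, 3)
      col <- pmin(pmax(col, 0), 1)
      refl <- matrix(stats::rnorm(4 * n, mean = rep(spec$reflectance, each = n),
                                  sd = rep(spec$reflectance_sd * spec$reflectance,
                                           each = n)), n, 4)
      refl <- pmax(refl, 1e-4)
      colnames(refl) <- c("green", "red", "reg", "nir")
      list(pos = geo$pos, nrm = geo$nrm, col = col, refl = refl,
           label = rep(mi - 1L, n))
    })
    cloud <- point_cloud(
      do.call(rbind, lapply(parts, `[[`, "pos")),
      normals = do.call(rbind, lapply(parts, `[[`, "nrm")),
      colors = do.call(rbind, lapply(parts, `[[`, "col")),
      attributes = list(material = unlist(lapply(parts, `[[`, "label"))))
    list(cloud = cloud,
         true_reflectance = do.call(rbind, lapply(parts, `[[`, "refl")),
         config = config)
  })
}

#' Ring of fisheye cameras around a scene
#'
#' @param config a `scene_config`.
#' @return list of `list(pose, model)` pairs.
#' @export
scene_cameras <- function(config) {
  cr <- config$camera_ring
  fe <- config$fisheye
  model <- fisheye_model(fe$p2, fe$p3, fe$p4, affine = fe$affine,
                         principal_point = fe$principal_point,
                         image_size = fe$image_size)
  lapply(seq_len(cr$count), function(i) {
    a <- 2 * pi * (i - 1) / cr$count
    center <- c(cr$radius * cos(a), cr$radius * sin(a), cr$height)
    list(pose = look_at_pose(center, cr$look_at), model = model)
  })
}

scene_reading <- function(config) {
  rad <- config$radiometry
  sunshine_reading(rad$nu, rad$gain, rad$tau, rad$sun_angle)
}

scene_calibration <- function(config, band, K = NULL, exposure_scale = 1) {
  rad <- config$radiometry
  band_calibration(band, f_number = rad$f_number, iso = rad$iso,
                   exposure = rad$exposure * exposure_scale,
                   A = rad$A, B = rad$B, C = rad$C, K = K)
}

#' Exact ray-casting visibility oracle against primitive surfaces
#'
#' Tests, for every point, whether the open segment from the camera centre
#' to the point intersects any occluding material surface (disc, sphere,
#' cylinder wall or box; blobs are point scatters and do not occlude).
#' This analytic test is independent of the pipeline's surfel-disk
#' visibility and serves as its reference.
#'
#' @param materials list of `material_spec`s.
#' @param origin camera centre (3-vector).
#' @param points n x 3 matrix of world points.
#' @return logical vector: TRUE where the point is occluded.
#' @export
oracle_occluded <- function(materials, origin, points) {
  points <- as_query_matrix(points)
  n <- nrow(points)
  o <- as.numeric(origin)
  dir <- sweep(points, 2, o)
  L <- sqrt(rowSums(dir^2))
  u <- dir / L
  tmax <- L * (1 - 1e-6)
  occ <- rep(FALSE, n)
  hit_in_range <- function(t) is.finite(t) & t > 1e-9 & t < tmax
  for (spec in materials) {
    p <- spec$params
    ctr <- p$center
    occ <- occ | switch(spec$geometry,
      plane = {
        # horizontal disc
        t <- (ctr[3] - o[3]) / u[, 3]
        hx <- o[1] + t * u[, 1] - ctr[1]
        hy <- o[2] + t * u[, 2] - ctr[2]
        hit_in_range(t) & (hx^2 + hy^2 <= p$radius^2)
      },
      sphere = {
        oc <- matrix(o - ctr, n, 3, byrow = TRUE)
        b <- rowSums(u * oc)
        cc <- rowSums(oc^2) - p$radius^2
        disc <- b^2 - cc
        t1 <- -b - sqrt(pmax(disc, 0))
        t2 <- -b + sqrt(pmax(disc, 0))
        disc > 0 & (hit_in_range(t1) | hit_in_range(t2))
      },
      cylinder = {
        dx <- o[1] - ctr[1]; dy <- o[2] - ctr[2]
        a <- u[, 1]^2 + u[, 2]^2
        b <- u[, 1] * dx + u[, 2] * dy
        cc <- dx^2 + dy^2 - p$radius^2
        disc <- b^2 - a * cc
        sq <- sqrt(pmax(disc, 0))
        t1 <- (-b - sq) / a
        t2 <- (-b + sq) / a
        z1 <- o[3] + t1 * u[, 3] - ctr[3]
        z2 <- o[3] + t2 * u[, 3] - ctr[3]
        ok1 <- hit_in_range(t1) & z1 >= 0 & z1 <= p$height
        ok2 <- hit_in_range(t2) & z2 >= 0 & z2 <= p$height
        disc > 0 & a > 1e-12 & (ok1 | ok2)
      },
      box = {
        h <- p$dims / 2
        lo <- ctr - h; hi <- ctr + h
        tmin <- rep(-Inf, n); tmx <- rep(Inf, n)
        for (ax in 1:3) {
          ua <- u[, ax]
          t1 <- (lo[ax] - o[ax]) / ua
          t2 <- (hi[ax] - o[ax]) / ua
          para <- abs(ua) < 1e-12
          tl <- pmin(t1, t2); th <- pmax(t1, t2)
          inside_slab <- o[ax] >= lo[ax] && o[ax] <= hi[ax]
          tl[para] <- if (inside_slab) -Inf else Inf
          th[para] <- if (inside_slab) Inf else -Inf
          tmin <- pmax(tmin, tl); tmx <- pmin(tmx, th)
        }
        enter <- ifelse(tmin > 1e-9, tmin, tmx)
        tmin <= tmx & hit_in_range(enter)
      },
      blob = rep(FALSE, n))
  }
  occ
}

#' Render multispectral captures of a synthetic scene
#'
#' For every camera: points that survive the analytic ray-casting oracle
#' deposit their true band reflectance into their projected pixel (nearest
#' point wins per pixel); pixel reflectances are converted to raw sensor
#' counts by inverting the radiometric chain with the configured true
#' calibration coefficients, and multiplicative Gaussian noise of the
#' configured relative sd is added.  Empty pixels are `NA`.
#'
#' @param scene output of [generate_scene()].
#' @param config the `scene_config` (defaults to the scene's own).
#' @return list of captures, each `list(pose, model, raw, reading)` with
#'   `raw` a named list of count matrices per band; plus attribute
#'   `calibrations` (per-band `band_calibration` without K).
#' @export
render_views <- function(scene, config = scene$config) {
  cams <- scene_cameras(config)
  cloud <- scene$cloud
  pos <- cloud$positions
  bands <- c("green", "red", "reg", "nir")
  reading <- scene_reading(config)
  rad <- config$radiometry
  captures <- with_seed(config$seed + 104729L, lapply(cams, function(cm) {
    inside <- in_frustum(cm$model, cm$pose, pos)
    vis <- which(inside)
    if (length(vis)) {
      occ <- oracle_occluded(config$materials, cm$pose$center,
                             pos[vis, , drop = FALSE])
      vis <- vis[!occ]
    }
    if (!length(vis)) {
      warning("camera sees no points; skipped")
      return(NULL)
    }
    px <- fisheye_project(cm$model, world_to_camera(cm$pose, pos[vis, , drop = FALSE]))
    xi <- pmin(pmax(round(px[, 1]), 0), cm$model$image_size[1] - 1)
    yi <- pmin(pmax(round(px[, 2]), 0), cm$model$image_size[2] - 1)
    depth <- sqrt(rowSums(sweep(pos[vis, , drop = FALSE], 2, cm$pose$center)^2))
    pix <- yi * cm$model$image_size[1] + xi
    ord <- order(pix, depth)
    first <- !duplicated(pix[ord])        # nearest point wins per pixel
    win <- vis[ord][first]
    wx <- xi[ord][first]; wy <- yi[ord][first]
    raw <- lapply(bands, function(b) {
      cal <- scene_calibration(config, b, K = rad$K_true[[b]])
      counts <- reflectance_to_pixel(scene$true_reflectance[win, b], cal, reading)
      if (config$image_noise_sd > 0) {
        counts <- counts * (1 + stats::rnorm(length(counts), 0,
                                             config$image_noise_sd))
      }
      g <- matrix(NA_real_, cm$model$image_size[2], cm$model$image_size[1])
      g[cbind(wy + 1, wx + 1)] <- pmax(counts, 0)
      g
    })
    names(raw) <- bands
    list(pose = cm$pose, model = cm$model, raw = raw, reading = reading,
         calibrations = structure(lapply(bands, scene_calibration,
                                         config = config), names = bands))
  }))
  captures <- Filter(Negate(is.null), captures)
  if (!length(captures)) stop("no camera rendered any point")
  captures
}

#' Synthesize calibration-panel shots for a scene configuration
#'
#' Emulates the field protocol: the reflectance panel is photographed at
#' several exposure levels at the start and the end of the session; panel
#' mean pixel values are generated by the exact radiometric inversion with
#' the configured true K.
#'
#' @param config a `scene_config`.
#' @return named list (per band) of `panel_shot` lists.
#' @export
simulate_panel_shots <- function(config) {
  rad <- config$radiometry
  # panel protocol: sunshine sensor aligned with the sun (angle 0), so the
  # panel ratio is free of the angular compensation term
  reading <- sunshine_reading(rad$nu, rad$gain, rad$tau, 0)
  bands <- c("green", "red", "reg", "nir")
  structure(lapply(bands, function(b) {
    shots <- list()
    for (session in 1:2) {
      for (ex in rad$exposure_levels) {
        cal_true <- scene_calibration(config, b, K = rad$K_true[[b]],
                                      exposure_scale = ex)
        mp <- reflectance_to_pixel(rad$panel_reflectance, cal_true, reading)
        shots[[length(shots) + 1L]] <-
          panel_shot(b, rad$panel_reflectance, mp, reading,
                     scene_calibration(config, b, exposure_scale = ex))
      }
    }
    shots
  }), names = bands)
}

#' Calibrate rendered captures to reflectance images
#'
#' Each capture's raw band images are converted with the capture's own
#' radiometric metadata plus the band calibration coefficients K recovered
#' from the panel (the panel shots' exposure context does not transfer —
#' only K does).
#'
#' @param captures output of [render_views()].
#' @param K named per-band calibration coefficients, or a list of
#'   `band_calibration`s with K set (e.g. from [panel_calibration()]), from
#'   which only the K values are taken.
#' @param r_max reflectance clip bound.
#' @return the captures with an `images` element of `reflectance_image`s.
#' @export
calibrate_captures <- function(captures, K, r_max = 2) {
  if (is.list(K)) {
    K <- vapply(K, function(cal) {
      if (inherits(cal, "band_calibration")) cal$K else as.numeric(cal)
    }, 0)
  }
  lapply(captures, function(cap) {
    cap$images <- lapply(names(cap$raw), function(b) {
      cal <- cap$calibrations[[b]]
      cal$K <- unname(K[[b]])
      calibrate_image(cap$raw[[b]], cal, cap$reading, r_max = r_max)
    })
    names(cap$images) <- names(cap$raw)
    cap
  })
}

#' Rigidly perturb a cloud and add position noise
#'
#' Registration test input: applies the transform, rotates normals with it,
#' then adds isotropic Gaussian position noise.
#'
#' @param cloud a `point_cloud`.
#' @param transform a `rigid_transform`.
#' @param noise_sd isotropic position noise sd (scene units).
#' @param seed integer seed for the noise.
#' @return the perturbed `point_cloud`.
#' @export
perturb_cloud <- function(cloud, transform, noise_sd = 0, seed = 1) {
  out <- apply_transform(transform, cloud)
  if (noise_sd > 0) {
    out$positions <- out$positions +
      with_seed(seed, matrix(stats::rnorm(3 * n_points(out), 0, noise_sd),
                             ncol = 3))
  }
  out
}

#' Random rigid transform with bounded magnitude
#'
#' @param max_angle_deg rotation bound (degrees).
#' @param max_translation translation norm bound.
#' @param seed integer seed.
#' @return a `rigid_transform`.
#' @export
random_rigid_transform <- function(max_angle_deg, max_translation, seed = 1) {
  with_seed(seed, {
    axis <- stats::rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    ang <- stats::runif(1, 0, max_angle_deg) * pi / 180
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    tdir <- stats::rnorm(3)
    tdir <- tdir / sqrt(sum(tdir^2))
    rigid_transform(R, tdir * stats::runif(1, 0, max_translation))
  })
}

#' Simulate a well-separated Gaussian mixture
#'
#' Component centres sit on a regular simplex (all pairwise centre
#' distances equal `separation * sd`), so every pair of components is
#' equally separated; balanced sizes up to remainder.
#'
#' @param n total points.
#' @param k components (2 <= k <= d + 1).
#' @param d dimension (default 11, the enriched feature count).
#' @param separation pairwise centre distance in within-component sd units
#'   (default 16).
#' @param sd within-component sd (default 1).
#' @param seed integer seed.
#' @return list with `x` (n x d matrix), `labels` (1..k), `k`.
#' @export
simulate_mixture <- function(n, k, d = 11, separation = 16, sd = 1, seed = 1) {
  if (k > d + 1) stop("a regular simplex with k vertices needs d >= k - 1")
  centers <- diag(separation * sd / sqrt(2), k)
  if (d > k) centers <- cbind(centers, matrix(0, k, d - k))
  with_seed(seed, {
    sizes <- rep(n %/% k, k)
    if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
    labels <- rep(seq_len(k), sizes)
    x <- centers[labels, , drop = FALSE] + matrix(stats::rnorm(n * d, 0, sd), n, d)
    list(x = x, labels = labels, k = k)
  })
}
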