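#' Sunshine-sensor reading
#'
#' The incident-light record attached to each multispectral capture: a raw
#' sensor count, the sensor's relative gain, its exposure time, and the angle
#' between the sun-ray direction and the sensor's own direction vector.
#'
#' @param nu sensor count value (dimensionless counts, >= 0).
#' @param gain relative gain factor (> 0).
#' @param tau exposure time in seconds (> 0).
#' @param sun_angle sun/sensor angle in degrees, in `[0, 90)`.
#' @return an object of class `sunshine_reading`.
#' @export
sunshine_reading <- function(nu, gain, tau, sun_angle = 0) {
  if (gain <= 0) stop("gain must be > 0")
  if (tau <= 0) stop("tau must be > 0")
  if (sun_angle < 0 || sun_angle >= 90) stop("sun_angle must be in [0, 90) degrees")
  if (nu < 0) stop("nu must be >= 0")
  structure(list(nu = nu, gain = gain, tau = tau, sun_angle = sun_angle),
            class = "sunshine_reading")
}

#' Per-band radiometric calibration metadata
#'
#' Camera constants for one spectral band: aperture f-number, ISO, exposure
#' time, the per-camera production coefficients A, B, C, and (once the panel
#' has been processed) the band calibration coefficient K.
#'
#' @param band one of `"green"`, `"red"`, `"reg"`, `"nir"`.
#' @param f_number aperture f-number (> 0); the sensor in the motivating
#'   system uses 2.2.
#' @param iso ISO setting (> 0); typically 100.
#' @param exposure exposure time in seconds (> 0).
#' @param A,B,C per-camera calibration coefficients; `A` must be nonzero.
#' @param K optional band calibration coefficient from the panel.
#' @return an object of class `band_calibration`.
#' @export
band_calibration <- function(band, f_number = 2.2, iso = 100, exposure,
                             A, B = 0, C = 0, K = NULL) {
  band <- match.arg(band, c("green", "red", "reg", "nir"))
  if (f_number <= 0) stop("f_number must be > 0")
  if (iso <= 0) stop("iso must be > 0")
  if (exposure <= 0) stop("exposure must be > 0")
  if (A == 0) stop("A must be nonzero")
  structure(list(band = band, f_number = f_number, iso = iso,
                 exposure = exposure, A = A, B = B, C = C, K = K),
            class = "band_calibration")
}

#' Incident solar irradiance from a sunshine-sensor reading
#'
#' The incident radiant flux is the sensor count normalised by gain and
#' exposure: `nu / (gain * tau)`.
#'
#' @param reading a `sunshine_reading`.
#' @return incident irradiance (counts per gain-second), >= 0.
#' @export
incident_irradiance <- function(reading) {
  stopifnot(inherits(reading, "sunshine_reading"))
  reading$nu / (reading$gain * reading$tau)
}

#' Reflected irradiance of raw pixel values
#'
#' Converts raw pixel intensity to reflected radiant flux using the
#' per-camera production coefficients:
#' `f^2 * (pixel - B) / (A * iso * exposure) + C`.
#' Affine in the pixel value; vectorised.
#'
#' @param pixel raw pixel value(s), >= 0.
#' @param cal a `band_calibration`.
#' @return reflected irradiance, same length as `pixel`.
#' @export
reflected_irradiance <- function(pixel, cal) {
  stopifnot(inherits(cal, "band_calibration"))
  if (any(pixel < 0, na.rm = TRUE)) stop("pixel values must be >= 0")
  denom <- cal$A * cal$iso * cal$exposure
  if (denom == 0) stop("A * iso * exposure must be nonzero")
  cal$f_number^2 * (pixel - cal$B) / denom + cal$C
}

#' A calibration-panel shot
#'
#' One observation of the reflectance panel in one band: the panel's known
#' reflectance, the mean raw pixel value over the panel region, and the
#' radiometric context of the shot.
#'
#' @param band band name.
#' @param known_reflectance panel reflectance Ri, in (0, 1).
#' @param mean_pixel mean raw value over the panel region.
#' @param reading the `sunshine_reading` at capture time.
#' @param calibration the shot's `band_calibration` (K not required).
#' @return an object of class `panel_shot`.
#' @export
panel_shot <- function(band, known_reflectance, mean_pixel, reading, calibration) {
  if (known_reflectance <= 0 || known_reflectance >= 1) {
    stop("known_reflectance must lie in (0, 1)")
  }
  stopifnot(inherits(reading, "sunshine_reading"),
            inherits(calibration, "band_calibration"))
  structure(list(band = band, known_reflectance = known_reflectance,
                 mean_pixel = mean_pixel, reading = reading,
                 calibration = calibration),
            class = "panel_shot")
}

#' Band calibration coefficient from panel shots
#'
#' For every valid shot, `Ki = Ri * incident / reflected`; the returned K is
#' the arithmetic mean over valid shots.  Shots with non-positive reflected
#' irradiance or a saturated panel region (mean pixel above 98% of the
#' dynamic range) are excluded.
#'
#' @param shots list of `panel_shot`s, all of one band (one or more; the
#'   field protocol takes three exposures at the start and end of a session).
#' @param dynamic_range sensor full-scale value; default 65535 (16-bit).
#' @return the shots' `band_calibration` with `K` set; attribute `n_used`
#'   records how many shots contributed.
#' @export
panel_calibration <- function(shots, dynamic_range = 65535) {
  if (inherits(shots, "panel_shot")) shots <- list(shots)
  stopifnot(length(shots) >= 1, all(vapply(shots, inherits, TRUE, "panel_shot")))
  bands <- vapply(shots, function(s) s$band, "")
  if (length(unique(bands)) != 1L) stop("all panel shots must be of one band")
  ks <- numeric(0)
  for (s in shots) {
    if (s$mean_pixel > 0.98 * dynamic_range) next  # saturated
    phi_ei <- incident_irradiance(s$reading)
    phi_er <- reflected_irradiance(s$mean_pixel, s$calibration)
    if (phi_er <= 0 || phi_ei <= 0) next
    ks <- c(ks, s$known_reflectance * phi_ei / phi_er)
  }
  if (!length(ks)) stop("panel calibration failed: no valid (unsaturated) shots")
  cal <- shots[[1]]$calibration
  cal$K <- mean(ks)
  attr(cal, "n_used") <- length(ks)
  cal
}

#' Calibrated surface reflectance of raw pixel values
#'
#' `R = K * reflected / (incident * cos(sun_angle))`, clipped to
#' `[0, r_max]`.  Specular or mis-modelled pixels can exceed physical
#' reflectance; they are clipped, not rejected, and the clip count is
#' reported via the `n_clipped` attribute.
#'
#' @param pixel raw pixel value(s); vectorised.
#' @param cal a `band_calibration` with `K` set.
#' @param reading the capture's `sunshine_reading`.
#' @param r_max upper clip bound (default 2).
#' @return reflectance value(s) in `[0, r_max]`, with attribute `n_clipped`.
#' @export
compute_reflectance <- function(pixel, cal, reading, r_max = 2) {
  stopifnot(inherits(cal, "band_calibration"), inherits(reading, "sunshine_reading"))
  if (is.null(cal$K)) stop("calibration carries no K; run panel_calibration first")
  phi_ei <- incident_irradiance(reading)
  ct <- cos(reading$sun_angle * pi / 180)
  if (phi_ei * ct <= 0) stop("non-positive incident irradiance")
  r <- cal$K * reflected_irradiance(pixel, cal) / (phi_ei * ct)
  n_clipped <- sum(r < 0 | r > r_max, na.rm = TRUE)
  r <- pmin(pmax(r, 0), r_max)
  attr(r, "n_clipped") <- n_clipped
  r
}

#' Invert the radiometric chain: reflectance to raw pixel value
#'
#' The exact inverse of [compute_reflectance()]: given a true surface
#' reflectance and the capture radiometry, returns the raw pixel count that
#' would produce it.  Used by the synthetic renderer and by round-trip
#' checks of the calibration chain.
#'
#' @param R true reflectance value(s).
#' @param cal a `band_calibration` with `K` set.
#' @param reading the capture's `sunshine_reading`.
#' @return raw pixel value(s).
#' @export
reflectance_to_pixel <- function(R, cal, reading) {
  stopifnot(inherits(cal, "band_calibration"), inherits(reading, "sunshine_reading"))
  if (is.null(cal$K)) stop("calibration carries no K")
  phi_ei <- incident_irradiance(reading)
  ct <- cos(reading$sun_angle * pi / 180)
  phi_er <- R * phi_ei * ct / cal$K
  (phi_er - cal$C) * cal$A * cal$iso * cal$exposure / cal$f_number^2 + cal$B
}

#' Normalized Difference Vegetation Index
#'
#' `(nir - red) / (nir + red)`, the standard vegetation vigour index; defined
#' as 0 when both reflectances are 0 so that non-finite values never reach
#' the clustering stage.  Vectorised.
#'
#' @param nir near-infrared reflectance (>= 0).
#' @param red red reflectance (>= 0).
#' @return NDVI in `[-1, 1]`.
#' @export
ndvi <- function(nir, red) {
  if (any(nir < 0, na.rm = TRUE) || any(red < 0, na.rm = TRUE)) {
    stop("reflectances must be >= 0")
  }
  s <- nir + red
  out <- ifelse(s == 0, 0, (nir - red) / s)
  out[is.na(nir) | is.na(red)] <- NA_real_
  out
}

#' Read a radiometric sidecar file
#'
#' Per-image radiometric metadata as a YAML (or JSON) sidecar with the
#' fields `nu`, `gain`, `tau`, `sun_angle`, `f_number`, `iso`, `exposure`,
#' `A`, `B`, `C`, optionally `K` and `band`.
#'
#' @param path sidecar path.
#' @return list with components `reading` (`sunshine_reading`) and
#'   `calibration` (`band_calibration`).
#' @export
read_radiometric_sidecar <- function(path) {
  meta <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("nu", "gain", "tau", "sun_angle", "f_number", "iso", "exposure",
            "A", "B", "C")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop(sprintf("sidecar '%s' lacks fields: %s", path, paste(miss, collapse = ", ")))
  }
  list(reading = sunshine_reading(meta$nu, meta$gain, meta$tau, meta$sun_angle),
       calibration = band_calibration(meta$band %||% "green",
                                      f_number = meta$f_number, iso = meta$iso,
                                      exposure = meta$exposure, A = meta$A,
                                      B = meta$B, C = meta$C, K = meta$K))
}

#' Write a radiometric sidecar file
#' @param reading a `sunshine_reading`.
#' @param calibration a `band_calibration`.
#' @param path output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_radiometric_sidecar <- function(reading, calibration, path) {
  meta <- list(band = calibration$band, nu = reading$nu, gain = reading$gain,
               tau = reading$tau, sun_angle = reading$sun_angle,
               f_number = calibration$f_number, iso = calibration$iso,
               exposure = calibration$exposure, A = calibration$A,
               B = calibration$B, C = calibration$C)
  if (!is.null(calibration$K)) meta$K <- calibration$K
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(meta, path, precision = 15)
  }
  invisible(path)
}

#' Single-band reflectance image
#'
#' A 2-D grid of calibrated reflectance values for one spectral band.
#' The grid is stored as a matrix indexed `[row = y + 1, col = x + 1]` with
#' 0-based pixel centres at integer coordinates; `NA` marks pixels with no
#' observation.
#'
#' @param band band name.
#' @param grid numeric matrix of reflectance values (NA allowed).
#' @return an object of class `reflectance_image` with `width`/`height`.
#' @export
reflectance_image <- function(band, grid) {
  grid <- as.matrix(grid)
  if (any(grid < 0, na.rm = TRUE)) stop("reflectance values must be >= 0")
  structure(list(band = band, grid = grid,
                 width = ncol(grid), height = nrow(grid)),
            class = "reflectance_image")
}

#' Calibrate a raw single-band image to reflectance
#'
#' Applies [compute_reflectance()] to every pixel of a raw count matrix.
#'
#' @param raw numeric matrix of raw counts (NA = missing pixel).
#' @param cal `band_calibration` with K.
#' @param reading capture `sunshine_reading`.
#' @param r_max clip bound passed through.
#' @return a `reflectance_image`.
#' @export
calibrate_image <- function(raw, cal, reading, r_max = 2) {
  vals <- compute_reflectance(as.vector(raw), cal, reading, r_max = r_max)
  g <- matrix(as.numeric(vals), nrow(raw), ncol(raw))
  img <- reflectance_image(cal$band, g)
  attr(img, "n_clipped") <- attr(vals, "n_clipped")
  img
}
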