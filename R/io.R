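#' Read a point cloud from file
#'
#' Supported formats: PLY (ASCII and binary little-endian, scalar vertex
#' properties only) and whitespace-delimited XYZ (`x y z [nx ny nz] [r g b]`).
#' Positions, normals, colours and any extra scalar vertex properties are
#' loaded losslessly and point order is preserved.  8-bit colour channels are
#' rescaled to `[0, 1]`.
#'
#' LAS is not supported by this build; request it with `format = "las"` and
#' you get an informative error.
#'
#' @param path file path.
#' @param format one of `"ply"`, `"xyz"`, `"las"`; inferred from the file
#'   extension when omitted.
#' @return a `point_cloud`.
#' @export
read_cloud <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("ply", "xyz", "las"))
  switch(format,
         ply = read_ply(path),
         xyz = read_xyz(path),
         las = stop("LAS I/O is not supported by this build; convert to PLY or XYZ"))
}

#' Write a point cloud to file
#'
#' The PLY writer emits positions as doubles, normals (if present) as
#' doubles, colours (if present) as 8-bit `red`/`green`/`blue`, and every
#' scalar attribute as a named double property (missing values as NaN).
#' The XYZ writer carries positions, normals and colours only.
#'
#' @param cloud a non-empty `point_cloud`.
#' @param path output path.
#' @param format `"ply"`, `"xyz"` or `"las"` (the latter unsupported);
#'   inferred from the extension when omitted.
#' @param binary write binary little-endian PLY instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = NULL, binary = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("ply", "xyz", "las"))
  switch(format,
         ply = write_ply(cloud, path, binary = binary),
         xyz = write_xyz(cloud, path),
         las = stop("LAS I/O is not supported by this build; use PLY or XYZ"))
  invisible(path)
}

## ---- PLY ----------------------------------------------------------------

ply_types <- list(
  char = c(1L, "integer"), int8 = c(1L, "integer"),
  uchar = c(1L, "integer"), uint8 = c(1L, "integer"),
  short = c(2L, "integer"), int16 = c(2L, "integer"),
  ushort = c(2L, "integer"), uint16 = c(2L, "integer"),
  int = c(4L, "integer"), int32 = c(4L, "integer"),
  uint = c(4L, "integer"), uint32 = c(4L, "integer"),
  float = c(4L, "double"), float32 = c(4L, "double"),
  double = c(8L, "double"), float64 = c(8L, "double"))

ply_unsigned <- c("uchar", "uint8", "ushort", "uint16", "uint", "uint32")

write_ply <- function(cloud, path, binary = FALSE) {
  n <- n_points(cloud)
  cols <- list(x = cloud$positions[, 1], y = cloud$positions[, 2],
               z = cloud$positions[, 3])
  types <- c(x = "double", y = "double", z = "double")
  if (!is.null(cloud$normals)) {
    cols$nx <- cloud$normals[, 1]; cols$ny <- cloud$normals[, 2]
    cols$nz <- cloud$normals[, 3]
    types[c("nx", "ny", "nz")] <- "double"
  }
  if (!is.null(cloud$colors)) {
    rgb8 <- round(pmin(pmax(cloud$colors, 0), 1) * 255)
    cols$red <- rgb8[, 1]; cols$green <- rgb8[, 2]; cols$blue <- rgb8[, 3]
    types[c("red", "green", "blue")] <- "uchar"
  }
  for (nm in attribute_schema(cloud)) {
    v <- cloud$attributes[[nm]]
    v[is.na(v)] <- NaN
    cols[[nm]] <- v
    types[nm] <- "double"
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           "comment cloudspectra point cloud",
           sprintf("element vertex %d", n),
           sprintf("property %s %s", types, names(cols)),
           "end_header")
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    for (i in seq_len(n)) {
      for (j in seq_along(cols)) {
        ty <- types[j]
        if (ty == "uchar") {
          writeBin(as.raw(cols[[j]][i]), con)
        } else {
          writeBin(as.numeric(cols[[j]][i]), con, size = 8, endian = "little")
        }
      }
    }
  } else {
    fmt_one <- function(v, ty) {
      if (ty == "uchar") formatC(v, format = "d") else formatC(v, format = "g", digits = 17)
    }
    mat <- vapply(seq_along(cols),
                  function(j) fmt_one(cols[[j]], types[j]), character(n))
    if (n == 1L) mat <- matrix(mat, nrow = 1)
    writeLines(apply(mat, 1, paste, collapse = " "), con, sep = "\n")
  }
  invisible(path)
}

parse_ply_header <- function(con) {
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) stop("malformed PLY: missing 'ply' magic (line 1)")
  fmt <- NULL; elements <- list(); cur <- NULL
  lineno <- 1L
  repeat {
    ln <- readLines(con, n = 1)
    lineno <- lineno + 1L
    if (!length(ln)) stop("malformed PLY: end_header not found")
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok) || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]),
                              props = character(0), types = character(0))
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop(sprintf("malformed PLY: property before element (line %d)", lineno))
      if (tok[2] == "list") {
        elements[[cur]]$list <- TRUE
        elements[[cur]]$props <- c(elements[[cur]]$props, tok[5])
        elements[[cur]]$types <- c(elements[[cur]]$types, "list")
      } else {
        if (is.null(ply_types[[tok[2]]])) {
          stop(sprintf("malformed PLY: unknown property type '%s' (line %d)", tok[2], lineno))
        }
        elements[[cur]]$props <- c(elements[[cur]]$props, tok[3])
        elements[[cur]]$types <- c(elements[[cur]]$types, tok[2])
      }
    } else if (tok[1] == "end_header") {
      break
    } else {
      stop(sprintf("malformed PLY header keyword '%s' (line %d)", tok[1], lineno))
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian")) {
    stop(sprintf("unsupported PLY format '%s'", fmt %||% "<missing>"))
  }
  list(format = fmt, elements = elements, header_lines = lineno)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- parse_ply_header(con)
  if (is.null(hdr$elements$vertex)) stop("malformed PLY: no vertex element")
  vert <- hdr$elements$vertex
  if (isTRUE(vert$list)) stop("PLY list properties on vertices are not supported")
  n <- vert$count
  p <- length(vert$props)
  if (hdr$format == "ascii") {
    vals <- scan(con, what = double(), n = n * p, quiet = TRUE)
    if (length(vals) != n * p) {
      stop(sprintf("malformed PLY: expected %d vertex values, got %d", n * p, length(vals)))
    }
    data <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  } else {
    sizes <- vapply(vert$types, function(t) as.integer(ply_types[[t]][1]), 1L)
    rs <- sum(sizes)
    raw <- readBin(con, "raw", n = n * rs)
    if (length(raw) != n * rs) {
      stop(sprintf("malformed PLY: expected %d data bytes, got %d", n * rs, length(raw)))
    }
    offs <- cumsum(c(0L, sizes[-p]))
    data <- matrix(0, n, p)
    base <- (seq_len(n) - 1L) * rs
    for (j in seq_len(p)) {
      idx <- as.vector(outer(seq_len(sizes[j]) + offs[j], base, "+"))
      what <- ply_types[[vert$types[j]]][2]
      data[, j] <- readBin(raw[idx], what, n = n, size = sizes[j],
                           endian = "little",
                           signed = !(vert$types[j] %in% ply_unsigned) ||
                             sizes[j] > 2L)
    }
  }
  colnames(data) <- vert$props
  need <- c("x", "y", "z")
  if (!all(need %in% vert$props)) stop("malformed PLY: vertex element lacks x/y/z")
  positions <- data[, need, drop = FALSE]
  normals <- NULL
  if (all(c("nx", "ny", "nz") %in% vert$props)) {
    normals <- data[, c("nx", "ny", "nz"), drop = FALSE]
    len <- sqrt(rowSums(normals^2))
    ok <- len > 0
    normals[ok, ] <- normals[ok, , drop = FALSE] / len[ok]
  }
  colors <- NULL
  if (all(c("red", "green", "blue") %in% vert$props)) {
    colors <- data[, c("red", "green", "blue"), drop = FALSE]
    ctypes <- vert$types[match(c("red", "green", "blue"), vert$props)]
    if (any(ctypes %in% c("uchar", "uint8", "ushort", "uint16"))) colors <- colors / 255
    colors <- pmin(pmax(colors, 0), 1)
  }
  taken <- c(need, "nx", "ny", "nz", "red", "green", "blue")
  extra <- setdiff(vert$props, taken)
  attributes <- list()
  for (nm in extra) {
    v <- data[, nm]
    v[is.nan(v)] <- NA_real_
    attributes[[nm]] <- v
  }
  point_cloud(positions, normals = normals, colors = colors,
              attributes = attributes)
}

## ---- XYZ ----------------------------------------------------------------

read_xyz <- function(path) {
  data <- tryCatch(as.matrix(utils::read.table(path)),
                   error = function(e) stop(sprintf("malformed XYZ file '%s': %s",
                                                    path, conditionMessage(e))))
  storage.mode(data) <- "double"
  nc <- ncol(data)
  if (!nc %in% c(3L, 6L, 9L)) {
    stop(sprintf("XYZ file must have 3, 6 or 9 columns, found %d", nc))
  }
  normals <- if (nc >= 6L) {
    nr <- data[, 4:6, drop = FALSE]
    len <- sqrt(rowSums(nr^2)); ok <- len > 0
    nr[ok, ] <- nr[ok, , drop = FALSE] / len[ok]
    nr
  }
  colors <- if (nc == 9L) {
    cl <- data[, 7:9, drop = FALSE]
    if (any(cl > 1)) cl <- cl / 255
    pmin(pmax(cl, 0), 1)
  }
  point_cloud(data[, 1:3, drop = FALSE], normals = normals, colors = colors)
}

write_xyz <- function(cloud, path) {
  if (length(attribute_schema(cloud))) {
    warning("XYZ format carries no extra attributes; they are dropped")
  }
  m <- cloud$positions
  if (!is.null(cloud$normals)) m <- cbind(m, cloud$normals)
  if (!is.null(cloud$colors)) {
    if (is.null(cloud$normals)) stop("XYZ with colors requires normals (x y z nx ny nz r g b)")
    m <- cbind(m, cloud$colors)
  }
  utils::write.table(formatC(m, format = "g", digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
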