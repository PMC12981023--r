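# Readers and writers for the package's artifact formats. File headers and
# sidecars always carry physical units (um); readers refuse to guess missing
# metadata.

#' Write a height field to TIFF or CSV
#'
#' TIFF output is a single-channel 32-bit float image holding normalized
#' elevations; the physical scale (`z_min`, `z_max`), grid spacing and origin
#' live in a JSON sidecar `<path>.json` written alongside. CSV output is a
#' plain elevation grid (one row per y line, um) with the same sidecar.
#'
#' @param surface A [height_field()].
#' @param path Output path ending in `.tif`, `.tiff` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_height_field <- function(surface, path) {
  stopifnot(inherits(surface, "height_field"))
  z <- surface$z
  zr <- range(z)
  meta <- list(format = "curvmech-height-field", units = "um",
               dx = surface$dx, dy = surface$dy, origin = surface$origin,
               z_min = zr[1], z_max = zr[2],
               nrow = nrow(z), ncol = ncol(z),
               name = surface$name %||% NA)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    zn <- if (diff(zr) > 0) (z - zr[1]) / diff(zr) else z * 0
    tiff::writeTIFF(zn, path, bits.per.sample = 32L)
  } else if (ext == "csv") {
    utils::write.table(z, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    stop("write_height_field: unsupported extension '", ext, "'")
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a height field written by [write_height_field()]
#'
#' @param path Path to the `.tif`/`.tiff`/`.csv` file; the JSON sidecar
#'   `<path>.json` must exist (the reader never silently assumes a 1-um
#'   grid).
#' @return A [height_field()].
#' @export
read_height_field <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("grid spacing unknown: missing metadata sidecar '", sidecar, "'")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("dx", "dy", "z_min", "z_max"))
    if (is.null(meta[[f]]))
      stop("grid spacing unknown: sidecar lacks field '", f, "'")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    zn <- tiff::readTIFF(path)
    z <- zn * (meta$z_max - meta$z_min) + meta$z_min
  } else if (ext == "csv") {
    z <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    dimnames(z) <- NULL
  } else {
    stop("read_height_field: unsupported extension '", ext, "'")
  }
  nm <- meta$name
  height_field(z, dx = meta$dx, dy = meta$dy,
               origin = if (!is.null(meta$origin)) as.numeric(meta$origin)
                        else c(0, 0),
               name = if (is.null(nm) || is.na(nm)) NULL else nm)
}

#' Write a triangle mesh as Wavefront OBJ
#'
#' Vertex coordinates in um; faces 1-based. A comment header records units.
#'
#' @param mesh A [tri_mesh()].
#' @param path Output `.obj` path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# curvmech mesh, units um",
               sprintf("# vertices %d faces %d", nrow(mesh$vertices),
                       nrow(mesh$faces))), con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ mesh
#'
#' Supports `v` and `f` records (triangular faces, plain or `a/b/c` index
#' syntax). Malformed records raise an error naming the line.
#'
#' @param path Path to the `.obj` file.
#' @param closed Passed to [tri_mesh()] validation.
#' @return A [tri_mesh()].
#' @export
read_obj <- function(path, closed = FALSE) {
  lines <- readLines(path)
  vs <- list(); fs <- list()
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "" || startsWith(s, "#")) next
    tok <- strsplit(s, "\\s+")[[1]]
    if (tok[1] == "v") {
      if (length(tok) < 4)
        stop("read_obj: malformed vertex at line ", ln)
      v <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(v))) stop("read_obj: malformed vertex at line ", ln)
      vs[[length(vs) + 1L]] <- v
    } else if (tok[1] == "f") {
      if (length(tok) != 4)
        stop("read_obj: only triangular faces supported (line ", ln, ")")
      idx <- suppressWarnings(
        as.integer(vapply(strsplit(tok[2:4], "/"), `[`, character(1), 1)))
      if (any(is.na(idx))) stop("read_obj: malformed face at line ", ln)
      fs[[length(fs) + 1L]] <- idx
    }
  }
  if (!length(vs) || !length(fs))
    stop("read_obj: no vertices or faces found in '", path, "'")
  tri_mesh(do.call(rbind, vs), do.call(rbind, fs), closed = closed)
}

#' Write a curvature field as CSV
#'
#' Columns: x, y, z (um), k1, k2, H (1/um), KG (1/um^2), dir1_deg, area
#' (um^2), valid.
#'
#' @param field A [curvature_field()].
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_curvature_csv <- function(field, path) {
  utils::write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}

#' Write an orientation landscape as CSV
#'
#' Columns: theta_deg plus the per-layer energy components (pN um), as in
#' [as.data.frame.orientation_landscape()].
#'
#' @param landscape An [orientation_landscape()].
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_landscape_csv <- function(landscape, path) {
  utils::write.csv(as.data.frame(landscape), path, row.names = FALSE)
  invisible(path)
}

#' Write fiber segments as CSV
#'
#' @param segments Segment data frame (layer, theta_deg, length_um,
#'   width_um, cx_um, cy_um).
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(segments, path) {
  utils::write.csv(segments, path, row.names = FALSE)
  invisible(path)
}

#' Read a fiber segment CSV
#'
#' @param path Path written by [write_segments_csv()].
#' @return Data frame.
#' @export
read_segments_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a rendered cell image as 16-bit grayscale TIFF
#'
#' @param image Numeric matrix in [0, 1].
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(is.matrix(image))
  tiff::writeTIFF(pmin(pmax(image, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale TIFF image as a matrix
#'
#' @param path Path to the image.
#' @return Numeric matrix in [0, 1] (first channel if multi-channel).
#' @export
read_image_tiff <- function(path) {
  im <- tiff::readTIFF(path)
  if (length(dim(im)) == 3L) im <- im[, , 1]
  im
}
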