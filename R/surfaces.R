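# Surface containers: gridded height fields and triangle meshes.
# Units are fixed package-wide: micrometres (um) for length, pN for force,
# pN*um for energy.

#' Construct a height-field surface
#'
#' A `height_field` stores substrate elevation `z(x, y)` on a regular grid,
#' the representation used for wrinkled and grooved hydrogel topographies.
#' Rows of `z` run along y, columns along x, so `z[i, j]` is the elevation at
#' `(x = origin[1] + (j-1)*dx, y = origin[2] + (i-1)*dy)`.
#'
#' @param z Numeric matrix of elevations (um), at least 3 x 3, all finite.
#' @param dx,dy Grid spacing (um), strictly positive.
#' @param origin Length-2 numeric, physical coordinates of `z[1, 1]` (um).
#' @param name Optional tag (e.g. a preset name).
#' @return An object of class `height_field` with fields `z`, `dx`, `dy`,
#'   `origin`, `name`.
#' @examples
#' hf <- height_field(matrix(0, 8, 8), dx = 1, dy = 1)
#' dim(hf$z)
#' @export
height_field <- function(z, dx, dy = dx, origin = c(0, 0), name = NULL) {
  z <- as.matrix(z)
  if (!is.numeric(z) || nrow(z) < 3L || ncol(z) < 3L)
    stop("height_field: elevation grid must be a numeric matrix of at least 3 x 3 nodes")
  if (any(!is.finite(z)))
    stop("height_field: elevations must all be finite")
  if (!is.numeric(dx) || length(dx) != 1L || dx <= 0 ||
      !is.numeric(dy) || length(dy) != 1L || dy <= 0)
    stop("height_field: dx and dy must be positive scalars")
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("height_field: origin must be two finite numbers")
  structure(list(z = z, dx = as.numeric(dx), dy = as.numeric(dy),
                 origin = as.numeric(origin), name = name),
            class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  cat(sprintf("height_field%s: %d x %d nodes, dx = %g um, dy = %g um\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$z), ncol(x$z), x$dx, x$dy))
  cat(sprintf("  extent: %g x %g um, elevation range [%.3g, %.3g] um\n",
              (ncol(x$z) - 1L) * x$dx, (nrow(x$z) - 1L) * x$dy,
              min(x$z), max(x$z)))
  invisible(x)
}

#' Physical x/y axes of a height field
#'
#' @param surface A `height_field`.
#' @return List with vectors `x` (length ncol) and `y` (length nrow) in um.
#' @export
height_field_axes <- function(surface) {
  stopifnot(inherits(surface, "height_field"))
  list(x = surface$origin[1] + (seq_len(ncol(surface$z)) - 1L) * surface$dx,
       y = surface$origin[2] + (seq_len(nrow(surface$z)) - 1L) * surface$dy)
}

#' Interpolate elevation at arbitrary points
#'
#' Bicubic Catmull-Rom interpolation (the default) reproduces quadratic
#' patches exactly and is used for normal-section extraction; bilinear is
#' kept for speed where only values are needed.
#'
#' @param surface A `height_field`.
#' @param x,y Physical coordinates (um), vectors of equal length.
#' @param method `"bicubic"` (default) or `"bilinear"`.
#' @return Elevations (um). Errors if any point lies outside the grid extent.
#' @export
height_field_interp <- function(surface, x, y,
                                method = c("bicubic", "bilinear")) {
  method <- match.arg(method)
  ax <- height_field_axes(surface)
  eps <- 1e-9 * max(surface$dx, surface$dy)
  if (any(x < min(ax$x) - eps | x > max(ax$x) + eps |
          y < min(ax$y) - eps | y > max(ax$y) + eps))
    stop("section out of bounds")
  fx <- (x - ax$x[1]) / surface$dx
  fy <- (y - ax$y[1]) / surface$dy
  z <- surface$z
  n <- nrow(z)
  if (method == "bilinear") {
    j0 <- pmin(pmax(floor(fx), 0), ncol(z) - 2L)
    i0 <- pmin(pmax(floor(fy), 0), nrow(z) - 2L)
    tx <- fx - j0
    ty <- fy - i0
    idx <- function(i, j) i + 1L + j * n  # column-major linear index
    return(z[idx(i0, j0)] * (1 - tx) * (1 - ty) +
             z[idx(i0, j0 + 1L)] * tx * (1 - ty) +
             z[idx(i0 + 1L, j0)] * (1 - tx) * ty +
             z[idx(i0 + 1L, j0 + 1L)] * tx * ty)
  }
  # Catmull-Rom cubic convolution, border nodes replicated
  j0 <- pmin(pmax(floor(fx), 0), ncol(z) - 2L)
  i0 <- pmin(pmax(floor(fy), 0), nrow(z) - 2L)
  tx <- fx - j0
  ty <- fy - i0
  wts <- function(t)
    list(w_1 = (-t^3 + 2 * t^2 - t) / 2,
         w0 = (3 * t^3 - 5 * t^2 + 2) / 2,
         w1 = (-3 * t^3 + 4 * t^2 + t) / 2,
         w2 = (t^3 - t^2) / 2)
  wx <- wts(tx); wy <- wts(ty)
  cl <- function(v, lim) pmin(pmax(v, 0L), lim)
  out <- numeric(length(x))
  for (a in -1:2) {
    ja <- cl(j0 + a, ncol(z) - 1L)
    wxa <- wx[[a + 2L]]
    for (b in -1:2) {
      ib <- cl(i0 + b, nrow(z) - 1L)
      out <- out + wxa * wy[[b + 2L]] * z[ib + 1L + ja * n]
    }
  }
  out
}

#' Construct a triangle-mesh surface
#'
#' Triangulated surfaces represent 3D microgels. Vertex coordinates are in um;
#' faces are 1-based vertex index triples wound counter-clockwise when viewed
#' from outside (outward orientation).
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (um).
#' @param faces m x 3 integer matrix of vertex indices.
#' @param normals Optional n x 3 matrix of per-vertex unit normals.
#' @param closed Logical; `TRUE` for closed microgel surfaces (validated via
#'   the Euler characteristic).
#' @param name Optional tag.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, normals = NULL, closed = FALSE,
                     name = NULL) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L || any(!is.finite(vertices)))
    stop("tri_mesh: vertices must be a finite n x 3 matrix")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("tri_mesh: face indices out of range")
  a <- mesh_face_areas(vertices, faces)
  if (any(a <= .Machine$double.eps * max(a)))
    stop("tri_mesh: degenerate (zero-area) triangle present")
  if (closed) {
    n_edges <- nrow(unique_mesh_edges(faces))
    chi <- nrow(vertices) - n_edges + nrow(faces)
    if (chi != 2L)
      stop("tri_mesh: surface flagged closed but Euler characteristic != 2")
  }
  structure(list(vertices = vertices, faces = faces, normals = normals,
                 closed = closed, name = name),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh%s: %d vertices, %d faces%s\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$vertices), nrow(x$faces),
              if (isTRUE(x$closed)) " (closed)" else ""))
  invisible(x)
}

mesh_face_areas <- function(vertices, faces) {
  e1 <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  e2 <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

unique_mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Area-weighted per-vertex normals of a mesh
#'
#' @param mesh A `tri_mesh`.
#' @return n x 3 matrix of unit normals (outward for outward-wound meshes).
#' @export
mesh_vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # 2*area-weighted
  vn <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    vn[, 1] <- vn[, 1] + tabulate2(f[, k], fn[, 1], nrow(v))
    vn[, 2] <- vn[, 2] + tabulate2(f[, k], fn[, 2], nrow(v))
    vn[, 3] <- vn[, 3] + tabulate2(f[, k], fn[, 3], nrow(v))
  }
  vn / pmax(sqrt(rowSums(vn^2)), .Machine$double.eps)
}

# sum `w` into bins `idx` (1..n); rowsum-based accumulator
tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
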