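# Curvature fields from the first/second fundamental forms.
#
# Sign convention (fixed package-wide): curvature is positive where the
# surface is convex toward the cell side -- above the gel for height fields,
# outward for closed microgel meshes. Ridge tops and sphere exteriors are
# positive, trough bottoms negative.

#' Construct a curvature field
#'
#' Per-node principal curvatures with derived mean and Gaussian curvature.
#' Usually produced by [height_field_curvature()] or [mesh_curvature()].
#'
#' @param k1,k2 Principal curvatures (1/um), with `k1 <= k2` nodewise.
#' @param dir1 Angle (rad) of the `k1` principal direction in the tangent
#'   plane, measured from the +x axis.
#' @param area Area weight per node (um^2).
#' @param valid Logical; nodes with trustworthy estimates.
#' @param x,y,z Optional node coordinates (um).
#' @return Object of class `curvature_field`: a list of per-node vectors
#'   `k1`, `k2`, `H`, `KG`, `dir1`, `area`, `valid` (+ coordinates).
#' @export
curvature_field <- function(k1, k2, dir1, area, valid = NULL,
                            x = NULL, y = NULL, z = NULL) {
  n <- length(k1)
  stopifnot(length(k2) == n, length(dir1) == n, length(area) == n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  swap <- which(valid & k1 > k2)
  if (length(swap)) {
    tmp <- k1[swap]; k1[swap] <- k2[swap]; k2[swap] <- tmp
    dir1[swap] <- dir1[swap] + pi / 2
  }
  dir1 <- dir1 %% pi
  structure(list(k1 = k1, k2 = k2, H = (k1 + k2) / 2, KG = k1 * k2,
                 dir1 = dir1, area = area, valid = valid,
                 x = x, y = y, z = z),
            class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  ok <- x$valid
  cat(sprintf("curvature_field: %d nodes (%d valid)\n", length(x$k1), sum(ok)))
  if (any(ok))
    cat(sprintf("  H range [%.4g, %.4g] 1/um; area-weighted mean |H| = %.4g 1/um\n",
                min(x$H[ok]), max(x$H[ok]),
                sum(abs(x$H[ok]) * x$area[ok]) / sum(x$area[ok])))
  invisible(x)
}

#' Principal curvatures of a height field
#'
#' Computes per-node principal curvatures of `z(x, y)` from the first and
#' second fundamental forms, using second-order central differences. The
#' boundary ring, where no full central stencil exists, is flagged invalid and
#' excluded from downstream statistics rather than estimated one-sided.
#'
#' @param surface A [height_field()].
#' @return A [curvature_field()] with one node per grid node (column-major
#'   order over the grid); `area` is the local surface area element
#'   `dx*dy*sqrt(1 + |grad z|^2)`.
#' @examples
#' ax <- seq(-40, 40, by = 1)
#' cap <- height_field(outer(ax, ax, function(y, x) sqrt(50^2 - x^2 - y^2)),
#'                     dx = 1)
#' cf <- height_field_curvature(cap)
#' mean(cf$H[cf$valid])  # ~ 1/50
#' @export
height_field_curvature <- function(surface) {
  stopifnot(inherits(surface, "height_field"))
  z <- surface$z
  if (nrow(z) < 3L || ncol(z) < 3L) stop("surface too small")
  if (any(!is.finite(z))) stop("height_field_curvature: NaN elevations")
  dx <- surface$dx; dy <- surface$dy
  nr <- nrow(z); nc <- ncol(z)

  # central differences on the interior; borders padded then masked invalid
  shift <- function(m, di, dj) {
    i <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    j <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
    m[i, j, drop = FALSE]
  }
  zx  <- (shift(z, 0, 1) - shift(z, 0, -1)) / (2 * dx)
  zy  <- (shift(z, 1, 0) - shift(z, -1, 0)) / (2 * dy)
  zxx <- (shift(z, 0, 1) - 2 * z + shift(z, 0, -1)) / dx^2
  zyy <- (shift(z, 1, 0) - 2 * z + shift(z, -1, 0)) / dy^2
  zxy <- (shift(z, 1, 1) - shift(z, 1, -1) - shift(z, -1, 1) +
            shift(z, -1, -1)) / (4 * dx * dy)

  W2 <- 1 + zx^2 + zy^2
  W <- sqrt(W2)
  # first fundamental form
  E <- 1 + zx^2; Ff <- zx * zy; G <- 1 + zy^2
  # second fundamental form w.r.t. the upward normal, negated so that
  # convex-up (cell-side) curvature is positive
  L <- -zxx / W; M <- -zxy / W; N <- -zyy / W

  # shape operator S = I^-1 II; eigenvalues are the principal curvatures
  det_I <- E * G - Ff^2
  s11 <- (G * L - Ff * M) / det_I
  s12 <- (G * M - Ff * N) / det_I
  s21 <- (E * M - Ff * L) / det_I
  s22 <- (E * N - Ff * M) / det_I
  tr <- s11 + s22
  dt <- s11 * s22 - s12 * s21
  disc <- sqrt(pmax(tr^2 / 4 - dt, 0))
  k1 <- tr / 2 - disc
  k2 <- tr / 2 + disc

  # eigenvector of S for k1, expressed in the (x, y) chart, then mapped to a
  # tangent-plane azimuth (adequate for the moderate slopes handled here);
  # of the two algebraic candidates keep the better-conditioned one
  na2 <- s12^2 + (k1 - s11)^2
  nb2 <- (k1 - s22)^2 + s21^2
  v1x <- ifelse(na2 >= nb2, s12, k1 - s22)
  v1y <- ifelse(na2 >= nb2, k1 - s11, s21)
  flat <- abs(v1x) + abs(v1y) < 1e-14  # umbilic: direction arbitrary
  v1x[flat] <- 1; v1y[flat] <- 0
  dir1 <- atan2(v1y, v1x) %% pi

  valid <- matrix(TRUE, nr, nc)
  valid[c(1L, nr), ] <- FALSE
  valid[, c(1L, nc)] <- FALSE

  ax <- height_field_axes(surface)
  curvature_field(k1 = as.vector(k1), k2 = as.vector(k2),
                  dir1 = as.vector(dir1),
                  area = as.vector(dx * dy * W),
                  valid = as.vector(valid),
                  x = rep(ax$x, each = nr), y = rep(ax$y, nc),
                  z = as.vector(z))
}

#' Normal curvature in a given tangent direction (Euler relation)
#'
#' At a surface point with principal curvatures `k1 <= k2` and `k1`-direction
#' azimuth `phi1`, the curvature of the normal section at azimuth `theta` is
#' `k_n(theta) = k1*cos^2(theta - phi1) + k2*sin^2(theta - phi1)`.
#'
#' @param k1,k2 Principal curvatures (1/um), `k1 <= k2`.
#' @param phi1 Azimuth of the `k1` principal direction (rad).
#' @param theta Azimuth of the section (rad); vectorized.
#' @return Normal curvature(s) (1/um).
#' @export
normal_curvature <- function(k1, k2, phi1, theta) {
  k1 * cos(theta - phi1)^2 + k2 * sin(theta - phi1)^2
}

#' Principal curvatures of a triangle mesh by local quadric fitting
#'
#' For each vertex, neighbours within `fit_radius` are expressed in the local
#' tangent frame (z along the vertex normal) and a full quadric
#' `h = a1 u + a2 v + a3 u^2 + a4 u v + a5 v^2` is fitted by least squares;
#' the Weingarten map built from the fitted forms gives principal curvatures
#' and directions. Quadric fitting is used (rather than a discrete Laplacian)
#' because principal directions are needed, not only mean curvature.
#' Convex-outward curvature is positive.
#'
#' @param mesh A [tri_mesh()], outward-wound.
#' @param fit_radius Neighbourhood radius (um); must capture >= 6 neighbours,
#'   vertices with fewer are flagged invalid.
#' @return A [curvature_field()], one node per vertex; `area` is one third of
#'   the incident triangle area.
#' @export
mesh_curvature <- function(mesh, fit_radius) {
  stopifnot(inherits(mesh, "tri_mesh"), fit_radius > 0)
  v <- mesh$vertices
  nv <- nrow(v)
  vn <- if (is.null(mesh$normals)) mesh_vertex_normals(mesh) else mesh$normals
  fa <- mesh_face_areas(v, mesh$faces)
  area <- (tabulate2(mesh$faces[, 1], fa, nv) +
             tabulate2(mesh$faces[, 2], fa, nv) +
             tabulate2(mesh$faces[, 3], fa, nv)) / 3

  # coarse spatial hash so neighbour search is not O(n^2)
  cell <- fit_radius
  key <- paste(floor(v[, 1] / cell), floor(v[, 2] / cell),
               floor(v[, 3] / cell))
  buckets <- split(seq_len(nv), key)
  key_of <- function(p, di, dj, dk)
    paste(floor(p[1] / cell) + di, floor(p[2] / cell) + dj,
          floor(p[3] / cell) + dk)

  k1 <- k2 <- dir1 <- numeric(nv)
  valid <- logical(nv)
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  for (i in seq_len(nv)) {
    cand <- integer(0)
    for (o in seq_len(nrow(offs))) {
      b <- buckets[[key_of(v[i, ], offs$di[o], offs$dj[o], offs$dk[o])]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- rowSums((v[cand, , drop = FALSE] -
                     matrix(v[i, ], length(cand), 3, byrow = TRUE))^2)
    nb <- cand[d2 <= fit_radius^2 & cand != i]
    if (length(nb) < 6L) { valid[i] <- FALSE; next }

    n <- vn[i, ]
    t1 <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- t1 - sum(t1 * n) * n; t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(n[2] * t1[3] - n[3] * t1[2],
            n[3] * t1[1] - n[1] * t1[3],
            n[1] * t1[2] - n[2] * t1[1])
    rel <- v[nb, , drop = FALSE] - matrix(v[i, ], length(nb), 3, byrow = TRUE)
    u <- rel %*% t1; w <- rel %*% t2; h <- rel %*% n
    X <- cbind(u, w, u^2, u * w, w^2)
    cf <- tryCatch(qr.coef(qr(X), h), error = function(e) rep(NA_real_, 5))
    if (any(!is.finite(cf))) { valid[i] <- FALSE; next }

    # fundamental forms of h(u,w) at the origin; height along the OUTWARD
    # normal means convex-outward has h < 0 curvature a3,a5 < 0 -> negate
    hu <- cf[1]; hw <- cf[2]
    E <- 1 + hu^2; Ff <- hu * hw; G <- 1 + hw^2
    Wn <- sqrt(1 + hu^2 + hw^2)
    L <- -2 * cf[3] / Wn; M <- -cf[4] / Wn; N <- -2 * cf[5] / Wn
    det_I <- E * G - Ff^2
    s11 <- (G * L - Ff * M) / det_I
    s12 <- (G * M - Ff * N) / det_I
    s21 <- (E * M - Ff * L) / det_I
    s22 <- (E * N - Ff * M) / det_I
    tr <- s11 + s22; dt <- s11 * s22 - s12 * s21
    disc <- sqrt(max(tr^2 / 4 - dt, 0))
    k1[i] <- tr / 2 - disc
    k2[i] <- tr / 2 + disc
    if (s12^2 + (k1[i] - s11)^2 >= (k1[i] - s22)^2 + s21^2) {
      v1u <- s12; v1w <- k1[i] - s11
    } else {
      v1u <- k1[i] - s22; v1w <- s21
    }
    if (abs(v1u) + abs(v1w) < 1e-14) { v1u <- 1; v1w <- 0 }
    # local frame angle -> tangent azimuth relative to the (t1, t2) frame;
    # report in that frame (meshes carry no global azimuth convention)
    dir1[i] <- atan2(v1w, v1u) %% pi
    valid[i] <- TRUE
  }
  curvature_field(k1 = k1, k2 = k2, dir1 = dir1, area = area, valid = valid,
                  x = v[, 1], y = v[, 2], z = v[, 3])
}

#' Convert a curvature field to a data frame
#'
#' @param x A `curvature_field`.
#' @param ... Unused.
#' @return data.frame with columns x, y, z, k1, k2, H, KG, dir1_deg, area,
#'   valid.
#' @export
as.data.frame.curvature_field <- function(x, ...) {
  n <- length(x$k1)
  data.frame(x = if (is.null(x$x)) rep(NA_real_, n) else x$x,
             y = if (is.null(x$y)) rep(NA_real_, n) else x$y,
             z = if (is.null(x$z)) rep(NA_real_, n) else x$z,
             k1 = x$k1, k2 = x$k2, H = x$H, KG = x$KG,
             dir1_deg = x$dir1 * 180 / pi, area = x$area, valid = x$valid)
}
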