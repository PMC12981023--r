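# Analytic fixture surfaces used across the suite. All built in code; units
# um throughout.

# spherical cap z = sqrt(R^2 - x^2 - y^2), convex up, sampled on [-half, half]
sphere_cap <- function(R = 50, half = 30, h = 1) {
  ax <- seq(-half, half, by = h)
  height_field(outer(ax, ax, function(y, x) sqrt(R^2 - x^2 - y^2)),
               dx = h, dy = h, origin = c(-half, -half))
}

# cylindrical ridge of radius R with axis along y
cylinder_ridge <- function(R = 100, half = 40, h = 1) {
  ax <- seq(-half, half, by = h)
  height_field(outer(ax, ax, function(y, x) sqrt(R^2 - x^2)),
               dx = h, dy = h, origin = c(-half, -half))
}

# quadratic patch with principal curvatures k1 (x) and k2 (y) at the origin
quad_patch <- function(k1 = -0.005, k2 = 0.02, half = 40, h = 1) {
  ax <- seq(-half, half, by = h)
  height_field(outer(ax, ax, function(y, x) -(k1 * x^2 + k2 * y^2) / 2),
               dx = h, dy = h, origin = c(-half, -half))
}

# sinusoidal grooves varying along x (groove axis along y)
sinusoid_x <- function(A = 10, lambda = 80, n = 161, h = 1) {
  ax <- (seq_len(n) - 1) * h
  height_field(outer(ax, ax, function(y, x) A * cos(2 * pi * x / lambda)),
               dx = h, dy = h)
}

flat_field <- function(c0 = 0, n = 21, h = 1) {
  height_field(matrix(c0, n, n), dx = h, dy = h)
}

# mean edge length of a mesh (for choosing quadric fit radii)
mesh_edge_length <- function(mesh) {
  e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  mean(sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2)))
}

mesh_curvature_auto <- function(mesh, k = 2.6) {
  mesh_curvature(mesh, fit_radius = k * mesh_edge_length(mesh))
}

# open cylinder mesh of radius R, axis z, for mesh-estimator checks
cylinder_mesh <- function(R = 25, L = 60, n_circ = 48, n_ax = 25) {
  th <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  zz <- seq(-L / 2, L / 2, length.out = n_ax)
  v <- cbind(R * cos(rep(th, n_ax)), R * sin(rep(th, n_ax)),
             rep(zz, each = n_circ))
  f <- NULL
  idx <- function(i, j) (i - 1) * n_circ + ((j - 1) %% n_circ) + 1
  for (i in seq_len(n_ax - 1)) {
    for (j in seq_len(n_circ)) {
      # wound so normals point outward
      f <- rbind(f, c(idx(i, j), idx(i, j + 1), idx(i + 1, j)),
                 c(idx(i + 1, j), idx(i, j + 1), idx(i + 1, j + 1)))
    }
  }
  tri_mesh(v, f)
}
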