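# Differential geometry: curvature fields, the Euler relation, normal
# sections, and the mesh estimator.

test_that("height-field curvature recovers analytic values on canonical surfaces", {
  # flat plane: identically zero
  cf <- height_field_curvature(flat_field(3))
  ok <- cf$valid
  expect_equal(max(abs(c(cf$k1[ok], cf$k2[ok], cf$H[ok], cf$KG[ok]))), 0)

  # sphere R = 50: H = 1/50 within 1% at interior nodes
  cf <- height_field_curvature(sphere_cap(R = 50, half = 30))
  expect_lt(max(abs(cf$H[cf$valid] - 0.02)) / 0.02, 0.01)
  expect_lt(max(abs(cf$KG[cf$valid] - 4e-4)) / 4e-4, 0.02)

  # cylinder R = 100: k2 = 0.01, k1 = 0, k2-direction across the ridge axis
  cf <- height_field_curvature(cylinder_ridge(R = 100, half = 40))
  ok <- cf$valid
  expect_lt(max(abs(cf$k2[ok] - 0.01)) / 0.01, 0.01)
  expect_lt(max(abs(cf$k1[ok])), 1e-8)
  # dir1 is the k1 (axis) direction: along y = 90 deg
  expect_lt(max(abs(cf$dir1[ok] * 180 / pi - 90)), 1)
})

test_that("curvature field maintains its algebraic invariants", {
  cf <- height_field_curvature(quad_patch())
  ok <- cf$valid
  expect_true(all(cf$k1[ok] <= cf$k2[ok] + 1e-12))
  expect_equal(cf$H, (cf$k1 + cf$k2) / 2, tolerance = 1e-12)
  expect_equal(cf$KG, cf$k1 * cf$k2, tolerance = 1e-12)
})

test_that("input validation rejects degenerate grids", {
  expect_error(height_field(matrix(0, 2, 5), dx = 1), "3 x 3")
  expect_error(height_field(matrix(c(NA, 1:8), 3, 3), dx = 1), "finite")
  expect_error(height_field(matrix(0, 5, 5), dx = -1), "positive")
})

test_that("normal_curvature satisfies the Euler relation identities", {
  # umbilic point: constant in theta
  expect_equal(normal_curvature(0.02, 0.02, 0.3, seq(0, pi, 0.1)),
               rep(0.02, length(seq(0, pi, 0.1))))
  # cylinder: zero along the axis, 1/R across
  expect_equal(normal_curvature(0, 0.01, 0, 0), 0)
  expect_equal(normal_curvature(0, 0.01, 0, pi / 2), 0.01)
  # symmetric saddle cancels at 45 degrees
  expect_equal(normal_curvature(-0.03, 0.03, 0, pi / 4), 0, tolerance = 1e-15)
})

test_that("extremes of normal curvature over theta are the principal curvatures", {
  cf <- height_field_curvature(quad_patch(k1 = -0.008, k2 = 0.015))
  i <- which(cf$valid)[c(10, 100, 500)]
  for (j in i) {
    th <- c(seq(0, pi, length.out = 361), cf$dir1[j], cf$dir1[j] + pi / 2)
    kn <- normal_curvature(cf$k1[j], cf$k2[j], cf$dir1[j], th)
    expect_lt(abs(max(kn) - cf$k2[j]), 1e-9)
    expect_lt(abs(min(kn) - cf$k1[j]), 1e-9)
  }
})

test_that("normal sections recover profile curvature and arc-length structure", {
  # flat plane: zero curvature, contour equals chord
  pr <- normal_section_profile(flat_field(0, n = 81), c(40, 40), 37, 20, 0.5)
  expect_equal(max(abs(pr$kappa)), 0)
  expect_equal(pr$contour, pr$chord)

  # along-groove section of a sinusoid is straight
  sn <- sinusoid_x(A = 10, lambda = 80)
  pr <- normal_section_profile(sn, c(80, 80), 90, 20, 0.5)
  expect_lt(max(abs(pr$kappa)), 1e-6)

  # cross-groove section at a ridge top: kappa(0) = A (2 pi / lambda)^2
  pr <- normal_section_profile(sn, c(80, 80), 0, 20, 0.5)
  k_true <- 10 * (2 * pi / 80)^2
  expect_lt(abs(profile_center_curvature(pr) - k_true) / k_true, 0.02)
  expect_gte(pr$contour, pr$chord)
})

test_that("section curvature matches the Euler relation on a quadratic patch", {
  k1 <- -0.005; k2 <- 0.02
  qs <- quad_patch(k1, k2)
  for (th in c(0, 17, 45, 60, 77, 90, 133)) {
    pr <- normal_section_profile(qs, c(0, 0), th, 15, 0.5)
    expect_equal(profile_center_curvature(pr),
                 normal_curvature(k1, k2, 0, th * pi / 180),
                 tolerance = 0.02)
  }
})

test_that("sections that leave the surface extent raise an error", {
  expect_error(
    normal_section_profile(flat_field(0, n = 21), c(10, 10), 0, 30, 0.5),
    "out of bounds")
})

test_that("estimators converge on analytic surfaces with at least order 1.5", {
  err_at <- function(h) {
    cf <- height_field_curvature(sphere_cap(R = 50, half = 24, h = h))
    max(abs(cf$H[cf$valid] - 0.02))
  }
  e2 <- err_at(2); e1 <- err_at(1)
  expect_gt(log2(e2 / e1), 1.5)

  err_cyl <- function(h) {
    cf <- height_field_curvature(cylinder_ridge(R = 100, half = 24, h = h))
    max(abs(cf$k2[cf$valid] - 0.01))
  }
  expect_gt(log2(err_cyl(2) / err_cyl(1)), 1.5)
})

test_that("rotating a patch by 90 degrees permutes principal directions only", {
  qs <- quad_patch(k1 = -0.005, k2 = 0.02)
  qr <- height_field(t(qs$z), dx = qs$dy, dy = qs$dx, origin = qs$origin)
  cf <- height_field_curvature(qs)
  cfr <- height_field_curvature(qr)
  ok <- cf$valid
  expect_equal(sort(c(stats::median(cf$k1[ok]), stats::median(cf$k2[ok]))),
               sort(c(stats::median(cfr$k1[cfr$valid]),
                      stats::median(cfr$k2[cfr$valid]))),
               tolerance = 1e-6)
  d0 <- stats::median(cf$dir1[ok]) * 180 / pi
  d90 <- stats::median(cfr$dir1[cfr$valid]) * 180 / pi
  expect_equal(abs(((d0 - d90 + 90) %% 180) - 90), 90, tolerance = 1)
})

test_that("mesh curvature is accurate on spheres and cylinders", {
  ico <- make_microgel(microgel_spec(diameter = 100, subdiv = 4))
  cf <- mesh_curvature_auto(ico)
  expect_true(all(cf$valid))
  expect_lt(max(abs(cf$H[cf$valid] - 0.02)) / 0.02, 0.02)

  cyl <- cylinder_mesh(R = 25)
  cf <- mesh_curvature_auto(cyl)
  ok <- cf$valid & abs(cf$z) < 20  # away from the open ends
  expect_lt(max(abs(cf$k2[ok] - 0.04)) / 0.04, 0.02)
  expect_lt(max(abs(cf$k1[ok])), 0.002)
})

test_that("vertices with too few neighbours are flagged invalid", {
  cyl <- cylinder_mesh(R = 25, n_circ = 24, n_ax = 9)
  cf <- mesh_curvature(cyl, fit_radius = 0.5)
  expect_false(any(cf$valid))
})

test_that("harmonic perturbation strictly increases microgel mean curvature", {
  smooth <- make_microgel(microgel_spec(diameter = 97.2, subdiv = 3))
  wrinkled <- make_microgel(microgel_spec(diameter = 97.2, amplitude = 4.8,
                                          l_min = 8, l_max = 14, seed = 2,
                                          subdiv = 3))
  h_s <- mean_abs_curvature(mesh_curvature_auto(smooth))
  h_w <- mean_abs_curvature(mesh_curvature_auto(wrinkled))
  expect_gt(h_w, h_s)
})

test_that("mesh containers validate indices, degenerate faces and closedness", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(tri_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(tri_mesh(rbind(v, c(0.5, 0, 0)),
                        rbind(c(1, 2, 3), c(1, 2, 4))), "degenerate")
  expect_error(tri_mesh(v, rbind(c(1, 2, 3)), closed = TRUE), "Euler")
})
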