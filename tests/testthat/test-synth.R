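# Synthetic topography generators: grooves, spectral wrinkle fields,
# constructed multiaxial surfaces, microgels. Every generator must be a pure
# function of (spec, seed).

test_that("groove surfaces hit the designed ridge-top circumferential curvature", {
  for (K in c(0.011, 0.018)) {
    A <- groove_amplitude_for_curvature(K, 60)
    gr <- make_groove_surface(A = A, lambda = 60)
    ctr <- attr(gr, "center")
    pr <- normal_section_profile(gr, ctr, 90, 15, 0.5)  # cross-groove
    expect_equal(profile_center_curvature(pr), K, tolerance = 0.01)
    pr0 <- normal_section_profile(gr, ctr, 0, 15, 0.5)  # along the axis
    expect_lt(max(abs(pr0$kappa)), 1e-6)
  }
  # zero amplitude collapses to a flat plane
  fl <- make_groove_surface(A = 0, lambda = 60)
  cf <- height_field_curvature(fl)
  expect_equal(max(abs(cf$H[cf$valid])), 0)
  expect_error(make_groove_surface(A = 1, lambda = 2, spacing = 1),
               "unresolvable")
})

test_that("a curved groove axis carries the requested axial curvature", {
  gr <- make_groove_surface(A = groove_amplitude_for_curvature(0.018, 60),
                            lambda = 60, axial_curvature = 0.005)
  pr <- normal_section_profile(gr, attr(gr, "center"), 0, 15, 0.5)
  expect_equal(profile_center_curvature(pr), 0.005, tolerance = 0.02)
})

test_that("wrinkle surfaces are deterministic and amplitude-controlled", {
  sp <- wrinkle_spec(lambda_c = 60, A = 5, anisotropy = 0.3, seed = 42)
  w1 <- make_wrinkle_surface(sp)
  w2 <- make_wrinkle_surface(sp)
  expect_identical(w1$z, w2$z)
  expect_equal(max(w1$z) - min(w1$z), 10, tolerance = 1e-9)
  w3 <- make_wrinkle_surface(wrinkle_spec(lambda_c = 60, A = 5,
                                          anisotropy = 0.3, seed = 43))
  expect_false(identical(w1$z, w3$z))
})

test_that("wrinkle mean curvature rises with amplitude and falls with wavelength", {
  h <- matrix(NA_real_, 3, 3)
  As <- c(4, 8, 16); lams <- c(50, 80, 120)
  for (i in 1:3) for (j in 1:3) {
    w <- make_wrinkle_surface(wrinkle_spec(lambda_c = lams[j], A = As[i],
                                           seed = 9))
    h[i, j] <- mean_abs_curvature(height_field_curvature(w))
  }
  for (j in 1:3) expect_true(all(diff(h[, j]) > 0))
  for (i in 1:3) expect_true(all(diff(h[i, ]) < 0))
})

test_that("anisotropy controls the uniaxial/multiaxial split of wrinkles", {
  mk <- function(a) make_wrinkle_surface(
    wrinkle_spec(lambda_c = 60, A = 5, anisotropy = a, seed = 3))
  c0 <- classify_regions(height_field_curvature(mk(0)))
  c1 <- classify_regions(height_field_curvature(mk(1)))
  uni1 <- sum(c1$adhesive_proportions[c("uniaxial_low", "uniaxial_high")])
  expect_gte(uni1, 0.95)
  expect_gt(c0$multiaxial_fraction, c1$multiaxial_fraction)
})

test_that("a single oblique wave reduces to the groove construction", {
  lam <- 60
  A <- groove_amplitude_for_curvature(0.015, lam)
  ms <- make_multiaxial_test_surface(A, directions_deg = 90,
                                     wavelengths = lam)
  gr <- make_groove_surface(A = A, lambda = lam)
  expect_equal(dim(ms$z), dim(gr$z))
  expect_equal(ms$z, gr$z, tolerance = 1e-9)
})

test_that("mutually orthogonal wave sets are flagged degenerate", {
  expect_warning(
    make_multiaxial_test_surface(c(1, 1), c(0, 90), c(40, 40)),
    "degenerate")
  expect_silent(make_multiaxial_test_surface(c(1, 1), c(0, 60), c(40, 40)))
})

test_that("two orthogonal waves give basal minima at the principal directions only", {
  # wavelengths above the fiber span keep sections in the near-crest
  # quadratic regime, where the Euler relation pins the extrema to the
  # principal directions
  ms <- suppressWarnings(
    make_multiaxial_test_surface(c(1.6, 0.8), c(0, 90), c(80, 80),
                                 grid_n = 161, spacing = 1))
  ol <- orientation_landscape(ms, attr(ms, "center"), model_params(),
                              theta_step = 2)
  expect_true(all(ol$basal_minima$theta_deg %in% c(0, 90)))
  expect_equal(ol$basal_argmin_deg, 0)  # the stronger-curvature direction
})

test_that("microgel meshes are deterministic, closed, and validated", {
  sp <- microgel_spec(diameter = 100, amplitude = 5, l_min = 6, l_max = 10,
                      seed = 4, subdiv = 3)
  m1 <- make_microgel(sp)
  m2 <- make_microgel(sp)
  expect_identical(m1$vertices, m2$vertices)
  expect_true(m1$closed)
  expect_error(microgel_spec(diameter = 100, amplitude = 30), "self-intersection")
})

test_that("smooth microgel spheres have mean curvature 2/diameter", {
  m <- make_microgel(microgel_spec(diameter = 100, subdiv = 4))
  expect_equal(mean_abs_curvature(mesh_curvature_auto(m)), 0.02,
               tolerance = 0.02)
})

test_that("small SICE microgels are curvier than large ones (preset calibration)", {
  h_small <- mean_abs_curvature(
    mesh_curvature_auto(load_preset("microgel-small")))
  h_large <- mean_abs_curvature(
    mesh_curvature_auto(load_preset("microgel-large")))
  expect_gt(h_small, h_large)
  # calibrated against the printed statistics (0.040 and 0.017 1/um)
  expect_equal(h_small, 0.040, tolerance = 0.15)
  expect_equal(h_large, 0.017, tolerance = 0.15)
})

test_that("wrinkle spec validation catches unresolvable wavelengths", {
  expect_error(wrinkle_spec(lambda_c = 6, A = 1, spacing = 2), "unresolvable")
})
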