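# Two-layer stress-fiber energy model: frozen component oracles, calibration
# inequalities, monotonicity, landscape structure, drug maps.

test_that("default parameters satisfy both calibration inequalities", {
  cal <- check_calibration(model_params())
  expect_true(cal$C1)
  expect_true(cal$C2)
  expect_error(model_params(L_f = 60), "C1")
  expect_error(model_params(B_f_a = 500), "C2")
})

test_that("basal energy components match closed-form values on a circular arc", {
  # kappa = 0.02 1/um, L_f = 20 um, defaults:
  #   U_bending = 0.5 * 2 * 0.02^2 * 20 = 0.008 pN um
  #   P = 10 * 0.02 * 20 = 4 pN -> N_FA = 10 + 4/0.05 = 90 -> U_FA = -9
  #   U_active = F (L - (2/kappa) sin(kappa L / 2))
  arc <- arc_profile(0.02, 20, step = 0.05)
  b <- basal_energy(arc, model_params())
  expect_equal(b$U_bending, 0.008, tolerance = 1e-6)
  expect_equal(b$N_FA, 90, tolerance = 1e-4)
  expect_equal(b$U_FA, -9, tolerance = 1e-4)
  expect_equal(b$U_active, 10 * (20 - (2 / 0.02) * sin(0.02 * 20 / 2)),
               tolerance = 1e-6)
  expect_equal(b$U_total, b$U_bending + b$U_active + b$U_FA)

  # flat: only the baseline adhesion term remains
  b0 <- basal_energy(arc_profile(0, 20), model_params())
  expect_equal(b0$U_bending, 0)
  expect_equal(b0$U_active, 0)
  expect_equal(b0$U_FA, -1)

  # curvature is energetically favored by basal fibers
  expect_lt(b$U_total, b0$U_total)
})

test_that("concave arcs shed adhesion units, floored at zero", {
  b <- basal_energy(arc_profile(-0.02, 20, step = 0.05), model_params())
  expect_equal(b$N_FA, 0)
  expect_equal(b$U_FA, 0)
})

test_that("profile/parameter length mismatch is rejected", {
  expect_error(basal_energy(arc_profile(0.01, 30), model_params()),
               "contour length")
})

test_that("apical energy matches closed-form values on flat and curved caps", {
  p <- model_params()
  # flat: delta = h_N = 5; U_bend = 32*20*25/27000; FA dominates bending
  a0 <- apical_energy(arc_profile(0, 34, step = 0.25), p)
  expect_equal(a0$delta, 5)
  expect_equal(a0$U_bending, 32 * 20 * 25 / 27000, tolerance = 1e-9)
  expect_equal(a0$U_FA, -1)
  expect_lt(a0$U_bending, abs(a0$U_FA))
  # whole-cap nuclear term: (N_f_a * 8 F delta / W)^2 / (2 k_nuc)
  expect_equal(a0$U_nuc, (10 * 8 * 10 * 5 / 30)^2 / (2 * 5000),
               tolerance = 1e-9)

  # parabolic cap at kappa = 0.04: g = kappa W^2 / 8 = 4.5, delta = 9.5,
  # and bending overtakes the FA term
  a1 <- apical_energy(cap_profile(0.04, 34, step = 0.25), p)
  expect_equal(a1$g, 4.5, tolerance = 1e-6)
  expect_equal(a1$delta, 9.5, tolerance = 1e-6)
  expect_equal(a1$U_bending, 32 * 20 * 9.5^2 / 27000, tolerance = 1e-6)
  expect_gt(a1$U_bending, abs(a1$U_FA))

  # deep trough clamps the deflection at zero
  a2 <- apical_energy(cap_profile(-0.06, 34, step = 0.25), p)
  expect_equal(a2$delta, 0)
  expect_equal(a2$U_bending, 0)
  expect_equal(a2$U_active, 0)

  # per-fiber share
  a3 <- apical_energy(arc_profile(0, 34), p, whole_cap = FALSE)
  expect_equal(a3$U_nuc, a0$U_nuc / 10, tolerance = 1e-12)
})

test_that("basal total energy strictly decreases with curvature up to 0.04", {
  p <- model_params()
  ks <- seq(0, 0.04, by = 0.002)
  u <- vapply(ks, function(k)
    basal_energy(arc_profile(k, p$L_f, step = 0.1), p)$U_total, numeric(1))
  expect_true(all(diff(u) < 0))
})

test_that("apical bending first exceeds the FA term near kappa = 0.013", {
  p <- model_params()
  excess <- function(k)
    with(apical_energy(cap_profile(k, 34, step = 0.1), p),
         U_bending - abs(U_FA))
  expect_lt(excess(0), 0)
  expect_gt(excess(0.04), 0)
  k_star <- stats::uniroot(excess, c(1e-4, 0.04))$root
  expect_gt(k_star, 0.005)
  expect_lt(k_star, 0.03)
  # closed-form crossover: 32 B (h_N + k W^2/8)^2 / W^3 = N0_a eps
  k_cf <- (sqrt(10 * 0.1 * 27000 / (32 * 20)) - 5) * 8 / 900
  expect_equal(k_star, k_cf, tolerance = 0.01)
})

test_that("nuclear strain energy grows with curvature and contractile machinery", {
  p <- model_params()
  nc <- nuclear_energy_curve(seq(0, 0.04, by = 0.002), p)
  expect_true(all(diff(nc$U_nuc) > 0))
  expect_equal(nc$U_nuc[1], (10 * 8 * 10 * 5 / 30)^2 / 1e4, tolerance = 1e-9)

  # halving F_a0 and N_f_a lowers the whole curve
  p_half <- model_params(F_a0 = 5, N_f_a = 5)
  nc_h <- nuclear_energy_curve(nc$K, p_half)
  expect_true(all(nc_h$U_nuc < nc$U_nuc))

  # monotone in each knob separately
  expect_true(all(nuclear_energy_curve(nc$K, model_params(F_a0 = 12))$U_nuc >=
                    nc$U_nuc))
  expect_true(all(nuclear_energy_curve(nc$K, model_params(N_f_a = 12))$U_nuc >=
                    nc$U_nuc))
})

test_that("energies carry the analytic length-scaling dimensions", {
  # scaling all lengths by s: kappa -> kappa/s, L -> s L, so the bending
  # integral (B/2) int kappa^2 ds scales by 1/s at fixed rigidity
  s <- 2
  b1 <- basal_energy(arc_profile(0.02, 20, step = 0.05), model_params())
  # the doubled-length parameter set intentionally sits outside the C1
  # calibration regime; that is fine for a pure dimension check
  p2 <- suppressWarnings(model_params(L_f = 40, check = FALSE))
  b2 <- basal_energy(arc_profile(0.02 / s, 20 * s, step = 0.05 * s), p2)
  expect_equal(b2$U_bending, b1$U_bending / s, tolerance = 1e-6)
})

test_that("drug perturbations follow the committed parameter map", {
  p <- model_params()
  expect_equal(apply_perturbation(p, "none"), p)

  cn <- apply_perturbation(p, "CN03")
  expect_equal(cn$F_a0, 20)
  expect_equal(cn$N_f_b / (cn$N_f_b + cn$N_f_a), 0.68, tolerance = 1e-12)
  expect_equal(cn$N_f_b + cn$N_f_a, p$N_f_b + p$N_f_a)

  y <- apply_perturbation(p, "Y27632")
  expect_equal(y$N_f_a, 0)
  expect_equal(y$F_a0, 5)

  expect_equal(apply_perturbation(p, "blebbistatin")$F_a0, 1)
  lat <- apply_perturbation(p, "latrunculinB")
  expect_equal(lat$N_f_a, 0.5)
  expect_equal(lat$N_f_b, 0.275)
  expect_error(apply_perturbation(p, "aspirin"))

  # actin disruption lowers the nuclear energy curve pointwise
  ks <- seq(0, 0.04, by = 0.004)
  u0 <- nuclear_energy_curve(ks, p)$U_nuc
  expect_true(all(nuclear_energy_curve(ks, lat)$U_nuc < u0))
  expect_true(all(
    nuclear_energy_curve(ks, apply_perturbation(p, "blebbistatin"))$U_nuc < u0))
})

test_that("orientation landscapes split the layers on uniaxial grooves", {
  for (K in c(0.011, 0.018)) {
    gr <- make_groove_surface(A = groove_amplitude_for_curvature(K, 60),
                              lambda = 60)
    ol <- orientation_landscape(gr, attr(gr, "center"), model_params(),
                                theta_step = 1)
    expect_equal(ol$basal_argmin_deg, 90)   # circumferential
    expect_equal(ol$apical_argmin_deg, 0)   # axial
    expect_equal(ol$basal$U_total,
                 ol$basal$U_bending + ol$basal$U_active + ol$basal$U_FA)
    expect_equal(ol$apical$U_total,
                 with(ol$apical, U_bending + U_active + U_FA + U_nuc))
  }
})

test_that("flat substrates give degenerate landscapes in both layers", {
  fl <- flat_field(0, n = 81)
  ol <- orientation_landscape(fl, c(40, 40), model_params(), theta_step = 5)
  expect_true(ol$basal_degenerate)
  expect_true(ol$apical_degenerate)
})

test_that("landscape errors name the offending azimuth when out of bounds", {
  # rectangular grid: the apical span fits along x but not along y
  fl <- height_field(matrix(0, 31, 41), dx = 1, dy = 1)
  expect_error(
    orientation_landscape(fl, c(20, 15), model_params(), theta_step = 45),
    "theta = 90")
})

test_that("coarse and dense landscape scans agree on the argmin within 1 degree", {
  gr <- make_groove_surface(A = groove_amplitude_for_curvature(0.018, 60),
                            lambda = 60)
  ctr <- attr(gr, "center")
  p <- model_params()
  ol1 <- orientation_landscape(gr, ctr, p, theta_step = 1)
  # dense rescan around the coarse argmin
  th_dense <- seq(ol1$basal_argmin_deg - 2, ol1$basal_argmin_deg + 2, by = 0.1)
  u_dense <- vapply(th_dense, function(th)
    basal_energy(normal_section_profile(gr, ctr, th, p$L_f / 2, 0.5),
                 p)$U_total, numeric(1))
  expect_lt(abs(th_dense[which.min(u_dense)] - ol1$basal_argmin_deg), 1 + 1e-9)
})
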