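# Structure-tensor orientation analysis, polar histograms, alignment
# fractions, CPI, and layer statistics.

stripe_image <- function(angle_deg, n = 128, period = 8) {
  ax <- seq_len(n)
  grad_dir <- deg2rad_ <- (angle_deg + 90) * pi / 180
  outer(ax, ax, function(i, j)
    sin(2 * pi * (j * cos(grad_dir) + i * sin(grad_dir)) / period))
}

test_that("structure tensor recovers stripe orientation with high coherence", {
  of <- structure_tensor_orientations(stripe_image(30), 1, 4)
  expect_lt(abs(stats::median(of$orientation_deg[of$mask]) - 30), 1)
  expect_gt(stats::median(of$coherence), 0.9)
})

test_that("white noise yields low coherence and constant images are masked", {
  set.seed(7)
  of <- structure_tensor_orientations(matrix(stats::rnorm(128^2), 128), 1, 4)
  expect_lt(stats::median(of$coherence), 0.2)

  ofc <- structure_tensor_orientations(matrix(1, 64, 64), 1, 4)
  expect_false(any(ofc$mask))
  expect_true(all(ofc$coherence == 0))
  expect_error(orientation_histogram(ofc), "masked")
})

test_that("orientation estimates are equivariant under 90-degree rotation", {
  img <- stripe_image(30)
  of0 <- structure_tensor_orientations(img, 1, 4)
  # rotate image by 90 deg CCW: new[i, j] = old[j, N - i + 1]
  img90 <- t(img)[, rev(seq_len(nrow(img)))]
  of90 <- structure_tensor_orientations(img90, 1, 4)
  o0 <- stats::median(of0$orientation_deg[of0$mask])
  o90 <- stats::median(of90$orientation_deg[of90$mask])
  expect_lt(abs(((o90 - o0 - 90 + 90) %% 180) - 90), 1)
  expect_equal(stats::median(of90$coherence), stats::median(of0$coherence),
               tolerance = 0.02)
})

test_that("orientation histograms normalize and localize correctly", {
  # a single segment puts all mass in one bin
  seg <- data.frame(theta_deg = 90, length_um = 10)
  h <- orientation_histogram(seg, n_bins = 18)
  expect_equal(sum(h$density), 1)
  expect_equal(h$density[which(h$bin_center_deg == 95)], 1)

  # two delta populations at 0 and 90 with 3:1 length weight
  seg2 <- data.frame(theta_deg = c(0, 0, 0, 90), length_um = c(1, 1, 1, 1))
  h2 <- orientation_histogram(seg2, n_bins = 18)
  expect_equal(h2$density[1], 0.75)
  expect_equal(h2$density[10], 0.25)

  # uniform orientations: no bin more than twice any other at n = 1e4
  set.seed(11)
  segu <- data.frame(theta_deg = stats::runif(1e4, 0, 180), length_um = 1)
  hu <- orientation_histogram(segu, n_bins = 18)
  expect_lt(max(hu$density), 2 * min(hu$density))

  expect_error(orientation_histogram(data.frame()), "empty")
  expect_error(orientation_histogram(seg, n_bins = 7))
})

test_that("alignment fraction behaves at its analytic anchors", {
  seg <- data.frame(theta_deg = rep(90, 10), length_um = 1)
  h <- orientation_histogram(seg, n_bins = 36)
  expect_equal(alignment_fraction(h, 90, 15), 1)
  expect_equal(alignment_fraction(h, 0, 15), 0)

  set.seed(3)
  segu <- data.frame(theta_deg = stats::runif(2e4, 0, 180), length_um = 1)
  hu <- orientation_histogram(segu, n_bins = 36)
  expect_equal(alignment_fraction(hu, 45, 15), 2 * 15 / 180, tolerance = 0.1)
  # periodic wrap around 0/180
  expect_equal(alignment_fraction(hu, 0, 15), 2 * 15 / 180, tolerance = 0.1)
})

test_that("CPI is 1 for a disk, the axis ratio for an ellipse, and reciprocal", {
  n <- 101
  ax <- seq_len(n) - 51
  disk <- outer(ax, ax, function(y, x) x^2 + y^2 <= 40^2)
  expect_equal(compute_cpi(disk, 0)$CPI, 1, tolerance = 0.02)

  # 2:1 ellipse with the major axis along x (axial)
  ell <- outer(ax, ax, function(y, x) (x / 40)^2 + (y / 20)^2 <= 1)
  st <- compute_cpi(ell, 0)
  expect_equal(st$CPI, 2, tolerance = 0.05)
  # swapping the axis definitions inverts the index exactly
  st_swap <- compute_cpi(ell, 90)
  expect_equal(st_swap$CPI, 1 / st$CPI, tolerance = 1e-12)

  expect_error(compute_cpi(matrix(FALSE, 5, 5), 0), "empty")
})

test_that("layer population statistics count and weigh segments correctly", {
  seg <- data.frame(layer = c(rep("basal", 7), rep("apical", 3)),
                    theta_deg = 0, length_um = c(rep(2, 7), rep(10, 3)),
                    width_um = c(rep(0.5, 7), rep(1, 3)))
  st <- layer_population_stats(seg)
  expect_equal(st$basal_fraction, 0.7)
  expect_equal(st$apical_fraction, 0.3)
  expect_equal(st$basal_fraction_length, 14 / 44)
  expect_equal(unname(st$mean_width), c(0.5, 1))

  seg_b <- seg[seg$layer == "basal", ]
  st_b <- layer_population_stats(seg_b)
  expect_equal(st_b$apical_fraction, 0)
  expect_error(layer_population_stats(data.frame()), "segments")
})
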