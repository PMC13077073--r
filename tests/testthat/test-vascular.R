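test_that("preprocessing handles degenerate stacks and is switchable to identity", {
  arr <- array(5, c(4, 8, 8))
  st <- volume_stack(arr, c(1, 1, 1))
  out <- preprocess_stack(st, preprocess_options(equalize = FALSE,
                                                 denoise = FALSE,
                                                 register = FALSE))
  expect_true(all(out$data == 0))  # degenerate range maps to 0
  off <- preprocess_options(equalize = FALSE, normalize = FALSE,
                            denoise = FALSE, register = FALSE)
  st2 <- volume_stack(array(stats::runif(4 * 8 * 8), c(4, 8, 8)), c(1, 1, 1))
  expect_identical(preprocess_stack(st2, off)$data, st2$data)
  expect_message(preprocess_stack(st2, preprocess_options(
    equalize = FALSE, normalize = FALSE, denoise = FALSE, register = FALSE,
    crosstalk_removal = TRUE)), "no-op")
})

test_that("slice registration recovers an injected integer shift", {
  set.seed(1)
  base <- matrix(0, 48, 48)
  base[15:20, 22:30] <- 1
  base[30:40, 8:12] <- 0.7
  base <- base + matrix(stats::runif(48 * 48, 0, 0.05), 48)
  arr <- array(0, c(3, 48, 48))
  arr[1, , ] <- base
  arr[2, , ] <- base
  sh <- mesokit:::shift2d(base, 3, -2)
  arr[3, , ] <- sh
  out <- preprocess_stack(volume_stack(arr, c(1, 1, 1)),
                          preprocess_options(equalize = FALSE,
                                             normalize = FALSE,
                                             denoise = FALSE,
                                             register = TRUE))
  inner <- 10:38
  expect_lt(max(abs(out$data[3, inner, inner] - base[inner, inner])), 0.06)
})

test_that("fixed-threshold segmentation of a separable phantom is exact", {
  g <- straight_tube_phantom(h = 1)
  m <- segment_vessels(g$stack, method = "fixed", threshold = 0.5,
                       min_size_voxels = 1L)
  expect_identical(m$voxels, g$truth$mask)
})

test_that("all-background stacks raise an empty-foreground error naming the threshold", {
  st <- volume_stack(array(stats::runif(1000, 0, 0.1), c(10, 10, 10)), c(1, 1, 1))
  expect_error(segment_vessels(st, method = "fixed", threshold = 0.5),
               "threshold used: 0.5")
})

test_that("Otsu segmentation of a noisy phantom reaches Dice >= 0.9", {
  spec <- phantom_spec(c(21, 21, 120), c(1, 1, 1),
                       list(list(start = c(10, 10, -10), end = c(10, 10, 1e4),
                                 radius_um = 5)),
                       background_intensity = 0.1, vessel_intensity = 1,
                       noise_sd = 0.18, psf_sigma_um = c(0, 0, 0))  # SNR ~ 5
  g <- generate_vascular_phantom(spec, seed = 7)
  m <- segment_vessels(g$stack, method = "otsu")
  dice <- 2 * sum(m$voxels & g$truth$mask) /
    (sum(m$voxels) + sum(g$truth$mask))
  expect_gte(dice, 0.9)
})

test_that("a straight tube yields one on-axis segment with no branch points", {
  g <- straight_tube_phantom(h = 1)
  cl <- extract_centerlines(vessel_mask(g$truth$mask, c(1, 1, 1)))
  expect_length(cl$segments, 1)
  expect_equal(nrow(cl$branch_points), 0)
  pts <- cl$segments[[1]]
  # within one voxel of the true axis, away from the cut tube ends (the
  # flat end faces leave a short medial-surface artifact)
  interior <- pts[, 3] > 10 & pts[, 3] < max(pts[, 3]) - 10
  expect_lt(max(abs(pts[interior, 1] - 10)), 1)
  expect_lt(max(abs(pts[interior, 2] - 10)), 1)
})

test_that("a Y-shaped phantom decomposes into 3 segments and 1 branch point", {
  ctr <- c(15, 15, 15)
  segs <- list(list(start = ctr, end = c(15, 15, 28), radius_um = 2),
               list(start = ctr, end = c(15, 26, 5), radius_um = 2),
               list(start = ctr, end = c(15, 4, 5), radius_um = 2))
  spec <- phantom_spec(c(31, 31, 31), c(1, 1, 1), segs, noise_sd = 0,
                       psf_sigma_um = c(0, 0, 0))
  g <- generate_vascular_phantom(spec, 1)
  cl <- extract_centerlines(vessel_mask(g$truth$mask, c(1, 1, 1)))
  expect_length(cl$segments, 3)
  expect_equal(nrow(cl$branch_points), 1)
  expect_lt(max(abs(cl$branch_points[1, ] - ctr)), 3)
})

test_that("a single-voxel mask yields one degenerate one-point segment", {
  vox <- array(FALSE, c(5, 5, 5))
  vox[3, 3, 3] <- TRUE
  cl <- extract_centerlines(vessel_mask(vox, c(1, 1, 1)))
  expect_length(cl$segments, 1)
  expect_equal(nrow(cl$segments[[1]]), 1)
  expect_equal(cl$flags[1], "degenerate")
  L <- segment_length(cl, 1)
  expect_equal(as.numeric(L), 0)
  expect_true(attr(L, "degenerate"))
})

test_that("diameter is twice the median radius, with even-count interpolation", {
  g <- make_graph(list(cbind(0, 0, 0:2), cbind(0, 0, 0:3)),
                  radii = list(c(3, 4, 5), c(2, 2, 2, 2)))
  expect_equal(segment_diameter(g, 1), 8)
  expect_equal(segment_diameter(g, 2), 4)
  g2 <- make_graph(list(cbind(0, 0, 0:1)), radii = list(c(NA_real_, NA_real_)))
  expect_error(segment_diameter(g2, 1), "no radius")
})

test_that("tube phantom diameter matches the analytic cylinder within a voxel", {
  g <- straight_tube_phantom(h = 1)
  cl <- extract_centerlines(vessel_mask(g$truth$mask, c(1, 1, 1)))
  expect_lt(abs(segment_diameter(cl, 1) - 10), 1)
})

test_that("segment length sums consecutive Euclidean distances", {
  g <- make_graph(list(cbind(0, 0, 0:10),
                       rbind(c(0, 0, 0), c(0, 3, 4), c(0, 6, 8))))
  expect_equal(as.numeric(segment_length(g, 1)), 10)
  expect_equal(as.numeric(segment_length(g, 2)), 10)
})

test_that("helical tube length is within 3% of the closed-form arc length", {
  t <- seq(0, 4 * pi, length.out = 200)
  R <- 20; pitch <- 30
  pts <- cbind(10 + pitch * t / (2 * pi), 40 + R * sin(t), 40 + R * cos(t))
  spec <- phantom_spec(c(80, 80, 80), c(1, 1, 1),
                       list(list(points = pts, radius_um = 3)),
                       noise_sd = 0, psf_sigma_um = c(0, 0, 0))
  g <- generate_vascular_phantom(spec, 1)
  cl <- extract_centerlines(vessel_mask(g$truth$mask, c(1, 1, 1)))
  expect_length(cl$segments, 1)
  L <- as.numeric(segment_length(cl, 1))
  L_true <- 4 * pi * sqrt(R^2 + (pitch / (2 * pi))^2)
  expect_lt(abs(L - L_true) / L_true, 0.03)
})

test_that("length respects the triangle inequality against endpoint distance", {
  g <- straight_tube_phantom(h = 1)
  cl <- extract_centerlines(vessel_mask(g$truth$mask, c(1, 1, 1)))
  for (i in seq_along(cl$segments)) {
    p <- cl$segments[[i]]
    chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    expect_gte(as.numeric(segment_length(cl, i)) + 1e-9, chord)
  }
})

test_that("inter-vessel distance is midpoint-to-midpoint with a pointwise option", {
  two <- make_graph(list(cbind(0, 0, 0:10), cbind(0, 50, 0:10)))
  expect_equal(inter_vessel_distance(two), c(50, 50))
  # mutual midpoint distances 30/40/60 -> per-segment minima (30, 30, 40)
  m3y <- -55 / 3
  m3x <- sqrt(1600 - m3y^2)
  tri <- make_graph(list(cbind(0, 0, -5:5),
                         cbind(0, 30, -5:5),
                         cbind(0, m3y, m3x + (-5:5))))
  d <- stats::dist(rbind(segment_midpoint(tri, 1), segment_midpoint(tri, 2),
                         segment_midpoint(tri, 3)))
  expect_equal(sort(as.numeric(d)), c(30, 40, 60), tolerance = 1e-9)
  ivd <- inter_vessel_distance(tri)
  expect_equal(ivd, c(30, 30, 40), tolerance = 1e-9)
  one <- make_graph(list(cbind(0, 0, 0:10)))
  expect_true(is.na(inter_vessel_distance(one)))
  # pointwise mode can only shrink distances
  expect_true(all(inter_vessel_distance(tri, mode = "pointwise") <= ivd + 1e-9))
})

test_that("vascular density is the exact vessel volume fraction", {
  vox <- array(TRUE, c(5, 5, 5))
  m <- vessel_mask(vox, c(1, 1, 1))
  roi <- array(TRUE, c(5, 5, 5))
  expect_equal(vascular_density(m, roi)$density, 1)
  m0 <- vessel_mask(array(FALSE, c(5, 5, 5)), c(1, 1, 1))
  expect_equal(vascular_density(m0, roi)$density, 0)
  expect_error(vascular_density(m, array(FALSE, c(5, 5, 5))), "empty ROI")
})

test_that("cylinder density matches the analytic volume fraction within 5%", {
  g <- straight_tube_phantom(h = 1)
  m <- vessel_mask(g$truth$mask, c(1, 1, 1))
  roi <- array(TRUE, dim(g$truth$mask))
  rho <- vascular_density(m, roi)$density
  rho_true <- pi * 25 / (21 * 21)
  expect_lt(abs(rho - rho_true) / rho_true, 0.05)
})

test_that("density is invariant to voxel-spacing rescaling", {
  g <- straight_tube_phantom(h = 1)
  roi <- array(TRUE, dim(g$truth$mask))
  r1 <- vascular_density(vessel_mask(g$truth$mask, c(1, 1, 1)), roi)$density
  r2 <- vascular_density(vessel_mask(g$truth$mask, c(2.5, 2.5, 2.5)), roi)$density
  expect_equal(r1, r2)
})

test_that("D and L are invariant under translation and 90-degree rotation", {
  spec <- phantom_spec(c(60, 60, 60), c(1, 1, 1),
                       list(list(start = c(30, 30, 5), end = c(30, 30, 55),
                                 radius_um = 4)),
                       noise_sd = 0, psf_sigma_um = c(0, 0, 0))
  g <- generate_vascular_phantom(spec, 1)
  base <- g$truth$mask
  cl0 <- extract_centerlines(vessel_mask(base, c(1, 1, 1)))
  # translate by (2, 3, -1) voxels
  tr <- array(FALSE, dim(base))
  tr[3:60, 4:60, 1:59] <- base[1:58, 1:57, 2:60]
  cl1 <- extract_centerlines(vessel_mask(tr, c(1, 1, 1)))
  # rotate 90 degrees: swap y/x axes
  rot <- aperm(base, c(1, 3, 2))
  cl2 <- extract_centerlines(vessel_mask(rot, c(1, 1, 1)))
  for (cl in list(cl1, cl2)) {
    expect_equal(segment_diameter(cl, 1), segment_diameter(cl0, 1),
                 tolerance = 0.05)
    # length tolerance absorbs scan-order-dependent end-cap erosion
    expect_equal(as.numeric(segment_length(cl, 1)),
                 as.numeric(segment_length(cl0, 1)), tolerance = 0.1)
  }
})

test_that("regional summaries follow the declared quartile convention", {
  df <- data.frame(region_label = "A", metric = c(1, 2, 3, 4, 5))
  s <- summarize_regions(df, metric_cols = "metric")
  expect_equal(s$median, 3)
  expect_equal(s$q1, 1.5)
  expect_equal(s$q3, 4.5)
  expect_equal(s$n, 5)
  # two regions with identical data give identical rows
  df2 <- rbind(data.frame(region_label = "A", metric = c(2, 4, 6)),
               data.frame(region_label = "B", metric = c(2, 4, 6)))
  s2 <- summarize_regions(df2, metric_cols = "metric")
  expect_equal(s2$median[1], s2$median[2])
  expect_equal(s2$q1[1], s2$q1[2])
  expect_error(summarize_regions(df, regions = "B"), "unknown region")
})

test_that("region-structured phantoms report the generator's diameters", {
  mk <- function(r) {
    spec <- phantom_spec(c(21, 21, 60), c(1, 1, 1),
                         list(list(start = c(10, 10, -10),
                                   end = c(10, 10, 1e3), radius_um = r)),
                         noise_sd = 0, psf_sigma_um = c(0, 0, 0))
    g <- generate_vascular_phantom(spec, 1)
    cl <- extract_centerlines(vessel_mask(g$truth$mask, c(1, 1, 1)))
    segment_metrics(cl, region_labels = sprintf("r%g", r))
  }
  met <- rbind(mk(2), mk(4))
  s <- summarize_regions(met, metric_cols = "diameter_um")
  expect_equal(s$median[s$region == "r2"], 4, tolerance = 0.15)
  expect_equal(s$median[s$region == "r4"], 8, tolerance = 0.15)
})
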