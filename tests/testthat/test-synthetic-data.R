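test_that("tube rasterization matches the brute-force voxel-in-capsule oracle", {
  spec <- phantom_spec(c(21, 21, 120), c(1, 1, 1),
                       list(list(start = c(10, 10, 5), end = c(10, 10, 105),
                                 radius_um = 5)),
                       noise_sd = 0, psf_sigma_um = c(0, 0, 0))
  g <- generate_vascular_phantom(spec, seed = 1)
  oracle <- oracle_capsule_count(c(21, 21, 120), c(1, 1, 1),
                                 c(10, 10, 5), c(10, 10, 105), 5)
  expect_identical(sum(g$truth$mask), as.integer(oracle))
})

test_that("full-length cylinder volume is within 5% of the analytic value", {
  g <- straight_tube_phantom(h = 1)
  analytic <- pi * 25 * 120 / 1  # r^2 pi * axial extent / voxel volume
  expect_lt(abs(sum(g$truth$mask) - analytic) / analytic, 0.05)
})

test_that("rasterized volume fraction converges with voxel refinement", {
  err <- vapply(c(1, 0.5), function(h) {
    g <- straight_tube_phantom(h = h)
    d <- dim(g$truth$mask)
    frac <- sum(g$truth$mask) / prod(d)
    frac_true <- pi * 25 / (21 * 21)  # tube area over ROI cross-section (um^2)
    abs(frac - frac_true) / frac_true
  }, numeric(1))
  expect_lt(err[2], err[1] * 0.75)
})

test_that("empty segment list yields pure background and an empty truth graph", {
  spec <- phantom_spec(c(8, 8, 8), c(1, 1, 1), list(),
                       background_intensity = 0.2, noise_sd = 0,
                       psf_sigma_um = c(0, 0, 0))
  g <- generate_vascular_phantom(spec, seed = 3)
  expect_true(all(g$stack$data == 0.2))
  expect_length(g$truth$centerlines$segments, 0)
})

test_that("phantom generation is a pure function of (spec, seed)", {
  spec <- phantom_spec(c(10, 12, 14), c(2, 1, 1),
                       list(list(start = c(9, 5, 0), end = c(9, 5, 13),
                                 radius_um = 2)),
                       noise_sd = 0.1)
  g1 <- generate_vascular_phantom(spec, seed = 42)
  g2 <- generate_vascular_phantom(spec, seed = 42)
  expect_identical(g1$stack$data, g2$stack$data)
  g3 <- generate_vascular_phantom(spec, seed = 43)
  expect_false(identical(g1$stack$data, g3$stack$data))
})

test_that("phantom spec validation rejects bad geometry and flags thin tubes", {
  expect_error(phantom_spec(c(8, 8, 8), c(0, 1, 1), list()), "spacing")
  expect_error(phantom_spec(c(8, 8, 8), c(1, 1, 1),
                            list(list(start = c(1, 1, 1), end = c(1, 1, 5),
                                      radius_um = 0))), "radii")
  expect_error(phantom_spec(c(8, 8, 8), c(1, 1, 1), list(),
                            background_intensity = 1, vessel_intensity = 0.5),
               "vessel_intensity")
  spec <- phantom_spec(c(10, 10, 10), c(10, 1, 1),
                       list(list(start = c(45, 5, 0), end = c(45, 5, 9),
                                 radius_um = 2)),
                       psf_sigma_um = c(0, 0, 0))
  expect_warning(g <- generate_vascular_phantom(spec, 1), "unresolvable")
  expect_true(g$truth$unresolvable[1])
})

test_that("one spike convolves to exactly the indicator kernel", {
  k <- indicator_kernel("GCaMP6s", frame_rate_hz = 7)
  spikes <- numeric(200)
  spikes[20] <- 1
  tr <- calcium_from_spikes(spikes, k)[1, ]
  expect_equal(tr[20:(19 + length(k))], unname(k), tolerance = 1e-12)
  expect_lt(max(abs(tr[1:19])), 1e-12)
})

test_that("uncoupled state-free scenes have near-zero mean pairwise correlation", {
  spec <- calcium_scene_spec(n_neurons = 30, n_regions = 3, duration_s = 300,
                             frame_rate_hz = 7, moving_gain = 1,
                             intra_region_coupling = 0, inter_region_coupling = 0,
                             neuropil_coeff = 0, noise_sd = 0.01, seed = 11)
  sc <- generate_calcium_scene(spec)
  dff <- compute_dff(sc$traces)
  cc <- correlation_matrix(dff)
  tt <- ncol(dff$dff)
  expect_lt(abs(mean(cc[upper.tri(cc)])), 3 / sqrt(tt))
})

test_that("null correlation spread matches the autocorrelation-corrected width", {
  spec <- calcium_scene_spec(n_neurons = 40, n_regions = 2, duration_s = 400,
                             frame_rate_hz = 7, moving_gain = 1,
                             intra_region_coupling = 0, inter_region_coupling = 0,
                             neuropil_coeff = 0, noise_sd = 0.01, seed = 21)
  sc <- generate_calcium_scene(spec)
  dff <- compute_dff(sc$traces)
  cc <- correlation_matrix(dff)
  emp <- stats::quantile(abs(cc[upper.tri(cc)]), 0.95)
  # null width for autocorrelated traces: var(r) ~ (1/T) sum_l rho(l)^2, with
  # rho from the indicator kernel (spikes are white)
  k <- indicator_kernel("GCaMP6s", 7)
  rho <- as.numeric(stats::convolve(k, k, conj = TRUE, type = "open"))
  rho <- rho / max(rho)
  t_eff <- ncol(dff$dff) / sum(rho^2)
  null95 <- 1.96 / sqrt(t_eff)
  expect_lt(emp, 2 * null95)
  expect_gt(emp, 0.5 * null95)
})

test_that("region coupling and locomotion gain order the correlations", {
  spec <- calcium_scene_spec(n_neurons = 60, n_regions = 3, duration_s = 600,
                             frame_rate_hz = 7, moving_gain = 3,
                             intra_region_coupling = 0.8,
                             inter_region_coupling = 0.1, seed = 5)
  sc <- generate_calcium_scene(spec)
  dff <- compute_dff(subtract_neuropil(sc$traces, 0.7))
  cc <- correlation_matrix(dff)
  same <- outer(sc$truth$region, sc$truth$region, `==`) & upper.tri(cc)
  diffr <- !outer(sc$truth$region, sc$truth$region, `==`) & upper.tri(cc)
  expect_gt(mean(cc[same]), mean(cc[diffr]))
  ccm <- correlation_matrix(dff, sc$truth$state == "moving")
  ccs <- correlation_matrix(dff, sc$truth$state == "stationary")
  expect_gt(mean(ccm[upper.tri(ccm)]), mean(ccs[upper.tri(ccs)]))
})

test_that("scene generation is deterministic per seed and validates durations", {
  spec <- calcium_scene_spec(n_neurons = 5, duration_s = 60, seed = 9)
  s1 <- generate_calcium_scene(spec)
  s2 <- generate_calcium_scene(spec)
  expect_identical(s1$traces$f, s2$traces$f)
  expect_error(calcium_scene_spec(duration_s = 1, indicator = "GCaMP6s"),
               "decay")
  expect_error(calcium_scene_spec(intra_region_coupling = 0.1,
                                  inter_region_coupling = 0.5), "intra")
})

test_that("bead blobs obey the Gaussian-convolution closed form", {
  # identity: no PSF blur leaves the bead width
  g1 <- generate_bead_stack(c(1e-6, 1e-6, 1e-6), 1.0,
                            positions_um = matrix(c(5, 5, 5), 1),
                            shape_voxels = c(101, 101, 101),
                            spacing_um = c(0.1, 0.1, 0.1))
  expect_equal(g1$truth$observed_fwhm_um, rep(1, 3), tolerance = 1e-6)
  # quadrature: equal PSF and bead FWHM give sqrt(2)
  g2 <- generate_bead_stack(1, 1, positions_um = matrix(c(5, 5, 5), 1),
                            shape_voxels = c(101, 101, 101),
                            spacing_um = c(0.1, 0.1, 0.1))
  expect_equal(g2$truth$observed_fwhm_um, rep(sqrt(2), 3), tolerance = 1e-12)
  prof <- g2$stack$data[, 51, 51]
  fit <- fit_fwhm(prof, 0.1)
  expect_equal(fit$fwhm_um, sqrt(2), tolerance = 0.02)
})

test_that("crowded bead fields raise an overlap warning", {
  expect_warning(
    generate_bead_stack(c(2, 1, 1), 0,
                        positions_um = rbind(c(5, 5, 5), c(5, 5, 8)),
                        shape_voxels = c(41, 41, 41),
                        spacing_um = c(0.27, 0.27, 0.27)),
    "overlap")
})

test_that("pollen-like AO samples are deterministic, bounded and peaked", {
  s1 <- generate_ao_sample(64, 5, seed = 4)
  s2 <- generate_ao_sample(64, 5, seed = 4)
  expect_identical(s1, s2)
  expect_gte(min(s1), 0)
  expect_lte(max(s1), 1)
  expect_error(generate_ao_sample(64, 0), "n_grains")
  sc <- generate_ao_sample(64, 1, seed = 1, centered = TRUE)
  pk <- which(sc == max(sc), arr.ind = TRUE)
  expect_equal(as.numeric(pk[1, ]), c(33, 33))
})
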