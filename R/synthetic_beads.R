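#' Generate a synthetic fluorescent bead z-stack
#'
#' Beads are modeled as 3D Gaussians so the imaged blob is the closed-form
#' Gaussian-Gaussian convolution: per axis,
#' `FWHM_obs = sqrt(FWHM_psf^2 + FWHM_bead^2)`.
#'
#' @param psf_fwhm_um numeric length-3 PSF FWHM `(z, y, x)` in um.
#' @param bead_fwhm_um numeric length-3 (or scalar) bead FWHM in um; use 0
#'   for point-like beads.
#' @param positions_um matrix (n x 3) of bead centres `(z, y, x)` in um.
#' @param shape_voxels integer length-3 stack size `(z, y, x)`.
#' @param spacing_um voxel spacing `(z, y, x)` um; the default z step is
#'   0.27 um (fine axial sampling for PSF measurement).
#' @param amplitude peak intensity per bead.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed (noise only).
#' @return list with `stack` (a [volume_stack()]) and `truth` (per-axis
#'   `psf_fwhm_um`, `bead_fwhm_um`, `observed_fwhm_um`, `positions_um`).
#' @export
generate_bead_stack <- function(psf_fwhm_um, bead_fwhm_um = 0, positions_um,
                                shape_voxels,
                                spacing_um = c(0.27, 0.056, 0.056),
                                amplitude = 1, noise_sd = 0, seed = 1L) {
  set.seed(seed)
  psf_fwhm_um <- rep(as.numeric(psf_fwhm_um), length.out = 3)
  bead_fwhm_um <- rep(as.numeric(bead_fwhm_um), length.out = 3)
  positions_um <- matrix(as.numeric(positions_um), ncol = 3)
  obs_fwhm <- sqrt(psf_fwhm_um^2 + bead_fwhm_um^2)
  if (any(obs_fwhm <= 0)) stop("observed FWHM must be > 0 on every axis")
  if (nrow(positions_um) >= 2) {
    dmin <- min(stats::dist(positions_um))
    if (dmin < 5 * max(obs_fwhm))
      warning(sprintf(
        "beads closer than 5x the largest FWHM (min separation %.2f um): blobs may overlap",
        dmin))
  }
  sigma <- obs_fwhm / (2 * sqrt(2 * log(2)))
  d <- as.integer(shape_voxels); sp <- as.numeric(spacing_um)
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
  img <- array(0, d)
  for (b in seq_len(nrow(positions_um))) {
    p <- positions_um[b, ]
    gz <- exp(-(ax[[1]] - p[1])^2 / (2 * sigma[1]^2))
    gy <- exp(-(ax[[2]] - p[2])^2 / (2 * sigma[2]^2))
    gx <- exp(-(ax[[3]] - p[3])^2 / (2 * sigma[3]^2))
    img <- img + amplitude * outer(outer(gz, gy), gx)
  }
  if (noise_sd > 0) img <- img + array(stats::rnorm(prod(d), sd = noise_sd), d)
  list(stack = volume_stack(img, sp),
       truth = list(psf_fwhm_um = psf_fwhm_um, bead_fwhm_um = bead_fwhm_um,
                    observed_fwhm_um = obs_fwhm, positions_um = positions_um))
}

#' Generate a structured "pollen-like" sample image for AO simulation
#'
#' Sparse bright textured grains on a dark background, normalized to
#' `[0, 1]`; deterministic per seed. Each grain is a Gaussian blob with a
#' smooth multiplicative texture outside its core (the core is untextured,
#' so a single centered grain peaks exactly at its centre).
#'
#' @param size_px image side length in pixels (powers of two recommended
#'   for FFT efficiency).
#' @param n_grains number of grains (> 0).
#' @param seed RNG seed.
#' @param centered if `TRUE` and `n_grains == 1`, place the grain at the
#'   image centre pixel.
#' @return numeric matrix `size_px x size_px` in `[0, 1]`.
#' @export
generate_ao_sample <- function(size_px = 128, n_grains = 12, seed = 1L,
                               centered = FALSE) {
  if (n_grains < 1) stop("n_grains must be >= 1 (uniform samples make the mean-intensity metric degenerate)")
  set.seed(seed)
  img <- matrix(0, size_px, size_px)
  yy <- matrix(seq_len(size_px), size_px, size_px)
  xx <- t(yy)
  if (centered && n_grains == 1) {
    centres <- matrix(c(size_px / 2 + 1, size_px / 2 + 1), 1, 2)
  } else {
    centres <- cbind(stats::runif(n_grains, 0.15, 0.85) * size_px,
                     stats::runif(n_grains, 0.15, 0.85) * size_px)
  }
  for (g in seq_len(n_grains)) {
    sig <- stats::runif(1, size_px / 32, size_px / 16)
    amp <- stats::runif(1, 0.6, 1)
    r2 <- (yy - centres[g, 1])^2 + (xx - centres[g, 2])^2
    blob <- amp * exp(-r2 / (2 * sig^2))
    # smooth texture, damped to 1 inside the grain core
    tex <- matrix(stats::rnorm(size_px^2), size_px)
    tex <- convolve_axis(array(tex, c(size_px, size_px, 1)), smooth_kernel(5), 1)
    tex <- convolve_axis(tex, smooth_kernel(5), 2)[, , 1]
    tex <- (tex - min(tex)) / max(diff(range(tex)), 1e-12)
    mod <- ifelse(r2 <= (sig / 2)^2, 1, 0.6 + 0.4 * tex)
    img <- img + blob * mod
  }
  img <- img - min(img)
  if (max(img) > 0) img <- img / max(img)
  img
}

smooth_kernel <- function(r) {
  k <- stats::dnorm(seq(-r, r), sd = r / 2)
  k / sum(k)
}
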