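#' Noll index to radial/azimuthal order
#'
#' @param j Noll index (>= 1; 1 is piston).
#' @return named integer vector `(n, m)`; `m` carries the trig convention
#'   sign (even j: cosine, odd j: sine).
#' @export
noll_to_nm <- function(j) {
  stopifnot(j >= 1)
  n <- 0L
  j1 <- j - 1L
  while (j1 > n) {
    n <- n + 1L
    j1 <- j1 - n
  }
  m <- (n %% 2L) + 2L * ((j1 + ((n + 1L) %% 2L)) %/% 2L)
  c(n = n, m = m)
}

# RMS-normalized (Noll) Zernike mode on coordinates rho (<=1), theta
zernike_mode <- function(j, rho, theta) {
  nm <- noll_to_nm(j)
  n <- nm["n"]; m <- nm["m"]
  R <- 0
  for (k in 0:((n - m) / 2)) {
    R <- R + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k)) *
      rho^(n - 2 * k)
  }
  if (m == 0) sqrt(n + 1) * R
  else if (j %% 2 == 0) sqrt(2 * (n + 1)) * R * cos(m * theta)
  else sqrt(2 * (n + 1)) * R * sin(m * theta)
}

#' Zernike basis stack over the unit pupil
#'
#' Modes are Noll-indexed starting at index 2 (piston excluded) and
#' RMS-normalized: a unit coefficient gives unit RMS phase over the pupil.
#'
#' @param n_modes number of modes (Noll 2 .. n_modes + 1).
#' @param grid_px pupil grid size in pixels.
#' @return list with `basis` (pixels-in-pupil x n_modes matrix), `mask`
#'   (logical grid, inside unit disc), `grid_px`.
#' @export
zernike_basis <- function(n_modes, grid_px) {
  n_max <- noll_to_nm(n_modes + 1L)["n"]
  if (grid_px < 4 * n_max)
    stop(sprintf("grid too coarse for mode order %d: need >= %d px (4 px per fringe at the pupil edge)",
                 n_max, 4 * n_max))
  ax <- seq(-1, 1, length.out = grid_px)
  xx <- matrix(ax, grid_px, grid_px)
  yy <- t(xx)
  rho <- sqrt(xx^2 + yy^2)
  theta <- atan2(yy, xx)
  mask <- rho <= 1
  basis <- vapply(seq_len(n_modes) + 1L,
                  function(j) zernike_mode(j, rho[mask], theta[mask]),
                  numeric(sum(mask)))
  list(basis = basis, mask = mask, grid_px = grid_px)
}

#' Pupil phase map from Zernike coefficients
#'
#' `phase = sum_k c_k Z_k(rho, theta)` on the unit disc, zero outside.
#' Coefficients are in radians RMS, Noll-indexed from 2 (piston excluded).
#'
#' @param coeffs numeric coefficient vector (element 1 = Noll index 2).
#' @param grid_px pupil grid size, or a precomputed [zernike_basis()].
#' @return `grid_px x grid_px` phase map (radians).
#' @export
zernike_phase <- function(coeffs, grid_px = 64L) {
  zb <- if (is.list(grid_px)) grid_px else zernike_basis(length(coeffs), grid_px)
  if (ncol(zb$basis) < length(coeffs)) stop("basis has fewer modes than coefficients")
  ph <- matrix(0, zb$grid_px, zb$grid_px)
  if (length(coeffs))
    ph[zb$mask] <- as.numeric(zb$basis[, seq_along(coeffs), drop = FALSE] %*% coeffs)
  ph
}

#' Pupil field container
#'
#' @param grid_px pupil grid size.
#' @param phase phase map (radians), `grid_px x grid_px`.
#' @param na numerical aperture.
#' @param wavelength_um excitation wavelength (um), default 0.92.
#' @return an object of class `PupilField` (circular amplitude mask plus
#'   phase).
#' @export
pupil_field <- function(grid_px = 64L, phase = NULL, na = 0.5,
                        wavelength_um = 0.92) {
  ax <- seq(-1, 1, length.out = grid_px)
  rho <- sqrt(outer(ax^2, ax^2, `+`))
  amp <- (rho <= 1) * 1
  if (is.null(phase)) phase <- matrix(0, grid_px, grid_px)
  stopifnot(identical(dim(phase), dim(amp)))
  if (any(!is.finite(phase[amp > 0]))) stop("phase must be finite inside the pupil")
  structure(list(grid_px = grid_px, amplitude = amp, phase = phase,
                 na = na, wavelength_um = wavelength_um),
            class = "PupilField")
}

fftshift2 <- function(m) {
  d <- dim(m)
  s <- floor(d / 2)
  m[c((s[1] + 1):d[1], 1:s[1]), c((s[2] + 1):d[2], 1:s[2])]
}

#' Two-photon point spread function from a pupil field
#'
#' Scalar Fourier-optics focal intensity: `PSF_1p = |FFT(A e^{i phi})|^2`
#' normalized to unit sum (unit focal energy). The two-photon excitation
#' distribution is `PSF_1p^2`; its raw sum (`excitation`) measures total
#' two-photon signal and falls as aberrations spread the focus. The `psf`
#' field holds the unit-sum-normalized two-photon PSF for shape metrics.
#'
#' @param pupil a [pupil_field()].
#' @param pad_factor zero-padding factor (>= 2 to avoid aliasing).
#' @return an object of class `TwoPhotonPsf`: list with `psf` (normalized
#'   2p PSF), `psf_onephoton`, `excitation` (= sum(PSF_1p^2)), `strehl`
#'   (peak of PSF_1p over the flat-phase peak), `grid_px`.
#' @export
two_photon_psf <- function(pupil, pad_factor = 2L) {
  stopifnot(inherits(pupil, "PupilField"))
  if (pad_factor < 2) stop("pad_factor must be >= 2 (unpadded pupils alias)")
  n <- pupil$grid_px
  np <- n * pad_factor
  fld <- matrix(0 + 0i, np, np)
  fld[1:n, 1:n] <- pupil$amplitude * exp(1i * pupil$phase)
  psf1 <- Mod(stats::fft(fld))^2
  psf1 <- fftshift2(psf1 / sum(psf1))
  # flat-phase reference for the Strehl ratio (same amplitude mask)
  fld0 <- matrix(0 + 0i, np, np)
  fld0[1:n, 1:n] <- pupil$amplitude
  psf1_0 <- Mod(stats::fft(fld0))^2
  strehl <- max(psf1) * sum(psf1_0) / (max(psf1_0) * 1)
  psf2_raw <- psf1^2
  structure(list(psf = psf2_raw / sum(psf2_raw), psf_onephoton = psf1,
                 excitation = sum(psf2_raw), strehl = strehl,
                 grid_px = np),
            class = "TwoPhotonPsf")
}

#' Simulate a two-photon image and its feedback metric
#'
#' The image is the sample convolved with the *unnormalized* two-photon
#' excitation kernel `PSF_1p^2`, so total fluorescence (and the mean-
#' intensity feedback metric) falls as aberration spreads the focus.
#' Optional Poisson photon noise at a configured photon budget and Gaussian
#' read noise.
#'
#' @param sample numeric matrix in `[0, 1]` (e.g. [generate_ao_sample()]),
#'   same size as the PSF grid.
#' @param psf a [two_photon_psf()] result.
#' @param photon_budget expected photon count for a unit-intensity pixel at
#'   the diffraction limit; `NULL` = noiseless.
#' @param read_noise_sd Gaussian read noise SD (photon units).
#' @param seed optional RNG seed for the noise.
#' @return list with `image` and `metric` (mean pixel intensity).
#' @export
simulate_image <- function(sample, psf, photon_budget = NULL,
                           read_noise_sd = 0, seed = NULL) {
  stopifnot(inherits(psf, "TwoPhotonPsf"))
  if (!is.null(photon_budget) && photon_budget <= 0)
    stop("photon budget must be positive")
  if (!all(dim(sample) == psf$grid_px))
    stop("sample and PSF grids are incompatible")
  kernel <- psf$psf * psf$excitation          # unnormalized PSF_1p^2
  img <- Re(stats::fft(stats::fft(sample) * stats::fft(fftshift2(kernel)),
                       inverse = TRUE)) / length(sample)
  img <- pmax(img, 0)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(photon_budget)) {
    img <- stats::rpois(length(img), img * photon_budget) / photon_budget
    dim(img) <- c(psf$grid_px, psf$grid_px)
  }
  if (read_noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), sd = read_noise_sd),
                        nrow(img))
  list(image = img, metric = mean(img))
}

#' Sensorless modal adaptive-optics optimization (simulation)
#'
#' Modes are optimized sequentially in Noll order: each mode's correction
#' coefficient is stepped over `steps` evenly spaced values spanning
#' `[-scan_range, scan_range]`, the tested coefficient with the peak
#' feedback metric is selected, and the accumulated corrections are
#' incorporated into all subsequent scans. The feedback metric is the mean
#' image intensity of the sample seen through the current total aberration.
#'
#' The `cycles` repetitions can be spent two ways:
#' * `strategy = "sweep"` (default): each cycle is a full pass over all
#'   modes. Later passes re-scan every mode against the already-corrected
#'   wavefront, which removes the inter-mode coupling error that a single
#'   pass leaves at large aberration amplitudes (the metric's conditional
#'   optimum for one mode shifts while other modes are still aberrated).
#' * `strategy = "average"`: all `cycles` scans of one mode are taken
#'   back-to-back and their metric curves averaged pointwise before
#'   selecting the peak — pure noise mitigation, one pass over modes.
#'
#' Both spend exactly `n_scanned_modes x steps x cycles` transitions.
#'
#' @param sample structured sample image (matrix), side = `grid_px *
#'   pad_factor`.
#' @param true_aberration numeric Zernike coefficients (radians RMS, Noll
#'   from 2) of the injected aberration.
#' @param n_modes number of modes to optimize (>= length of the aberration).
#' @param steps scan points per cycle (odd, so 0 is tested).
#' @param cycles number of scan repetitions averaged per mode.
#' @param scan_range half-width of the symmetric scan interval (radians).
#' @param photon_budget,read_noise_sd noise model (see [simulate_image()]);
#'   `NULL` budget = noiseless.
#' @param seed RNG seed for the noise.
#' @param grid_px pupil grid size; `pad_factor` zero-padding factor.
#' @param include_tip_tilt scan the tip/tilt modes (Noll 2-3) too. Off by
#'   default: they only translate the focus, so an intensity metric carries
#'   no information about them (like piston); scanning them under noise
#'   would pick an arbitrary image shift.
#' @param strategy `"sweep"` (cycles = full passes over all modes) or
#'   `"average"` (cycles = repeated scans per mode, curves averaged).
#' @return an object of class `AoResult`: `corrected` (chosen corrections),
#'   `residual` (true + corrections), `metric_trajectory`, `transitions`
#'   (= n_modes * steps * cycles), `scans` (per-mode averaged curves),
#'   `range_limited` flag, `metric_initial`, `metric_final`.
#' @export
sensorless_optimize <- function(sample, true_aberration, n_modes = NULL,
                                steps = 21L, cycles = 5L, scan_range = 1.5,
                                photon_budget = NULL, read_noise_sd = 0,
                                seed = 1L, grid_px = 64L, pad_factor = 2L,
                                include_tip_tilt = FALSE,
                                strategy = c("sweep", "average")) {
  strategy <- match.arg(strategy)
  if (steps %% 2 == 0) stop("steps must be odd so that 0 is a tested grid point")
  if (scan_range <= 0) stop("scan_range must be positive and symmetric about 0")
  if (is.null(n_modes)) n_modes <- length(true_aberration)
  true <- rep(0, n_modes)
  true[seq_along(true_aberration)] <- true_aberration
  range_limited <- any(abs(true) > scan_range)
  scan_idx <- if (include_tip_tilt) seq_len(n_modes)
              else setdiff(seq_len(n_modes), 1:2)  # coeff 1,2 = Noll 2,3
  if (!include_tip_tilt && any(true[intersect(1:2, seq_len(n_modes))] != 0))
    warning("tip/tilt aberration present but not scanned (invisible to the intensity metric)")

  zb <- zernike_basis(n_modes, grid_px)
  fs <- stats::fft(sample)
  set.seed(seed)
  eval_metric <- function(coeffs) {
    ph <- zernike_phase(coeffs, zb)
    pp <- pupil_field(grid_px, ph)
    psf <- two_photon_psf(pp, pad_factor)
    kernel <- psf$psf * psf$excitation
    img <- Re(stats::fft(fs * stats::fft(fftshift2(kernel)), inverse = TRUE)) /
      length(sample)
    img <- pmax(img, 0)
    if (!is.null(photon_budget)) {
      img <- stats::rpois(length(img), img * photon_budget) / photon_budget
    }
    if (read_noise_sd > 0)
      img <- img + stats::rnorm(length(img), sd = read_noise_sd)
    mean(img)
  }

  corr <- rep(0, n_modes)
  scan_vals <- seq(-scan_range, scan_range, length.out = steps)
  trajectory <- numeric(0)
  scans <- vector("list", n_modes)
  metric_initial <- eval_metric(true)

  scan_one <- function(k, n_rep) {
    curves <- matrix(0, n_rep, steps)
    for (cy in seq_len(n_rep)) {
      for (s in seq_len(steps)) {
        test <- corr
        test[k] <- scan_vals[s]
        m <- eval_metric(true + test)
        curves[cy, s] <- m
        trajectory <<- c(trajectory, m)
      }
    }
    avg <- colMeans(curves)
    # accept the maximizer; on (numerical) ties prefer the smallest correction
    near <- which(avg >= max(avg) * (1 - 1e-9))
    corr[k] <<- scan_vals[near[which.min(abs(scan_vals[near]))]]
    scans[[k]] <<- data.frame(coefficient = scan_vals, metric = avg)
    invisible(NULL)
  }
  if (strategy == "average") {
    for (k in scan_idx) scan_one(k, cycles)
  } else {
    for (cy in seq_len(cycles)) for (k in scan_idx) scan_one(k, 1L)
  }
  metric_final <- eval_metric(true + corr)
  structure(list(corrected = corr, residual = true + corr,
                 metric_trajectory = trajectory,
                 transitions = length(scan_idx) * steps * cycles,
                 scans = scans, range_limited = range_limited,
                 metric_initial = metric_initial,
                 metric_final = metric_final,
                 scan_range = scan_range, steps = steps, cycles = cycles),
            class = "AoResult")
}

#' @export
print.AoResult <- function(x, ...) {
  cat(sprintf("AoResult: %d modes, %d transitions, residual RMS %.3f rad (metric %.4g -> %.4g)%s\n",
              length(x$corrected), x$transitions,
              sqrt(sum(x$residual^2)), x$metric_initial, x$metric_final,
              if (x$range_limited) " [range-limited]" else ""))
  invisible(x)
}

#' Number of coefficient transitions of a modal scan
#'
#' Each scanned mode is stepped over `steps` values in each of `cycles`
#' passes, one image per coefficient transition:
#' `transitions = n_modes x steps x cycles`.
#'
#' @param n_modes number of scanned modes.
#' @param steps scan points per cycle.
#' @param cycles number of cycles.
#' @return total transition count.
#' @export
ao_transition_count <- function(n_modes, steps = 21L, cycles = 5L) {
  as.numeric(n_modes) * steps * cycles
}

#' Root-mean-square of a Zernike coefficient vector (radians)
#' @param coeffs coefficient vector (RMS-normalized modes).
#' @return total RMS wavefront error.
#' @export
zernike_rms <- function(coeffs) sqrt(sum(coeffs^2))
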