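#' Specification of a synthetic calcium imaging scene
#'
#' Describes a population of neurons grouped into cortical regions whose
#' spiking is driven by region-shared latent drives. Pairwise signal
#' correlation is `intra_region_coupling` within a region and
#' `inter_region_coupling` across regions at the latent level; during
#' "moving" locomotion epochs the shared drives are multiplied by
#' `moving_gain`, raising both activity and correlations, as in
#' state-dependent cortical dynamics.
#'
#' @param n_neurons number of neurons.
#' @param n_regions number of regions (neurons split evenly).
#' @param region_centers_um optional list/matrix of region centres `(y, x)`
#'   um; default: centres spaced 1500 um apart on a line.
#' @param frame_rate_hz imaging frame rate (Hz).
#' @param duration_s recording duration (s).
#' @param indicator `"GCaMP6s"` (rise 0.18 s, decay 1.5 s) or `"GCaMP6f"`
#'   (rise 0.08 s, decay 0.4 s).
#' @param base_rate_hz baseline spike rate per neuron.
#' @param moving_gain multiplier applied to the shared drives during moving
#'   frames (1 = state-independent).
#' @param intra_region_coupling,inter_region_coupling latent correlation
#'   levels, `intra >= inter >= 0`.
#' @param neuropil_coeff neuropil contamination coefficient in `[0, 1)`.
#' @param noise_sd per-frame fluorescence noise SD (fraction of baseline).
#' @param scatter_um SD of neuron scatter around its region centre (um).
#' @param target_moving_frac fraction of time in the moving state.
#' @param seed RNG seed stored in the spec (generation uses it).
#' @return a `CalciumSceneSpec` list.
#' @export
calcium_scene_spec <- function(n_neurons = 60, n_regions = 3,
                               region_centers_um = NULL,
                               frame_rate_hz = 7, duration_s = 600,
                               indicator = c("GCaMP6s", "GCaMP6f"),
                               base_rate_hz = 0.4, moving_gain = 3,
                               intra_region_coupling = 0.8,
                               inter_region_coupling = 0.1,
                               neuropil_coeff = 0.7, noise_sd = 0.02,
                               scatter_um = 150, target_moving_frac = 0.3,
                               seed = 1L) {
  indicator <- match.arg(indicator)
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be > 0")
  if (!(intra_region_coupling >= inter_region_coupling &&
        inter_region_coupling >= 0))
    stop("need intra_region_coupling >= inter_region_coupling >= 0")
  if (neuropil_coeff < 0 || neuropil_coeff >= 1)
    stop("neuropil_coeff must be in [0, 1)")
  kin <- indicator_kinetics(indicator)
  if (duration_s < kin["decay_s"])
    stop("duration shorter than one indicator decay constant")
  if (is.null(region_centers_um)) {
    region_centers_um <- cbind(rep(0, n_regions),
                               (seq_len(n_regions) - 1) * 1500)
  }
  structure(list(n_neurons = n_neurons, n_regions = n_regions,
                 region_centers_um = region_centers_um,
                 frame_rate_hz = frame_rate_hz, duration_s = duration_s,
                 indicator = indicator, base_rate_hz = base_rate_hz,
                 moving_gain = moving_gain,
                 intra_region_coupling = intra_region_coupling,
                 inter_region_coupling = inter_region_coupling,
                 neuropil_coeff = neuropil_coeff, noise_sd = noise_sd,
                 scatter_um = scatter_um,
                 target_moving_frac = target_moving_frac, seed = seed),
            class = "CalciumSceneSpec")
}

#' Indicator kinetics (rise/decay time constants, s)
#' @param indicator `"GCaMP6s"` or `"GCaMP6f"`.
#' @return named numeric `(rise_s, decay_s)`.
#' @export
indicator_kinetics <- function(indicator = c("GCaMP6s", "GCaMP6f")) {
  indicator <- match.arg(indicator)
  if (indicator == "GCaMP6s") c(rise_s = 0.18, decay_s = 1.5)
  else c(rise_s = 0.08, decay_s = 0.4)
}

#' Difference-of-exponentials calcium indicator kernel
#'
#' `k(t) = exp(-t/decay) - exp(-t/rise)`, normalized to unit peak, sampled
#' at the frame rate out to 5 decay constants.
#'
#' @param indicator `"GCaMP6s"` or `"GCaMP6f"`.
#' @param frame_rate_hz sampling rate (Hz).
#' @return numeric kernel vector (first sample at t = 0).
#' @export
indicator_kernel <- function(indicator = c("GCaMP6s", "GCaMP6f"),
                             frame_rate_hz = 7) {
  kin <- indicator_kinetics(match.arg(indicator))
  t <- seq(0, 5 * kin["decay_s"], by = 1 / frame_rate_hz)
  k <- exp(-t / kin["decay_s"]) - exp(-t / kin["rise_s"])
  k / max(k)
}

#' Convolve spike trains with an indicator kernel
#'
#' @param spikes matrix (neurons x frames) of spike counts, or a vector.
#' @param kernel indicator kernel from [indicator_kernel()].
#' @return matrix of calcium signals, same shape as `spikes`.
#' @export
calcium_from_spikes <- function(spikes, kernel) {
  if (is.vector(spikes)) spikes <- matrix(spikes, nrow = 1)
  t(apply(spikes, 1, function(s) {
    out <- stats::convolve(s, rev(kernel), type = "open")
    out[seq_along(s)]
  }))
}

#' Generate a two-state locomotion speed trace
#'
#' A semi-Markov alternation of stationary and moving bouts (exponential
#' bout durations) with speeds emulating an air-floating platform:
#' stationary ~1.2 mm/s, moving ~70-90 mm/s.
#'
#' @param n_frames number of frames.
#' @param frame_rate_hz frame rate (Hz).
#' @param target_moving_frac expected fraction of moving frames.
#' @param mean_stationary_bout_s mean stationary bout duration (s).
#' @return list with `speed_mm_s`, `state` (character), `frame_rate_hz`.
#' @export
generate_locomotion <- function(n_frames, frame_rate_hz,
                                target_moving_frac = 0.3,
                                mean_stationary_bout_s = 30) {
  mean_moving <- mean_stationary_bout_s * target_moving_frac /
    (1 - target_moving_frac)
  state <- character(0)
  cur <- "stationary"
  while (length(state) < n_frames) {
    mu <- if (cur == "stationary") mean_stationary_bout_s else mean_moving
    len <- max(1L, round(stats::rexp(1, 1 / mu) * frame_rate_hz))
    state <- c(state, rep(cur, len))
    cur <- if (cur == "stationary") "moving" else "stationary"
  }
  state <- state[seq_len(n_frames)]
  speed <- numeric(n_frames)
  st <- state == "stationary"
  speed[st] <- abs(stats::rnorm(sum(st), mean = 1.2, sd = 1.26))
  speed[!st] <- pmax(15, stats::rnorm(sum(!st), mean = 80, sd = 45))
  list(speed_mm_s = speed, state = state, frame_rate_hz = frame_rate_hz)
}

# smooth unit-variance latent drive: low-pass filtered white noise
smooth_drive <- function(n_frames, frame_rate_hz, tau_s = 0.5) {
  a <- exp(-1 / (tau_s * frame_rate_hz))
  x <- stats::filter(stats::rnorm(n_frames), a, method = "recursive")
  x <- as.numeric(x) * sqrt(1 - a^2)
  (x - mean(x)) / stats::sd(x)
}

#' Generate a synthetic calcium scene (trace level)
#'
#' Spikes are drawn from inhomogeneous Poisson processes whose rates follow
#' a mixture of a global drive, a region-shared drive, and a private drive,
#' weighted so that the latent correlation is `intra_region_coupling` within
#' and `inter_region_coupling` across regions. Shared drives are multiplied
#' by `moving_gain` during moving frames. Spike trains are convolved with
#' the indicator kernel; a neuropil signal (low-pass-filtered population
#' average) contaminates each measured trace at `neuropil_coeff`.
#'
#' @param spec a [calcium_scene_spec()].
#' @return list with `traces` (a [fluorescence_traces()]), `truth` (spikes,
#'   somatic signal, state mask), `locomotion` (speed trace).
#' @export
generate_calcium_scene <- function(spec) {
  stopifnot(inherits(spec, "CalciumSceneSpec"))
  set.seed(spec$seed)
  fr <- spec$frame_rate_hz
  nt <- round(spec$duration_s * fr)
  nn <- spec$n_neurons
  region <- rep(seq_len(spec$n_regions), length.out = nn)
  region <- sort(region)

  loco <- generate_locomotion(nt, fr, spec$target_moving_frac)
  moving <- loco$state == "moving"
  gain <- ifelse(moving, spec$moving_gain, 1)

  g <- smooth_drive(nt, fr)                      # global drive
  R <- vapply(seq_len(spec$n_regions), function(r) smooth_drive(nt, fr),
              numeric(nt))                       # region drives
  w_g <- sqrt(spec$inter_region_coupling)
  w_r <- sqrt(spec$intra_region_coupling - spec$inter_region_coupling)
  w_p <- sqrt(1 - spec$intra_region_coupling)

  kern <- indicator_kernel(spec$indicator, fr)
  spikes <- matrix(0L, nn, nt)
  for (i in seq_len(nn)) {
    e <- smooth_drive(nt, fr)
    u <- gain * (w_g * g + w_r * R[, region[i]]) + w_p * e
    lam <- spec$base_rate_hz * pmax(0, 1 + u) / fr
    spikes[i, ] <- stats::rpois(nt, lam)
  }
  s <- calcium_from_spikes(spikes, kern)         # somatic signal, unit peak/spike

  npil <- as.numeric(stats::filter(colMeans(s),
                                   exp(-1 / (2 * fr)), method = "recursive"))
  npil <- npil * (1 - exp(-1 / (2 * fr)))
  f0 <- 100
  f_meas <- f0 * (1 + s + spec$neuropil_coeff *
                    matrix(npil, nn, nt, byrow = TRUE))
  if (spec$noise_sd > 0)
    f_meas <- f_meas + f0 * matrix(stats::rnorm(nn * nt, sd = spec$noise_sd), nn, nt)
  f_npil <- f0 * (1 + matrix(npil, nn, nt, byrow = TRUE))

  pos <- spec$region_centers_um[region, , drop = FALSE] +
    matrix(stats::rnorm(2 * nn, sd = spec$scatter_um), nn, 2)

  traces <- fluorescence_traces(f = f_meas, f_neuropil = f_npil,
                                frame_rate_hz = fr, positions_um = pos,
                                region_labels = paste0("R", region))
  list(traces = traces,
       truth = list(spikes = spikes, somatic = s, state = loco$state,
                    region = region),
       locomotion = loco)
}

#' Render a calcium scene as a pixel movie
#'
#' Rasterizes a (small) calcium scene into a movie: each neuron is a disk
#' ROI whose pixels carry the measured somatic fluorescence; all other
#' pixels carry the neuropil signal; optional per-pixel Gaussian noise.
#'
#' @param spec a [calcium_scene_spec()] (keep `n_neurons` modest).
#' @param fov_px movie frame size in pixels (square).
#' @param roi_radius_px ROI disk radius in pixels.
#' @param pixel_noise_sd per-pixel additive noise SD (fluorescence units).
#' @return list with `movie` (frames x y x x array), `roi_masks` (list of
#'   logical matrices), `scene` (the output of [generate_calcium_scene()]).
#' @export
generate_calcium_movie <- function(spec, fov_px = 64, roi_radius_px = 2,
                                   pixel_noise_sd = 0) {
  scene <- generate_calcium_scene(spec)
  nn <- spec$n_neurons
  nt <- ncol(scene$traces$f)
  # lay ROIs on a grid with margins
  side <- ceiling(sqrt(nn))
  cent <- expand.grid(y = seq_len(side), x = seq_len(side))[seq_len(nn), ]
  cent <- round(cbind(cent$y, cent$x) / (side + 1) * fov_px)
  roi_masks <- vector("list", nn)
  yy <- matrix(seq_len(fov_px), fov_px, fov_px)
  xx <- t(yy)
  for (i in seq_len(nn)) {
    roi_masks[[i]] <- (yy - cent[i, 1])^2 + (xx - cent[i, 2])^2 <=
      roi_radius_px^2
  }
  any_roi <- Reduce(`|`, roi_masks)
  f0 <- 100
  npil_px <- scene$traces$f_neuropil[1, ]  # shared neuropil field level
  movie <- array(0, c(nt, fov_px, fov_px))
  for (t in seq_len(nt)) {
    fr_img <- matrix(npil_px[t] - f0 * (1 - spec$neuropil_coeff), fov_px, fov_px)
    for (i in seq_len(nn)) fr_img[roi_masks[[i]]] <- scene$traces$f[i, t]
    movie[t, , ] <- fr_img
  }
  if (pixel_noise_sd > 0)
    movie <- movie + array(stats::rnorm(length(movie), sd = pixel_noise_sd),
                           dim(movie))
  list(movie = movie, roi_masks = roi_masks, scene = scene)
}
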