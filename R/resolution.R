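#' Ring-sampling field-of-view layout
#'
#' Resolution is characterized at the field centre and at points along
#' three concentric rings (radii 1.33, 2.66 and 3.99 mm) sampled every 45
#' degrees: 25 positions in total.
#'
#' @param ring_radii_mm ring radii (mm).
#' @param angle_step_deg angular sampling step (degrees).
#' @return an object of class `FovLayout`: data.frame with `label`,
#'   `radius_mm`, `angle_deg`, `x_mm`, `y_mm`.
#' @export
fov_positions <- function(ring_radii_mm = c(1.33, 2.66, 3.99),
                          angle_step_deg = 45) {
  angles <- seq(0, 360 - angle_step_deg, by = angle_step_deg)
  rows <- data.frame(label = "center", radius_mm = 0, angle_deg = 0,
                     x_mm = 0, y_mm = 0)
  ring_names <- LETTERS[seq_along(ring_radii_mm) + 1]  # rings B, C, D ...
  for (i in seq_along(ring_radii_mm)) {
    r <- ring_radii_mm[i]
    rows <- rbind(rows, data.frame(
      label = paste0("ring_", ring_names[i]),
      radius_mm = r, angle_deg = angles,
      x_mm = r * cos(angles * pi / 180),
      y_mm = r * sin(angles * pi / 180)))
  }
  structure(rows, class = c("FovLayout", "data.frame"))
}

#' Fit a Gaussian to a 1D intensity profile and report its FWHM
#'
#' Least-squares fit of `A * exp(-(x - mu)^2 / (2 sigma^2)) + offset`;
#' `FWHM = 2 sqrt(2 ln 2) sigma`.
#'
#' @param profile numeric intensity profile (single dominant peak, >= 7
#'   samples).
#' @param spacing_um sample spacing (um).
#' @param min_r2 minimum fit R-squared; poorer fits raise an error carrying
#'   the diagnostics.
#' @return an object of class `FwhmFit`: list with `fwhm_um`, `sigma_um`,
#'   `mu_um`, `amplitude`, `offset`, `r_squared`.
#' @export
fit_fwhm <- function(profile, spacing_um, min_r2 = 0.5) {
  y <- as.numeric(profile)
  if (length(y) < 7) stop("profile needs at least 7 samples across the peak")
  x <- (seq_along(y) - 1) * spacing_um
  off0 <- min(y)
  a0 <- max(y) - off0
  if (a0 <= 0) stop("flat profile: no peak to fit")
  mu0 <- x[which.max(y)]
  above <- which(y - off0 > a0 / 2)
  sig0 <- max(spacing_um, (x[max(above)] - x[min(above)]) / 2.3548)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)) + off,
                      start = list(A = a0, mu = mu0, sigma = sig0, off = off0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop(sprintf("Gaussian fit failed to converge: %s",
                                     conditionMessage(e))))
  p <- stats::coef(fit)
  resid <- y - stats::predict(fit)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  if (!is.finite(r2) || r2 < min_r2)
    stop(sprintf("Gaussian fit rejected: R^2 = %.3f (A = %.3g, sigma = %.3g um)",
                 r2, p["A"], abs(p["sigma"])))
  sigma <- abs(unname(p["sigma"]))
  structure(list(fwhm_um = 2 * sqrt(2 * log(2)) * sigma, sigma_um = sigma,
                 mu_um = unname(p["mu"]), amplitude = unname(p["A"]),
                 offset = unname(p["off"]), r_squared = r2),
            class = "FwhmFit")
}

#' Characterize PSF resolution from a bead z-stack
#'
#' Beads are detected as local intensity maxima above a prominence
#' threshold (or supplied), refined to sub-voxel positions by per-axis
#' quadratic interpolation; x, y and z line profiles through each peak are
#' fit with [fit_fwhm()]. Beads within `border_fwhm_mult` FWHM of the stack
#' border are excluded from the summary.
#'
#' @param stack a [volume_stack()].
#' @param bead_positions optional n x 3 matrix of voxel indices (1-based,
#'   `(z, y, x)`) to use instead of detection.
#' @param prominence detection threshold as a fraction of the intensity
#'   range above background.
#' @param profile_halfwidth_um half-length of the fitted profile per axis
#'   (um); default: the full axis. Profiles assume no second bead sits on
#'   the same axis line through the peak (generic bead fields); restrict
#'   the halfwidth for regular grids of beads.
#' @param border_fwhm_mult border exclusion margin in units of the fitted
#'   FWHM.
#' @return list with `fits` (per-bead data.frame: per-axis FWHM and R^2)
#'   and `summary` (per-axis mean and SD over beads).
#' @export
characterize_stack <- function(stack, bead_positions = NULL, prominence = 0.3,
                               profile_halfwidth_um = NULL,
                               border_fwhm_mult = 3) {
  stopifnot(inherits(stack, "VolumeStack"))
  arr <- stack$data; sp <- stack$spacing_um; d <- dim(arr)
  if (is.null(bead_positions)) {
    bg <- stats::median(arr)
    thr <- bg + prominence * (max(arr) - bg)
    if (max(arr) <= bg) stop("no beads detected (flat stack)")
    if (max(arr) - bg < 5 * stats::mad(arr))
      stop("no beads detected (no maxima prominent above the noise floor)")
    cand <- which(arr > thr)
    if (!length(cand)) stop("no beads detected above the prominence threshold")
    lab <- label3d_cpp(array(arr > thr, d))
    nlab <- max(lab)
    bead_positions <- t(vapply(seq_len(nlab), function(l) {
      idx <- which(lab == l)
      arrayInd(idx[which.max(arr[idx])], d)[1, ]
    }, numeric(3)))
  }
  bead_positions <- matrix(as.numeric(bead_positions), ncol = 3)
  if (nrow(bead_positions) < 1) stop("no beads to characterize")

  fits <- list()
  for (b in seq_len(nrow(bead_positions))) {
    pk <- refine_peak(arr, bead_positions[b, ])
    row <- list(bead = b, z_vox = pk[1], y_vox = pk[2], x_vox = pk[3])
    ok <- TRUE
    for (ax in 1:3) {
      prof <- axis_profile(arr, round(pk), ax, profile_halfwidth_um, sp)
      ft <- tryCatch(fit_fwhm(prof, sp[ax]), error = function(e) NULL)
      axis_name <- c("z", "y", "x")[ax]
      if (is.null(ft)) {
        row[[paste0("fwhm_", axis_name, "_um")]] <- NA_real_
        row[[paste0("r2_", axis_name)]] <- NA_real_
        ok <- FALSE
      } else {
        row[[paste0("fwhm_", axis_name, "_um")]] <- ft$fwhm_um
        row[[paste0("r2_", axis_name)]] <- ft$r_squared
        # border exclusion: peak too close to the stack edge on this axis
        lim_um <- (d[ax] - 1) * sp[ax]
        pos_um <- (pk[ax] - 1) * sp[ax]
        if (pos_um < border_fwhm_mult * ft$fwhm_um ||
            lim_um - pos_um < border_fwhm_mult * ft$fwhm_um)
          ok <- FALSE
      }
    }
    row$included <- ok
    fits[[b]] <- as.data.frame(row)
  }
  fits <- do.call(rbind, fits)
  if (all(is.na(fits$fwhm_z_um) & is.na(fits$fwhm_y_um) & is.na(fits$fwhm_x_um)))
    stop("no usable bead fits (no bead profile converged)")
  inc <- fits[fits$included, , drop = FALSE]
  if (!nrow(inc)) inc <- fits
  summary <- data.frame(
    axis = c("z", "y", "x"),
    mean_fwhm_um = c(mean(inc$fwhm_z_um, na.rm = TRUE),
                     mean(inc$fwhm_y_um, na.rm = TRUE),
                     mean(inc$fwhm_x_um, na.rm = TRUE)),
    sd_fwhm_um = c(stats::sd(inc$fwhm_z_um, na.rm = TRUE),
                   stats::sd(inc$fwhm_y_um, na.rm = TRUE),
                   stats::sd(inc$fwhm_x_um, na.rm = TRUE)),
    n = nrow(inc))
  list(fits = fits, summary = summary)
}

# quadratic sub-voxel refinement of a local maximum, per axis
refine_peak <- function(arr, pos) {
  d <- dim(arr)
  pos <- as.numeric(pos)
  out <- pos
  for (ax in 1:3) {
    i <- pos[ax]
    if (i <= 1 || i >= d[ax]) next
    idx <- function(k) {
      p <- pos; p[ax] <- k
      arr[p[1], p[2], p[3]]
    }
    y0 <- idx(i - 1); y1 <- idx(i); y2 <- idx(i + 1)
    den <- y0 - 2 * y1 + y2
    if (den < 0) out[ax] <- i + 0.5 * (y0 - y2) / den
  }
  out
}

axis_profile <- function(arr, pos, axis, halfwidth_um, spacing) {
  d <- dim(arr)
  if (is.null(halfwidth_um)) {
    n_half <- d[axis]  # whole axis
  } else {
    n_half <- ceiling(halfwidth_um / spacing[axis])
  }
  rng <- max(1, pos[axis] - n_half):min(d[axis], pos[axis] + n_half)
  if (axis == 1) arr[rng, pos[2], pos[3]]
  else if (axis == 2) arr[pos[1], rng, pos[3]]
  else arr[pos[1], pos[2], rng]
}

#' Analytic system geometry of a circular field of view
#'
#' `area = pi (d/2)^2`; `volume = area x depth`; the spatial bandwidth
#' product is the FOV area in um^2 divided by the square of the lateral
#' resolution element.
#'
#' @param fov_diameter_mm FOV diameter (mm).
#' @param depth_mm accessible imaging depth (mm).
#' @param lateral_res_um lateral resolution element (um).
#' @return list with `area_mm2`, `volume_mm3`, `sbp`, and `rounded`
#'   (area/volume to 2 decimals, sbp to 3 significant figures).
#' @export
system_geometry <- function(fov_diameter_mm = 8, depth_mm = 0.9,
                            lateral_res_um = 1.0) {
  if (fov_diameter_mm <= 0 || depth_mm <= 0 || lateral_res_um <= 0)
    stop("all geometry inputs must be positive")
  area <- pi * (fov_diameter_mm / 2)^2
  volume <- area * depth_mm
  sbp <- area * 1e6 / lateral_res_um^2
  list(area_mm2 = area, volume_mm3 = volume, sbp = sbp,
       rounded = list(area_mm2 = round(area, 2), volume_mm3 = round(volume, 2),
                      sbp = signif(sbp, 3)))
}
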