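#' Specification of a synthetic vascular phantom
#'
#' Describes a tubular phantom emulating a mesoscale vascular z-stack:
#' a voxel grid with anisotropic spacing (the imaging configuration this
#' emulates uses ~1.67 um lateral pitch and a 10 um z-step) and a list of
#' straight or polyline tube segments with known radii.
#'
#' @param shape_voxels integer length-3 grid size `(z, y, x)`.
#' @param spacing_um numeric length-3 voxel spacing `(z, y, x)` in um.
#' @param segments list of tubes; each a list with `start` and `end`
#'   (length-3 um positions, `(z, y, x)`) and `radius_um` (> 0). A tube may
#'   instead carry `points`, an n x 3 polyline (um), for curved vessels.
#' @param background_intensity,vessel_intensity intensity levels
#'   (`vessel_intensity > background_intensity`).
#' @param noise_sd additive Gaussian noise SD.
#' @param psf_sigma_um Gaussian blur applied after rasterization, sigma in
#'   um `(z, y, x)`; default a sub-voxel optical blur.
#' @return a `PhantomSpec` list.
#' @export
phantom_spec <- function(shape_voxels, spacing_um, segments,
                         background_intensity = 0.1, vessel_intensity = 1,
                         noise_sd = 0, psf_sigma_um = c(0.5, 0.5, 0.5)) {
  spacing_um <- as.numeric(spacing_um)
  if (any(spacing_um <= 0)) stop("spacing components must be > 0")
  if (vessel_intensity <= background_intensity)
    stop("vessel_intensity must exceed background_intensity")
  for (sg in segments) {
    if (is.null(sg$radius_um) || sg$radius_um <= 0) stop("all tube radii must be > 0")
  }
  structure(list(shape_voxels = as.integer(shape_voxels), spacing_um = spacing_um,
                 segments = segments, background_intensity = background_intensity,
                 vessel_intensity = vessel_intensity, noise_sd = noise_sd,
                 psf_sigma_um = psf_sigma_um),
            class = "PhantomSpec")
}

#' Generate a vascular phantom stack with ground truth
#'
#' Rasterizes each tube (a voxel is vessel iff its centre lies within the
#' tube radius of the tube axis), applies a small Gaussian optical blur, and
#' adds Gaussian noise. The ground truth carries the exact axes, radii, and
#' the noise-free rasterized mask.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed; generation is a pure function of
#'   `(spec, seed)`.
#' @return list with `stack` (a [volume_stack()]) and `truth` (list with
#'   `centerlines` (a `CenterlineGraph` of the true axes), `mask` (logical
#'   array), `radii_um`, `unresolvable` flag per tube).
#' @export
generate_vascular_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "PhantomSpec"))
  set.seed(seed)
  d <- spec$shape_voxels; sp <- spec$spacing_um
  mask <- array(FALSE, d)
  zs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  xs <- (seq_len(d[3]) - 1) * sp[3]

  true_segments <- list(); true_radii <- list(); unresolvable <- logical(0)
  for (sg in spec$segments) {
    pts <- if (!is.null(sg$points)) as.matrix(sg$points)
           else rbind(as.numeric(sg$start), as.numeric(sg$end))
    r <- sg$radius_um
    mask <- mask | rasterize_polyline_tube(pts, r, zs, ys, xs)
    # resample the true axis at ~min-spacing pitch for the ground truth
    true_segments[[length(true_segments) + 1L]] <- resample_polyline(pts, min(sp))
    true_radii[[length(true_radii) + 1L]] <-
      rep(r, nrow(true_segments[[length(true_segments)]]))
    unresolvable <- c(unresolvable, r < max(sp) / 2)
  }
  if (any(unresolvable))
    warning(sprintf("%d tube(s) thinner than half the largest voxel spacing may be unresolvable",
                    sum(unresolvable)))

  img <- array(spec$background_intensity, d)
  img[mask] <- spec$vessel_intensity
  if (any(spec$psf_sigma_um > 0))
    img <- gaussian_blur3d(img, spec$psf_sigma_um, sp)
  if (spec$noise_sd > 0)
    img <- img + array(stats::rnorm(prod(d), sd = spec$noise_sd), d)

  truth <- list(
    centerlines = structure(list(segments = true_segments, radii = true_radii,
                                 branch_points = matrix(numeric(0), 0, 3),
                                 spacing_um = sp,
                                 flags = rep("", length(true_segments))),
                            class = "CenterlineGraph"),
    mask = mask,
    radii_um = vapply(spec$segments, function(s) s$radius_um, numeric(1)),
    unresolvable = unresolvable)
  list(stack = volume_stack(img, sp), truth = truth)
}

# voxel-centre-in-tube rasterization of a polyline tube, restricted to the
# tube's bounding box for speed
rasterize_polyline_tube <- function(pts, radius, zs, ys, xs) {
  mask <- array(FALSE, c(length(zs), length(ys), length(xs)))
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    lo <- pmin(a, b) - radius; hi <- pmax(a, b) + radius
    iz <- which(zs >= lo[1] & zs <= hi[1])
    iy <- which(ys >= lo[2] & ys <= hi[2])
    ix <- which(xs >= lo[3] & xs <= hi[3])
    if (!length(iz) || !length(iy) || !length(ix)) next
    g <- expand.grid(z = zs[iz], y = ys[iy], x = xs[ix])
    p <- as.matrix(g)[, c("z", "y", "x"), drop = FALSE]
    u <- b - a
    len2 <- sum(u^2)
    if (len2 == 0) {
      dd <- sqrt(rowSums(sweep(p, 2, a, `-`)^2))
    } else {
      t <- pmin(1, pmax(0, (sweep(p, 2, a, `-`) %*% u) / len2))
      proj <- sweep(t %*% t(u), 2, a, `+`)
      dd <- sqrt(rowSums((p - proj)^2))
    }
    inside <- array(FALSE, c(length(iz), length(iy), length(ix)))
    inside[] <- dd <= radius
    mask[iz, iy, ix] <- mask[iz, iy, ix] | inside
  }
  mask
}

# resample a polyline at roughly equal arc-length pitch
resample_polyline <- function(pts, pitch) {
  if (nrow(pts) == 1) return(pts)
  seglen <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- seq(0, total, by = max(pitch, total / 10000))
  if (s[length(s)] < total) s <- c(s, total)
  out <- matrix(0, length(s), 3)
  for (k in seq_along(s)) {
    i <- max(which(cum <= s[k] + 1e-12))
    if (i >= nrow(pts)) { out[k, ] <- pts[nrow(pts), ]; next }
    f <- (s[k] - cum[i]) / seglen[i]
    out[k, ] <- pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
  }
  out
}
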