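#' 3D intensity volume with physical voxel spacing
#'
#' The basic image container used throughout the package: a numeric 3D array
#' in `(z, y, x)` axis order together with the voxel spacing in microns.
#' Voxel indices are 0-based in physical terms: the centre of voxel
#' `[i, j, k]` (1-based R index) sits at `((i-1)*dz, (j-1)*dy, (k-1)*dx)` um.
#'
#' @param data numeric 3D array, axis order `(z, y, x)`.
#' @param spacing_um numeric length-3, voxel spacing `(z, y, x)` in microns.
#' @return An object of class `VolumeStack`.
#' @export
volume_stack <- function(data, spacing_um) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) || any(spacing_um <= 0))
    stop("`spacing_um` must be 3 positive finite values (z, y, x)")
  structure(list(data = data, spacing_um = spacing_um), class = "VolumeStack")
}

#' @export
print.VolumeStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("VolumeStack: %d x %d x %d voxels (z,y,x), spacing %s um\n",
              d[1], d[2], d[3], paste(signif(x$spacing_um, 4), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.VolumeStack <- function(x) dim(x$data)

#' Physical coordinates (um) of voxel indices
#'
#' @param idx integer matrix (n x 3) of 1-based voxel indices `(z, y, x)`.
#' @param spacing_um voxel spacing `(z, y, x)` in um.
#' @return numeric matrix (n x 3) of voxel-centre positions in um.
#' @keywords internal
voxel_to_um <- function(idx, spacing_um) {
  sweep(idx - 1, 2, spacing_um, `*`)
}

#' Anisotropic Euclidean distance transform
#'
#' For every voxel, the physical distance (um) to the centre of the nearest
#' background voxel, honouring anisotropic spacing (exact separable EDT).
#'
#' @param mask logical 3D array; `TRUE` = foreground.
#' @param spacing_um voxel spacing `(z, y, x)` in um.
#' @return numeric 3D array of distances in um (0 on background).
#' @export
distance_transform <- function(mask, spacing_um) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  edt3d_cpp(mask, as.numeric(spacing_um))
}

#' Write a volume as a multi-page TIFF
#'
#' Writes one 32-bit float page per z-slice plus a small JSON sidecar
#' (`<path>.meta.json`) recording the voxel spacing so
#' [read_volume_tiff()] can restore it.
#'
#' @param vol a [volume_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "VolumeStack"))
  pages <- lapply(seq_len(dim(vol$data)[1]), function(z) vol$data[z, , , drop = TRUE])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  jsonlite::write_json(list(spacing_um = vol$spacing_um, unit = "micron"),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_volume_tiff()]
#'
#' @param path TIFF file path.
#' @param spacing_um optional spacing override; if `NULL`, read from the
#'   JSON sidecar written by [write_volume_tiff()] (error if absent).
#' @return a [volume_stack()].
#' @export
read_volume_tiff <- function(path, spacing_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (is.null(spacing_um)) {
    meta <- paste0(path, ".meta.json")
    if (!file.exists(meta))
      stop("no spacing sidecar found; pass `spacing_um`")
    spacing_um <- as.numeric(unlist(jsonlite::read_json(meta)$spacing_um))
  }
  d2 <- dim(pages[[1]])
  arr <- array(0, dim = c(length(pages), d2[1], d2[2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  volume_stack(arr, spacing_um)
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Sigma is given in physical um per axis and converted to voxels via the
#' spacing; axes with zero sigma are left untouched. Reflective boundaries.
#'
#' @param arr numeric 3D array `(z, y, x)`.
#' @param sigma_um numeric length-3 Gaussian sigma in um `(z, y, x)`.
#' @param spacing_um voxel spacing `(z, y, x)` in um.
#' @return smoothed array, same dim.
#' @export
gaussian_blur3d <- function(arr, sigma_um, spacing_um) {
  sig_vox <- sigma_um / spacing_um
  out <- arr
  for (ax in 1:3) {
    s <- sig_vox[ax]
    if (!is.finite(s) || s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  out
}

# 1D convolution along one axis with reflective padding
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1L) %/% 2L
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  n <- nrow(m)
  ipad <- c(pmin(n, (r + 1):2), 1:n, pmax(1L, (n - 1):(n - r)))
  mp <- m[ipad, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  res <- array(out, dim = da)
  aperm(res, order(perm))
}
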