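#' Raw fluorescence traces container
#'
#' @param f neurons x frames matrix of ROI-averaged fluorescence.
#' @param f_neuropil optional matrix of the same shape: neuropil traces.
#' @param frame_rate_hz imaging frame rate (Hz).
#' @param positions_um neurons x 2 matrix of ROI centroids (um).
#' @param region_labels per-neuron region labels.
#' @return an object of class `FluorescenceTraces`.
#' @export
fluorescence_traces <- function(f, f_neuropil = NULL, frame_rate_hz,
                                positions_um = NULL, region_labels = NULL) {
  f <- as.matrix(f)
  if (!is.null(f_neuropil)) {
    f_neuropil <- as.matrix(f_neuropil)
    if (!identical(dim(f_neuropil), dim(f)))
      stop("f_neuropil must match the shape of f")
  }
  if (!is.null(positions_um)) {
    positions_um <- as.matrix(positions_um)
    if (any(!is.finite(positions_um))) stop("positions must be finite")
  }
  structure(list(f = f, f_neuropil = f_neuropil,
                 frame_rate_hz = frame_rate_hz,
                 positions_um = positions_um,
                 region_labels = region_labels),
            class = "FluorescenceTraces")
}

#' dF/F traces container
#' @param dff neurons x frames matrix of dF/F.
#' @param f0 per-neuron baseline fluorescence (> 0).
#' @param frame_rate_hz frame rate (Hz).
#' @param positions_um neurons x 2 centroids (um).
#' @param region_labels per-neuron labels.
#' @return an object of class `DffTraces`.
#' @export
dff_traces <- function(dff, f0, frame_rate_hz, positions_um = NULL,
                       region_labels = NULL) {
  dff <- as.matrix(dff)
  if (any(f0 <= 0)) stop("every f0 must be > 0")
  if (any(!is.finite(dff))) stop("dff must be finite")
  structure(list(dff = dff, f0 = f0, frame_rate_hz = frame_rate_hz,
                 positions_um = positions_um, region_labels = region_labels),
            class = "DffTraces")
}

#' Extract ROI-averaged fluorescence traces from a movie
#'
#' Per frame, the trace value is the mean of the pixels inside the ROI; the
#' neuropil trace is the mean over an annulus around the ROI bounding disk,
#' excluding all ROI pixels.
#'
#' @param movie frames x y x x numeric array.
#' @param roi_masks list of logical y x x matrices (one per ROI).
#' @param annulus_px inner and outer annulus margins in pixels beyond the
#'   ROI radius, `c(inner, outer)`.
#' @param frame_rate_hz frame rate carried into the result.
#' @param positions_um,region_labels optional metadata carried through.
#' @return a [fluorescence_traces()].
#' @export
extract_traces <- function(movie, roi_masks, annulus_px = c(2, 6),
                           frame_rate_hz = 7, positions_um = NULL,
                           region_labels = NULL) {
  stopifnot(length(dim(movie)) == 3L)
  nn <- length(roi_masks)
  nt <- dim(movie)[1]
  d2 <- dim(movie)[c(2, 3)]
  any_roi <- Reduce(`|`, roi_masks)
  flat <- matrix(movie, nrow = nt)  # frames x pixels (column-major y,x)
  f <- matrix(0, nn, nt)
  fn <- matrix(0, nn, nt)
  yy <- matrix(seq_len(d2[1]), d2[1], d2[2])
  xx <- t(matrix(seq_len(d2[2]), d2[2], d2[1]))
  for (i in seq_len(nn)) {
    m <- roi_masks[[i]]
    if (!identical(dim(m), d2)) stop(sprintf("ROI %d does not match movie frame size", i))
    if (!any(m)) stop(sprintf("ROI %d is empty", i))
    f[i, ] <- rowMeans(flat[, which(m), drop = FALSE])
    cy <- mean(yy[m]); cx <- mean(xx[m])
    r_roi <- sqrt(max((yy[m] - cy)^2 + (xx[m] - cx)^2))
    rr <- sqrt((yy - cy)^2 + (xx - cx)^2)
    ann <- rr > r_roi + annulus_px[1] & rr <= r_roi + annulus_px[2] & !any_roi
    if (!any(ann)) ann <- rr <= r_roi + annulus_px[2] & !any_roi
    fn[i, ] <- if (any(ann)) rowMeans(flat[, which(ann), drop = FALSE]) else 0
  }
  fluorescence_traces(f, fn, frame_rate_hz, positions_um, region_labels)
}

#' Subtract the neuropil component from somatic traces
#'
#' `f_corrected = f - coeff * f_neuropil`. If the correction drives any
#' trace at or below zero, a constant offset is added to keep the minimum
#' above a small positive floor; the adjustment is recorded in the
#' `offset_applied` attribute.
#'
#' @param traces a [fluorescence_traces()] with neuropil traces.
#' @param coeff contamination coefficient in `[0, 1)`.
#' @param floor_value minimum allowed corrected fluorescence.
#' @return a [fluorescence_traces()] with corrected `f` (neuropil dropped).
#' @export
subtract_neuropil <- function(traces, coeff = 0.7, floor_value = 1e-6) {
  stopifnot(inherits(traces, "FluorescenceTraces"))
  if (is.null(traces$f_neuropil)) stop("no neuropil traces present")
  if (coeff < 0 || coeff >= 1) stop("coeff must be in [0, 1)")
  fc <- traces$f - coeff * traces$f_neuropil
  offset <- 0
  if (min(fc) <= floor_value) {
    offset <- floor_value - min(fc)
    fc <- fc + offset
  }
  out <- fluorescence_traces(fc, NULL, traces$frame_rate_hz,
                             traces$positions_um, traces$region_labels)
  attr(out, "offset_applied") <- offset
  out
}

#' Compute dF/F with a percentile baseline
#'
#' `dF/F = (f - f0) / f0`, with `f0` the given percentile (default 15th) of
#' each neuron's entire recording, computed with linear interpolation
#' between order statistics.
#'
#' @param traces a [fluorescence_traces()].
#' @param percentile baseline percentile in (0, 100).
#' @return a [dff_traces()].
#' @export
compute_dff <- function(traces, percentile = 15) {
  stopifnot(inherits(traces, "FluorescenceTraces"))
  f0 <- apply(traces$f, 1, stats::quantile, probs = percentile / 100,
              type = 7, names = FALSE)
  if (any(f0 <= 0)) {
    bad <- which(f0 <= 0)
    stop(sprintf("non-positive baseline f0 for neuron(s) %s (possible neuropil over-subtraction)",
                 paste(bad, collapse = ", ")))
  }
  dff <- sweep(sweep(traces$f, 1, f0, `-`), 1, f0, `/`)
  dff_traces(dff, f0, traces$frame_rate_hz, traces$positions_um,
             traces$region_labels)
}

#' Transient-based signal-to-noise ratio of dF/F traces
#'
#' Declared contract: transients are excursions above
#' `median + k * MAD` lasting at least `min_frames` frames; SNR is the mean
#' transient peak amplitude (above the median) divided by the SD of the
#' trace with transient frames removed. Neurons with no detected transient
#' get SNR 0 and a flag.
#'
#' @param dff a [dff_traces()] (>= 100 frames).
#' @param k MAD multiplier for transient detection.
#' @param min_frames minimum transient duration in frames.
#' @return data.frame with `snr`, `n_transients`, `flag` per neuron.
#' @export
compute_snr <- function(dff, k = 3, min_frames = 2L) {
  stopifnot(inherits(dff, "DffTraces"))
  if (ncol(dff$dff) < 100) stop("SNR needs at least 100 frames")
  res <- t(apply(dff$dff, 1, function(x) {
    med <- stats::median(x)
    thr <- med + k * stats::mad(x)
    above <- x > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    tr <- which(r$values & r$lengths >= min_frames)
    if (!length(tr)) return(c(snr = 0, n = 0))
    in_transient <- logical(length(x))
    peaks <- vapply(tr, function(j) {
      in_transient[starts[j]:ends[j]] <<- TRUE
      max(x[starts[j]:ends[j]]) - med
    }, numeric(1))
    noise_sd <- stats::sd(x[!in_transient])
    c(snr = mean(peaks) / noise_sd, n = length(tr))
  }))
  data.frame(snr = res[, "snr"], n_transients = res[, "n"],
             flag = ifelse(res[, "n"] == 0, "no transients", ""))
}

#' Pairwise Pearson correlation matrix of dF/F traces
#'
#' @param dff a [dff_traces()].
#' @param frame_mask optional logical (or integer) frame selector; must keep
#'   at least 30 frames.
#' @return symmetric correlation matrix with unit diagonal; rows/columns of
#'   zero-variance traces are set to `NA` (excluded downstream).
#' @export
correlation_matrix <- function(dff, frame_mask = NULL) {
  stopifnot(inherits(dff, "DffTraces"))
  x <- dff$dff
  if (!is.null(frame_mask)) x <- x[, frame_mask, drop = FALSE]
  if (ncol(x) < 30) stop("frame selection keeps fewer than 30 frames")
  v <- apply(x, 1, stats::var)
  zero <- v == 0 | !is.finite(v)
  cc <- suppressWarnings(stats::cor(t(x)))
  if (any(zero)) {
    message(sprintf("%d zero-variance trace(s) excluded from correlations",
                    sum(zero)))
    cc[zero, ] <- NA_real_
    cc[, zero] <- NA_real_
  }
  diag(cc)[!zero] <- 1
  cc
}

#' Binned correlation-versus-distance profile
#'
#' @param corr symmetric correlation matrix.
#' @param positions_um neurons x 2 centroid matrix (um).
#' @param bin_width_um distance bin width (um), > 0.
#' @return data.frame per bin `[k*w, (k+1)*w)`: `bin_lo`, `bin_hi`,
#'   `mean_r`, `sd_r`, `n_pairs` (empty bins emitted with `n_pairs = 0`).
#' @export
correlation_vs_distance <- function(corr, positions_um, bin_width_um = 50) {
  if (bin_width_um <= 0) stop("bin width must be > 0")
  positions_um <- as.matrix(positions_um)
  n <- nrow(corr)
  iu <- which(upper.tri(corr), arr.ind = TRUE)
  d <- sqrt(rowSums((positions_um[iu[, 1], , drop = FALSE] -
                       positions_um[iu[, 2], , drop = FALSE])^2))
  r <- corr[iu]
  nb <- floor(max(d) / bin_width_um) + 1L
  bin <- pmin(nb, floor(d / bin_width_um) + 1L)
  out <- data.frame(bin_lo = (seq_len(nb) - 1) * bin_width_um,
                    bin_hi = seq_len(nb) * bin_width_um,
                    mean_r = NA_real_, sd_r = NA_real_, n_pairs = 0L)
  for (b in seq_len(nb)) {
    rb <- r[bin == b & !is.na(r)]
    out$n_pairs[b] <- length(rb)
    if (length(rb)) {
      out$mean_r[b] <- mean(rb)
      out$sd_r[b] <- stats::sd(rb)
    }
  }
  out
}

#' Number of unordered neuron pairs
#'
#' `n(n-1)/2`: the number of cross-correlation pairs among `n` cells.
#'
#' @param n number of cells (>= 2).
#' @return the pair count (numeric, exact for n well beyond 1e5).
#' @export
count_pairs <- function(n) {
  if (n < 2) stop("need at least 2 cells")
  n <- as.numeric(n)
  n * (n - 1) / 2
}
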