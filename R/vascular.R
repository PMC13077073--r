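#' Binary vessel mask
#'
#' @param voxels logical 3D array `(z, y, x)`; `TRUE` = vessel.
#' @param spacing_um voxel spacing `(z, y, x)` in um.
#' @return an object of class `VesselMask`.
#' @export
vessel_mask <- function(voxels, spacing_um) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !is.logical(voxels))
    stop("`voxels` must be a logical 3D array")
  structure(list(voxels = voxels, spacing_um = as.numeric(spacing_um)),
            class = "VesselMask")
}

#' Preprocessing options for vascular stacks
#'
#' Each step can be switched off independently. Steps are applied in order:
#' per-slice adaptive histogram equalization, min-max normalization to
#' `[0, 1]`, Gaussian denoising, per-slice rigid translation registration to
#' the middle slice. Crosstalk and dura removal are documented no-ops in
#' single-channel data and only emit a notice when requested.
#'
#' @param equalize,normalize,denoise,register logical switches.
#' @param crosstalk_removal,dura_removal logical; no-op placeholders.
#' @param denoise_sigma_um Gaussian sigma `(z, y, x)` in um for denoising.
#' @return a named list of options.
#' @export
preprocess_options <- function(equalize = TRUE, normalize = TRUE,
                               denoise = TRUE, register = TRUE,
                               crosstalk_removal = FALSE, dura_removal = FALSE,
                               denoise_sigma_um = c(0, 1, 1)) {
  list(equalize = equalize, normalize = normalize, denoise = denoise,
       register = register, crosstalk_removal = crosstalk_removal,
       dura_removal = dura_removal, denoise_sigma_um = denoise_sigma_um)
}

#' Preprocess a vascular image stack
#'
#' @param stack a [volume_stack()].
#' @param options a [preprocess_options()] list.
#' @return a preprocessed [volume_stack()].
#' @export
preprocess_stack <- function(stack, options = preprocess_options()) {
  stopifnot(inherits(stack, "VolumeStack"))
  arr <- stack$data
  if (length(dim(arr)) != 3L) stop("preprocess_stack expects a 3D stack")
  if (isTRUE(options$crosstalk_removal))
    message("crosstalk removal requested: no-op on single-channel data")
  if (isTRUE(options$dura_removal))
    message("dura removal requested: no-op (no reference channel)")

  if (isTRUE(options$equalize)) {
    rng <- range(arr)
    if (diff(rng) > 0) {
      sc <- (arr - rng[1]) / diff(rng)
      for (z in seq_len(dim(arr)[1])) {
        sl <- sc[z, , , drop = TRUE]
        eq <- EBImage::clahe(EBImage::Image(sl), nx = 4L, ny = 4L)
        sc[z, , ] <- EBImage::imageData(eq)
      }
      arr <- sc
    }
  }
  if (isTRUE(options$normalize)) {
    rng <- range(arr)
    arr <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else array(0, dim(arr))
  }
  if (isTRUE(options$denoise)) {
    arr <- gaussian_blur3d(arr, options$denoise_sigma_um, stack$spacing_um)
  }
  if (isTRUE(options$register)) {
    arr <- register_slices(arr)
  }
  volume_stack(arr, stack$spacing_um)
}

# Per-slice integer rigid translation to the middle slice via phase
# correlation; shifted-in borders are zero-filled.
register_slices <- function(arr) {
  nz <- dim(arr)[1]
  ref <- arr[ceiling(nz / 2), , , drop = TRUE]
  fr <- stats::fft(ref)
  for (z in seq_len(nz)) {
    sl <- arr[z, , , drop = TRUE]
    cc <- Re(stats::fft(fr * Conj(stats::fft(sl)), inverse = TRUE))
    pk <- arrayInd(which.max(cc), dim(cc)) - 1L
    sh <- ifelse(pk > dim(cc) / 2, pk - dim(cc), pk)  # (dy, dx) to apply
    arr[z, , ] <- shift2d(sl, sh[1], sh[2])
  }
  arr
}

shift2d <- function(m, dy, dx) {
  out <- matrix(0, nrow(m), ncol(m))
  ys <- seq_len(nrow(m)) - dy; xs <- seq_len(ncol(m)) - dx
  ok_y <- ys >= 1 & ys <= nrow(m); ok_x <- xs >= 1 & xs <= ncol(m)
  out[which(ok_y), which(ok_x)] <- m[ys[ok_y], xs[ok_x]]
  out
}

#' Global Otsu threshold of an intensity array
#'
#' @param x numeric array or vector.
#' @param nbins number of histogram bins.
#' @return the threshold value (between-class variance maximizer).
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)), nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Segment vessels by thresholding
#'
#' A classical intensity-threshold segmenter with small-object removal;
#' stands in front of the centerline/morphometry pipeline for synthetic
#' phantoms with separable intensities.
#'
#' @param stack a [volume_stack()] (typically preprocessed).
#' @param method `"otsu"` (global Otsu) or `"fixed"`.
#' @param threshold threshold value, required for `method = "fixed"`.
#' @param min_size_voxels connected components smaller than this are removed.
#' @param keep_components if finite, keep only the N largest components.
#' @return a [vessel_mask()].
#' @export
segment_vessels <- function(stack, method = c("otsu", "fixed"), threshold = NULL,
                            min_size_voxels = 27L, keep_components = Inf) {
  stopifnot(inherits(stack, "VolumeStack"))
  method <- match.arg(method)
  thr <- if (method == "fixed") {
    if (is.null(threshold)) stop("`threshold` required for method = 'fixed'")
    threshold
  } else {
    otsu_threshold(stack$data)
  }
  vox <- stack$data > thr
  if (any(vox) && (min_size_voxels > 1L || is.finite(keep_components))) {
    lab <- label3d_cpp(vox)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_size_voxels)
    if (is.finite(keep_components) && length(keep) > keep_components)
      keep <- keep[order(sizes[keep], decreasing = TRUE)][seq_len(keep_components)]
    vox <- array(lab %in% keep, dim(vox))
  }
  if (!any(vox))
    stop(sprintf("segmentation produced an empty foreground (threshold used: %.6g)", thr))
  vessel_mask(vox, stack$spacing_um)
}

#' Extract a branch-decomposed centerline graph from a vessel mask
#'
#' 3D homotopic thinning of the mask followed by decomposition of the
#' skeleton at branch points (voxels with >= 3 skeleton neighbours). The
#' per-point radius is the anisotropic Euclidean distance (um) from the
#' centerline voxel to the nearest background voxel. Branch voxels are
#' appended to adjacent segments for geometric continuity but carry `NA`
#' radius so junctions do not inflate diameters.
#'
#' @param mask a [vessel_mask()].
#' @param min_segment_voxels segments with fewer interior skeleton voxels
#'   are dropped as skeletonization spurs (unless nothing else remains).
#' @param smooth_window odd moving-average window (points) applied to the
#'   segment coordinates; damps the voxel staircase that would otherwise
#'   inflate arc lengths of oblique or curved vessels. 1 = off. Endpoints
#'   are preserved.
#' @return an object of class `CenterlineGraph` with elements `segments`
#'   (list of n x 3 um coordinate matrices, `(z, y, x)`), `radii` (list of
#'   per-point radii, um), `branch_points` (m x 3 um), `flags`.
#' @export
extract_centerlines <- function(mask, min_segment_voxels = 3L,
                                smooth_window = 5L) {
  stopifnot(inherits(mask, "VesselMask"))
  vox <- mask$voxels; sp <- mask$spacing_um
  if (!any(vox)) stop("cannot extract centerlines from an empty mask")
  edt <- edt3d_cpp(vox, sp)
  skel <- skeletonize3d_cpp(vox, edt)
  idx <- which(skel, arr.ind = TRUE)  # (z, y, x), 1-based
  n <- nrow(idx)
  d <- dim(vox)
  lin <- idx[, 1] + d[1] * ((idx[, 2] - 1) + d[2] * (idx[, 3] - 1))
  id_of <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(lin[i]), i, envir = id_of)

  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  adj <- vector("list", n)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nl <- nb[ok, 1] + d[1] * ((nb[ok, 2] - 1) + d[2] * (nb[ok, 3] - 1))
    who <- which(ok)
    for (m in seq_along(who)) {
      j <- id_of[[as.character(nl[m])]]
      if (!is.null(j)) adj[[who[m]]] <- c(adj[[who[m]]], j)
    }
  }
  deg <- lengths(adj)
  is_branch <- deg >= 3L

  pos_um <- voxel_to_um(idx, sp)
  rad <- edt[lin]

  # branch clusters -> junction coordinates (centroid of each 26-connected
  # cluster of branch voxels)
  branch_xyz <- matrix(numeric(0), 0, 3)
  if (any(is_branch)) {
    bid <- which(is_branch)
    comp <- components_of(bid, adj)
    branch_xyz <- do.call(rbind, lapply(comp, function(cc)
      colMeans(pos_um[cc, , drop = FALSE])))
  }

  # segments: connected components of non-branch skeleton voxels
  nb_ids <- which(!is_branch)
  segments <- list(); radii <- list(); flags <- character(0)
  if (length(nb_ids)) {
    comp <- components_of(nb_ids, adj, restrict = !is_branch)
    for (cc in comp) {
      path <- order_path(cc, adj, is_branch)
      pts <- pos_um[path, , drop = FALSE]
      rr <- rad[path]
      fl <- if (length(path) == 1L && deg[path] == 0L) "degenerate" else ""
      # attach adjacent branch voxels at the ends for geometric continuity
      ends <- c(path[1], path[length(path)])
      for (e in c(1, 2)) {
        bnb <- adj[[ends[e]]][is_branch[adj[[ends[e]]]]]
        if (length(bnb)) {
          b <- bnb[1]
          if (e == 1) { pts <- rbind(pos_um[b, ], pts); rr <- c(NA_real_, rr) }
          else { pts <- rbind(pts, pos_um[b, ]); rr <- c(rr, NA_real_) }
        }
      }
      if (smooth_window > 1L && nrow(pts) > smooth_window)
        pts <- smooth_polyline(pts, smooth_window)
      segments[[length(segments) + 1L]] <- unname(pts)
      radii[[length(radii) + 1L]] <- rr
      flags <- c(flags, fl)
      attr(segments[[length(segments)]], "n_interior") <- length(cc)
    }
  }
  n_int <- vapply(segments, function(s) attr(s, "n_interior"), numeric(1))
  keep <- n_int >= min_segment_voxels | flags == "degenerate"
  if (!any(keep)) keep[which.max(n_int)] <- TRUE  # never return an empty graph
  if (any(!keep))
    message(sprintf("dropped %d short skeleton spur(s) (< %d voxels)",
                    sum(!keep), min_segment_voxels))
  structure(list(segments = segments[keep], radii = radii[keep],
                 branch_points = branch_xyz, spacing_um = sp,
                 flags = flags[keep]),
            class = "CenterlineGraph")
}

# centered moving average of polyline coordinates; endpoints kept fixed
smooth_polyline <- function(pts, w) {
  if (w %% 2 == 0) w <- w + 1L
  k <- rep(1 / w, w)
  out <- apply(pts, 2, function(v) {
    sm <- as.numeric(stats::filter(v, k, sides = 2))
    sm[is.na(sm)] <- v[is.na(sm)]
    sm
  })
  out[1, ] <- pts[1, ]
  out[nrow(pts), ] <- pts[nrow(pts), ]
  out
}

# connected components of `ids` under adjacency `adj`, optionally restricted
# to nodes where `restrict` is TRUE
components_of <- function(ids, adj, restrict = NULL) {
  inset <- logical(length(adj)); inset[ids] <- TRUE
  seen <- logical(length(adj))
  out <- list()
  for (s in ids) {
    if (seen[s]) next
    comp <- integer(0); stack <- s; seen[s] <- TRUE
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      comp <- c(comp, u)
      for (v in adj[[u]]) {
        if (inset[v] && !seen[v] &&
            (is.null(restrict) || restrict[v])) {
          seen[v] <- TRUE; stack <- c(stack, v)
        }
      }
    }
    out[[length(out) + 1L]] <- comp
  }
  out
}

# order a component of non-branch skeleton voxels into a path
order_path <- function(cc, adj, is_branch) {
  if (length(cc) == 1L) return(cc)
  inset <- logical(length(adj)); inset[cc] <- TRUE
  degl <- vapply(cc, function(u) sum(inset[adj[[u]]]), numeric(1))
  start <- cc[which(degl <= 1)[1]]
  if (is.na(start)) start <- cc[1]  # cycle: arbitrary start
  path <- start; prev <- -1L; cur <- start
  repeat {
    nxt <- setdiff(adj[[cur]][inset[adj[[cur]]]], path)
    if (!length(nxt)) break
    # prefer the closest next voxel (avoids diagonal skips in thick spots)
    cur <- nxt[1]
    path <- c(path, cur)
    if (length(path) >= length(cc)) break
  }
  path
}

#' Vessel segment diameter
#'
#' `D = 2 x median(r_j)` over the per-point centerline radii of the segment
#' (junction-attached points excluded).
#'
#' @param graph a `CenterlineGraph`.
#' @param segment_id integer segment index.
#' @return diameter in um.
#' @export
segment_diameter <- function(graph, segment_id) {
  stopifnot(inherits(graph, "CenterlineGraph"))
  r <- graph$radii[[segment_id]]
  r <- r[!is.na(r)]
  if (!length(r)) stop(sprintf("segment %d has no radius samples", segment_id))
  2 * stats::median(r)
}

#' Vessel segment length
#'
#' Sum of Euclidean distances between consecutive centerline points (um).
#' A one-point (degenerate) segment has length 0, flagged via the
#' `"degenerate"` attribute.
#'
#' @param graph a `CenterlineGraph`.
#' @param segment_id integer segment index.
#' @return length in um.
#' @export
segment_length <- function(graph, segment_id) {
  stopifnot(inherits(graph, "CenterlineGraph"))
  p <- graph$segments[[segment_id]]
  if (nrow(p) < 2) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  dp <- diff(p)
  sum(sqrt(rowSums(dp^2)))
}

#' Inter-vessel distance
#'
#' For each segment, the minimum Euclidean distance from its midpoint (the
#' centerline point at half arc length) to the midpoints of all other
#' segments. With `mode = "pointwise"` the minimum is instead taken over all
#' centerline points of the other segments.
#'
#' @param graph a `CenterlineGraph`.
#' @param mode `"midpoint"` (default) or `"pointwise"`.
#' @return numeric vector, one IVD (um) per segment; `NA` when fewer than
#'   two segments exist.
#' @export
inter_vessel_distance <- function(graph, mode = c("midpoint", "pointwise")) {
  stopifnot(inherits(graph, "CenterlineGraph"))
  mode <- match.arg(mode)
  ns <- length(graph$segments)
  if (ns < 2) return(rep(NA_real_, ns))
  mids <- t(vapply(seq_len(ns), function(i) segment_midpoint(graph, i), numeric(3)))
  out <- numeric(ns)
  for (i in seq_len(ns)) {
    others <- setdiff(seq_len(ns), i)
    if (mode == "midpoint") {
      dd <- sqrt(rowSums(sweep(mids[others, , drop = FALSE], 2, mids[i, ], `-`)^2))
    } else {
      dd <- vapply(others, function(j) {
        pts <- graph$segments[[j]]
        min(sqrt(rowSums(sweep(pts, 2, mids[i, ], `-`)^2)))
      }, numeric(1))
    }
    out[i] <- min(dd)
  }
  out
}

#' Midpoint of a segment (point at half arc length)
#' @param graph a `CenterlineGraph`.
#' @param segment_id integer segment index.
#' @return numeric length-3 `(z, y, x)` position in um.
#' @export
segment_midpoint <- function(graph, segment_id) {
  p <- graph$segments[[segment_id]]
  if (nrow(p) == 1) return(as.numeric(p[1, ]))
  step <- sqrt(rowSums(diff(p)^2))
  cum <- c(0, cumsum(step))
  as.numeric(p[which.min(abs(cum - cum[length(cum)] / 2)), ])
}

#' Vascular volume density
#'
#' `rho = V_v / V_ROI`: the vessel volume fraction inside a region of
#' interest, with volumes counted in voxels times the physical voxel volume.
#'
#' @param mask a [vessel_mask()].
#' @param roi logical array of the same dimensions (the ROI).
#' @return a list with `vessel_volume_um3`, `roi_volume_um3`, `density`.
#' @export
vascular_density <- function(mask, roi) {
  stopifnot(inherits(mask, "VesselMask"))
  if (!identical(dim(roi), dim(mask$voxels)))
    stop("`roi` must match the mask dimensions")
  if (!any(roi)) stop("empty ROI")
  voxvol <- prod(mask$spacing_um)
  vv <- sum(mask$voxels & roi) * voxvol
  vr <- sum(roi) * voxvol
  list(vessel_volume_um3 = vv, roi_volume_um3 = vr, density = vv / vr)
}

#' Per-segment morphometry table
#'
#' Computes diameter, length and inter-vessel distance for every segment of
#' a centerline graph.
#'
#' @param graph a `CenterlineGraph`.
#' @param region_labels optional per-segment region labels.
#' @return a data.frame with one row per segment.
#' @export
segment_metrics <- function(graph, region_labels = NULL) {
  ns <- length(graph$segments)
  ivd <- inter_vessel_distance(graph)
  data.frame(
    segment_id = seq_len(ns),
    diameter_um = vapply(seq_len(ns), function(i)
      tryCatch(segment_diameter(graph, i), error = function(e) NA_real_), numeric(1)),
    length_um = vapply(seq_len(ns), function(i)
      as.numeric(segment_length(graph, i)), numeric(1)),
    ivd_um = ivd,
    region_label = if (is.null(region_labels)) rep(NA_character_, ns)
      else as.character(region_labels)
  )
}

#' Regional boxplot summaries of vascular metrics
#'
#' Per region and metric: median, quartiles (exclusive-median convention,
#' R quantile type 6), Tukey whiskers (most extreme observation within
#' 1.5 x IQR of the quartiles) and n.
#'
#' @param metrics data.frame with a `region_label` column and numeric metric
#'   columns (e.g. from [segment_metrics()]).
#' @param regions optional character vector of allowed region labels;
#'   metrics carrying a label outside this set raise an error.
#' @param metric_cols columns to summarize; default: all numeric columns
#'   except `segment_id`.
#' @return data.frame with one row per region x metric.
#' @export
summarize_regions <- function(metrics, regions = NULL, metric_cols = NULL) {
  stopifnot(is.data.frame(metrics), "region_label" %in% names(metrics))
  labs <- as.character(metrics$region_label)
  if (is.null(regions)) regions <- unique(labs)
  if (any(!labs %in% regions))
    stop(sprintf("unknown region label(s): %s",
                 paste(unique(setdiff(labs, regions)), collapse = ", ")))
  if (is.null(metric_cols)) {
    metric_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))],
                           "segment_id")
  }
  rows <- list()
  for (rg in regions) {
    sub <- metrics[labs == rg, , drop = FALSE]
    for (mc in metric_cols) {
      v <- sub[[mc]][is.finite(sub[[mc]])]
      if (!length(v)) next
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
      iqr <- q[3] - q[1]
      lo <- v[v >= q[1] - 1.5 * iqr]; hi <- v[v <= q[3] + 1.5 * iqr]
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, metric = mc, n = length(v),
        median = q[2], q1 = q[1], q3 = q[3],
        whisker_low = min(lo), whisker_high = max(hi))
    }
  }
  do.call(rbind, rows)
}
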