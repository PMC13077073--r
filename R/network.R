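#' Classify locomotion frames into stationary and moving states
#'
#' The speed trace is boxcar-smoothed, thresholded (moving iff smoothed
#' speed >= threshold), and bouts shorter than `min_bout_s` are merged into
#' the surrounding state. Fractions and per-state speed statistics are
#' computed on the raw (unsmoothed) speeds.
#'
#' @param speed_mm_s per-frame speed (mm/s), resampled to the imaging rate.
#' @param frame_rate_hz frame rate (Hz).
#' @param speed_threshold_mm_s moving threshold (mm/s).
#' @param min_bout_s minimum bout duration (s); shorter bouts are absorbed.
#' @param smooth_s boxcar smoothing window (s).
#' @return an object of class `StateMask`: list with `state` (character
#'   per frame), `fractions`, `speed_stats` (per-state mean/SD), plus an
#'   `empty_state` flag when one state never occurs.
#' @export
classify_locomotion <- function(speed_mm_s, frame_rate_hz,
                                speed_threshold_mm_s = 10,
                                min_bout_s = 0.5, smooth_s = 0.5) {
  if (any(speed_mm_s < 0)) stop("speeds must be >= 0")
  n <- length(speed_mm_s)
  w <- max(1L, round(smooth_s * frame_rate_hz))
  if (w %% 2 == 0) w <- w + 1L
  sm <- as.numeric(stats::filter(speed_mm_s, rep(1 / w, w), sides = 2))
  # edge frames: shrink the window instead of dropping
  na <- which(is.na(sm))
  for (i in na) {
    lo <- max(1, i - w %/% 2); hi <- min(n, i + w %/% 2)
    sm[i] <- mean(speed_mm_s[lo:hi])
  }
  moving <- sm >= speed_threshold_mm_s

  min_len <- max(1L, round(min_bout_s * frame_rate_hz))
  repeat {
    r <- rle(moving)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_len)
    # never absorb the only occurrence of a state at the trace edges blindly;
    # absorb the shortest offending bout first
    if (!length(short)) break
    j <- short[which.min(r$lengths[short])]
    r$values[j] <- !r$values[j]
    moving <- inverse.rle(r)
  }

  state <- ifelse(moving, "moving", "stationary")
  fr_mov <- mean(moving)
  stats_of <- function(v) {
    if (!length(v)) c(mean = NA_real_, sd = NA_real_)
    else c(mean = mean(v), sd = stats::sd(v))
  }
  structure(list(
    state = state,
    fractions = c(stationary = 1 - fr_mov, moving = fr_mov),
    speed_stats = rbind(stationary = stats_of(speed_mm_s[!moving]),
                        moving = stats_of(speed_mm_s[moving])),
    empty_state = fr_mov %in% c(0, 1)),
    class = "StateMask")
}

#' Build a thresholded functional-connectivity graph
#'
#' An undirected edge joins every unordered neuron pair whose Pearson
#' correlation is strictly greater than the threshold (signed r by default,
#' following the convention "correlation threshold > 0.3"; set
#' `absolute = TRUE` to threshold on |r|). Edges are partitioned into
#' intra- and inter-region counts by the labels.
#'
#' @param corr symmetric correlation matrix with unit diagonal (`NA`
#'   rows/columns are excluded).
#' @param labels per-neuron region labels (length = nrow(corr)).
#' @param threshold edge threshold (default 0.3).
#' @param absolute threshold on `|r|` instead of signed r.
#' @return an object of class `ConnectivityGraph`: list with `edges`
#'   (data.frame `from, to, weight, intra`), `n_edges`, `intra_edges`,
#'   `inter_edges`, `threshold`, `labels`, and `igraph` (the graph object).
#' @export
build_connectivity_graph <- function(corr, labels, threshold = 0.3,
                                     absolute = FALSE) {
  n <- nrow(corr)
  if (length(labels) != n) stop("labels length must match the matrix")
  if (n > 1) {
    off <- corr[upper.tri(corr)]
    ok <- !is.na(off)
    if (any(abs(corr - t(corr)) > 1e-8, na.rm = TRUE))
      stop("correlation matrix must be symmetric")
  }
  iu <- which(upper.tri(corr), arr.ind = TRUE)
  w <- corr[iu]
  val <- if (absolute) abs(w) else w
  keep <- !is.na(val) & val > threshold
  edges <- data.frame(from = iu[keep, 1], to = iu[keep, 2], weight = w[keep])
  edges$intra <- labels[edges$from] == labels[edges$to]
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(n), region = as.character(labels)))
  if (nrow(edges)) igraph::E(g)$weight <- edges$weight
  structure(list(edges = edges, n_edges = nrow(edges),
                 intra_edges = sum(edges$intra),
                 inter_edges = sum(!edges$intra),
                 threshold = threshold, labels = labels, igraph = g),
            class = "ConnectivityGraph")
}

#' @export
print.ConnectivityGraph <- function(x, ...) {
  cat(sprintf("ConnectivityGraph: %d nodes, %d edges (r > %.2f): %d intra-, %d inter-region\n",
              length(x$labels), x$n_edges, x$threshold, x$intra_edges,
              x$inter_edges))
  invisible(x)
}

#' Compare functional connectivity between locomotion states
#'
#' Correlation matrices are computed separately on stationary and moving
#' frames, thresholded identically, and the per-state graphs plus edge-count
#' deltas reported.
#'
#' @param dff a [dff_traces()].
#' @param state_mask a `StateMask` from [classify_locomotion()] (or a
#'   character vector of per-frame states).
#' @param labels per-neuron region labels.
#' @param threshold edge threshold (default 0.3).
#' @return list with `stationary` and `moving` ([build_connectivity_graph()]
#'   results) and `delta` (data.frame of stationary/moving/delta counts).
#' @export
compare_states <- function(dff, state_mask, labels, threshold = 0.3) {
  stopifnot(inherits(dff, "DffTraces"))
  state <- if (inherits(state_mask, "StateMask")) state_mask$state else state_mask
  if (length(state) != ncol(dff$dff))
    stop("state mask length must match the frame count")
  for (s in c("stationary", "moving")) {
    if (sum(state == s) < 30)
      stop(sprintf("state '%s' has fewer than 30 frames; record longer", s))
  }
  gs <- build_connectivity_graph(correlation_matrix(dff, state == "stationary"),
                                 labels, threshold)
  gm <- build_connectivity_graph(correlation_matrix(dff, state == "moving"),
                                 labels, threshold)
  delta <- data.frame(
    quantity = c("total_edges", "intra_edges", "inter_edges"),
    stationary = c(gs$n_edges, gs$intra_edges, gs$inter_edges),
    moving = c(gm$n_edges, gm$intra_edges, gm$inter_edges))
  delta$delta <- delta$moving - delta$stationary
  list(stationary = gs, moving = gm, delta = delta)
}

#' Per-node graph-theoretic metrics
#'
#' The correlation matrix is binarized at `r > threshold` (default 0.1) for
#' degree and (unweighted triangle-ratio) clustering coefficient; strength
#' is the sum of suprathreshold edge weights at each node. Isolated nodes
#' get clustering 0.
#'
#' @param corr symmetric correlation matrix.
#' @param labels optional per-neuron region labels carried into the table.
#' @param threshold binarization threshold (default 0.1).
#' @return data.frame per node: `degree`, `clustering`, `strength`, plus
#'   population means in the `"means"` attribute.
#' @export
graph_metrics <- function(corr, labels = NULL, threshold = 0.1) {
  n <- nrow(corr)
  adj <- !is.na(corr) & corr > threshold
  diag(adj) <- FALSE
  adj <- adj & t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  deg <- igraph::degree(g)
  clus <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  w <- corr
  w[!adj] <- 0
  strength <- rowSums(w, na.rm = TRUE)
  out <- data.frame(node = seq_len(n), degree = as.integer(deg),
                    clustering = clus, strength = strength)
  if (!is.null(labels)) out$region <- as.character(labels)
  attr(out, "means") <- c(degree = mean(deg), clustering = mean(clus),
                          strength = mean(strength))
  out
}

#' Export a connectivity graph
#'
#' @param graph a `ConnectivityGraph`.
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"` (CSV).
#' @return `path`, invisibly.
#' @export
write_connectivity_graph <- function(graph, path,
                                     format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph$igraph, path, format = "graphml")
  } else {
    utils::write.csv(graph$edges, path, row.names = FALSE)
  }
  invisible(path)
}
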