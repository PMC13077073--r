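#' Write a centerline graph as SWC
#'
#' One SWC tree per connected component; nodes carry `(x, y, z)` in um and
#' the per-point radius (um; junction-attached points without a radius get
#' the segment median). Segments sharing a branch-point coordinate are
#' connected through a single SWC node.
#'
#' @param graph a `CenterlineGraph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(graph, path) {
  stopifnot(inherits(graph, "CenterlineGraph"))
  lines <- c("# SWC centerline export (mesokit)",
             "# columns: id type x y z radius parent (um)")
  node_id <- 0L
  seen <- new.env(hash = TRUE)  # coordinate key -> node id
  key <- function(p) paste(sprintf("%.3f", p), collapse = ",")
  for (si in seq_along(graph$segments)) {
    pts <- graph$segments[[si]]
    rr <- graph$radii[[si]]
    med <- stats::median(rr, na.rm = TRUE)
    if (!is.finite(med)) med <- 0
    rr[is.na(rr)] <- med
    prev <- -1L
    for (i in seq_len(nrow(pts))) {
      k <- key(pts[i, ])
      existing <- seen[[k]]
      if (!is.null(existing)) {
        prev <- existing
        next
      }
      node_id <- node_id + 1L
      assign(k, node_id, envir = seen)
      # SWC stores x y z; our points are (z, y, x)
      lines <- c(lines, sprintf("%d 2 %.3f %.3f %.3f %.3f %d",
                                node_id, pts[i, 3], pts[i, 2], pts[i, 1],
                                rr[i], prev))
      prev <- node_id
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write dF/F (or raw) traces as CSV
#'
#' Neurons x frames matrix with id/position/region header columns.
#'
#' @param traces a `DffTraces` or `FluorescenceTraces` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  m <- if (inherits(traces, "DffTraces")) traces$dff else traces$f
  df <- data.frame(neuron = seq_len(nrow(m)))
  if (!is.null(traces$positions_um)) {
    df$y_um <- traces$positions_um[, 1]
    df$x_um <- traces$positions_um[, 2]
  }
  if (!is.null(traces$region_labels)) df$region <- traces$region_labels
  out <- cbind(df, as.data.frame(m))
  names(out)[(ncol(df) + 1):ncol(out)] <- paste0("f", seq_len(ncol(m)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a density result (or any small result list) as JSON
#'
#' @param x a named list of scalars/vectors.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
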