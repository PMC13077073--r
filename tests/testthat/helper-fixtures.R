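# Shared fixtures and independent oracles, built in code at test time.

# Brute-force oracle: count voxel centres inside a capsule (cylinder with
# hemispherical caps) around segment a-b. Independent of the package's
# rasterizer.
oracle_capsule_count <- function(dim_vox, spacing, a, b, radius) {
  zs <- (seq_len(dim_vox[1]) - 1) * spacing[1]
  ys <- (seq_len(dim_vox[2]) - 1) * spacing[2]
  xs <- (seq_len(dim_vox[3]) - 1) * spacing[3]
  cnt <- 0L
  u <- b - a
  len2 <- sum(u^2)
  for (z in zs) for (y in ys) {
    p <- cbind(z, y, xs)
    t <- pmin(1, pmax(0, (sweep(p, 2, a, `-`) %*% u) / len2))
    proj <- sweep(t %*% t(u), 2, a, `+`)
    cnt <- cnt + sum(rowSums((p - proj)^2) <= radius^2)
  }
  cnt
}

# straight axis-aligned tube phantom spanning the full x extent
straight_tube_phantom <- function(h = 1, radius = 5, dims = c(21, 21, 120),
                                  noise_sd = 0) {
  d <- round(dims / h)
  spec <- phantom_spec(d, rep(h, 3),
                       list(list(start = c((dims[1] - 1) / 2, (dims[2] - 1) / 2, -10),
                                 end = c((dims[1] - 1) / 2, (dims[2] - 1) / 2, 1e4),
                                 radius_um = radius)),
                       noise_sd = noise_sd, psf_sigma_um = c(0, 0, 0))
  generate_vascular_phantom(spec, seed = 1)
}

# hand-built centerline graph from explicit point/radius lists
make_graph <- function(segments, radii = NULL, spacing = c(1, 1, 1)) {
  if (is.null(radii)) radii <- lapply(segments, function(s) rep(1, nrow(s)))
  structure(list(segments = segments, radii = radii,
                 branch_points = matrix(numeric(0), 0, 3),
                 spacing_um = spacing,
                 flags = rep("", length(segments))),
            class = "CenterlineGraph")
}

# brute-force per-node degree / triangle clustering / strength oracle
oracle_graph_metrics <- function(corr, threshold) {
  n <- nrow(corr)
  adj <- corr > threshold
  diag(adj) <- FALSE
  deg <- rowSums(adj)
  clus <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k < 2) { clus[i] <- 0; next }
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[nb[a], nb[b]]) links <- links + 1
    clus[i] <- 2 * links / (k * (k - 1))
  }
  w <- corr
  w[!adj] <- 0
  list(degree = deg, clustering = clus, strength = rowSums(w))
}

# random symmetric correlation-like matrix with unit diagonal
random_corr <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, -0.5, 0.9), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}
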