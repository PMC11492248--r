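# Independent oracles: deliberately naive implementations used only to
# check the package's production code paths.

# O(N^2) double-loop contact detection (strict < cutoff).
brute_contacts <- function(a, b, cutoff, box = NULL, min_image_xy = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  out <- matrix(FALSE, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- a[i, ] - b[j, ]
    if (min_image_xy) {
      d[1] <- d[1] - box[1] * round(d[1] / box[1])
      d[2] <- d[2] - box[2] * round(d[2] / box[2])
    }
    out[i, j] <- sqrt(sum(d^2)) < cutoff
  }
  out
}

# The same O(N^2) contact oracle, vectorised with outer() so the
# 200-scene equivalence check stays fast; still a full all-pairs
# computation with no spatial acceleration.
brute_contacts_vec <- function(a, b, cutoff, box = NULL,
                               min_image_xy = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  if (min_image_xy) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
  }
  dx^2 + dy^2 + dz^2 < cutoff^2
}

# Textbook O(N^2) DBSCAN reference: full distance matrix, core points by
# row counts, clusters as connected components of the core-core graph
# (igraph), border points attached to the first core neighbour in scan
# order.  Entirely independent of the package's binned implementation.
ref_dbscan <- function(points, eps, min_pts) {
  p <- as.matrix(points)
  n <- nrow(p)
  D <- as.matrix(stats::dist(p))
  nb <- D <= eps
  core <- rowSums(nb) >= min_pts
  labels <- rep(-1L, n)
  if (any(core)) {
    ci <- which(core)
    g <- igraph::graph_from_adjacency_matrix(nb[ci, ci, drop = FALSE],
                                             mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    # relabel components by first core point in scan order
    first <- tapply(seq_along(ci), comp, min)
    remap <- order(order(first)) - 1L
    labels[ci] <- remap[comp]
    # border points join their nearest core neighbour (ties to the
    # lower label), matching the package's deterministic convention
    for (i in which(!core)) {
      cn <- ci[nb[i, ci]]
      if (length(cn)) {
        best <- cn[D[i, cn] == min(D[i, cn])]
        labels[i] <- min(labels[best])
      }
    }
  }
  labels
}

# Cluster labelings as sets of member-index sets (noise excluded).
label_sets <- function(labels) {
  s <- split(seq_along(labels), labels)
  s <- s[names(s) != "-1"]
  unname(lapply(s, sort)) |> (\(x) x[order(vapply(x, min, 1L))])()
}

# Longhand two-pass population Pearson correlation.
longhand_pearson <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  sa <- sqrt(sum((a - ma)^2) / length(a))
  sb <- sqrt(sum((b - mb)^2) / length(b))
  sum((a - ma) * (b - mb)) / length(a) / (sa * sb)
}

# Rotate points about a centre with an explicitly constructed matrix.
rotate_points <- function(p, angle_deg, axis, center) {
  R <- rotation_matrix(angle_deg, axis)
  sweep(sweep(as.matrix(p), 2, center) %*% t(R), 2, center, "+")
}

# A random unit vector perpendicular to v (seeded by the caller).
perp_axis <- function(v) {
  repeat {
    u <- stats::rnorm(3)
    u <- u - sum(u * v) / sum(v^2) * v
    if (sqrt(sum(u^2)) > 1e-3) return(u / sqrt(sum(u^2)))
  }
}

# Small dimple-scene fixture shared by several tests.
dimple_scene <- function(n = 200, box = c(400, 400, 300), A = -30,
                         s = 60, seed = 1) {
  surf <- surface_params("gauss_dimple", c0 = box[3] / 2, A = A,
                         x0 = box[1] / 2, y0 = box[2] / 2, sx = s, sy = s)
  make_membrane_frame(surf, n_per_leaflet = n, box = box, seed = seed)
}
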