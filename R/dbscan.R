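#' Lipid clustering specification
#'
#' @param eps neighbourhood distance in Angstrom (default 28).
#' @param min_pts minimum molecules per cluster, counting the point
#'   itself (default 5).
#' @param convention `"raw"` Euclidean (default) or `"min_image"` in the
#'   membrane plane.
#' @return an object of class `cluster_spec`.
#' @export
cluster_spec <- function(eps = 28, min_pts = 5,
                         convention = c("raw", "min_image")) {
  if (eps <= 0) stop("eps must be > 0")
  if (min_pts < 1) stop("min_pts must be >= 1")
  structure(list(eps = eps, min_pts = as.integer(min_pts),
                 convention = match.arg(convention)),
            class = "cluster_spec")
}

# Neighbour lists within eps, by spatial binning on the first two
# coordinates (bin width = eps); z handled exactly in the distance.
.eps_neighbours <- function(p, eps, box, min_image_xy) {
  n <- nrow(p)
  if (min_image_xy) {
    nbin <- pmax(1L, floor(box[1:2] / eps))
    w <- box[1:2] / nbin
    ix <- floor((p[, 1] %% box[1]) / w[1]) %% nbin[1]
    iy <- floor((p[, 2] %% box[2]) / w[2]) %% nbin[2]
    wrap <- function(i, k) ((i %% k) + k) %% k
  } else {
    ix <- floor((p[, 1] - min(p[, 1])) / eps)
    iy <- floor((p[, 2] - min(p[, 2])) / eps)
    nbin <- c(Inf, Inf); wrap <- function(i, k) i
  }
  idx <- split(seq_len(n), paste(ix, iy))
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1)
      cand <- c(cand, idx[[paste(wrap(ix[i] + dx, nbin[1]),
                                 wrap(iy[i] + dy, nbin[2]))]])
    cand <- unique(cand)
    dx <- p[i, 1] - p[cand, 1]; dy <- p[i, 2] - p[cand, 2]
    if (min_image_xy) {
      dx <- min_image(dx, box[1]); dy <- min_image(dy, box[2])
    }
    d2 <- dx^2 + dy^2
    if (ncol(p) >= 3) d2 <- d2 + (p[i, 3] - p[cand, 3])^2
    nb[[i]] <- cand[d2 <= eps^2]
  }
  nb
}

#' Density-based clustering (DBSCAN) of reference points
#'
#' In-package DBSCAN with the standard semantics: a core point has at
#' least `min_pts` neighbours within `eps` (including itself); clusters
#' are connected sets of core points plus their border points; all other
#' points are noise (label -1).  Labels are contiguous integers from 0,
#' numbered by each cluster's first core point in input order.  A border
#' point reachable from several clusters joins the cluster of its
#' nearest core neighbour (distance ties go to the lower label), so the
#' partition is deterministic and independent of input order — unlike
#' the classic scan-order algorithm, whose border assignment depends on
#' expansion order.
#'
#' @param points N x 2 or N x 3 matrix of reference points (Angstrom).
#' @param spec a [cluster_spec()].
#' @param box box edges, required for the minimum-image convention.
#' @param ids optional point ids (default 1..N).
#' @return object of class `cluster_labeling`: list with `labels`
#'   (integer vector, -1 = noise), `ids`, `n_clusters`, `cluster_sizes`,
#'   `n_noise`.
#' @export
dbscan_cluster <- function(points, spec = cluster_spec(), box = NULL,
                           ids = NULL) {
  p <- as.matrix(points)
  if (!nrow(p)) stop("need at least one point")
  mi <- spec$convention == "min_image"
  if (mi && is.null(box)) stop("box required for minimum-image clustering")
  nb <- .eps_neighbours(p, spec$eps, box, mi)
  n <- nrow(p)
  core <- lengths(nb) >= spec$min_pts
  labels <- rep(-1L, n)
  cl <- -1L
  # connected components of the core-core graph, in scan order
  for (i in which(core)) {
    if (labels[i] != -1L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]][core[nb[[i]]]]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] != -1L) next
      labels[j] <- cl
      queue <- c(queue, nb[[j]][core[nb[[j]]]])
    }
  }
  # border points: nearest core neighbour, ties to the lower label
  dist1 <- function(i, j) {
    d <- p[i, ] - p[j, ]
    if (mi) {
      d[1] <- min_image(d[1], box[1]); d[2] <- min_image(d[2], box[2])
    }
    sqrt(sum(d^2))
  }
  for (i in which(!core)) {
    cn <- nb[[i]][core[nb[[i]]]]
    if (!length(cn)) next
    dd <- vapply(cn, dist1, numeric(1), i = i)
    best <- cn[dd == min(dd)]
    labels[i] <- min(labels[best])
  }
  sizes <- if (cl >= 0) tabulate(labels[labels >= 0] + 1L, cl + 1L)
           else integer(0)
  structure(list(labels = labels, ids = ids %||% seq_len(n),
                 n_clusters = cl + 1L, cluster_sizes = sizes,
                 n_noise = sum(labels == -1L)),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf("cluster_labeling: %d points, %d clusters (sizes %s), %d noise\n",
              length(x$labels), x$n_clusters,
              paste(x$cluster_sizes, collapse = ","), x$n_noise))
  invisible(x)
}

#' Grid search of DBSCAN parameters minimising the non-clustered group
#'
#' Utility mirroring how the clustering parameters can be chosen: scan
#' (eps, min_pts) combinations on one frame's reference points and
#' report the noise count for each, so the pair minimising the size of
#' the non-clustered group of a species of interest can be picked.
#'
#' @param points reference points of the species in the chosen frame.
#' @param eps_grid,min_pts_grid candidate values.
#' @param box,convention as in [dbscan_cluster()].
#' @return data.frame with `eps`, `min_pts`, `n_noise`, `n_clusters`,
#'   sorted by `n_noise`.
#' @export
tune_cluster_params <- function(points, eps_grid = seq(16, 40, by = 4),
                                min_pts_grid = 3:8, box = NULL,
                                convention = "raw") {
  g <- expand.grid(eps = eps_grid, min_pts = min_pts_grid)
  res <- t(apply(g, 1, function(r) {
    cl <- dbscan_cluster(points, cluster_spec(r[1], r[2], convention), box)
    c(n_noise = cl$n_noise, n_clusters = cl$n_clusters)
  }))
  out <- cbind(g, as.data.frame(res))
  out[order(out$n_noise, out$eps), ]
}
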