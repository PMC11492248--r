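#' Assign lipid molecules to leaflets from the first frame
#'
#' The bilayer midplane is the mean z of all lipid phosphate-role (PO4)
#' beads in the frame; molecules whose PO4 bead sits above the midplane
#' are "upper", the rest "lower".  The assignment is made once, on the
#' first frame, and reused unchanged for all later frames (molecules are
#' categorised by their initial positions).
#'
#' @param frame the first [bead_frame()] of a trajectory.
#' @param quiet suppress the single-leaflet warning?
#' @return named character vector, molecule id -> `"upper"`/`"lower"`.
#' @export
assign_leaflets <- function(frame, quiet = FALSE) {
  b <- frame$beads
  po4 <- b[b$name == "PO4", , drop = FALSE]
  if (!nrow(po4)) stop("no lipid PO4 beads in frame; cannot assign leaflets")
  mid <- mean(po4$z)
  zmol <- tapply(po4$z, po4$molid, mean)
  lf <- ifelse(zmol > mid, "upper", "lower")
  if (length(unique(lf)) == 1 && !quiet)
    warning("all lipids assigned to one leaflet (flat z distribution?)")
  stats::setNames(as.character(lf), names(zmol))
}

#' Cluster count and size time series for one lipid species
#'
#' Per frame, clusters the species' reference points (centres of
#' geometry for every species — the clustering convention) restricted to
#' one leaflet, with leaflet membership frozen at the first frame, and
#' reports the number of clusters, the mean cluster size, and the noise
#' count.  Mean size is `NA` when a frame has no clusters.
#'
#' @param frames a [bead_trajectory()] or list of frames.
#' @param species lipid species (alias-aware, e.g. `"GM3"` or `"DPG3"`).
#' @param leaflet `"upper"` or `"lower"`.
#' @param spec a [cluster_spec()] (defaults: eps 28 Angstrom, min 5).
#' @param leaflets optional precomputed leaflet assignment.
#' @return data.frame of class `cluster_series` with `frame`, `time_ps`,
#'   `n_clusters`, `mean_size`, `n_noise`; per-frame labelings in the
#'   `labelings` attribute.
#' @export
cluster_series <- function(frames, species, leaflet = "upper",
                           spec = cluster_spec(), leaflets = NULL) {
  frames <- as_trajectory(frames)
  if (!any(species_matches(frames[[1]]$beads$species, species)))
    stop("species '", species, "' not present in the trajectory")
  leaflets <- leaflets %||% assign_leaflets(frames[[1]], quiet = TRUE)
  keep_mol <- names(leaflets)[leaflets == leaflet]
  out <- data.frame(frame = integer(), time_ps = numeric(),
                    n_clusters = integer(), mean_size = numeric(),
                    n_noise = integer())
  labs <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    rp <- resolve_reference_points(fr, "lipid-molecule", species = species,
                                   use_d_bead = FALSE)
    sel <- rp$ids %in% as.integer(keep_mol)
    if (!any(sel))
      stop("species '", species, "' absent from the ", leaflet,
           " leaflet in frame ", i)
    cl <- dbscan_cluster(rp$points[sel, , drop = FALSE], spec,
                         box = fr$box, ids = rp$ids[sel])
    out[i, ] <- list(i, fr$time, cl$n_clusters,
                     if (cl$n_clusters) mean(cl$cluster_sizes) else NA_real_,
                     cl$n_noise)
    labs[[i]] <- cl
  }
  class(out) <- c("cluster_series", "data.frame")
  attr(out, "labelings") <- labs
  out
}

#' Planar Delaunay triangulation of the membrane surface, coloured by height
#'
#' Triangulates the (x, y) positions of the upper-leaflet PO4 beads and
#' assigns each triangle the mean z of its three vertices — the 2D
#' triangulated-membrane height map.
#'
#' @param points N x 3 matrix of PO4 bead coordinates (Angstrom).
#' @return list of class `height_triangulation`: `vertices` (the input
#'   points) and `triangles` (data.frame with vertex indices `i`, `j`,
#'   `k` and `value`, the mean vertex height).
#' @export
height_triangulation <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) < 3) stop("need at least 3 points to triangulate")
  sv <- svd(scale(p[, 1:2], scale = FALSE), nu = 0, nv = 0)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("points are collinear in (x, y); cannot triangulate")
  dd <- deldir::deldir(p[, 1], p[, 2], suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  tri <- do.call(rbind, lapply(tl, function(t)
    data.frame(i = t$ptNum[1], j = t$ptNum[2], k = t$ptNum[3])))
  tri$value <- (p[tri$i, 3] + p[tri$j, 3] + p[tri$k, 3]) / 3
  structure(list(vertices = p, triangles = tri),
            class = "height_triangulation")
}

#' @export
print.height_triangulation <- function(x, ...) {
  cat(sprintf("height_triangulation: %d vertices, %d triangles, mean z %.2f A\n",
              nrow(x$vertices), nrow(x$triangles), mean(x$triangles$value)))
  invisible(x)
}

#' Write a triangulation as an OFF-style text file with per-face values
#'
#' @param x a [height_triangulation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_triangulation <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(x$vertices), nrow(x$triangles)), con)
  writeLines(sprintf("%.3f %.3f %.3f", x$vertices[, 1], x$vertices[, 2],
                     x$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d %.3f", x$triangles$i - 1L,
                     x$triangles$j - 1L, x$triangles$k - 1L,
                     x$triangles$value), con)
  invisible(path)
}
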