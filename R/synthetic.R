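#' Default plasma-membrane leaflet compositions
#'
#' The asymmetric plasma-membrane mixture used throughout: upper leaflet
#' POPC/DOPC/POPE/DOPE/CHOL/DPG3 in ratio 25:25:8:7:25:10, lower leaflet
#' POPC/DOPC/POPE/DOPE/CHOL/POPS/DOPS/POP2 in ratio 5:5:20:20:25:8:7:10.
#' Species names follow the CG residue-name conventions (DPG3 = GM3,
#' POP2 = PIP2) so selections written for real trajectories also work on
#' synthetic scenes.
#'
#' @return list with named integer ratio vectors `upper` and `lower`.
#' @export
default_composition <- function() {
  list(upper = c(POPC = 25, DOPC = 25, POPE = 8, DOPE = 7, CHOL = 25,
                 DPG3 = 10),
       lower = c(POPC = 5, DOPC = 5, POPE = 20, DOPE = 20, CHOL = 25,
                 POPS = 8, DOPS = 7, POP2 = 10))
}

# Blue-noise-like in-plane placement: dart throwing with a minimum
# spacing, accelerated by a cell grid (cell edge spacing/sqrt(2), so a
# 5x5 neighbourhood bounds the conflict search).  Deterministic given
# the RNG state.
.bluenoise_xy <- function(n, lx, ly, spacing, max_attempts = 400L * n) {
  cs <- spacing / sqrt(2)
  ncx <- max(1L, ceiling(lx / cs)); ncy <- max(1L, ceiling(ly / cs))
  grid <- matrix(0L, ncx, ncy)
  xs <- ys <- numeric(n)
  placed <- 0L
  for (att in seq_len(max_attempts)) {
    x <- stats::runif(1, 0, lx); y <- stats::runif(1, 0, ly)
    cx <- min(ncx, 1L + floor(x / cs)); cy <- min(ncy, 1L + floor(y / cs))
    ok <- TRUE
    for (ix in max(1, cx - 2):min(ncx, cx + 2)) {
      for (iy in max(1, cy - 2):min(ncy, cy + 2)) {
        j <- grid[ix, iy]
        if (j > 0L && (xs[j] - x)^2 + (ys[j] - y)^2 < spacing^2) {
          ok <- FALSE; break
        }
      }
      if (!ok) break
    }
    if (!ok) next
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
    grid[cx, cy] <- placed
    if (placed == n) return(cbind(xs, ys, deparse.level = 0))
  }
  stop("could not place ", n, " lipids at ", spacing,
       " A spacing in a ", lx, " x ", ly, " A patch (box too small)")
}

# Build the bead rows for one leaflet laid on an analytic surface.
# Each lipid gets a PO4-role bead on the surface and a body bead (a
# centre-of-geometry proxy) displaced toward the bilayer midplane; GM3
# lipids additionally get a headgroup D-role bead above the surface.
.leaflet_beads <- function(xy, species, surface, side, molid0,
                           thickness, d_offset = 3, body_offset = 5) {
  zs <- surface_eval(surface, xy[, 1], xy[, 2])
  sgn <- if (side == "upper") 1 else -1
  if (side == "lower") zs <- zs - thickness
  rows <- vector("list", nrow(xy))
  for (i in seq_len(nrow(xy))) {
    mid <- molid0 + i
    r <- data.frame(name = c("PO4", "C1A"),
                    resid = mid, molid = mid, species = species[i],
                    x = xy[i, 1], y = xy[i, 2],
                    z = c(zs[i], zs[i] - sgn * body_offset))
    if (species_matches(species[i], "GM3")[1])
      r <- rbind(r, data.frame(name = "D1", resid = mid, molid = mid,
                               species = species[i], x = xy[i, 1],
                               y = xy[i, 2], z = zs[i] + sgn * d_offset))
    rows[[i]] <- r
  }
  do.call(rbind, rows)
}

#' Generate a synthetic bilayer patch on an analytic surface
#'
#' Lays two leaflets of coarse-grained lipids on a known parametric
#' surface: upper-leaflet PO4 beads sit exactly at z(x, y), lower-leaflet
#' PO4 beads at z(x, y) minus the bilayer thickness.  In-plane positions
#' use blue-noise placement with a minimum spacing (default 8 Angstrom,
#' a realistic CG area per lipid) so planted cluster geometry is
#' controllable.  Species are apportioned to the requested ratio by the
#' largest-remainder rule and assigned to positions in a seeded random
#' permutation.  The exact surface is recorded in the scene truth.
#'
#' @param surface a [surface_params()] ground-truth surface.
#' @param composition list with `upper`/`lower` named ratio vectors;
#'   default [default_composition()].
#' @param n_per_leaflet lipids per leaflet.
#' @param box box edges in Angstrom (default 500 x 500 x 500, a 50 nm
#'   cube).
#' @param seed RNG seed; fixed seed gives bit-identical frames.
#' @param spacing minimum in-plane spacing (Angstrom).
#' @param thickness bilayer thickness (Angstrom, default 40).
#' @return a [bead_frame()] with a `truth` attribute (see
#'   [scene_truth()]).
#' @export
make_membrane_frame <- function(surface = surface_params("plane", c0 = 50),
                                composition = default_composition(),
                                n_per_leaflet = 400,
                                box = c(500, 500, 500), seed = 1,
                                spacing = 8, thickness = 40) {
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  if (n_per_leaflet <= 0) stop("n_per_leaflet must be positive")
  for (lf in c("upper", "lower"))
    if (n_per_leaflet < length(composition[[lf]]))
      stop("n_per_leaflet must be at least the number of species (",
           lf, " leaflet)")
  set.seed(seed)
  counts <- lapply(composition, largest_remainder, total = n_per_leaflet)
  beads <- list(); molid0 <- 0L
  for (lf in c("upper", "lower")) {
    xy <- .bluenoise_xy(n_per_leaflet, box[1], box[2], spacing)
    sp <- unname(sample(rep(names(counts[[lf]]), counts[[lf]])))
    beads[[lf]] <- .leaflet_beads(xy, sp, surface, lf, molid0, thickness)
    molid0 <- molid0 + n_per_leaflet
  }
  fr <- bead_frame(do.call(rbind, beads), box = box, time = 0, frame = 1L)
  attr(fr, "truth") <- list(surface = surface, counts = counts,
                            composition = composition,
                            thickness = thickness)
  fr
}

#' Plant lipid clusters of known membership into a scene
#'
#' Relocates `k` disjoint groups of `size` molecules of one species into
#' compact blobs (sampled within a disk of radius `spread`, with the
#' blob diameter capped just below the clustering eps so every planted
#' blob is recoverable as a single DBSCAN cluster when `size >=
#' min_pts`).  Blob centres are mutually separated by more than
#' 2 * (spread + eps); the species' remaining molecules are re-placed at
#' least eps from every blob member and from each other, so they are
#' guaranteed noise.  Ground-truth labels (cluster id per molecule, -1
#' for the remainder) are recorded in the scene truth.
#'
#' @param frame a synthetic [bead_frame()] (the truth surface, when
#'   present, is used to keep relocated PO4 beads on the surface).
#' @param species species to plant (alias-aware).
#' @param k number of clusters.
#' @param size molecules per cluster.
#' @param spread blob radius in Angstrom.
#' @param seed RNG seed.
#' @param eps clustering neighbourhood distance the construction guards
#'   against (default 28 Angstrom).
#' @return the modified frame; planted labels in
#'   `scene_truth(frame)$planted_clusters`.
#' @export
plant_species_clusters <- function(frame, species, k, size, spread,
                                   seed = 1, eps = 28) {
  if (spread <= 0) stop("spread must be > 0")
  b <- frame$beads
  mols <- sort(unique(b$molid[species_matches(b$species, species)]))
  if (k * size > length(mols))
    stop("k * size exceeds the ", length(mols), " molecules of ", species)
  set.seed(seed)
  lx <- frame$box[1]; ly <- frame$box[2]
  margin <- spread + eps
  min_cc <- 2 * (spread + eps) + 4   # centre-centre separation, with slack
  centers <- matrix(NA_real_, 0, 2)
  for (att in seq_len(20000L)) {
    c0 <- c(stats::runif(1, margin, lx - margin),
            stats::runif(1, margin, ly - margin))
    if (!nrow(centers) ||
        min(sqrt(rowSums((centers - rep(c0, each = nrow(centers)))^2))) >
          min_cc) centers <- rbind(centers, c0)
    if (nrow(centers) == k) break
  }
  if (nrow(centers) < k)
    stop("could not place ", k, " blob centres separated by ", min_cc,
         " A in this box (impossible packing)")

  # sample `m` points in a disk whose radius is capped just below eps/2,
  # so every pair of blob members is within the neighbourhood distance
  # and the blob is recoverable as one cluster by construction
  blob_xy <- function(centre, m) {
    r_eff <- min(spread, 0.49 * eps)
    r <- r_eff * sqrt(stats::runif(m)); th <- stats::runif(m, 0, 2 * pi)
    cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
  }

  truth <- attr(frame, "truth")
  surf <- truth$surface
  move_mol <- function(beads, mid, new_xy) {
    rows <- which(beads$molid == mid)
    old <- colMeans(beads[rows, c("x", "y")])
    dz <- 0
    if (!is.null(surf))
      dz <- surface_eval(surf, new_xy[1], new_xy[2]) -
        surface_eval(surf, old[1], old[2])
    beads$x[rows] <- beads$x[rows] + (new_xy[1] - old[1])
    beads$y[rows] <- beads$y[rows] + (new_xy[2] - old[2])
    beads$z[rows] <- beads$z[rows] + dz
    beads
  }

  labels <- stats::setNames(rep(-1L, length(mols)), mols)
  picked <- sample(mols, k * size)
  all_xy <- matrix(NA_real_, 0, 2)
  for (ci in seq_len(k)) {
    members <- picked[((ci - 1) * size + 1):(ci * size)]
    xy <- blob_xy(centers[ci, ], size)
    for (j in seq_len(size)) b <- move_mol(b, members[j], xy[j, ])
    labels[as.character(members)] <- ci - 1L
    all_xy <- rbind(all_xy, xy)
  }
  # scatter the remainder: > eps from every blob member and each other
  rest <- setdiff(mols, picked)
  for (mid in rest) {
    placed <- FALSE
    for (att in seq_len(20000L)) {
      c0 <- c(stats::runif(1, 0, lx), stats::runif(1, 0, ly))
      d <- sqrt(rowSums((all_xy - rep(c0, each = nrow(all_xy)))^2))
      if (min(d) > eps + 1) {
        b <- move_mol(b, mid, c0)
        all_xy <- rbind(all_xy, c0)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not isolate remaining ", species,
           " molecules (impossible packing)")
  }
  out <- bead_frame(b, frame$box, frame$time, frame$frame)
  truth$planted_clusters <- labels
  truth$planted_species <- species
  attr(out, "truth") <- truth
  out
}

#' Rigid icosahedral capsid shell
#'
#' Beads on a sphere arranged around the 12 vertex directions of an
#' icosahedron — a stand-in for a ~25 nm-diameter virus capsid (default
#' radius 125 Angstrom).  Each vertex group ("pentamer") carries a
#' pentamer index 1-12 as its molecule id; residue ids are sequential
#' across the shell.  The shell is pure geometry (coordinates only).
#'
#' @param center sphere centre (Angstrom).
#' @param radius sphere radius (Angstrom, default 125).
#' @param beads_per_face beads per pentamer (>= 1; the first bead of
#'   each pentamer sits exactly on the vertex direction).
#' @param seed RNG seed for the within-face bead scatter.
#' @param box box edges for the resulting fragment.
#' @return a [bead_frame()] fragment with species `"CAPS"`.
#' @export
make_capsid_shell <- function(center = c(250, 250, 250), radius = 125,
                              beads_per_face = 10, seed = 1,
                              box = c(500, 500, 500)) {
  if (radius <= 0) stop("radius must be > 0")
  if (beads_per_face < 1) stop("beads_per_face must be >= 1")
  set.seed(seed)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi),
             c(1, phi, 0), c(1, -phi, 0), c(-1, phi, 0), c(-1, -phi, 0),
             c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v <- v / sqrt(1 + phi^2)
  rows <- list()
  rid <- 0L
  for (pent in 1:12) {
    dirs <- matrix(v[pent, ], 1)
    while (nrow(dirs) < beads_per_face) {
      # random direction within a 20-degree cap around the vertex
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      d <- v[pent, ] + 0.35 * u
      d <- d / sqrt(sum(d^2))
      if (sum(d * v[pent, ]) > cos(20 * pi / 180)) dirs <- rbind(dirs, d)
    }
    rows[[pent]] <- data.frame(
      name = "BB", resid = rid + seq_len(beads_per_face),
      molid = pent, species = "CAPS",
      x = center[1] + radius * dirs[, 1],
      y = center[2] + radius * dirs[, 2],
      z = center[3] + radius * dirs[, 3])
    rid <- rid + beads_per_face
  }
  bead_frame(do.call(rbind, rows), box = box)
}

#' Construct a synthetic trajectory with scripted rotations and dimples
#'
#' Builds an n-frame trajectory from a base scene: capsid beads (species
#' `"CAPS"`) are rigidly rotated about their initial centroid per the
#' rotation schedule; membrane beads are re-laid on each frame's surface
#' (each bead keeps its (x, y) and its z-offset from the base surface,
#' so PO4 beads track the scheduled surface exactly).  Frame times are
#' strictly increasing multiples of `dt`.  The schedules become the
#' scene truth.
#'
#' @param base a base [bead_frame()] (typically a merged membrane +
#'   capsid scene; membrane re-laying needs the membrane truth surface).
#' @param n_frames number of frames.
#' @param angles rotation schedule in degrees, length `n_frames`
#'   (angles are reduced to [0, 360)); NULL for no rotation.
#' @param axis rotation axis (length 3).
#' @param dimple_schedule list of `n_frames` [surface_params()] objects,
#'   or NULL to keep the base surface.
#' @param seed RNG seed for the optional per-frame z jitter.
#' @param noise_sd per-frame Gaussian z jitter on membrane beads
#'   (Angstrom; default 0, frames are exactly re-laid).
#' @param dt frame spacing in ps.
#' @return a [bead_trajectory()] with a `truth` attribute.
#' @export
make_trajectory <- function(base, n_frames, angles = NULL,
                            axis = c(0, 0, 1), dimple_schedule = NULL,
                            seed = 1, noise_sd = 0, dt = 1000) {
  if (!is.null(angles) && length(angles) != n_frames)
    stop("rotation schedule length (", length(angles),
         ") does not match n_frames (", n_frames, ")")
  if (!is.null(dimple_schedule) && length(dimple_schedule) != n_frames)
    stop("dimple schedule length (", length(dimple_schedule),
         ") does not match n_frames (", n_frames, ")")
  if (!is.null(angles)) angles <- angles %% 360
  truth0 <- attr(base, "truth")
  base_surf <- truth0$surface
  if (!is.null(dimple_schedule) && is.null(base_surf))
    stop("membrane re-laying needs a base scene with a truth surface")
  b0 <- base$beads
  cap <- species_matches(b0$species, "CAPS")
  centroid <- if (any(cap)) colMeans(b0[cap, c("x", "y", "z")])
  mem <- !cap
  zoff <- NULL
  if (!is.null(dimple_schedule))
    zoff <- b0$z[mem] - surface_eval(base_surf, b0$x[mem], b0$y[mem])
  set.seed(seed)
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    b <- b0
    if (!is.null(angles) && any(cap)) {
      R <- rotation_matrix(angles[i], axis)
      xyz <- as.matrix(b[cap, c("x", "y", "z")])
      xyz <- sweep(xyz, 2, centroid)
      b[cap, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, centroid, "+")
    }
    if (!is.null(dimple_schedule))
      b$z[mem] <- surface_eval(dimple_schedule[[i]], b$x[mem], b$y[mem]) +
        zoff
    if (noise_sd > 0)
      b$z[mem] <- b$z[mem] + stats::rnorm(sum(mem), 0, noise_sd)
    frames[[i]] <- bead_frame(b, base$box, time = (i - 1) * dt, frame = i)
  }
  tr <- bead_trajectory(frames)
  attr(tr, "truth") <- c(truth0[!names(truth0) %in% "surface"], list(
    surface = if (is.null(dimple_schedule)) base_surf,
    surface_schedule = dimple_schedule,
    rotation_schedule = angles, rotation_axis = axis))
  tr
}
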