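#' Contact specification
#'
#' @param cutoff contact cutoff in Angstrom; a contact is a pair of
#'   reference points strictly closer than this (distance == cutoff is
#'   not a contact).
#' @param convention `"min_image"` (minimum image in x and y, the
#'   membrane-plane periodic directions; raw in z) or `"raw"`.
#' @return an object of class `contact_spec`.
#' @export
contact_spec <- function(cutoff = 10, convention = c("min_image", "raw")) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  structure(list(cutoff = cutoff, convention = match.arg(convention)),
            class = "contact_spec")
}

# Neighbour search by spatial binning in (x, y) with bin width = cutoff.
# Returns a logical contact matrix.  Correctness is defined by the
# brute-force O(N^2) oracle in the test suite, not by this acceleration.
.binned_contacts <- function(a, b, cutoff, box, min_image_xy) {
  na <- nrow(a); nb <- nrow(b)
  out <- matrix(FALSE, na, nb)
  if (min_image_xy) {
    nbin <- pmax(1L, floor(box[1:2] / cutoff))
    w <- box[1:2] / nbin
    cell <- function(p) {
      ix <- floor((p[, 1] %% box[1]) / w[1]) %% nbin[1]
      iy <- floor((p[, 2] %% box[2]) / w[2]) %% nbin[2]
      cbind(ix, iy)
    }
    wrap <- function(i, n) ((i %% n) + n) %% n
  } else {
    ox <- min(a[, 1], b[, 1]); oy <- min(a[, 2], b[, 2])
    cell <- function(p) cbind(floor((p[, 1] - ox) / cutoff),
                              floor((p[, 2] - oy) / cutoff))
    nbin <- c(Inf, Inf)
    wrap <- function(i, n) i
  }
  ca <- cell(a); cb <- cell(b)
  keyb <- paste(cb[, 1], cb[, 2])
  bidx <- split(seq_len(nb), keyb)
  for (i in seq_len(na)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(wrap(ca[i, 1] + dx, nbin[1]), wrap(ca[i, 2] + dy, nbin[2]))
      cand <- c(cand, bidx[[k]])
    }
    cand <- unique(cand)
    if (!length(cand)) next
    dx <- a[i, 1] - b[cand, 1]; dy <- a[i, 2] - b[cand, 2]
    dz <- a[i, 3] - b[cand, 3]
    if (min_image_xy) {
      dx <- min_image(dx, box[1]); dy <- min_image(dy, box[2])
    }
    out[i, cand] <- dx^2 + dy^2 + dz^2 < cutoff^2
  }
  out
}

#' Single-frame contact matrix between two reference-point sets
#'
#' A contact is two reference points strictly closer than the cutoff
#' (default 10 Angstrom Euclidean).  Distances honour the minimum-image
#' convention in the membrane plane by default; `"raw"` reproduces naive
#' behaviour.  Neighbour search uses spatial binning with bin width equal
#' to the cutoff.
#'
#' @param points_a,points_b N x 3 matrices (Angstrom), or lists from
#'   [resolve_reference_points()].
#' @param spec a [contact_spec()].
#' @param box box edges (Angstrom); required for minimum-image.
#' @param ids_a,ids_b optional id vectors for dimnames (taken from
#'   reference-point lists automatically).
#' @return logical matrix of class `contact_matrix` (rows = A, columns =
#'   B) with `ids_a`, `ids_b`, `species_b` and `spec` attributes.
#' @export
contact_matrix <- function(points_a, points_b, spec = contact_spec(),
                           box = NULL, ids_a = NULL, ids_b = NULL) {
  species_b <- NULL
  if (is.list(points_a) && !is.null(points_a$points)) {
    ids_a <- ids_a %||% points_a$ids; points_a <- points_a$points
  }
  if (is.list(points_b) && !is.null(points_b$points)) {
    ids_b <- ids_b %||% points_b$ids; species_b <- points_b$species
    points_b <- points_b$points
  }
  a <- as.matrix(points_a); b <- as.matrix(points_b)
  if (!nrow(a) || !nrow(b)) stop("point lists must be nonempty")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("non-finite coordinates in contact input")
  mi <- spec$convention == "min_image"
  if (mi && is.null(box))
    stop("box required for the minimum-image convention")
  m <- .binned_contacts(a, b, spec$cutoff, box, mi)
  structure(m, ids_a = ids_a %||% seq_len(nrow(a)),
            ids_b = ids_b %||% seq_len(nrow(b)),
            species_b = species_b, spec = spec, class = "contact_matrix")
}

#' Contact matrices over a trajectory
#'
#' Resolves reference points (protein residues vs lipid molecules by
#' default) in every frame and computes one [contact_matrix()] per
#' frame.
#'
#' @param frames a [bead_trajectory()] or list of frames.
#' @param species_a,species_b species filters for the two sides
#'   (side A defaults to the protein role, side B to lipids).
#' @param spec a [contact_spec()].
#' @return list of `contact_matrix` objects, class `contact_trajectory`.
#' @export
contact_trajectory <- function(frames, species_a = "CAPS", species_b = NULL,
                               spec = contact_spec()) {
  frames <- as_trajectory(frames)
  if (is.null(species_b)) {
    sp <- unique(frames[[1]]$beads$species)
    species_b <- sp[!species_matches(sp, species_a)]
  }
  lapply(frames, function(fr) {
    ra <- resolve_reference_points(fr, "protein-residue", species = species_a)
    rb <- resolve_reference_points(fr, "lipid-molecule", species = species_b)
    contact_matrix(ra, rb, spec = spec, box = fr$box)
  }) |> structure(class = "contact_trajectory")
}

.check_consistent_ids <- function(mats) {
  ia <- attr(mats[[1]], "ids_a"); ib <- attr(mats[[1]], "ids_b")
  for (m in mats)
    if (!identical(attr(m, "ids_a"), ia) || !identical(attr(m, "ids_b"), ib))
      stop("inconsistent id sets across frames")
  list(ids_a = ia, ids_b = ib)
}

#' Contact frequencies over frames
#'
#' Per-pair counts (number of frames in which the pair is in contact)
#' and per-residue totals (sum over all partners), the quantity written
#' into B-factor columns for visualisation.
#'
#' @param mats a list of [contact_matrix()] objects (one per frame).
#' @return list with `pair` (count matrix) and `residue` (named vector
#'   of per-residue totals).
#' @export
contact_frequency <- function(mats) {
  if (!length(mats)) stop("need at least one frame of contacts")
  ids <- .check_consistent_ids(mats)
  pair <- Reduce(`+`, lapply(mats, function(m)
    matrix(as.integer(m), nrow(m), ncol(m))))
  dimnames(pair) <- list(ids$ids_a, ids$ids_b)
  list(pair = pair,
       residue = stats::setNames(rowSums(pair), ids$ids_a))
}

#' Occupancy fraction of a residue by a lipid species
#'
#' The fraction of frames, within a window, in which the residue is in
#' contact with at least one molecule of the species of interest.
#'
#' @param mats list of [contact_matrix()] objects.
#' @param residue residue id (must be in `ids_a`).
#' @param species optional lipid species (alias-aware); all molecules
#'   when `NULL`.
#' @param window frame-index window `c(start, end)` (inclusive); the
#'   whole trajectory when `NULL`.
#' @return occupancy fraction in [0, 1].
#' @export
occupancy <- function(mats, residue, species = NULL, window = NULL) {
  ids <- .check_consistent_ids(mats)
  ri <- match(residue, ids$ids_a)
  if (is.na(ri)) stop("residue ", residue, " not present in contact matrices")
  window <- window %||% c(1L, length(mats))
  window <- as.integer(window)
  window[1] <- max(window[1], 1L); window[2] <- min(window[2], length(mats))
  if (window[1] > window[2]) stop("empty frame window")
  cols <- seq_along(ids$ids_b)
  if (!is.null(species)) {
    sp <- attr(mats[[1]], "species_b")
    if (is.null(sp)) stop("contact matrices carry no species information")
    cols <- which(species_matches(sp, species))
    if (!length(cols)) return(0)
  }
  hit <- vapply(mats[window[1]:window[2]],
                function(m) any(m[ri, cols]), logical(1))
  mean(hit)
}
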