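#' Coarse-grained bead frame
#'
#' The central container for one trajectory frame: a bead table plus box
#' vectors and the frame time.  Coordinates are in Angstrom, times in
#' picoseconds, everywhere inside the package; unit conversions happen
#' only at file boundaries (GRO and TRR use nm).
#'
#' @param beads a data.frame with columns `name` (bead name, e.g. "PO4",
#'   "BB"), `resid` (integer residue id), `molid` (integer molecule id),
#'   `species` (residue/species label, e.g. "POPC", "DPG3", "CAPS"),
#'   and coordinates `x`, `y`, `z` in Angstrom.
#' @param box numeric length-3 box edge lengths in Angstrom.
#' @param time frame time in ps.
#' @param frame integer frame index.
#' @return an object of class `bead_frame`.
#' @export
bead_frame <- function(beads, box, time = 0, frame = 1L) {
  req <- c("name", "resid", "molid", "species", "x", "y", "z")
  missing_cols <- setdiff(req, names(beads))
  if (length(missing_cols))
    stop("beads table lacks columns: ", paste(missing_cols, collapse = ", "))
  beads <- as.data.frame(beads)[req]
  beads$name <- as.character(beads$name)
  beads$species <- as.character(beads$species)
  beads$resid <- as.integer(beads$resid)
  beads$molid <- as.integer(beads$molid)
  if (!all(is.finite(as.matrix(beads[c("x", "y", "z")]))))
    stop("bead coordinates must all be finite")
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive lengths (Angstrom)")
  structure(list(beads = beads, box = box, time = as.numeric(time),
                 frame = as.integer(frame)),
            class = "bead_frame")
}

#' @export
print.bead_frame <- function(x, ...) {
  cat(sprintf("bead_frame: %d beads, %d molecules, %d species\n",
              nrow(x$beads), length(unique(x$beads$molid)),
              length(unique(x$beads$species))))
  cat(sprintf("  box %.1f x %.1f x %.1f A, t = %g ps (frame %d)\n",
              x$box[1], x$box[2], x$box[3], x$time, x$frame))
  invisible(x)
}

#' @export
nbeads <- function(frame) UseMethod("nbeads")

#' @export
nbeads.bead_frame <- function(frame) nrow(frame$beads)

#' Bead coordinates as a matrix
#' @param frame a [bead_frame()].
#' @param idx optional row indices.
#' @return an N x 3 numeric matrix (Angstrom).
#' @export
coords <- function(frame, idx = NULL) {
  m <- as.matrix(frame$beads[c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Select beads by species, bead name, leaflet, and residue range
#'
#' Resolution is order-stable: indices come back in bead-table order, so
#' repeated calls with the same frame and filters give identical results.
#' Species matching honours the GM3/DPG3 and PIP2/POP2 aliases.
#'
#' @param frame a [bead_frame()].
#' @param species optional character vector of species labels.
#' @param name optional character vector of bead names.
#' @param leaflet optional `"upper"` or `"lower"`; requires `leaflets`.
#' @param leaflets named character vector from [assign_leaflets()]
#'   (molid -> leaflet), required when `leaflet` is given.
#' @param resid optional length-2 integer range `c(lo, hi)`.
#' @return integer vector of bead row indices.
#' @export
select_beads <- function(frame, species = NULL, name = NULL,
                         leaflet = NULL, leaflets = NULL, resid = NULL) {
  b <- frame$beads
  keep <- rep(TRUE, nrow(b))
  if (!is.null(species)) keep <- keep & species_matches(b$species, species)
  if (!is.null(name)) keep <- keep & b$name %in% name
  if (!is.null(resid)) {
    stopifnot(length(resid) == 2)
    keep <- keep & b$resid >= resid[1] & b$resid <= resid[2]
  }
  if (!is.null(leaflet)) {
    if (is.null(leaflets))
      stop("leaflet filtering needs a leaflet assignment (see assign_leaflets)")
    keep <- keep & !is.na(leaflets[as.character(b$molid)]) &
      leaflets[as.character(b$molid)] == leaflet
  }
  which(keep)
}

#' Merge two bead frames (e.g. a membrane patch and a capsid shell)
#'
#' Molecule ids of `b` are shifted above those of `a` so ids stay unique;
#' box and time are taken from `a`.
#'
#' @param a,b [bead_frame()] objects.
#' @return a combined `bead_frame`.
#' @export
merge_frames <- function(a, b) {
  shift <- max(a$beads$molid) - min(b$beads$molid) + 1L
  bb <- b$beads
  bb$molid <- bb$molid + shift
  bead_frame(rbind(a$beads, bb), a$box, a$time, a$frame)
}

#' Bead trajectory: an ordered list of frames
#'
#' Validates that all frames have the same bead count and strictly
#' increasing times.
#'
#' @param frames list of [bead_frame()] objects.
#' @return an object of class `bead_trajectory` (a list of frames).
#' @export
bead_trajectory <- function(frames) {
  if (!length(frames)) stop("empty trajectory")
  stopifnot(all(vapply(frames, inherits, logical(1), "bead_frame")))
  n <- vapply(frames, nbeads, integer(1))
  if (length(unique(n)) != 1)
    stop("frames have inconsistent bead counts: ",
         paste(unique(n), collapse = ", "))
  tt <- vapply(frames, function(f) f$time, numeric(1))
  if (length(tt) > 1 && any(diff(tt) <= 0))
    stop("frame times must be strictly increasing")
  for (i in seq_along(frames)) frames[[i]]$frame <- i
  structure(frames, class = "bead_trajectory")
}

#' @export
print.bead_trajectory <- function(x, ...) {
  tt <- vapply(x, function(f) f$time, numeric(1))
  cat(sprintf("bead_trajectory: %d frames x %d beads, t = %g..%g ps\n",
              length(x), nbeads(x[[1]]), min(tt), max(tt)))
  invisible(x)
}

as_trajectory <- function(x) {
  if (inherits(x, "bead_trajectory")) return(x)
  if (inherits(x, "bead_frame")) return(bead_trajectory(list(x)))
  bead_trajectory(x)
}

#' Ground truth attached to a synthetic scene
#'
#' Synthetic generators attach a `truth` attribute recording the analytic
#' surface, planted cluster labels, rotation schedule, and planted
#' contact pairs.  This accessor retrieves it.
#'
#' @param x a frame or trajectory produced by the synthetic generators.
#' @return the truth list, or `NULL` for non-synthetic input.
#' @export
scene_truth <- function(x) attr(x, "truth", exact = TRUE)
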