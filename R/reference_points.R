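#' Reference points for contact analysis
#'
#' Maps each protein residue or lipid molecule to the single point used
#' in contact detection: the backbone (BB) bead for a protein residue,
#' the centre of geometry of all beads for a lipid molecule — except
#' GM3 (residue name DPG3), whose centre of geometry is buried in the
#' membrane and which therefore uses its carboxyl-group D bead on the
#' second sugar ring.
#'
#' @param frame a [bead_frame()].
#' @param role `"protein-residue"` or `"lipid-molecule"`.
#' @param species optional species filter (alias-aware).
#' @param use_d_bead for lipids, substitute the D bead for GM3/DPG3
#'   molecules (the contact-analysis convention).  Set `FALSE` to use
#'   plain centres of geometry for every species (the lipid-clustering
#'   convention).
#' @param d_bead_pattern regular expression identifying the D-role bead
#'   name within a GM3 molecule.
#' @return list with `points` (M x 3 matrix, Angstrom), `ids` (residue
#'   ids or molecule ids, in ascending order) and `species` (per point).
#' @export
resolve_reference_points <- function(frame, role = c("protein-residue",
                                                     "lipid-molecule"),
                                     species = NULL, use_d_bead = TRUE,
                                     d_bead_pattern = "^D") {
  role <- match.arg(role)
  b <- frame$beads
  if (!is.null(species)) b <- b[species_matches(b$species, species), ,
                               drop = FALSE]
  if (!nrow(b)) stop("no beads match the requested species")
  if (role == "protein-residue") {
    ids <- sort(unique(b$resid))
    bb <- b[b$name == "BB", , drop = FALSE]
    missing <- setdiff(ids, bb$resid)
    if (length(missing))
      stop("protein residue(s) lacking a BB bead: ",
           paste(utils::head(missing, 5), collapse = ", "))
    bb <- bb[match(ids, bb$resid), , drop = FALSE]
    list(points = as.matrix(bb[c("x", "y", "z")]), ids = ids,
         species = bb$species)
  } else {
    ids <- sort(unique(b$molid))
    pts <- matrix(NA_real_, length(ids), 3,
                  dimnames = list(NULL, c("x", "y", "z")))
    spc <- character(length(ids))
    rows <- split(seq_len(nrow(b)), factor(b$molid, levels = ids))
    for (i in seq_along(ids)) {
      m <- b[rows[[i]], , drop = FALSE]
      spc[i] <- m$species[1]
      if (use_d_bead && species_matches(spc[i], "GM3")[1]) {
        d <- grepl(d_bead_pattern, m$name)
        if (!any(d))
          stop("GM3 molecule ", ids[i], " lacks a D bead (pattern '",
               d_bead_pattern, "')")
        pts[i, ] <- as.numeric(m[which(d)[1], c("x", "y", "z")])
      } else {
        pts[i, ] <- colMeans(m[c("x", "y", "z")])
      }
    }
    list(points = pts, ids = ids, species = spc)
  }
}
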