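#' Capsid orientation angle time series
#'
#' Tracks the rotation of a rigid body (the capsid) by the body-fixed
#' vector between two chosen residues' BB beads: per frame, the unit
#' vector from residue `residue_a` to residue `residue_b` is dotted with
#' the first frame's unit vector and the (clamped) arc-cosine is
#' reported in degrees.  The residue pair should span the body —
#' approximately parallel to the capsid diameter — because rotation
#' about the axis parallel to the reference vector is invisible to a
#' single-vector measure.
#'
#' @param frames a [bead_trajectory()] or list of frames.
#' @param residue_a,residue_b residue ids of the two anchor residues.
#' @param species optional species filter for the anchors (default
#'   `"CAPS"`, the capsid shell label).
#' @return data.frame of class `orientation_series` with `frame`,
#'   `time_ps`, `angle_deg` (in [0, 180]; 0 at the reference frame).
#' @export
orientation_angles <- function(frames, residue_a, residue_b,
                               species = "CAPS") {
  frames <- as_trajectory(frames)
  anchor <- function(fr, rid) {
    b <- fr$beads
    sel <- b$resid == rid & b$name == "BB"
    if (!is.null(species)) sel <- sel & species_matches(b$species, species)
    i <- which(sel)
    if (!length(i)) stop("residue ", rid, " (BB bead) missing in frame ",
                         fr$frame)
    as.numeric(b[i[1], c("x", "y", "z")])
  }
  unitv <- function(fr) {
    v <- anchor(fr, residue_b) - anchor(fr, residue_a)
    n <- sqrt(sum(v^2))
    if (n == 0) stop("zero-length orientation vector in frame ", fr$frame)
    v / n
  }
  v0 <- unitv(frames[[1]])
  ang <- vapply(frames, function(fr) {
    v <- unitv(fr)
    d <- clamp(sum(v * v0), -1, 1)
    # atan2 form of arccos(v . v0): identical in exact arithmetic but
    # stable near 0 and 180 degrees, where acos loses precision
    cr <- c(v[2] * v0[3] - v[3] * v0[2],
            v[3] * v0[1] - v[1] * v0[3],
            v[1] * v0[2] - v[2] * v0[1])
    atan2(sqrt(sum(cr^2)), d) * 180 / pi
  }, numeric(1))
  out <- data.frame(frame = seq_along(frames),
                    time_ps = vapply(frames, function(f) f$time, numeric(1)),
                    angle_deg = ang)
  class(out) <- c("orientation_series", "data.frame")
  out
}

#' @export
plot.orientation_series <- function(x, window = 200, ...) {
  graphics::plot(x$time_ps, x$angle_deg, type = "l", col = "grey70",
                 xlab = "time (ps)", ylab = "angle (deg)",
                 ylim = c(0, 180), ...)
  graphics::lines(x$time_ps, rolling_mean(x$angle_deg, window), lwd = 2)
  invisible(x)
}
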