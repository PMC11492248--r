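#' Gridded lipid counts and height deviations for one frame
#'
#' Tiles the membrane plane [0, Lx) x [0, Ly) with squares of the given
#' edge (default 18 Angstrom; a final partial column/row is kept as a
#' smaller square so molecule counts are conserved).  For each square i
#' it records L_i, the number of molecules of the species of interest
#' whose reference point (centre of geometry) falls in the square, and
#' Delta-z_i, the deviation of the mean height of the PO4 beads in the
#' square from the mean height of all PO4 beads of the designated
#' leaflet in that frame.  Squares containing no PO4 bead get `NA`
#' height deviation and are excluded from the correlation's N; squares
#' with PO4 beads but no molecules of the species still count, with
#' L_i = 0.
#'
#' @param frame a [bead_frame()].
#' @param species lipid species of interest (alias-aware).
#' @param edge grid square edge in Angstrom (default 18).
#' @param leaflet which molecules to count, by initial leaflet
#'   (`"upper"`, `"lower"`, or `NULL` for all).
#' @param dz_source PO4 beads defining the height field: `"upper"`
#'   (default, the curvature convention) or `"all"`.
#' @param leaflets optional leaflet assignment (frozen from frame 1 of a
#'   trajectory); computed from this frame when absent.
#' @return data.frame of class `grid_field` with `square`, `ix`, `iy`,
#'   `L`, `dz`; attributes `species`, `edge`, `frame`, `time_ps`.
#' @export
grid_fields <- function(frame, species, edge = 18, leaflet = "upper",
                        dz_source = c("upper", "all"), leaflets = NULL) {
  dz_source <- match.arg(dz_source)
  if (any(frame$box[1:2] < edge))
    stop("box in-plane dimensions must fit at least one grid square")
  leaflets <- leaflets %||% assign_leaflets(frame, quiet = TRUE)
  nx <- ceiling(frame$box[1] / edge); ny <- ceiling(frame$box[2] / edge)
  sq_of <- function(x, y) {
    ix <- pmin(floor((x %% frame$box[1]) / edge), nx - 1)
    iy <- pmin(floor((y %% frame$box[2]) / edge), ny - 1)
    ix + nx * iy + 1L
  }
  g <- expand.grid(ix = 0:(nx - 1), iy = 0:(ny - 1))
  g$square <- seq_len(nrow(g))

  # species molecule counts by reference point
  rp <- resolve_reference_points(frame, "lipid-molecule", species = species,
                                 use_d_bead = FALSE)
  sel <- rep(TRUE, length(rp$ids))
  if (!is.null(leaflet))
    sel <- leaflets[as.character(rp$ids)] == leaflet & !is.na(
      leaflets[as.character(rp$ids)])
  if (!any(sel))
    warning("species '", species, "' absent from the requested leaflet; ",
            "all counts zero")
  Lcnt <- tabulate(sq_of(rp$points[sel, 1], rp$points[sel, 2]), nrow(g))

  # PO4 height field
  b <- frame$beads
  po4 <- b[b$name == "PO4", , drop = FALSE]
  if (dz_source == "upper") {
    lf <- leaflets[as.character(po4$molid)]
    po4 <- po4[!is.na(lf) & lf == "upper", , drop = FALSE]
  }
  if (!nrow(po4)) stop("no PO4 beads available for the height field")
  sq <- sq_of(po4$x, po4$y)
  zbar <- tapply(po4$z, factor(sq, levels = g$square), mean)
  dz <- as.numeric(zbar) - mean(po4$z)

  out <- data.frame(square = g$square, ix = g$ix, iy = g$iy,
                    L = as.integer(Lcnt), dz = dz)
  structure(out, species = species, edge = edge, frame = frame$frame,
            time_ps = frame$time,
            class = c("grid_field", "data.frame"))
}

#' Cross-correlation between lipid counts and height deviation
#'
#' The per-frame correlation
#' \deqn{\rho = \frac{1}{N}\sum_i \frac{(L_i - \langle L\rangle)
#'   (\Delta z_i - \langle\Delta z\rangle)}{\sigma_L\,\sigma_{\Delta z}}}
#' over the N grid squares with a defined height deviation, using
#' population (1/N) moments within the frame.  Returns `NA` when either
#' field has zero variance.
#'
#' @param field a [grid_fields()] result.
#' @return list with `rho` and `n` (squares used).
#' @export
cross_correlation <- function(field) {
  ok <- !is.na(field$dz)
  n <- sum(ok)
  if (n < 2) stop("need at least 2 grid squares with defined height")
  L <- field$L[ok]; dz <- field$dz[ok]
  sL <- sqrt(mean((L - mean(L))^2))
  sz <- sqrt(mean((dz - mean(dz))^2))
  if (sL == 0 || sz == 0) return(list(rho = NA_real_, n = n))
  list(rho = mean((L - mean(L)) * (dz - mean(dz))) / (sL * sz), n = n)
}

#' Per-frame lipid-density / curvature correlation time series
#'
#' One correlation per frame per species, with molecules stratified by
#' the leaflet they occupied in the first frame.
#'
#' @param frames a [bead_trajectory()] or list of frames.
#' @param species character vector of species of interest.
#' @param edge grid edge (Angstrom).
#' @param leaflet initial-leaflet stratum for the counts.
#' @param dz_source see [grid_fields()].
#' @return data.frame of class `correlation_series` with `frame`,
#'   `time_ps`, `species`, `leaflet_origin`, `rho`, `n_squares`.
#' @export
correlation_series <- function(frames, species, edge = 18,
                               leaflet = "upper", dz_source = "upper") {
  frames <- as_trajectory(frames)
  leaflets <- assign_leaflets(frames[[1]], quiet = TRUE)
  out <- vector("list", length(frames) * length(species))
  k <- 0
  for (i in seq_along(frames)) for (sp in species) {
    gf <- grid_fields(frames[[i]], sp, edge = edge, leaflet = leaflet,
                      dz_source = dz_source, leaflets = leaflets)
    cc <- cross_correlation(gf)
    k <- k + 1
    out[[k]] <- data.frame(frame = i, time_ps = frames[[i]]$time,
                           species = sp, leaflet_origin = leaflet,
                           rho = cc$rho, n_squares = cc$n)
  }
  res <- do.call(rbind, out)
  class(res) <- c("correlation_series", "data.frame")
  res
}
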