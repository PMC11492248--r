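#' Per-bead normal curvatures and unsigned Gaussian curvature
#'
#' Evaluates, from the analytic derivatives of a fitted (or analytic)
#' surface, the normal curvatures along the box axes,
#' \deqn{\kappa_x = z_{xx} / (1 + z_x^2)^{3/2}, \quad
#'       \kappa_y = z_{yy} / (1 + z_y^2)^{3/2},}
#' and the unsigned Gaussian curvature |K| = |kappa_x * kappa_y| at each
#' planar position.  The box axes are treated as the principal
#' directions, the usual Monge-patch reading for a nearly planar
#' membrane; see [shape_operator_curvatures()] for the full
#' eigen-decomposition alternative.
#'
#' @param surface a [surface_fit()] or [surface_params()] object.
#' @param xy data.frame or matrix of planar positions; for a fit the
#'   default is the fitted bead positions.
#' @return data.frame with `x`, `y`, `kx`, `ky` (1/Angstrom) and
#'   `abs_K` (1/Angstrom^2).
#' @export
bead_curvatures <- function(surface, xy = NULL) {
  if (inherits(surface, "surface_fit")) {
    params <- structure(list(form_id = surface$form,
                             pars = surface$coefficients),
                        class = "surface_params")
    if (is.null(xy)) xy <- surface$data[c("x", "y")]
  } else if (inherits(surface, "surface_params")) {
    params <- surface
    if (is.null(xy)) stop("xy positions required for an analytic surface")
  } else stop("surface must be a surface_fit or surface_params")
  xy <- as.data.frame(as.matrix(xy))
  names(xy)[1:2] <- c("x", "y")
  g1 <- surface_eval(params, xy$x, xy$y, "grad")
  g2 <- surface_eval(params, xy$x, xy$y, "hess")
  kx <- g2$zxx / (1 + g1$zx^2)^(3 / 2)
  ky <- g2$zyy / (1 + g1$zy^2)^(3 / 2)
  data.frame(x = xy$x, y = xy$y, kx = kx, ky = ky, abs_K = abs(kx * ky))
}

#' Principal curvatures from the full shape operator
#'
#' Eigen-decomposition of the Monge-patch shape operator (Weingarten
#' map), offered as the alternative to the axis-aligned convention of
#' [bead_curvatures()].  Requires the mixed second partial, so it is
#' available for forms that are polynomial in x and y or at positions
#' where the mixed term can be obtained by central differences.
#'
#' @param surface a [surface_fit()] or [surface_params()] object.
#' @param xy planar positions.
#' @param h finite-difference step (Angstrom) for the mixed partial.
#' @return data.frame with `k1`, `k2` (principal curvatures, |k1| >=
#'   |k2|) and `abs_K`.
#' @export
shape_operator_curvatures <- function(surface, xy, h = 1e-3) {
  if (inherits(surface, "surface_fit"))
    surface <- structure(list(form_id = surface$form,
                              pars = surface$coefficients),
                         class = "surface_params")
  xy <- as.data.frame(as.matrix(xy)); names(xy)[1:2] <- c("x", "y")
  g1 <- surface_eval(surface, xy$x, xy$y, "grad")
  g2 <- surface_eval(surface, xy$x, xy$y, "hess")
  # z_xy by central differences of the analytic z_x in y
  zxy <- (surface_eval(surface, xy$x, xy$y + h, "grad")$zx -
            surface_eval(surface, xy$x, xy$y - h, "grad")$zx) / (2 * h)
  n <- nrow(xy)
  k1 <- k2 <- numeric(n)
  for (i in seq_len(n)) {
    E <- 1 + g1$zx[i]^2; F <- g1$zx[i] * g1$zy[i]; G <- 1 + g1$zy[i]^2
    w <- sqrt(E + G - 1)
    L <- g2$zxx[i] / w; M <- zxy[i] / w; N <- g2$zyy[i] / w
    S <- solve(matrix(c(E, F, F, G), 2), matrix(c(L, M, M, N), 2))
    ev <- sort(eigen(S, only.values = TRUE)$values, decreasing = TRUE)
    k1[i] <- ev[1]; k2[i] <- ev[2]
  }
  data.frame(x = xy$x, y = xy$y, k1 = k1, k2 = k2, abs_K = abs(k1 * k2))
}

#' Per-frame membrane curvature time series
#'
#' Fits the upper-leaflet PO4 bead cloud of every frame independently
#' (no warm start by default, so each frame stands on its own) and
#' reports the arithmetic mean of the per-bead unsigned Gaussian
#' curvature together with the fit's RMS residual.
#'
#' @param frames a [bead_trajectory()] or list of frames.
#' @param form surface form id.
#' @param leaflets optional leaflet assignment; computed from the first
#'   frame and frozen when absent.
#' @param selection optional function(frame, leaflets) -> bead indices;
#'   default selects upper-leaflet PO4 beads.
#' @param warm_start reuse each frame's coefficients to initialise the
#'   next fit?
#' @param store_fits keep the per-frame `surface_fit` objects in the
#'   `fits` attribute?
#' @return data.frame of class `curvature_series` with columns `frame`,
#'   `time_ps`, `mean_abs_K` (1/Angstrom^2) and `rms_residual_A`.
#' @export
curvature_series <- function(frames, form = "gauss_dimple", leaflets = NULL,
                             selection = NULL, warm_start = FALSE,
                             store_fits = FALSE) {
  frames <- as_trajectory(frames)
  if (is.null(leaflets)) leaflets <- assign_leaflets(frames[[1]], quiet = TRUE)
  if (is.null(selection))
    selection <- function(fr, lf)
      select_beads(fr, name = "PO4", leaflet = "upper", leaflets = lf)
  out <- data.frame(frame = integer(), time_ps = numeric(),
                    mean_abs_K = numeric(), rms_residual_A = numeric())
  fits <- vector("list", length(frames))
  init <- NULL
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    idx <- selection(fr, leaflets)
    if (!length(idx))
      stop("empty bead selection in frame ", i)
    fit <- surface_fit(coords(fr, idx), form = form, box = fr$box,
                       init = if (warm_start) init)
    fit$time <- fr$time; fit$frame <- i
    cv <- bead_curvatures(fit)
    out[i, ] <- list(i, fr$time, mean(cv$abs_K), fit$rms_residual)
    if (warm_start) init <- fit$coefficients
    if (store_fits) fits[[i]] <- fit
  }
  class(out) <- c("curvature_series", "data.frame")
  if (store_fits) attr(out, "fits") <- fits
  out
}

#' @export
plot.curvature_series <- function(x, window = 200, ...) {
  graphics::plot(x$time_ps, x$mean_abs_K, type = "l", col = "grey70",
                 xlab = "time (ps)", ylab = "mean |K| (A^-2)", ...)
  graphics::lines(x$time_ps, rolling_mean(x$mean_abs_K, window), lwd = 2)
  invisible(x)
}
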