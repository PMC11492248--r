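#' Analytic surface parameters
#'
#' A small container pairing a registered form id with a named parameter
#' vector; used both as ground truth in the synthetic generators and as
#' an optional initial guess for [surface_fit()].
#'
#' @param form_id a registered surface form (see [surface_forms()]).
#' @param ... named parameters; unnamed defaults of the form are zero
#'   except widths, which must be given when the form has them.
#' @return an object of class `surface_params`.
#' @export
surface_params <- function(form_id = "gauss_dimple", ...) {
  form <- surface_form(form_id)
  supplied <- c(...)
  p <- stats::setNames(rep(0, length(form$par_names)), form$par_names)
  if (length(supplied)) {
    bad <- setdiff(names(supplied), form$par_names)
    if (length(bad)) stop("unknown parameters for form '", form_id, "': ",
                          paste(bad, collapse = ", "))
    p[names(supplied)] <- supplied
  }
  if (all(c("sx", "sy") %in% form$par_names) && any(p[c("sx", "sy")] <= 0))
    stop("dimple widths sx, sy must be > 0")
  structure(list(form_id = form_id, pars = p), class = "surface_params")
}

#' Evaluate a parametric surface and its derivatives
#'
#' @param params a [surface_params()] object.
#' @param x,y planar coordinates (Angstrom).
#' @param what `"z"`, `"grad"` or `"hess"`.
#' @return heights, or a list of first/second partials.
#' @export
surface_eval <- function(params, x, y, what = c("z", "grad", "hess")) {
  what <- match.arg(what)
  form <- surface_form(params$form_id)
  switch(what,
         z = unname(form$height(params$pars, x, y)),
         grad = form$grad(params$pars, x, y),
         hess = form$hess(params$pars, x, y))
}

#' Fit a Monge-patch height function to a bead cloud
#'
#' Fits the height surface z(x, y) of a registered form to points by
#' least squares: the membrane-curvature workhorse.  Nonlinear forms (the
#' default plane-plus-Gaussian-dimple) are fitted by Levenberg-Marquardt
#' (via \pkg{minpack.lm}) with an analytic parameter Jacobian; forms
#' linear in their parameters are solved exactly by QR.  Given a
#' [bead_frame()], the fit uses the upper-leaflet PO4 beads.
#'
#' @param points an N x 3 matrix, a data.frame with `x`,`y`,`z`, or a
#'   [bead_frame()].
#' @param form a registered form id; default `"gauss_dimple"`.
#' @param init optional [surface_params()] or named start vector;
#'   defaults to the form's deterministic initialisation (plane at the
#'   mean height, dimple on the lowest bead, widths of box/6).
#' @param box optional box edges (Angstrom), used by the initialisation;
#'   taken from the frame when fitting a `bead_frame`.
#' @param leaflets optional leaflet assignment for `bead_frame` input;
#'   computed from the frame itself when absent.
#' @param control list of convergence controls: `ftol` (relative cost
#'   change, default 1e-10) and `maxiter` (default 1024).
#' @return an object of class `surface_fit` with components
#'   `coefficients`, `form`, `rms_residual` (Angstrom), `data` (the
#'   points with fitted heights and residuals), and convergence info.
#' @examples
#' tr <- surface_params("gauss_dimple", c0 = 60, A = -30,
#'                      x0 = 250, y0 = 250, sx = 80, sy = 80)
#' xy <- expand.grid(x = seq(5, 495, by = 14), y = seq(5, 495, by = 14))
#' pts <- cbind(xy, z = surface_eval(tr, xy$x, xy$y))
#' fit <- surface_fit(pts, box = c(500, 500, 100))
#' coef(fit)["A"]   # recovers -30
#' @export
surface_fit <- function(points, form = "gauss_dimple", init = NULL,
                        box = NULL, leaflets = NULL, control = list()) {
  time <- 0; frame_idx <- NA_integer_
  if (inherits(points, "bead_frame")) {
    fr <- points
    if (is.null(leaflets)) leaflets <- assign_leaflets(fr, quiet = TRUE)
    idx <- select_beads(fr, name = "PO4", leaflet = "upper",
                        leaflets = leaflets)
    if (!length(idx)) stop("no upper-leaflet PO4 beads to fit")
    points <- coords(fr, idx)
    box <- box %||% fr$box
    time <- fr$time; frame_idx <- fr$frame
  }
  pts <- as.data.frame(as.matrix(points))
  names(pts)[1:3] <- c("x", "y", "z")
  if (!all(is.finite(as.matrix(pts)))) stop("points must be finite")
  fdef <- surface_form(form)
  npar <- length(fdef$par_names)
  if (nrow(pts) < npar)
    stop(sprintf("need at least %d points to fit form '%s', got %d",
                 npar, form, nrow(pts)))
  sv <- svd(scale(cbind(pts$x, pts$y), scale = FALSE), nu = 0, nv = 0)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("points are collinear in (x, y); the surface is unidentifiable")
  ctl <- utils::modifyList(list(ftol = 1e-10, maxiter = 1024), control)

  if (is.null(init)) {
    p0 <- fdef$init(pts$x, pts$y, pts$z, box)
  } else if (inherits(init, "surface_params")) {
    if (init$form_id != form) stop("init is for form '", init$form_id, "'")
    p0 <- init$pars
  } else p0 <- init[fdef$par_names]

  if (isTRUE(fdef$linear)) {
    X <- fdef$design(pts$x, pts$y)
    qrX <- qr(X)
    if (qrX$rank < npar)
      stop("design matrix is rank-deficient (degenerate point layout)")
    cf <- stats::setNames(as.numeric(qr.coef(qrX, pts$z)), fdef$par_names)
    conv <- list(converged = TRUE, iterations = 0L, message = "linear solve")
  } else {
    res_fn <- function(p) {
      p <- stats::setNames(p, fdef$par_names)
      pts$z - fdef$height(p, pts$x, pts$y)
    }
    jac_fn <- if (!is.null(fdef$jac)) function(p) {
      p <- stats::setNames(p, fdef$par_names)
      -fdef$jac(p, pts$x, pts$y)
    }
    out <- minpack.lm::nls.lm(
      par = p0, fn = res_fn, jac = jac_fn,
      control = minpack.lm::nls.lm.control(
        ftol = ctl$ftol, ptol = 1e-12, maxiter = min(ctl$maxiter, 1024)))
    if (!out$info %in% 1:4)
      stop("Levenberg-Marquardt did not converge (", out$message,
           "); last iterate: ",
           paste(sprintf("%s=%.4g", fdef$par_names, out$par), collapse = ", "))
    cf <- stats::setNames(as.numeric(out$par), fdef$par_names)
    conv <- list(converged = TRUE, iterations = out$niter,
                 message = out$message)
  }
  # widths are identified only up to sign; report them positive
  for (w in intersect(c("sx", "sy", "wx", "wy"), names(cf)))
    cf[w] <- abs(cf[w])
  fitted_z <- fdef$height(cf, pts$x, pts$y)
  res <- pts$z - fitted_z
  structure(list(coefficients = cf, form = form,
                 rms_residual = sqrt(mean(res^2)),
                 data = cbind(pts, fitted = fitted_z, residual = res),
                 convergence = conv, time = time, frame = frame_idx),
            class = "surface_fit")
}

#' @export
print.surface_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Monge-patch surface fit (form '%s', %d beads)\n",
              x$form, nrow(x$data)))
  print(round(x$coefficients, digits))
  cat(sprintf("RMS residual: %.4g A\n", x$rms_residual))
  invisible(x)
}

#' @export
coef.surface_fit <- function(object, ...) object$coefficients

#' @export
fitted.surface_fit <- function(object, ...) object$data$fitted

#' @export
residuals.surface_fit <- function(object, ...) object$data$residual

#' @export
deviance.surface_fit <- function(object, ...) sum(object$data$residual^2)

#' Predict surface heights at new planar positions
#' @param object a [surface_fit()].
#' @param newdata data.frame with `x` and `y` (Angstrom); defaults to the
#'   fitted bead positions.
#' @param ... unused.
#' @return numeric vector of heights (Angstrom).
#' @export
predict.surface_fit <- function(object, newdata = NULL, ...) {
  fdef <- surface_form(object$form)
  if (is.null(newdata)) return(object$data$fitted)
  fdef$height(object$coefficients, newdata$x, newdata$y)
}

#' @export
summary.surface_fit <- function(object, ...) {
  cv <- bead_curvatures(object)
  structure(list(fit = object, mean_abs_K = mean(cv$abs_K),
                 n = nrow(object$data)),
            class = "summary.surface_fit")
}

#' @export
print.summary.surface_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("mean |K| over %d beads: %.4g A^-2\n", x$n, x$mean_abs_K))
  invisible(x)
}

#' Draw bead heights from a fitted surface
#'
#' Simulates new z values at the fitted (x, y) positions: the fitted
#' height plus Gaussian noise with the fit's RMS residual as standard
#' deviation.  Useful for parametric-bootstrap style checks.
#'
#' @param object a [surface_fit()].
#' @param nsim number of replicate height vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a data.frame with `nsim` columns of simulated heights.
#' @export
simulate.surface_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$data)
  out <- as.data.frame(replicate(
    nsim, object$data$fitted + stats::rnorm(n, 0, object$rms_residual)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Contour plot of a fitted membrane surface
#' @param x a [surface_fit()].
#' @param n grid resolution per axis.
#' @param points overlay the fitted beads?
#' @param ... passed to [graphics::image()].
#' @export
plot.surface_fit <- function(x, n = 80, points = TRUE, ...) {
  gx <- seq(min(x$data$x), max(x$data$x), length.out = n)
  gy <- seq(min(x$data$y), max(x$data$y), length.out = n)
  g <- expand.grid(x = gx, y = gy)
  z <- matrix(predict(x, g), n, n)
  graphics::image(gx, gy, z, xlab = "x (A)", ylab = "y (A)",
                  main = sprintf("fitted surface ('%s')", x$form),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::contour(gx, gy, z, add = TRUE)
  if (points) graphics::points(x$data$x, x$data$y, pch = ".", col = "white")
  invisible(x)
}
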