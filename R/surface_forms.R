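# Registry of parametric Monge-patch height functions z(x, y).
#
# Each form supplies the height, its first and second partial derivatives
# in x and y (analytic, used for curvature), the derivative of the height
# with respect to each parameter (analytic Jacobian for the LM fit), a
# deterministic initialisation rule, and whether the model is linear in
# its parameters (in which case the fit is solved exactly by QR).

.surface_forms <- new.env(parent = emptyenv())

#' Register a Monge-patch surface form
#'
#' Adds a height-function family to the registry used by [surface_fit()].
#'
#' @param form_id identifier string.
#' @param par_names character vector of parameter names.
#' @param height function(p, x, y) -> z.
#' @param grad function(p, x, y) -> list(zx, zy) of first partials.
#' @param hess function(p, x, y) -> list(zxx, zyy) of pure second partials.
#' @param jac function(p, x, y) -> N x npar matrix of d z / d p, or NULL
#'   for linear forms.
#' @param init function(x, y, z, box) -> named start vector.
#' @param linear is the model linear in its parameters?
#' @param design for linear forms, function(x, y) -> design matrix.
#' @return `form_id`, invisibly.
#' @export
register_surface_form <- function(form_id, par_names, height, grad, hess,
                                  jac = NULL, init, linear = FALSE,
                                  design = NULL) {
  assign(form_id, list(form_id = form_id, par_names = par_names,
                       height = height, grad = grad, hess = hess,
                       jac = jac, init = init, linear = linear,
                       design = design),
         envir = .surface_forms)
  invisible(form_id)
}

#' Look up a registered surface form
#' @param form_id identifier string.
#' @return the form definition list.
#' @export
surface_form <- function(form_id) {
  if (!exists(form_id, envir = .surface_forms))
    stop("unknown surface form '", form_id, "'; available: ",
         paste(surface_forms(), collapse = ", "))
  get(form_id, envir = .surface_forms)
}

#' List registered surface forms
#' @return character vector of form ids.
#' @export
surface_forms <- function() sort(ls(.surface_forms))

## ---- plane: z = c0 + c1 x + c2 y ------------------------------------

register_surface_form(
  "plane",
  par_names = c("c0", "c1", "c2"),
  height = function(p, x, y) p[["c0"]] + p[["c1"]] * x + p[["c2"]] * y,
  grad = function(p, x, y)
    list(zx = rep(p[["c1"]], length(x)), zy = rep(p[["c2"]], length(x))),
  hess = function(p, x, y)
    list(zxx = rep(0, length(x)), zyy = rep(0, length(x))),
  init = function(x, y, z, box) c(c0 = mean(z), c1 = 0, c2 = 0),
  linear = TRUE,
  design = function(x, y) cbind(c0 = 1, c1 = x, c2 = y)
)

## ---- gauss_dimple: plane + anisotropic Gaussian depression ----------
# z = c0 + c1 x + c2 y + A exp(-((x-x0)^2/(2 sx^2) + (y-y0)^2/(2 sy^2)))
# The default family: a roughly planar plasma-membrane patch with one
# capsid-induced dimple (A < 0 means a downward depression).

.gauss_core <- function(p, x, y) {
  u <- (x - p[["x0"]]) / p[["sx"]]
  v <- (y - p[["y0"]]) / p[["sy"]]
  list(u = u, v = v, g = exp(-(u^2 + v^2) / 2))
}

register_surface_form(
  "gauss_dimple",
  par_names = c("c0", "c1", "c2", "A", "x0", "y0", "sx", "sy"),
  height = function(p, x, y) {
    k <- .gauss_core(p, x, y)
    p[["c0"]] + p[["c1"]] * x + p[["c2"]] * y + p[["A"]] * k$g
  },
  grad = function(p, x, y) {
    k <- .gauss_core(p, x, y)
    list(zx = p[["c1"]] - p[["A"]] * k$g * k$u / p[["sx"]],
         zy = p[["c2"]] - p[["A"]] * k$g * k$v / p[["sy"]])
  },
  hess = function(p, x, y) {
    k <- .gauss_core(p, x, y)
    list(zxx = p[["A"]] * k$g * (k$u^2 - 1) / p[["sx"]]^2,
         zyy = p[["A"]] * k$g * (k$v^2 - 1) / p[["sy"]]^2)
  },
  jac = function(p, x, y) {
    k <- .gauss_core(p, x, y)
    cbind(c0 = rep(1, length(x)), c1 = x, c2 = y, A = k$g,
          x0 = p[["A"]] * k$g * k$u / p[["sx"]],
          y0 = p[["A"]] * k$g * k$v / p[["sy"]],
          sx = p[["A"]] * k$g * k$u^2 / p[["sx"]],
          sy = p[["A"]] * k$g * k$v^2 / p[["sy"]])
  },
  # Deterministic, basin-reasonable start: plane at the mean height, the
  # dimple centred on the lowest bead with amplitude min(z) - mean(z) and
  # widths of a sixth of the box edge.
  init = function(x, y, z, box) {
    i <- which.min(z)
    lx <- if (!is.null(box)) box[1] else diff(range(x))
    ly <- if (!is.null(box)) box[2] else diff(range(y))
    a0 <- min(z) - mean(z)
    c(c0 = mean(z), c1 = 0, c2 = 0,
      A = if (a0 == 0) -1e-3 else a0,
      x0 = x[i], y0 = y[i], sx = lx / 6, sy = ly / 6)
  }
)

## ---- biquadratic: full quadratic polynomial in (x, y) ---------------

register_surface_form(
  "biquadratic",
  par_names = c("c0", "c1", "c2", "c3", "c4", "c5"),
  height = function(p, x, y)
    p[["c0"]] + p[["c1"]] * x + p[["c2"]] * y + p[["c3"]] * x^2 +
      p[["c4"]] * x * y + p[["c5"]] * y^2,
  grad = function(p, x, y)
    list(zx = p[["c1"]] + 2 * p[["c3"]] * x + p[["c4"]] * y,
         zy = p[["c2"]] + p[["c4"]] * x + 2 * p[["c5"]] * y),
  hess = function(p, x, y)
    list(zxx = rep(2 * p[["c3"]], length(x)),
         zyy = rep(2 * p[["c5"]], length(x))),
  init = function(x, y, z, box)
    c(c0 = mean(z), c1 = 0, c2 = 0, c3 = 0, c4 = 0, c5 = 0),
  linear = TRUE,
  design = function(x, y)
    cbind(c0 = 1, c1 = x, c2 = y, c3 = x^2, c4 = x * y, c5 = y^2)
)

## ---- cosine: separable cosine bump ----------------------------------
# z = c0 + A cos(pi (x - x0) / (2 wx)) cos(pi (y - y0) / (2 wy)),
# an alternative single-depression family with compact-looking support.

register_surface_form(
  "cosine",
  par_names = c("c0", "A", "x0", "y0", "wx", "wy"),
  height = function(p, x, y)
    p[["c0"]] + p[["A"]] * cos(pi * (x - p[["x0"]]) / (2 * p[["wx"]])) *
      cos(pi * (y - p[["y0"]]) / (2 * p[["wy"]])),
  grad = function(p, x, y) {
    ax <- pi / (2 * p[["wx"]]); ay <- pi / (2 * p[["wy"]])
    cx <- cos(ax * (x - p[["x0"]])); sx <- sin(ax * (x - p[["x0"]]))
    cy <- cos(ay * (y - p[["y0"]])); sy <- sin(ay * (y - p[["y0"]]))
    list(zx = -p[["A"]] * ax * sx * cy, zy = -p[["A"]] * ay * cx * sy)
  },
  hess = function(p, x, y) {
    ax <- pi / (2 * p[["wx"]]); ay <- pi / (2 * p[["wy"]])
    cx <- cos(ax * (x - p[["x0"]])); cy <- cos(ay * (y - p[["y0"]]))
    list(zxx = -p[["A"]] * ax^2 * cx * cy, zyy = -p[["A"]] * ay^2 * cx * cy)
  },
  jac = function(p, x, y) {
    ax <- pi / (2 * p[["wx"]]); ay <- pi / (2 * p[["wy"]])
    dx <- x - p[["x0"]]; dy <- y - p[["y0"]]
    cx <- cos(ax * dx); sx <- sin(ax * dx)
    cy <- cos(ay * dy); sy <- sin(ay * dy)
    cbind(c0 = rep(1, length(x)), A = cx * cy,
          x0 = p[["A"]] * ax * sx * cy,
          y0 = p[["A"]] * ay * cx * sy,
          wx = p[["A"]] * ax * dx / p[["wx"]] * sx * cy,
          wy = p[["A"]] * ay * dy / p[["wy"]] * cx * sy)
  },
  init = function(x, y, z, box) {
    i <- which.min(z)
    lx <- if (!is.null(box)) box[1] else diff(range(x))
    ly <- if (!is.null(box)) box[2] else diff(range(y))
    a0 <- min(z) - mean(z)
    c(c0 = mean(z), A = if (a0 == 0) -1e-3 else a0,
      x0 = x[i], y0 = y[i], wx = lx / 4, wy = ly / 4)
  }
)
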