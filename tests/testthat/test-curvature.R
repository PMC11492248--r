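grid_pts <- function(truth, n = 30, box = c(500, 500, 200)) {
  xy <- expand.grid(x = seq(box[1] / (2 * n), box[1], by = box[1] / n),
                    y = seq(box[2] / (2 * n), box[2], by = box[2] / n))
  cbind(xy, z = surface_eval(truth, xy$x, xy$y))
}

test_that("a flat bead cloud fits to an exact plane", {
  pts <- cbind(expand.grid(x = seq(0, 100, 10), y = seq(0, 100, 10)), z = 50)
  fit <- surface_fit(pts, form = "gauss_dimple", box = c(100, 100, 100))
  cf <- coef(fit)
  expect_equal(unname(cf["c0"]), 50, tolerance = 1e-6)
  expect_lt(max(abs(cf[c("c1", "c2", "A")])), 1e-6)
  expect_lt(fit$rms_residual, 1e-6)
  # plane form solves exactly
  fitp <- surface_fit(pts, form = "plane")
  expect_equal(unname(coef(fitp)), c(50, 0, 0), tolerance = 1e-10)
})

test_that("noise-free dimple parameters are recovered to 1e-4 relative", {
  truth <- surface_params("gauss_dimple", c0 = 60, c1 = 0.01, c2 = -0.02,
                          A = -30, x0 = 250, y0 = 250, sx = 80, sy = 80)
  fit <- surface_fit(grid_pts(truth), box = c(500, 500, 200))
  cf <- coef(fit)
  tp <- truth$pars
  nz <- abs(tp) > 1e-8
  expect_lt(max(abs((cf[nz] - tp[nz]) / tp[nz])), 1e-4)
  expect_lt(fit$rms_residual, 1e-6)
})

test_that("underdetermined and degenerate fits are refused", {
  expect_error(surface_fit(cbind(x = 1:3, y = 1:3, z = 1), "gauss_dimple"),
               "at least 8")
  line <- cbind(x = 1:20, y = 2 * (1:20) + 1, z = rnorm(20))
  expect_error(surface_fit(line, "plane"), "collinear")
})

test_that("curvature formulas match closed forms on canonical surfaces", {
  # plane: zero curvature everywhere
  pl <- surface_params("plane", c0 = 5, c1 = 0.3, c2 = -0.2)
  cv <- bead_curvatures(pl, expand.grid(x = -5:5, y = -5:5))
  expect_true(all(cv$abs_K == 0))
  # paraboloid z = (x^2 + y^2) / (2R): kx = ky = 1/R at the apex
  R <- 100
  pb <- surface_params("biquadratic", c3 = 1 / (2 * R), c5 = 1 / (2 * R))
  at0 <- bead_curvatures(pb, data.frame(x = 0, y = 0))
  expect_equal(at0$kx, 1 / R, tolerance = 1e-12)
  expect_equal(at0$ky, 1 / R, tolerance = 1e-12)
  expect_equal(at0$abs_K, 1e-4, tolerance = 1e-12)
  # Gaussian dimple centre: kx = -A/sx^2
  gd <- surface_params("gauss_dimple", c0 = 50, A = -30, x0 = 0, y0 = 0,
                       sx = 80, sy = 80)
  atc <- bead_curvatures(gd, data.frame(x = 0, y = 0))
  expect_equal(atc$kx, 30 / 6400, tolerance = 1e-12)
  expect_equal(atc$ky, 30 / 6400, tolerance = 1e-12)
})

test_that("analytic curvatures agree with central finite differences", {
  gd <- surface_params("gauss_dimple", c0 = 50, c1 = 0.05, c2 = 0.01,
                       A = -30, x0 = 200, y0 = 180, sx = 80, sy = 60)
  set.seed(7)
  xy <- data.frame(x = runif(40, 50, 350), y = runif(40, 50, 310))
  cv <- bead_curvatures(gd, xy)
  h <- 0.05   # large enough that the second difference is not all round-off
  z <- function(x, y) surface_eval(gd, x, y)
  zx <- (z(xy$x + h, xy$y) - z(xy$x - h, xy$y)) / (2 * h)
  zy <- (z(xy$x, xy$y + h) - z(xy$x, xy$y - h)) / (2 * h)
  zxx <- (z(xy$x + h, xy$y) - 2 * z(xy$x, xy$y) + z(xy$x - h, xy$y)) / h^2
  zyy <- (z(xy$x, xy$y + h) - 2 * z(xy$x, xy$y) + z(xy$x, xy$y - h)) / h^2
  expect_equal(cv$kx, zxx / (1 + zx^2)^1.5, tolerance = 1e-6)
  expect_equal(cv$ky, zyy / (1 + zy^2)^1.5, tolerance = 1e-6)
})

test_that("shape-operator curvatures reduce to the axis convention", {
  # on an axis-aligned dimple at its centre the two conventions coincide
  gd <- surface_params("gauss_dimple", c0 = 50, A = -30, x0 = 0, y0 = 0,
                       sx = 80, sy = 60)
  so <- shape_operator_curvatures(gd, data.frame(x = 0, y = 0))
  ax <- bead_curvatures(gd, data.frame(x = 0, y = 0))
  expect_equal(sort(abs(c(so$k1, so$k2))), sort(abs(c(ax$kx, ax$ky))),
               tolerance = 1e-6)
  expect_equal(so$abs_K, ax$abs_K, tolerance = 1e-6)
})

test_that("mean |K| is translation invariant and scales as s^-2", {
  truth <- surface_params("gauss_dimple", c0 = 60, A = -25, x0 = 220,
                          y0 = 260, sx = 70, sy = 90)
  pts <- as.matrix(grid_pts(truth))
  base <- mean(bead_curvatures(surface_fit(pts, box = c(500, 500, 200)))$abs_K)
  shifted <- sweep(pts, 2, c(31.7, -12.3, 140))
  mshift <- mean(bead_curvatures(surface_fit(shifted,
                                             box = c(500, 500, 200)))$abs_K)
  expect_equal(mshift, base, tolerance = 1e-8)
  for (s in c(2, 0.5)) {
    ms <- mean(bead_curvatures(surface_fit(pts * s,
                                           box = c(500, 500, 200) * s))$abs_K)
    expect_equal(ms, base / s^2, tolerance = 1e-6)
  }
})

test_that("mean |K| vanishes exactly for affine surfaces only", {
  pts <- cbind(expand.grid(x = seq(0, 400, 25), y = seq(0, 400, 25)))
  pts$z <- 30 + 0.1 * pts$x - 0.05 * pts$y
  flat <- surface_fit(pts, box = c(400, 400, 100))
  expect_lt(mean(bead_curvatures(flat)$abs_K), 1e-12)
  dim <- surface_params("gauss_dimple", c0 = 30, A = -20, x0 = 200,
                        y0 = 200, sx = 60, sy = 60)
  pts$z <- surface_eval(dim, pts$x, pts$y)
  expect_gt(mean(bead_curvatures(surface_fit(pts,
                                             box = c(400, 400, 100)))$abs_K),
            1e-9)
})

test_that("curvature series reports one entry per frame, zero when flat", {
  fr <- make_membrane_frame(surface_params("plane", c0 = 100),
                            n_per_leaflet = 120, box = c(400, 400, 200),
                            seed = 1)
  tr <- make_trajectory(fr, 10, seed = 2)
  cs <- curvature_series(tr, form = "plane")
  expect_identical(nrow(cs), 10L)
  expect_true(all(cs$mean_abs_K == 0))
  expect_identical(cs$frame, 1:10)
})

test_that("fit object methods behave like a standard R model", {
  truth <- surface_params("gauss_dimple", c0 = 60, A = -30, x0 = 250,
                          y0 = 250, sx = 80, sy = 80)
  fit <- surface_fit(grid_pts(truth, n = 20), box = c(500, 500, 200))
  expect_named(coef(fit), surface_form("gauss_dimple")$par_names)
  expect_length(fitted(fit), 400)
  expect_equal(fitted(fit) + residuals(fit), fit$data$z)
  expect_equal(deviance(fit), sum(residuals(fit)^2))
  expect_equal(predict(fit, data.frame(x = 250, y = 250)),
               unname(surface_eval(truth, 250, 250)), tolerance = 1e-4)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(400L, 3L))
  expect_output(print(fit), "gauss_dimple")
  expect_output(print(summary(fit)), "mean \\|K\\|")
})
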