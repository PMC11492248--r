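test_that("largest-remainder apportionment reproduces the leaflet mixture", {
  up <- largest_remainder(default_composition()$upper, 1000)
  expect_identical(unname(up), c(250L, 250L, 80L, 70L, 250L, 100L))
  # conservation holds for awkward totals and ratios
  set.seed(42)
  for (i in 1:20) {
    parts <- stats::setNames(sample(0:9, 5, replace = TRUE), letters[1:5])
    parts[1] <- parts[1] + 1          # keep at least one positive part
    n <- sample(1:500, 1)
    cnt <- largest_remainder(parts, n)
    expect_identical(sum(cnt), n)
    expect_true(all(cnt >= 0))
  }
  expect_error(largest_remainder(c(a = -1, b = 2), 10), ">= 0")
  expect_error(largest_remainder(c(a = 0, b = 0), 10), "positive")
})

test_that("membrane beads sit exactly on the requested surface", {
  fr <- make_membrane_frame(surface_params("plane", c0 = 50),
                            n_per_leaflet = 120, box = c(400, 400, 200),
                            seed = 3)
  b <- fr$beads
  up_po4 <- b$name == "PO4" & b$z > 25
  expect_identical(sum(up_po4), 120L)
  expect_true(all(b$z[up_po4] == 50))            # exact, not approximate
  expect_true(all(b$z[b$name == "PO4" & !up_po4] == 10))  # 40 A below
  # composition counts recorded in truth match the frame
  cnt <- scene_truth(fr)$counts$upper
  expect_identical(sum(cnt), 120L)
  tab <- table(b$species[up_po4])
  expect_identical(as.integer(tab[names(cnt)[cnt > 0]]),
                   unname(cnt[cnt > 0]))
})

test_that("scene generation is bit-identical for a fixed seed", {
  a <- make_membrane_frame(n_per_leaflet = 80, seed = 11)
  b <- make_membrane_frame(n_per_leaflet = 80, seed = 11)
  expect_identical(a, b)
  c <- make_membrane_frame(n_per_leaflet = 80, seed = 12)
  expect_false(identical(a$beads$x, c$beads$x))
})

test_that("generator rejects impossible inputs", {
  expect_error(make_membrane_frame(box = c(0, 500, 500)), "box")
  expect_error(make_membrane_frame(n_per_leaflet = -5), "positive")
  expect_error(make_membrane_frame(n_per_leaflet = 3), "number of species")
  # more lipids than an 80 A patch can hold at 8 A spacing
  expect_error(make_membrane_frame(n_per_leaflet = 500,
                                   box = c(80, 80, 100)), "too small")
})

test_that("minimum in-plane spacing is honoured", {
  fr <- make_membrane_frame(n_per_leaflet = 150, box = c(400, 400, 200),
                            seed = 5)
  b <- fr$beads
  for (lf in c(50, 10)) {
    po4 <- b[b$name == "PO4" & b$z == lf, ]
    expect_gte(min(stats::dist(po4[c("x", "y")])), 8)
  }
})

test_that("planted clusters match their recorded ground truth", {
  fr <- make_membrane_frame(n_per_leaflet = 500, box = c(500, 500, 200),
                            seed = 2)
  pl <- plant_species_clusters(fr, "DPG3", k = 2, size = 20, spread = 15,
                               seed = 4)
  truth <- scene_truth(pl)$planted_clusters
  sizes <- table(truth[truth >= 0])
  expect_identical(length(sizes), 2L)
  expect_true(all(sizes == 20))
  # below the DBSCAN minimum: construction still succeeds
  pl4 <- plant_species_clusters(fr, "DPG3", k = 1, size = 4, spread = 10,
                                seed = 4)
  expect_identical(sum(scene_truth(pl4)$planted_clusters == 0), 4L)
})

test_that("planted blob separation verified by brute-force scan", {
  fr <- make_membrane_frame(n_per_leaflet = 400, box = c(600, 600, 200),
                            seed = 8)
  pl <- plant_species_clusters(fr, "DPG3", k = 3, size = 8, spread = 15,
                               seed = 1)
  truth <- scene_truth(pl)$planted_clusters
  rp <- resolve_reference_points(pl, "lipid-molecule", species = "DPG3",
                                 use_d_bead = FALSE)
  lab <- truth[as.character(rp$ids)]
  # exhaustive pairwise distances between members of different blobs
  for (i in 0:1) for (j in (i + 1):2) {
    d <- pair_dist_xy <- as.matrix(stats::dist(rp$points[, 1:2]))
    dd <- d[lab == i, lab == j]
    expect_gt(min(dd), 56)
  }
  # remainder is far from every blob member
  d <- as.matrix(stats::dist(rp$points[, 1:2]))
  expect_gt(min(d[lab == -1, lab >= 0]), 28)
})

test_that("capsid shell is a labelled sphere of the right size", {
  cap <- make_capsid_shell(center = c(0, 0, 0), radius = 125,
                           beads_per_face = 9, seed = 6,
                           box = c(500, 500, 500))
  p <- coords(cap)
  expect_true(all(abs(sqrt(rowSums(p^2)) - 125) < 1e-6))
  d <- stats::dist(p)
  expect_lte(max(d), 250 + 1e-9)
  expect_gte(max(d), 0.95 * 250)
  expect_identical(sort(unique(cap$beads$molid)), 1:12)
  expect_true(all(table(cap$beads$molid) == 9))
  expect_identical(cap$beads$resid, 1:108)
  expect_error(make_capsid_shell(beads_per_face = 0), ">= 1")
  expect_error(make_capsid_shell(radius = -1), "> 0")
})

test_that("scripted trajectories respect schedules and rigidity", {
  fr <- dimple_scene(n = 100, seed = 3)
  cap <- make_capsid_shell(center = c(200, 200, 250), radius = 60,
                           beads_per_face = 5, seed = 1,
                           box = fr$box)
  sc <- merge_frames(fr, cap)
  attr(sc, "truth") <- scene_truth(fr)
  expect_error(make_trajectory(sc, 5, angles = c(0, 10)), "schedule length")
  surf <- scene_truth(fr)$surface
  tr <- make_trajectory(sc, 4, angles = c(0, 30, 60, 90), axis = c(0, 0, 1),
                        dimple_schedule = replicate(4, surf,
                                                    simplify = FALSE),
                        seed = 9)
  tt <- vapply(tr, function(f) f$time, numeric(1))
  expect_true(all(diff(tt) > 0))
  # rigid rotation preserves intra-capsid distances to < 1e-6 A
  sel <- species_matches(tr[[1]]$beads$species, "CAPS")
  d1 <- stats::dist(coords(tr[[1]], which(sel)))
  d4 <- stats::dist(coords(tr[[4]], which(sel)))
  expect_lt(max(abs(d1 - d4)), 1e-6)
  # membrane PO4 beads stay exactly on the scheduled surface
  b4 <- tr[[4]]$beads
  up <- b4$name == "PO4" & !sel & b4$z > mean(b4$z[b4$name == "PO4"])
  expect_equal(b4$z[up], surface_eval(surf, b4$x[up], b4$y[up]),
               tolerance = 1e-12)
  # constant schedules with a fixed seed give identical frames
  tr2 <- make_trajectory(sc, 3, angles = rep(0, 3),
                         dimple_schedule = replicate(3, surf,
                                                     simplify = FALSE),
                         seed = 9)
  expect_identical(tr2[[1]]$beads, tr2[[3]]$beads)
})

test_that("dimple deepening produces non-decreasing mean curvature", {
  fr <- make_membrane_frame(surface_params("gauss_dimple", c0 = 150,
                                           A = -1e-6, x0 = 200, y0 = 200,
                                           sx = 70, sy = 70),
                            n_per_leaflet = 250, box = c(400, 400, 300),
                            seed = 13)
  amps <- seq(0, -40, length.out = 5)
  sched <- lapply(amps, function(a)
    surface_params("gauss_dimple", c0 = 150, A = ifelse(a == 0, -1e-9, a),
                   x0 = 200, y0 = 200, sx = 70, sy = 70))
  tr <- make_trajectory(fr, 5, dimple_schedule = sched, seed = 2)
  cs <- curvature_series(tr)
  expect_true(all(diff(cs$mean_abs_K) >= -1e-15))
  # matches the quadrature of the analytic surface at the bead positions
  lf <- assign_leaflets(tr[[1]], quiet = TRUE)
  for (i in c(2, 5)) {
    idx <- select_beads(tr[[i]], name = "PO4", leaflet = "upper",
                        leaflets = lf)
    ana <- bead_curvatures(sched[[i]], coords(tr[[i]], idx)[, 1:2])
    expect_equal(cs$mean_abs_K[i], mean(ana$abs_K), tolerance = 0.01)
  }
})
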