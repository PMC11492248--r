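test_that("leaflet assignment splits on the first-frame midplane", {
  fr <- make_membrane_frame(surface_params("plane", c0 = 50),
                            n_per_leaflet = 60, seed = 1)
  lf <- assign_leaflets(fr, quiet = TRUE)
  b <- fr$beads
  po4 <- b[b$name == "PO4", ]
  expect_true(all(lf[as.character(po4$molid[po4$z == 50])] == "upper"))
  expect_true(all(lf[as.character(po4$molid[po4$z == 10])] == "lower"))
  # frozen at frame 1: later frames crossing the midplane change nothing
  fr2 <- fr
  fr2$beads$z <- 100 - fr2$beads$z      # swap the leaflets geometrically
  expect_identical(assign_leaflets(fr, quiet = TRUE), lf)
  # degenerate single-leaflet input warns
  fr3 <- fr
  fr3$beads <- fr3$beads[fr3$beads$z >= 45, ]
  expect_warning(assign_leaflets(fr3), "one leaflet")
  fr4 <- fr
  fr4$beads <- fr4$beads[fr4$beads$name != "PO4", ]
  expect_error(assign_leaflets(fr4), "PO4")
})

test_that("DBSCAN semantics: cores, borders, noise", {
  # 5 points within 28 A of one centre: one cluster, no noise
  p5 <- rbind(c(0, 0), c(10, 0), c(0, 10), c(-10, 0), c(0, -10))
  cl <- dbscan_cluster(p5, cluster_spec())
  expect_identical(cl$labels, rep(0L, 5))
  expect_identical(cl$n_noise, 0L)
  # 4 mutually close points below min_pts: all noise
  cl4 <- dbscan_cluster(p5[1:4, ], cluster_spec())
  expect_identical(cl4$labels, rep(-1L, 4))
  expect_identical(cl4$n_clusters, 0L)
  # labels are contiguous from zero across separated groups
  p2 <- rbind(p5, p5 + 500)
  cl2 <- dbscan_cluster(p2, cluster_spec())
  expect_identical(sort(unique(cl2$labels)), 0:1)
  expect_true(all(cl2$cluster_sizes >= 5))
})

test_that("binned DBSCAN matches the textbook oracle on random scenes", {
  skip_if_not_installed("igraph")
  set.seed(202)
  for (i in 1:20) {
    n <- 300L
    p <- cbind(runif(n, 0, 400), runif(n, 0, 400))
    cl <- dbscan_cluster(p, cluster_spec())
    ref <- ref_dbscan(p, 28, 5)
    expect_identical(label_sets(cl$labels), label_sets(ref))
    expect_identical(which(cl$labels == -1L), which(ref == -1L))
    # bookkeeping: sizes + noise = total
    expect_identical(sum(cl$cluster_sizes) + cl$n_noise, n)
  }
})

test_that("DBSCAN is invariant to input permutation up to relabeling", {
  set.seed(9)
  p <- cbind(runif(200, 0, 300), runif(200, 0, 300))
  base <- dbscan_cluster(p, cluster_spec())
  for (i in 1:5) {
    perm <- sample(nrow(p))
    shuffled <- dbscan_cluster(p[perm, ], cluster_spec())
    relabelled <- integer(nrow(p))
    relabelled[perm] <- shuffled$labels
    expect_identical(label_sets(base$labels), label_sets(relabelled))
  }
})

test_that("shrinking eps never reduces the noise count", {
  set.seed(33)
  p <- cbind(runif(250, 0, 350), runif(250, 0, 350))
  noise <- vapply(c(40, 34, 28, 22, 16, 10), function(e)
    dbscan_cluster(p, cluster_spec(eps = e))$n_noise, integer(1))
  expect_true(all(diff(noise) >= 0))
})

test_that("periodic clustering joins blobs across the box edge", {
  p <- rbind(cbind(runif(6, 0, 5), runif(6, 0, 5)),
             cbind(runif(6, 395, 400), runif(6, 0, 5)))
  raw <- dbscan_cluster(p, cluster_spec())
  per <- dbscan_cluster(p, cluster_spec(convention = "min_image"),
                        box = c(400, 400, 100))
  expect_identical(raw$n_clusters, 2L)
  expect_identical(per$n_clusters, 1L)
})

test_that("cluster series recovers planted clusters exactly", {
  skip_if_not_installed("mclust")
  fr <- make_membrane_frame(n_per_leaflet = 300, box = c(600, 600, 200),
                            seed = 21)
  pl <- plant_species_clusters(fr, "DPG3", k = 3, size = 10, spread = 14,
                               seed = 5)
  cs <- cluster_series(list(pl), "GM3", "upper")
  expect_identical(cs$n_clusters, 3L)
  expect_identical(cs$mean_size, 10)
  truth <- scene_truth(pl)$planted_clusters
  lab <- attr(cs, "labelings")[[1]]
  ari <- mclust::adjustedRandIndex(truth[as.character(lab$ids)], lab$labels)
  expect_identical(ari, 1)
  expect_identical(cs$n_noise, sum(truth == -1L))
})

test_that("isolated molecules yield zero clusters and missing mean size", {
  fr <- make_membrane_frame(n_per_leaflet = 60, box = c(900, 900, 200),
                            seed = 31, spacing = 30)
  cs <- cluster_series(list(fr), "DPG3", "upper",
                       cluster_spec(eps = 28, min_pts = 5))
  expect_identical(cs$n_clusters, 0L)
  expect_true(is.na(cs$mean_size))
  expect_error(cluster_series(list(fr), "NOPE"), "not present")
})

test_that("merging two blobs below eps separation merges the clusters", {
  blob <- function(cx) cbind(cx + runif(8, -5, 5), runif(8, -5, 5))
  set.seed(12)
  far <- rbind(blob(0), blob(100))
  near <- rbind(blob(0), blob(20))
  cl_far <- dbscan_cluster(far, cluster_spec())
  cl_near <- dbscan_cluster(near, cluster_spec())
  expect_identical(cl_far$n_clusters, 2L)
  expect_identical(cl_near$n_clusters, 1L)
  expect_identical(mean(cl_near$cluster_sizes),
                   2 * mean(cl_far$cluster_sizes))
  # brute-force oracle agrees on the merged scene
  skip_if_not_installed("igraph")
  expect_identical(label_sets(cl_near$labels),
                   label_sets(ref_dbscan(near, 28, 5)))
})

test_that("height triangulation averages vertex heights per triangle", {
  sq <- rbind(c(0, 0, 50), c(10, 0, 50), c(0, 10, 50), c(10, 10, 50))
  ht <- height_triangulation(sq)
  expect_identical(nrow(ht$triangles), 2L)
  expect_true(all(ht$triangles$value == 50))
  # one low apex colours its incident triangles (50 + 50 + 20) / 3
  apex <- rbind(c(0, 0, 50), c(20, 0, 50), c(0, 20, 50), c(20, 20, 50),
                c(10, 10, 20))
  ht2 <- height_triangulation(apex)
  touch <- apply(ht2$triangles[c("i", "j", "k")] == 5, 1, any)
  expect_true(all(ht2$triangles$value[touch] == 40))
  expect_true(all(ht2$triangles$value[!touch] == 50))
  expect_error(height_triangulation(rbind(c(0, 0, 1), c(1, 1, 1),
                                          c(2, 2, 1))), "collinear")
})

test_that("triangle count obeys Euler's relation for planar Delaunay", {
  set.seed(44)
  p <- cbind(runif(60, 0, 100), runif(60, 0, 100), runif(60, 40, 60))
  ht <- height_triangulation(p)
  hull <- grDevices::chull(p[, 1], p[, 2])
  # planar triangulation of n points with h hull points: 2n - h - 2 faces
  expect_identical(nrow(ht$triangles), 2L * 60L - length(hull) - 2L)
})

test_that("parameter tuning surfaces the minimum-noise settings", {
  fr <- make_membrane_frame(n_per_leaflet = 200, box = c(500, 500, 200),
                            seed = 2)
  pl <- plant_species_clusters(fr, "DPG3", k = 2, size = 8, spread = 12,
                               seed = 3)
  rp <- resolve_reference_points(pl, "lipid-molecule", species = "DPG3",
                                 use_d_bead = FALSE)
  tg <- tune_cluster_params(rp$points, eps_grid = c(10, 28),
                            min_pts_grid = c(5, 9))
  expect_identical(names(tg), c("eps", "min_pts", "n_noise", "n_clusters"))
  # the planted geometry is found at the default parameters
  best <- tg[tg$eps == 28 & tg$min_pts == 5, ]
  expect_lte(best$n_noise, min(tg$n_noise[tg$eps == 10]))
})
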