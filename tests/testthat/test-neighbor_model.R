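test_that("tessellation adjacency handles simplices and degenerate frames", {
  # tetrahedron: all 6 pairs adjacent
  tet <- toy_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  g <- voronoi_neighbors(tet, ratio_cutoff = 100)
  expect_equal(nrow(g$edges), 6L)
  expect_identical(g$provenance, "voronoi")
  # two cells: degenerate fallback, single edge
  expect_warning(g2 <- voronoi_neighbors(toy_frame(rbind(c(0, 0, 0),
                                                         c(1, 0, 0)))),
                 "degenerate")
  expect_equal(nrow(g2$edges), 1L)
  # coplanar square falls back to a 2-D tessellation
  sq <- toy_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  expect_warning(g3 <- voronoi_neighbors(sq, ratio_cutoff = 100),
                 "coplanar|2-D")
  expect_gte(nrow(g3$edges), 4L)
  # collinear points chain consecutively
  line <- toy_frame(cbind(0:3, 0, 0))
  expect_warning(g4 <- voronoi_neighbors(line, ratio_cutoff = 100))
  key <- apply(g4$edges, 1L, function(e) paste(sort(e), collapse = "-"))
  expect_setequal(key, c("c1-c2", "c2-c3", "c3-c4"))
  expect_error(voronoi_neighbors(toy_frame(matrix(c(0, 0, 0), 1))),
               "2 cells")
})

test_that("3-D Delaunay adjacency matches the scipy oracle on random sets", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  for (seed in 1:6) {
    set.seed(seed)
    pts <- matrix(runif(30, 0, 10), 10L, 3L)
    ours <- cellmigrl:::.delaunay_edges_3d(pts)
    ref <- scipy_delaunay_edges(pts)
    k <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
    expect_identical(k(ours), k(ref))
  }
})

test_that("lattice frames keep face neighbors and prune long diagonals", {
  latt <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2))
  tab <- toy_frame(latt, diameter = 1)
  g <- voronoi_neighbors(tab, ratio_cutoff = 2, radii = rep(0.5, 27L))
  key <- apply(g$edges, 1L, function(e) paste(sort(e), collapse = "-"))
  # all 54 face-adjacent (distance 1) pairs present
  d <- as.matrix(dist(latt))
  for (i in 1:26) for (j in (i + 1):27) {
    if (d[i, j] == 1)
      expect_true(paste(sort(tab$name[c(i, j)]), collapse = "-") %in% key)
    if (d[i, j] > 2)  # long diagonals beyond the ratio cutoff pruned
      expect_false(paste(sort(tab$name[c(i, j)]), collapse = "-") %in% key)
  }
})

test_that("pair features carry distance, sizes, and the contact ratio", {
  tab <- toy_frame(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 3, 0)),
                   diameter = c(2, 3, 2))
  f <- pair_features(tab, "c1", "c2")
  expect_equal(unname(f["distance"]), 4)
  expect_equal(unname(f["size_a"]), 2)
  expect_equal(unname(f["size_b"]), 3)
  expect_equal(unname(f["ratio"]), 4 / unname(f["radius_sum"]))
  expect_equal(unname(f["n_cells_total"]), 3)
  # symmetry
  g <- pair_features(tab, "c2", "c1")
  expect_equal(unname(f["distance"]), unname(g["distance"]))
  expect_equal(unname(f["ratio"]), unname(g["ratio"]))
  # coincident cells
  tab2 <- toy_frame(rbind(c(0, 0, 0), c(0, 0, 0), c(5, 5, 5)))
  expect_equal(unname(pair_features(tab2, "c1", "c2")["distance"]), 0)
  expect_equal(unname(pair_features(tab2, "c1", "c2")["ratio"]), 0)
  expect_error(pair_features(tab, "c1", "zz"), "not in frame")
})

test_that("estimate_radius follows the equal-share closed form", {
  tab1 <- toy_frame(matrix(c(0, 0, 0), 1), diameter = 2)
  # N = 1, w = 1: the sphere holding the whole embryo volume
  est <- estimate_radius("ABa", tab1, embryo_volume = 4 * pi / 3)
  expect_equal(est$radius, 1)
  expect_equal(est$generation, 1L)
  v <- 500
  r1 <- estimate_radius("C", tab1, embryo_volume = v)$radius
  tab2 <- toy_frame(rbind(c(0, 0, 0), c(5, 0, 0)))
  r2 <- estimate_radius("C", tab2, embryo_volume = v)$radius
  expect_equal(r2, r1 / 2^(1 / 3))                 # doubling N scaling law
  # generation weight hook
  rw <- estimate_radius("Cpa", tab1, embryo_volume = v,
                        weight_fn = function(g) 8)$radius
  expect_equal(rw, 2 * r1)
  expect_error(estimate_radius("C", tab1, embryo_volume = -1), "volume")
})

test_that("direct and secondary neighbors follow graph definitions", {
  # 7-cell cross: centre adjacent to the 6 arm cells
  cross <- toy_frame(rbind(c(0, 0, 0), c(2, 0, 0), c(-2, 0, 0),
                           c(0, 2, 0), c(0, -2, 0), c(0, 0, 2),
                           c(0, 0, -2)), diameter = 2)
  nb <- neighbors_of(cross, "c1", ratio_cutoff = 100)
  expect_setequal(nb, paste0("c", 2:7))
  expect_false("c1" %in% nb)
  # equals the incident voronoi edges by definition
  g <- voronoi_neighbors(cross, ratio_cutoff = 100)
  inc <- unique(c(g$edges[g$edges[, 1] == "c1", 2],
                  g$edges[g$edges[, 2] == "c1", 1]))
  expect_setequal(nb, inc)
  # isolated far cell: all its ratios exceed the cutoff
  iso <- rbind(cross, data.frame(frame = 0L, name = "far", x = 500, y = 0,
                                 z = 0, diameter = 2))
  expect_length(neighbors_of(iso, "far", ratio_cutoff = 2), 0L)

  # chain A-B-C: secondary of A = {C}; full triangle: empty
  suppressWarnings({
    chain <- toy_frame(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)),
                       names = c("A", "B", "C"))
    expect_setequal(secondary_neighbors(chain, "A"), "C")
    tri <- toy_frame(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 2, 0)))
    expect_length(secondary_neighbors(tri, "c1", ratio_cutoff = 100), 0L)
  })
  expect_error(neighbors_of(cross, "nope"), "not in frame")
})

test_that("secondary neighbors of the migrating cell lie ahead on the path", {
  sc <- corridor_fixture()
  tab <- frame_table(sc$series, 0L)
  sec <- secondary_neighbors(tab, "Cpaaa")
  expect_gt(length(sec), 0L)
  x_mig <- tab$x[tab$name == "Cpaaa"]
  expect_gt(mean(tab$x[tab$name %in% sec]), x_mig)
})

test_that("random-forest neighbor classifier recovers Voronoi ground truth", {
  ng <- neighbor_ground_truth_fixture()
  clf <- train_classifier(ng$frames[1:8], ng$graphs[1:8], seed = 7L)
  # determinism of the seeded training
  clf2 <- train_classifier(ng$frames[1:8], ng$graphs[1:8], seed = 7L)
  probe <- cellmigrl:::pair_feature_matrix(ng$frames[[9]],
                                           t(utils::combn(20L, 2L)))
  expect_identical(predict(clf, probe), predict(clf2, probe))

  # held-out balanced accuracy >= 0.9, pooled over 4 unseen embryos
  bal <- classifier_balanced_accuracy(clf, ng, test = 9:12)
  expect_gte(bal, 0.9)

  # tetrahedron agreement with the tessellation oracle
  tet <- toy_frame(rbind(c(0, 0, 0), c(6, 0, 0), c(3, 5, 0), c(3, 2, 5)),
                   diameter = 5)
  feats <- cellmigrl:::pair_feature_matrix(tet, t(utils::combn(4L, 2L)))
  expect_true(all(predict(clf, feats)))

  # a frame whose graph has every pair as an edge leaves no negatives
  suppressWarnings({
    tri <- toy_frame(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 2, 0)))
    gtri <- voronoi_neighbors(tri, ratio_cutoff = 100)
    expect_error(train_classifier(list(tri), list(gtri), seed = 1L),
                 "single class")
  })
  # serialization round trip
  f <- withr::local_tempfile(fileext = ".rds")
  save_classifier(clf, f)
  expect_identical(predict(load_classifier(f), probe), predict(clf, probe))
})

test_that("neighbors_of with a classifier model returns plausible sets", {
  sc <- corridor_fixture()
  tab <- frame_table(sc$series, 0L)
  g <- voronoi_neighbors(tab)
  clf <- train_classifier(list(tab), list(g), seed = 1L)
  nb <- neighbors_of(tab, "Cpaaa", model = clf)
  expect_false("Cpaaa" %in% nb)
  truth <- neighbors_of(tab, "Cpaaa")
  # in-sample prediction should recover most true neighbors
  expect_gte(length(intersect(nb, truth)) / length(truth), 0.5)
})
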