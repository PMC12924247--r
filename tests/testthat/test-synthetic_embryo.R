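test_that("embryo generation is deterministic and respects the eggshell", {
  sp <- scenario_spec(seed = 1L)
  s1 <- generate_embryo(sp)
  s2 <- generate_embryo(sp)
  expect_identical(s1$cells, s2$cells)
  expect_false(identical(generate_embryo(scenario_spec(seed = 2L))$cells,
                         s1$cells))
  inside <- with(s1$cells, (x / sp$eggshell[1])^2 + (y / sp$eggshell[2])^2 +
                   (z / sp$eggshell[3])^2)
  expect_true(all(inside <= 1 + 1e-9))
  validate_series(s1)   # passes all container invariants
  # an over-constrained packing (every candidate site excluded) errors
  expect_error(cellmigrl:::pack_cells(5L, c(10, 10, 10), 3,
                                      exclude_fn = function(p) TRUE),
               "infeasible")
})

test_that("packed frames keep >= 90% of adjacent pairs in the (0.3, 0.8) band", {
  fracs <- vapply(1:5, function(seed) {
    tab <- frame_table(generate_embryo(scenario_spec(seed = seed)), 0L)
    g <- voronoi_neighbors(tab)
    r <- cellmigrl:::cell_radii(tab)
    i <- match(g$edges[, 1], tab$name)
    j <- match(g$edges[, 2], tab$name)
    d <- sqrt((tab$x[i] - tab$x[j])^2 + (tab$y[i] - tab$y[j])^2 +
                (tab$z[i] - tab$z[j])^2)
    ratio <- d / (r[i] + r[j])
    mean(ratio > 0.3 & ratio < 0.8)
  }, numeric(1))
  expect_true(all(fracs >= 0.9))
})

test_that("migration scenario ends as a target neighbor with monotone approach", {
  sc <- corridor_fixture()
  s <- sc$series
  sp <- scenario_spec(seed = 1L)
  expect_equal(nrow(sc$path), n_frames(s))
  # ground-truth path aligns with the migrating cell's per-frame positions
  mig <- s$cells[s$cells$name == "Cpaaa", ]
  mig <- mig[order(mig$frame), ]
  expect_lt(max(abs(mig$x - sc$path[, 1])), 4 * sp$jitter_sd)
  # final frame: migrating and target are Voronoi neighbors
  tabN <- frame_table(s, n_frames(s) - 1L)
  expect_true("ABarpaapp" %in% neighbors_of(tabN, "Cpaaa"))
  # approach is ~monotone (Spearman <= -0.9)
  da <- distance_array(s, "Cpaaa", "ABarpaapp")
  expect_lte(cor(seq_along(da$values), da$values, method = "spearman"),
             -0.9)
  # seed change: different jitter, same endpoints
  sc2 <- generate_migration_scenario(scenario_spec(seed = 9L))
  expect_equal(sc2$path[1L, ], sc$path[1L, ])
  expect_equal(sc2$path[nrow(sc2$path), ], sc$path[nrow(sc$path), ])
  expect_false(identical(sc2$series$cells, s$cells))
})

test_that("scenario speed matches the implied path length", {
  sc <- corridor_fixture()
  mig <- sc$series$cells[sc$series$cells$name == "Cpaaa", ]
  mig <- mig[order(mig$frame), ]
  steps <- sqrt(diff(mig$x)^2 + diff(mig$y)^2 + diff(mig$z)^2)
  total_time <- (n_frames(sc$series) - 1L) * sc$series$frame_interval
  implied <- sum(sqrt(diff(sc$path[, 1])^2)) / total_time
  expect_lt(abs(sum(steps) / total_time - implied) / implied, 0.1)
})

test_that("remove_cells deletes exactly the named cells", {
  s <- generate_embryo(scenario_spec(n_cells = 10L, seed = 2L))
  expect_identical(remove_cells(s, character())$cells, s$cells)
  drop <- unique(s$cells$name)[1:2]
  s2 <- remove_cells(s, drop)
  expect_true(all(table(s2$cells$frame) == 8L))
  keep <- s$cells[!(s$cells$name %in% drop), ]
  rownames(keep) <- NULL
  expect_identical(s2$cells, keep)               # others bit-identical
  expect_error(remove_cells(s, "ghost"), "ghost")
  # removing the migrating cell breaks environment construction downstream
  sc <- corridor_fixture()
  s3 <- remove_cells(sc$series, "Cpaaa")
  expect_error(create_tissue_env(s3, "Cpaaa", "ABarpaapp"),
               "not in series")
})

test_that("divide_cell replaces a parent by suffixed children", {
  s <- toy_series(nf = 4L, n = 2L)
  d <- divide_cell(s, "Ca", division_frame = 2L)
  expect_false(any(d$cells$name == "Ca" & d$cells$frame >= 2L))
  expect_true(all(c("Caa", "Cap") %in% d$cells$name))
  kids <- d$cells[d$cells$frame == 2L & d$cells$name %in% c("Caa", "Cap"), ]
  expect_equal(nrow(kids), 2L)
  expect_equal(kids$diameter, rep(4 / 2^(1 / 3), 2L))
  expect_true(all(kids$name %in% lineage_children("Ca")))
  validate_series(d)
  # upsampling respects the division boundary
  u <- upsample(d, 5L)
  expect_equal(max(u$cells$frame[u$cells$name == "Ca"]), 5L * 2L - 5L)
  expect_equal(min(u$cells$frame[u$cells$name == "Caa"]), 5L * 2L)
  expect_error(divide_cell(s, "Ca", 99L), "not present")
})
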