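test_that("canonical TSV round-trips bit-exactly, including unicode names", {
  s <- toy_series(nf = 2L, n = 3L)
  s$cells$x <- s$cells$x + pi * 1e-3          # non-representable decimals
  s$cells$name[1:2] <- c("Cµa", "Cµb")        # unicode preserved verbatim
  s <- embryo_series(s$cells, s$frame_interval)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_series(s, path)
  s2 <- read_series(path)
  expect_identical(s2$cells$x, s$cells$x)
  expect_identical(s2$cells$name, s$cells$name)
  expect_equal(s2$cells, s$cells)

  # also round-trip a generated 10-cell series
  g <- generate_embryo(scenario_spec(n_cells = 10L, seed = 3L))
  write_series(g, path)
  expect_equal(read_series(g |> write_series(path))$cells, g$cells)
})

test_that("read_series validates format and units", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("frame\tname\tx\ty\tz", bad)   # missing diameter
  expect_error(read_series(bad), "diameter")

  # pixel-space conversion: x = 100 px at 0.254 um/px -> 25.4 um
  d <- withr::local_tempdir()
  writeLines("name,x,y,z,diameter", file.path(d, "t001.csv"))
  cat("a,100,10,5,20\nb,50,40,10,20\n", file = file.path(d, "t001.csv"),
      append = TRUE)
  s <- read_series(d, dialect = "acetree")
  expect_equal(s$cells$x[s$cells$name == "a"], 25.4)
  expect_equal(s$cells$z[s$cells$name == "a"], 0.5)   # plane index * 0.1

  # invariant violations surface as errors
  expect_error(embryo_series(data.frame(frame = 0L, name = "a", x = 1,
                                        y = 1, z = 1, diameter = -2)),
               "diameter")
  expect_error(write_series(structure(list(cells = data.frame()),
                                      class = "embryo_series"), tempfile()))
  dup <- toy_series()$cells
  dup <- rbind(dup, dup[1L, ])
  expect_error(embryo_series(dup), "duplicate")
})

test_that("upsampling refines the grid linearly and exactly at knots", {
  s <- toy_series(nf = 5L, n = 2L, interval = 60)
  u <- upsample(s, 10L)
  expect_equal(n_frames(u), 10L * 4L + 1L)            # factor*(N-1)+1
  expect_equal(u$frame_interval, 6)                   # 60 s -> 6 s
  # exact at original frame times
  for (f in 0:4) {
    orig <- frame_table(s, f)
    up <- frame_table(u, 10L * f)
    expect_equal(up$x, orig$x)
    expect_equal(up$diameter, orig$diameter)
  }
  # linear between: cell moving (0,0,0) -> (10,0,0) over one interval
  lin <- embryo_series(data.frame(frame = 0:1, name = "m",
                                  x = c(0, 10), y = 0, z = 0, diameter = 4))
  ul <- upsample(lin, 10L)
  expect_equal(frame_table(ul, 1L)$x, 1.0)
  expect_equal(frame_table(ul, 7L)$x, 7.0)
  # downsampling by taking every f-th frame reproduces the input
  down <- u$cells[u$cells$frame %% 10L == 0L, ]
  down$frame <- down$frame %/% 10L
  rownames(down) <- NULL
  expect_equal(down, s$cells)
  expect_error(upsample(s, 0L), "positive")
  expect_error(upsample(embryo_series(s$cells[s$cells$frame == 0, ]), 10L),
               "2 frames")
})

test_that("upsampling does not interpolate across appearance/disappearance", {
  cells <- rbind(
    data.frame(frame = 0:2, name = "P", x = c(0, 1, 2), y = 0, z = 0,
               diameter = 4),
    data.frame(frame = 1:2, name = "Pa", x = c(5, 6), y = 0, z = 0,
               diameter = 3))
  s <- embryo_series(cells)
  u <- upsample(s, 4L)
  pa_frames <- sort(u$cells$frame[u$cells$name == "Pa"])
  expect_equal(min(pa_frames), 4L)        # born at the boundary copy
  expect_equal(max(pa_frames), 8L)
  # cell-name sets at original frame times preserved
  for (f in 0:2)
    expect_setequal(frame_table(u, 4L * f)$name, frame_table(s, f)$name)
})

test_that("lineage_children builds the admissible suffix set", {
  kids <- lineage_children("Cpaa")
  expect_true(all(c("Cpaaa", "Cpaap") %in% kids))
  expect_length(kids, 6L)
  expect_true(all(startsWith(kids, "Cpaa")))
  expect_error(lineage_children(""), "non-empty")
})

test_that("migration_window intersects lifetimes and is symmetric", {
  cells <- rbind(
    data.frame(frame = 3:20, name = "m", x = 0, y = 0, z = 0, diameter = 4),
    data.frame(frame = 8:30, name = "t", x = 9, y = 0, z = 0, diameter = 4),
    data.frame(frame = 0:30, name = "bg", x = 20, y = 0, z = 0,
               diameter = 4))
  # re-index frames from 0 by adding a frame-0 record
  cells <- rbind(cells,
                 data.frame(frame = 0:2, name = "m0", x = -5, y = 0, z = 0,
                            diameter = 4))
  s <- embryo_series(cells)
  expect_equal(unname(migration_window(s, "m", "t")), c(8, 20))
  expect_equal(migration_window(s, "m", "t"), migration_window(s, "t", "m"))
  expect_equal(unname(migration_window(s, "m", "m")), c(3, 20))
  expect_error(migration_window(s, "m0", "t"), "window")
  expect_error(migration_window(s, "nope", "t"), "not in series")
})
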