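# Raster I/O, resampling, occurrence de-duplication and GeoJSON rasterizing.

test_that("ASC write/read round-trips values, grid and nodata", {
  r <- tiny_raster(3, 4)
  r$values[2, 3] <- NA
  f <- withr::local_tempfile(fileext = ".asc")
  write_raster(r, f)
  r2 <- read_raster(f)
  expect_equal(r2$values, r$values, tolerance = 1e-9)
  expect_equal(r2$grid$nrows, 3L)
  expect_equal(r2$grid$ncols, 4L)
  expect_equal(r2$grid$cellsize, r$grid$cellsize)
  expect_true(is.na(r2$values[2, 3]))
  # header order is canonical
  hdr <- readLines(f, n = 6)
  expect_equal(sub(" .*", "", hdr),
               c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                 "NODATA_value"))
  # re-writing a read file reproduces values
  f2 <- withr::local_tempfile(fileext = ".asc")
  write_raster(r2, f2)
  expect_equal(read_raster(f2)$values, r$values, tolerance = 1e-6)
})

test_that("malformed ASC inputs raise parse errors naming the problem", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999",
               "1 2 3 4", "5 6 7"), f)
  expect_error(read_raster(f), "expected 3 values")
  writeLines(c("ncols 3", "xllcorner 0", "yllcorner 0", "cellsize 1",
               "1 2 3"), f)
  expect_error(read_raster(f), "missing header")
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "1 oops"), f)
  expect_error(read_raster(f), "non-numeric")
})

test_that("nearest-neighbour resampling is identity on the source grid and exact under coarsening", {
  src <- tiny_raster(4, 4, cellsize = 100)
  same <- resample_nearest(src, src$grid)
  expect_identical(same$values, src$values)

  # 2x coarsening of a checkerboard: target centers land in known source cells
  g <- make_grid(4, 4, 1)
  chk <- raster_layer(outer(1:4, 1:4, function(r, c) (r + c) %% 2), g)
  tgt <- make_grid(2, 2, 2)
  out <- resample_nearest(chk, tgt)
  # hand-computed index mapping: target centers are (1,3), (3,3), (1,1),
  # (3,1); y = 3 lies in the half-open band [3,4) which is source row 1,
  # y = 1 in [1,2) which is row 3; x = 1 -> col 2, x = 3 -> col 4
  expect_equal(out$values[1, 1], chk$values[1, 2])
  expect_equal(out$values[1, 2], chk$values[1, 4])
  expect_equal(out$values[2, 1], chk$values[3, 2])
  expect_equal(out$values[2, 2], chk$values[3, 4])

  # idempotent on its own output grid
  again <- resample_nearest(out, tgt)
  expect_identical(again$values, out$values)

  # nodata propagates; disjoint extents error
  chk$values[1, 2] <- NA
  expect_true(is.na(resample_nearest(chk, tgt)$values[1, 1]))
  far <- make_grid(2, 2, 1, xmin = 100, ymin = 100)
  expect_error(resample_nearest(chk, far), "disjoint")
})

test_that("grid de-duplication keeps one record per species per cell, first in input order", {
  occ <- data.frame(species = c("a", "a", "b", "a"),
                    group = "g",
                    x = c(150, 160, 170, 1500),
                    y = c(150, 160, 170, 150))
  out <- dedup_grid(occ, 1000)
  # two "a" records share the (0,0) km cell; "b" shares it but is another species
  expect_equal(nrow(out), 3)
  expect_equal(out$x[out$species == "a" & out$x < 1000], 150)

  # non-finite coordinates are rejected with a warning
  occ2 <- rbind(occ, data.frame(species = "c", group = "g", x = NaN, y = 1))
  expect_warning(out2 <- dedup_grid(occ2, 1000), "non-finite")
  expect_false("c" %in% out2$species)
})

test_that("dedup_grid matches the brute-force distinct (species, cell) count and ignores multiplicity", {
  set.seed(42)
  n <- 500
  occ <- data.frame(species = sample(letters[1:5], n, TRUE), group = "g",
                    x = runif(n, 0, 5000), y = runif(n, 0, 5000))
  cs <- 1000
  out <- dedup_grid(occ, cs)
  key <- unique(paste(occ$species, floor(occ$x / cs), floor(occ$y / cs)))
  expect_equal(nrow(out), length(key))
  # duplicating every record changes nothing
  out2 <- dedup_grid(rbind(occ, occ), cs)
  expect_equal(out2, out)
})

test_that("GeoJSON polygons rasterize by cell-center containment with holes", {
  g <- make_grid(10, 10, 1)
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(id = 7),
    geometry = list(type = "Polygon", coordinates = list(
      list(list(1, 1), list(9, 1), list(9, 9), list(1, 9), list(1, 1)),
      list(list(4, 4), list(6, 4), list(6, 6), list(4, 6), list(4, 4)))))))
  f <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE, digits = NA)
  r <- rasterize_geojson(f, g, label_property = "id")
  expect_equal(r$values[1, 1], 0)          # outside (center 0.5, 9.5)
  expect_equal(r$values[5, 5], 0)          # inside the hole (center 4.5, 5.5)
  expect_equal(r$values[3, 3], 7)          # in the ring
  expect_equal(sum(r$values == 7), 8 * 8 - 2 * 2)
})

test_that("occurrence CSV round-trips through read/write", {
  occ <- data.frame(species = c("a", "b"), group = c("g1", "g2"),
                    x = c(1.5, 2.5), y = c(3.5, 4.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, f)
  expect_equal(read_occurrences(f), occ)
})
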