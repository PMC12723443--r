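# Relative preference index and terrain profiles.

pref_fixture <- function() {
  g <- make_grid(10, 10, 100)
  lc <- raster_layer(matrix(rep(c(1, 2), each = 50), 10, 10), g,
                     name = "lc", kind = "categorical")
  suit <- raster_layer(matrix(1, 10, 10), g, kind = "categorical")
  list(g = g, lc = lc, suit = suit)
}

test_that("RF identities: full occupancy gives 10^4, none gives 0, ratio is exact", {
  fx <- pref_fixture()
  # occupy every cell of class 1 (cols 1..5), none of class 2
  cells <- which(fx$lc$values == 1)
  ctr <- cell_center(fx$g, cells)
  occ <- data.frame(species = "s", group = "g", x = ctr$x, y = ctr$y)
  rf <- rf_index(occ, fx$suit, fx$lc)
  expect_equal(rf$RF[rf$class == 1], 1e4)
  expect_equal(rf$RF[rf$class == 2], 0)
  # U = 3 cells, S = 50 cells in class 2 -> RF = 3/50 * 1e4 = 600
  ctr2 <- cell_center(fx$g, which(fx$lc$values == 2)[1:3])
  occ2 <- data.frame(species = "s", group = "g", x = ctr2$x, y = ctr2$y)
  rf2 <- rf_index(occ2, fx$suit, fx$lc)
  expect_equal(rf2$RF[rf2$class == 2], 600)
  # absent classes report NA, never 0
  expect_true(all(is.na(rf2$RF[rf2$class %in% 3:6])))
})

test_that("RF is invariant to record duplication and cell-area rescaling", {
  fx <- pref_fixture()
  set.seed(1)
  cells <- sample(100, 20)
  ctr <- cell_center(fx$g, cells)
  occ <- data.frame(species = "s", group = "g", x = ctr$x, y = ctr$y)
  rf1 <- rf_index(occ, fx$suit, fx$lc)
  rf2 <- rf_index(rbind(occ, occ, occ), fx$suit, fx$lc)
  expect_equal(rf2$RF, rf1$RF)

  # same layout on a grid with 10x the cell size: RF unchanged
  g2 <- make_grid(10, 10, 1000)
  lc2 <- raster_layer(fx$lc$values, g2, name = "lc", kind = "categorical")
  suit2 <- raster_layer(fx$suit$values, g2, kind = "categorical")
  ctr2 <- cell_center(g2, cells)
  occ2 <- data.frame(species = "s", group = "g", x = ctr2$x, y = ctr2$y)
  rf3 <- rf_index(occ2, suit2, lc2)
  expect_equal(rf3$RF, rf1$RF)
})

test_that("occupied unsuitable cells are excluded under the default U definition", {
  fx <- pref_fixture()
  sv <- matrix(0, 10, 10); sv[, 1:2] <- 1    # suitable: cols 1-2 (class 1)
  suit <- raster_layer(sv, fx$g, kind = "categorical")
  ctr <- cell_center(fx$g, c(which(sv == 1)[1:4], which(sv == 0)[1:5]))
  occ <- data.frame(species = "s", group = "g", x = ctr$x, y = ctr$y)
  rf <- rf_index(occ, suit, fx$lc)
  expect_equal(rf$U_area[rf$class == 1], 4 * 100^2)
  expect_true(all(rf$U_area <= rf$S_area, na.rm = TRUE))
  # the alternative counts them
  rf2 <- rf_index(occ, suit, fx$lc, within_suitable_only = FALSE)
  expect_gt(sum(rf2$U_area), sum(rf$U_area))
})

test_that("Horn slope/aspect reproduce inclined-plane closed forms", {
  g <- make_grid(12, 12, 10)
  xcoord <- matrix(rep((1:12 - 0.5) * 10, each = 12), 12, 12)
  # plane descending eastward at 10 degrees: aspect = east (90)
  dem <- raster_layer(-xcoord * tan(10 * pi / 180), g, name = "dem")
  sa <- slope_aspect(dem)
  inner <- sa$slope$values[2:11, 2:11]
  expect_equal(unique(round(as.vector(inner), 6)), 10)
  expect_equal(unique(round(as.vector(sa$aspect$values[2:11, 2:11]), 6)), 90)
  expect_true(all(is.na(sa$slope$values[1, ])))   # edge cells undefined

  # plane descending southward: aspect = 180
  ycoord <- matrix(rep((12:1 - 0.5) * 10, times = 12), 12, 12)
  dem2 <- raster_layer(ycoord * tan(5 * pi / 180), g, name = "dem")
  sa2 <- slope_aspect(dem2)
  expect_equal(unique(round(as.vector(sa2$slope$values[2:11, 2:11]), 6)), 5)
  expect_equal(unique(round(as.vector(sa2$aspect$values[2:11, 2:11]), 6)), 180)

  # constant surface: slope 0, aspect undefined
  sa3 <- slope_aspect(raster_layer(matrix(7, 12, 12), g, name = "dem"))
  expect_equal(unique(as.vector(sa3$slope$values[2:11, 2:11])), 0)
  expect_true(all(is.na(sa3$aspect$values)))
  expect_error(slope_aspect(raster_layer(matrix(1, 2, 2),
                                         make_grid(2, 2, 1))), "3x3")

  # replicate padding extends to the border
  sa4 <- slope_aspect(dem, edge = "replicate")
  expect_true(all(is.finite(sa4$slope$values)))
})

test_that("terrain profiles match sort-based quantile oracles", {
  g <- make_grid(5, 5, 100)
  vals <- matrix(c(1:25), 5, 5)
  st <- raster_stack(list(raster_layer(vals, g, name = "dem")))
  mask_all <- raster_layer(matrix(1, 5, 5), g, kind = "categorical")
  pr <- terrain_profiles(list(g1 = mask_all), st, variables = "dem")
  expect_equal(pr$median, 13)
  expect_equal(pr$q1, unname(quantile(1:25, 0.25)))
  expect_equal(pr$q3, unname(quantile(1:25, 0.75)))

  # {1,2,3,4,5}: median 3, quartiles 2 and 4
  m5 <- matrix(0, 5, 5); m5[1, ] <- 1
  pr5 <- terrain_profiles(list(g1 = raster_layer(m5, g, kind = "categorical")),
                          raster_stack(list(raster_layer(
                            matrix(rep(1:5, each = 5), 5, 5),
                            g, name = "dem"))), variables = "dem")
  expect_equal(c(pr5$q1, pr5$median, pr5$q3), c(2, 3, 4))

  # single-cell mask: IQR 0; empty mask flagged with n = 0
  one <- matrix(0, 5, 5); one[2, 2] <- 1
  pr1 <- terrain_profiles(list(g1 = raster_layer(one, g, kind = "categorical")),
                          st, variables = "dem")
  expect_equal(pr1$median, vals[2, 2])
  expect_equal(pr1$q3 - pr1$q1, 0)
  empty <- raster_layer(matrix(0, 5, 5), g, kind = "categorical")
  pr0 <- terrain_profiles(list(g1 = empty), st, variables = "dem")
  expect_equal(pr0$n, 0)
  expect_true(is.na(pr0$median))
})
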