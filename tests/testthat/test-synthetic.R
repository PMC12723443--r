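# Ground-truth landscape generator: determinism, correlation control,
# suitability closed forms, sampling consistency, reserves/regions.

test_that("identical seeds yield bit-identical bundles", {
  cfg <- landscape_config(nrows = 32, ncols = 32, n_env_layers = 3, seed = 7)
  b1 <- simulate_bundle(cfg, n_species_per_group = 1, n_presences = 50)
  b2 <- simulate_bundle(cfg, n_species_per_group = 1, n_presences = 50)
  for (nm in names(b1$stack))
    expect_identical(b1$stack[[nm]]$values, b2$stack[[nm]]$values)
  expect_identical(b1$occurrences, b2$occurrences)
  expect_identical(b1$reserves$values, b2$reserves$values)
  expect_identical(b1$regions$values, b2$regions$values)
})

test_that("climate-layer cross-correlations track the target matrix", {
  # identity target: all off-diagonal |r| small
  cfg <- landscape_config(nrows = 128, ncols = 128, n_env_layers = 4,
                          seed = 11)
  st <- generate_env_stack(cfg)
  X <- sapply(paste0("bio", 1:4), function(nm) as.vector(st[[nm]]$values))
  R <- cor(X)
  expect_lt(max(abs(R[upper.tri(R)])), 0.3)

  # requested r = 0.9 between layers 1 and 2 is reproduced within 0.1
  C <- diag(3); C[1, 2] <- C[2, 1] <- 0.9
  cfg2 <- landscape_config(nrows = 128, ncols = 128, n_env_layers = 3,
                           target_correlation = C, seed = 5)
  st2 <- generate_env_stack(cfg2)
  r12 <- cor(as.vector(st2[["bio1"]]$values), as.vector(st2[["bio2"]]$values))
  expect_lt(abs(r12 - 0.9), 0.1)
})

test_that("invalid generator configurations are rejected", {
  C <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3, 3)
  expect_error(landscape_config(n_env_layers = 3, target_correlation = C),
               "positive semidefinite")
  expect_error(landscape_config(nrows = 4), ">= 8")
  expect_error(landscape_config(cellsize = 0), "positive")
})

test_that("true suitability follows the logistic closed forms", {
  cfg <- landscape_config(nrows = 16, ncols = 16, n_env_layers = 2, seed = 2)
  st <- generate_env_stack(cfg)

  # no drivers, intercept 0 -> exactly 0.5 everywhere
  g0 <- true_group("flat", "bio1", beta = 1, intercept = 0)
  g0$beta <- 0; g0$beta2 <- 0     # keep constructor guard but test constant
  expect_equal(unique(as.vector(make_true_suitability(st, g0)$values)), 0.5)

  # intercept -2, no effective drivers -> logistic(-2)
  gi <- true_group("rare", "bio1", beta = 1, intercept = -2)
  gi$beta <- 0
  expect_equal(unique(as.vector(make_true_suitability(st, gi)$values)),
               plogis(-2), tolerance = 1e-12)

  # steep single driver: suitability ~ 1 above the driver mean, ~ 0 below
  gs <- true_group("step", "bio1", beta = 50)
  s <- make_true_suitability(st, gs)$values
  z <- st[["bio1"]]$values
  zz <- (z - mean(z)) / sd(z)
  expect_true(all(s[zz > 0.5] > 0.999))
  expect_true(all(s[zz < -0.5] < 0.001))

  expect_error(make_true_suitability(st, true_group("bad", "nope", 1)),
               "nope")
  expect_error(true_group("null", "bio1", beta = 0), "nonzero")
})

test_that("occurrence sampling is proportional to suitability x effort", {
  g <- make_grid(10, 10, 100)
  # all mass on one cell
  v <- matrix(0, 10, 10); v[3, 7] <- 1
  suit <- raster_layer(v, g)
  occ <- sample_occurrences(suit, 50, seed = 1)
  cell <- cell_from_xy(g, occ$x, occ$y)
  expect_true(all(cell == (7 - 1) * 10 + 3))  # column-major index of (3, 7)

  # uniform suitability: per-cell counts consistent with uniform multinomial
  unif <- raster_layer(matrix(1, 10, 10), g)
  occ2 <- sample_occurrences(unif, 5000, seed = 2)
  counts <- tabulate(cell_from_xy(g, occ2$x, occ2$y), nbins = 100)
  expect_gt(chisq.test(counts)$p.value, 0.01)

  # two-level suitability 0.9 / 0.1 in equal areas: high share ~ 0.9
  two <- raster_layer(matrix(rep(c(0.9, 0.1), each = 50), 10, 10), g)
  occ3 <- sample_occurrences(two, 5000, seed = 3)
  hi <- two$values[cell_from_xy(g, occ3$x, occ3$y)] == 0.9
  expect_lt(abs(mean(hi) - 0.9), 0.05)

  # effort multiplies the weights; all-zero weights error
  zero <- raster_layer(matrix(0, 10, 10), g)
  expect_error(sample_occurrences(zero, 10, seed = 1), "zero")
  eff <- raster_layer(matrix(c(1, rep(0, 99)), 10, 10), g)
  occ4 <- sample_occurrences(unif, 30, effort = eff, seed = 4)
  expect_true(all(cell_from_xy(g, occ4$x, occ4$y) == 1L))
})

test_that("log-density of sampled cells scales linearly with log-weight (slope ~ 1)", {
  g <- make_grid(40, 40, 100)
  set.seed(9)
  w <- matrix(exp(rnorm(1600, sd = 0.8)), 40, 40)
  suit <- raster_layer(w / max(w), g)
  occ <- sample_occurrences(suit, 10000, seed = 10)
  counts <- tabulate(cell_from_xy(g, occ$x, occ$y), nbins = 1600)
  keep <- counts > 0
  fit <- lm(log(counts[keep]) ~ log(as.vector(suit$values)[keep]))
  expect_lt(abs(coef(fit)[2] - 1), 0.15)
})

test_that("reserves and regions form valid masks and a full partition", {
  g <- make_grid(30, 30, 100)
  rr <- generate_reserves_and_regions(g, n_reserves = 3, n_regions = 4,
                                      seed = 3)
  expect_true(all(rr$reserves$values %in% c(0, 1)))
  expect_gt(sum(rr$reserves$values), 0)
  lab <- rr$regions$values
  expect_true(all(lab %in% 1:4))
  expect_equal(sum(table(lab)), 900)       # every cell labelled exactly once
  expect_setequal(unique(as.vector(lab)), 1:4)

  # degenerate cases
  empty <- generate_reserves_and_regions(g, 0, 1, seed = 1)
  expect_equal(sum(empty$reserves$values), 0)
  expect_equal(unique(as.vector(empty$regions$values)), 1)
})

test_that("every sampled occurrence falls on a cell with finite covariates", {
  cfg <- landscape_config(nrows = 32, ncols = 32, n_env_layers = 3, seed = 4)
  b <- simulate_bundle(cfg, n_species_per_group = 1, n_presences = 100)
  cells <- cell_from_xy(b$stack$grid, b$occurrences$x, b$occurrences$y)
  vals <- stack_values_at(b$stack, cells)
  expect_true(all(is.finite(vals)))
  for (tr in b$true_suitability) {
    v <- tr$values[is.finite(tr$values)]
    expect_true(all(v >= 0 & v <= 1))
  }
})
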