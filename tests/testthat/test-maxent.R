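# Maximum-entropy core: feature construction, optimizer correctness against
# brute-force oracles, logistic output identities, contribution and
# jackknife behaviour, and the tie-corrected AUC estimator.

make_feature_stack <- function(vals, cellsize = 1) {
  # single-layer stack from a vector of values laid out on a 1 x n grid
  g <- make_grid(1, length(vals), cellsize)
  raster_stack(list(raster_layer(matrix(vals, 1), g, name = "v1")))
}

test_that("features are min-max scaled on the background with quadratic and hinge transforms", {
  st <- make_feature_stack(c(2, 3, 4, 2.5))
  fs <- build_features(st, 1:4, classes = c("linear", "quadratic"))
  Fm <- feature_matrix(fs, st, 1:4)
  expect_equal(unname(Fm[2, "v1:linear"]), 0.5)        # value 3 in [2, 4]
  expect_equal(unname(Fm[2, "v1:quadratic"]), 0.25)
  expect_true(all(Fm >= 0 & Fm <= 1))

  # hinge definition: knot 0.6 at scaled value 0.8 -> (0.8-0.6)/(1-0.6)
  fs2 <- fs
  fs2$definitions <- list(list(variable = "v1", transform = "hinge",
                               knot = 0.6))
  st2 <- make_feature_stack(c(0, 0.8, 1))
  fs2$scaling <- list(v1 = c(lo = 0, hi = 1))
  Fm2 <- feature_matrix(fs2, st2, 1:3)
  expect_equal(unname(Fm2[2, 1]), 0.5)
  expect_equal(unname(Fm2[1, 1]), 0)

  # constant stacks are rejected
  stc <- make_feature_stack(rep(1, 4))
  expect_error(build_features(stc, 1:4), "constant")
})

test_that("huge regularization shrinks all coefficients to zero (uniform model, gain 0)", {
  set.seed(1)
  st <- make_feature_stack(runif(50))
  fit <- maxent_fit(build_features(st, 1:50, classes = "linear"),
                    st, presence_cells = c(3, 7, 10, 20, 30), 1:50,
                    beta_multiplier = 1e6)
  expect_true(all(fit$lambda == 0))
  expect_equal(fit$gain, 0, tolerance = 1e-9)
  P <- predict_logistic(fit, st)
  expect_equal(unique(as.vector(P$values)), 0.5, tolerance = 1e-12)
})

test_that("one-feature fit matches a 1-D brute-force minimization of the same objective", {
  # binary feature over 4 background cells, presences on the feature=1 cells
  st <- make_feature_stack(c(1, 1, 0, 0))
  fs <- build_features(st, 1:4, classes = "linear")
  pres <- c(1, 1, 2, 2, 3)      # 4 presences on feature = 1, one on 0
  fit <- maxent_fit(fs, st, pres, 1:4, beta_multiplier = 0, tol = 1e-12)
  obj <- function(l) -0.8 * l + log(2 * exp(l) + 2)   # fbar = 4/5
  grid <- seq(-10, 10, by = 1e-4)
  lam_star <- grid[which.min(obj(grid))]
  expect_equal(unname(fit$lambda[1]), lam_star, tolerance = 1e-3)
  expect_equal(lam_star, log(4), tolerance = 1e-3)    # closed form check
})

test_that("background normalization, entropy and the logistic closed form hold after fitting", {
  set.seed(2)
  st <- tiny_stack(12, 12, 3, seed = 5)
  valid <- finite_cells(st)
  pres <- sample(valid, 20)
  fs <- build_features(st, valid, classes = c("linear", "quadratic", "hinge"))
  fit <- maxent_fit(fs, st, pres, valid)
  Fm <- feature_matrix(fs, st, valid)
  q <- exp(as.vector(Fm %*% fit$lambda) - fit$log_partition)
  expect_equal(sum(q), 1, tolerance = 1e-9)
  expect_gte(fit$entropy, 0)

  # logistic output: hand-computed 3-cell closed form
  lam <- fit$lambda
  eta3 <- as.vector(Fm[1:3, , drop = FALSE] %*% lam)
  P <- predict_logistic(fit, st, cells = valid[1:3])
  q3 <- exp(eta3 - fit$log_partition)
  expect_equal(P, q3 * exp(fit$entropy) / (1 + q3 * exp(fit$entropy)),
               tolerance = 1e-12)
})

test_that("duplicated feature columns split the coefficient of the single-column fit", {
  g <- make_grid(1, 60, 1)
  set.seed(3)
  v <- runif(60)
  st1 <- raster_stack(list(raster_layer(matrix(v, 1), g, name = "a")))
  st2 <- raster_stack(list(raster_layer(matrix(v, 1), g, name = "a"),
                           raster_layer(matrix(v, 1), g, name = "b")))
  pres <- order(v, decreasing = TRUE)[1:8]
  f1 <- maxent_fit(build_features(st1, 1:60, classes = "linear"), st1,
                   pres, 1:60, beta_multiplier = 0, tol = 1e-10)
  f2 <- maxent_fit(build_features(st2, 1:60, classes = "linear"), st2,
                   pres, 1:60, beta_multiplier = 0, tol = 1e-10)
  expect_equal(sum(f2$lambda), unname(f1$lambda[1]), tolerance = 1e-2)
  # objective equivalence is the real contract
  expect_equal(f2$objective, f1$objective, tolerance = 1e-6)
})

test_that("increasing the L1 multiplier never increases the active set", {
  set.seed(4)
  st <- tiny_stack(10, 10, 4, seed = 6)
  pres <- sample(100, 15)
  fs <- build_features(st, 1:100, classes = c("linear", "quadratic"))
  nnz <- sapply(c(0.5, 2, 8), function(bm) {
    fit <- maxent_fit(fs, st, pres, 1:100, beta_multiplier = bm)
    sum(abs(fit$lambda) > 1e-8)
  })
  expect_true(all(diff(nnz) <= 0))
})

test_that("percent contribution sums to 100 and credits the driving variable", {
  set.seed(5)
  g <- make_grid(20, 20, 1)
  z <- matrix(rnorm(400), 20, 20)
  noise <- matrix(rnorm(400), 20, 20)
  st <- raster_stack(list(raster_layer(z, g, name = "driver"),
                          raster_layer(noise, g, name = "noise")))
  pres <- order(as.vector(z), decreasing = TRUE)[1:30]
  fit <- maxent_fit(build_features(st, 1:400, classes = "linear"), st,
                    pres, 1:400)
  pc <- percent_contribution(fit)
  expect_equal(sum(pc), 100, tolerance = 1e-6)
  expect_gt(pc["driver"], pc["noise"])

  # single-variable model -> 100%
  st1 <- raster_stack(list(raster_layer(z, g, name = "driver")))
  fit1 <- maxent_fit(build_features(st1, 1:400, classes = "linear"), st1,
                     pres, 1:400)
  expect_equal(unname(percent_contribution(fit1)["driver"]), 100)
})

test_that("jackknife gains separate informative from noise variables", {
  set.seed(6)
  g <- make_grid(25, 20, 1)
  z <- matrix(rnorm(500), 25, 20)
  noise <- matrix(rnorm(500), 25, 20)
  st <- raster_stack(list(raster_layer(z, g, name = "driver"),
                          raster_layer(noise, g, name = "noise")))
  pres <- order(as.vector(z), decreasing = TRUE)[1:40]
  fs <- build_features(st, 1:500, classes = "linear")
  jk <- jackknife_gain(fs, st, pres, 1:500)
  jk <- jk[order(jk$variable), ]
  expect_lt(jk$with_only[jk$variable == "noise"], 0.05)
  expect_gt(jk$with_only[jk$variable == "driver"], 0.5)
  # removing the noise variable barely changes the full gain
  fit_full <- maxent_fit(fs, st, pres, 1:500)
  expect_lt(abs(jk$without[jk$variable == "noise"] - fit_full$gain),
            0.05 * abs(fit_full$gain))

  # single-variable input: the "without" model is uniform -> gain 0
  st1 <- raster_stack(list(raster_layer(z, g, name = "driver")))
  fs1 <- build_features(st1, 1:500, classes = "linear")
  jk1 <- jackknife_gain(fs1, st1, pres, 1:500)
  expect_equal(jk1$without, 0)
})

test_that("rank-based AUC equals brute-force pair counting with 0.5 tie credit", {
  expect_equal(auc_rank(c(3, 4), c(1, 2)), 1)
  expect_equal(auc_rank(rep(1, 5), rep(1, 7)), 0.5)
  expect_error(auc_rank(numeric(0), 1), "nonempty")
  set.seed(7)
  for (i in 1:20) {
    p <- sample(round(runif(20, 0, 5), 1), 20, TRUE)
    b <- sample(round(runif(30, 0, 5), 1), 30, TRUE)
    expect_equal(auc_rank(p, b), auc_brute(p, b), tolerance = 1e-12)
  }
})

test_that("subsample evaluation applies the reliability rule and flags uniform species", {
  cfg <- landscape_config(nrows = 48, ncols = 48, n_env_layers = 3, seed = 8)
  st <- generate_env_stack(cfg)
  valid <- finite_cells(st)
  # species occupying uniformly random cells: AUC ~ 0.5, gets excluded
  set.seed(9)
  cells <- sample(valid, 60)
  rep0 <- suppressWarnings(
    evaluate_subsample(st, cells, n_background = 1500, n_replicates = 5,
                       seed = 3, classes = "linear", species = "null_sp"))
  expect_lt(abs(rep0$auc_mean - 0.5), 0.07)
  expect_true(rep0$excluded)
  expect_equal(rep0$cv, rep0$auc_sd / rep0$auc_mean)
  expect_error(evaluate_subsample(st, cells[1:5], species = "few"), "few")
})

test_that("objective decreases monotonically across cycles (spot check via refit path)", {
  set.seed(10)
  st <- tiny_stack(8, 8, 2, seed = 11)
  pres <- sample(64, 10)
  fs <- build_features(st, 1:64, classes = "linear")
  objs <- sapply(c(1, 2, 5, 50), function(mi)
    suppressWarnings(maxent_fit(fs, st, pres, 1:64, max_iter = mi)$objective))
  expect_true(all(diff(objs) <= 1e-12))
})
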