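# Synthetic landscapes with known ground truth: correlated smoothed Gaussian
# fields for climate-like covariates, a low-frequency DEM with Horn-derived
# slope/aspect, a rule-based land-cover mosaic, city-kernel population and
# nighttime-light surfaces, logistic true-suitability surfaces per ecological
# group, and presence-only sampling proportional to suitability x effort.

# Evaluate code under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed
#'
#' Stable 31-bit mixing of a root seed with string tokens (stage names,
#' species labels, replicate numbers) so per-stage, per-species seeds are
#' reproducible and adding a species does not perturb the others'.
#'
#' @param root Integer root seed.
#' @param ... Tokens (coerced to character) identifying the consumer.
#' @return An integer in `[0, 2^31)`.
#' @export
derive_seed <- function(root, ...) {
  h <- as.numeric(root) %% 2147483647
  for (tok in as.character(c(...))) {
    for (cc in utf8ToInt(tok)) h <- (h * 31 + cc) %% 2147483647
  }
  as.integer(h)
}

#' Configuration for the synthetic landscape generator
#'
#' @param nrows,ncols Grid dimensions (>= 8).
#' @param cellsize Cell size in metres (default 300, the analysis resolution).
#' @param n_env_layers Number of climate-like continuous layers (`bio1`...).
#' @param target_correlation Symmetric positive semidefinite correlation
#'   matrix (unit diagonal) for the climate layers; identity by default.
#' @param smoothing_scale Gaussian smoothing standard deviation in cells
#'   controlling spatial autocorrelation of the climate fields.
#' @param env_skew Right-skew of the climate-layer marginals: each layer is
#'   a standardized exponentiated Gaussian field `exp(env_skew * g)`,
#'   emulating the strong right skew of precipitation-type variables
#'   (0 gives Gaussian marginals).
#' @param n_landcover_classes Number of land-cover classes (2-6; 6 gives the
#'   named cropland/forest/grassland/water/barren/impervious mosaic).
#' @param n_city_seeds Number of population kernels.
#' @param seed Integer RNG seed; the whole bundle is deterministic given it.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(nrows = 128, ncols = 128, cellsize = 300,
                             n_env_layers = 6, target_correlation = NULL,
                             smoothing_scale = 6, env_skew = 1,
                             n_landcover_classes = 6,
                             n_city_seeds = 3, seed = 1) {
  if (nrows < 8 || ncols < 8) stop("nrows and ncols must be >= 8")
  if (cellsize <= 0) stop("cellsize must be positive")
  if (is.null(target_correlation)) target_correlation <- diag(n_env_layers)
  C <- as.matrix(target_correlation)
  if (nrow(C) != n_env_layers || ncol(C) != n_env_layers)
    stop("target_correlation must be ", n_env_layers, " x ", n_env_layers)
  if (max(abs(C - t(C))) > 1e-8 || any(abs(diag(C) - 1) > 1e-8))
    stop("target_correlation must be symmetric with unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("target_correlation is not positive semidefinite")
  if (!(n_landcover_classes %in% 2:6))
    stop("n_landcover_classes must be between 2 and 6")
  if (env_skew < 0) stop("env_skew must be nonnegative")
  structure(list(nrows = as.integer(nrows), ncols = as.integer(ncols),
                 cellsize = cellsize, n_env_layers = as.integer(n_env_layers),
                 target_correlation = C, smoothing_scale = smoothing_scale,
                 env_skew = env_skew,
                 n_landcover_classes = as.integer(n_landcover_classes),
                 n_city_seeds = as.integer(n_city_seeds),
                 seed = as.integer(seed)),
            class = "landscape_config")
}

# Separable Gaussian smoothing of a matrix, edge-renormalized so borders are
# not attenuated.
gauss_smooth <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_cells))
  kern <- stats::dnorm(-half:half, sd = sd_cells)
  kern <- kern / sum(kern)
  conv_cols <- function(mat) {
    n <- nrow(mat)
    out <- apply(mat, 2, function(v) {
      full <- stats::convolve(v, kern, type = "open")
      full[(half + 1):(half + n)]
    })
    ones <- stats::convolve(rep(1, n), kern, type = "open")[(half + 1):(half + n)]
    out / ones
  }
  t(conv_cols(t(conv_cols(m))))
}

# One standardized smoothed Gaussian random field.
smooth_field <- function(nr, nc, sd_cells) {
  f <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sd_cells)
  (f - mean(f)) / stats::sd(f)
}

#' Generate the synthetic environmental stack
#'
#' Climate layers (`bio1`, `bio2`, ...) are smoothed Gaussian fields,
#' empirically whitened and mixed through the Cholesky factor of the target
#' correlation so their pairwise Pearson correlations match
#' `target_correlation` closely. A low-frequency DEM yields Horn slope and
#' aspect; NDVI loads negatively on elevation; population density is a sum of
#' city kernels, nighttime lights a saturating transform of it; land cover is
#' a rule-based categorical mosaic.
#'
#' @param config A [landscape_config()].
#' @return An [raster_stack()] with layers `bio1..bioN`, `dem`, `slo`,
#'   `asp`, `ndvi`, `lc`, `pop`, `net`.
#' @export
generate_env_stack <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$nrows; nc <- config$ncols
  g <- make_grid(nr, nc, config$cellsize)
  with_seed(config$seed, {
    k <- config$n_env_layers
    sk <- config$env_skew %||% 0
    Fm <- vapply(seq_len(k), function(i) {
      f <- as.vector(smooth_field(nr, nc, config$smoothing_scale))
      if (sk > 0) f <- as.vector(scale(exp(sk * f)))
      f
    }, numeric(nr * nc))
    # empirical whitening: exact sample correlation = target after mixing
    S <- stats::cov(Fm)
    W <- backsolve(chol(S), diag(k))
    Z <- scale(Fm %*% W)             # exactly uncorrelated, unit variance
    L <- suppressWarnings(chol(config$target_correlation, pivot = TRUE))
    piv <- attr(L, "pivot")
    X <- Z %*% L[, order(piv), drop = FALSE]
    layers <- lapply(seq_len(k), function(i)
      raster_layer(matrix(X[, i], nr, nc), g, name = paste0("bio", i)))

    dem_f <- smooth_field(nr, nc, max(2 * config$smoothing_scale, 10))
    dem <- raster_layer(matrix(800 + 400 * dem_f, nr, nc), g, name = "dem")
    sa <- slope_aspect(dem, edge = "replicate")

    ndvi_f <- smooth_field(nr, nc, config$smoothing_scale)
    ndvi_v <- stats::plogis(1.1 * ndvi_f - 0.8 * dem_f)
    ndvi <- raster_layer(matrix(ndvi_v, nr, nc), g, name = "ndvi")

    rc <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    pop_v <- rep(0, nr * nc)
    for (ci in seq_len(config$n_city_seeds)) {
      r0 <- stats::runif(1, 1, nr); c0 <- stats::runif(1, 1, nc)
      amp <- stats::runif(1, 200, 2000)
      sig <- stats::runif(1, 2, max(3, config$smoothing_scale))
      d2 <- (rc$row - r0)^2 + (rc$col - c0)^2
      pop_v <- pop_v + amp * exp(-d2 / (2 * sig^2))
    }
    pop <- raster_layer(matrix(pop_v, nr, nc), g, name = "pop")
    net_v <- 63 * (1 - exp(-pop_v / max(stats::quantile(pop_v, 0.98), 1)))
    net <- raster_layer(matrix(pmin(net_v, 63), nr, nc), g, name = "net")

    wet <- smooth_field(nr, nc, config$smoothing_scale)
    lc_v <- .landcover_rules(wet, ndvi_v, dem_f, pop_v,
                             config$n_landcover_classes)
    lc <- raster_layer(matrix(lc_v, nr, nc), g, name = "lc",
                       kind = "categorical")

    all_layers <- c(layers, list(dem, sa$slope, sa$aspect, ndvi, lc, pop, net))
    raster_stack(all_layers)
  })
}

# Land-cover codes: 1 cropland, 2 forest, 3 grassland, 4 water, 5 barren,
# 6 impervious (matching the six classes summarized in preference profiles).
.landcover_rules <- function(wet, ndvi, demf, pop, k) {
  n <- length(wet)
  if (k < 6) {
    qs <- stats::quantile(wet, probs = seq(0, 1, length.out = k + 1))
    return(as.numeric(cut(wet, breaks = unique(qs), include.lowest = TRUE,
                          labels = FALSE)))
  }
  lc <- rep(1, n)                                   # cropland default
  lc[demf > stats::median(demf)] <- 3               # grassland uplands
  lc[ndvi > stats::quantile(ndvi, 0.75)] <- 2       # forest
  lc[ndvi < stats::quantile(ndvi, 0.12)] <- 5       # barren
  lc[wet > stats::quantile(wet, 0.92)] <- 4         # water
  lc[pop > stats::quantile(pop, 0.95)] <- 6         # impervious
  lc
}

#' Define a ground-truth ecological group
#'
#' The true suitability of the group is
#' `logistic(intercept + sum_j beta_j z_j + beta2_j z_j^2)` where `z_j` is the
#' named driver layer standardized to mean 0, sd 1.
#'
#' @param name Group label.
#' @param drivers Character vector of driver layer names.
#' @param beta Linear coefficients on the standardized drivers.
#' @param beta2 Quadratic coefficients (default all 0).
#' @param intercept Intercept on the logit scale.
#' @return A `true_group` object.
#' @export
true_group <- function(name, drivers, beta, beta2 = NULL, intercept = 0) {
  if (is.null(beta2)) beta2 <- rep(0, length(drivers))
  stopifnot(length(beta) == length(drivers), length(beta2) == length(drivers))
  if (all(beta == 0) && all(beta2 == 0))
    stop("at least one coefficient must be nonzero")
  structure(list(name = name, drivers = drivers, beta = beta, beta2 = beta2,
                 intercept = intercept), class = "true_group")
}

#' Ground-truth suitability surface for a group
#'
#' @param stack Environmental [raster_stack()].
#' @param group A [true_group()].
#' @return A [raster_layer()] with values in (0, 1); `NA` where any driver
#'   is missing.
#' @export
make_true_suitability <- function(stack, group) {
  missing_l <- setdiff(group$drivers, names(stack))
  if (length(missing_l))
    stop("driver layer(s) not in stack: ", paste(missing_l, collapse = ", "))
  g <- stack$grid
  eta <- matrix(group$intercept, g$nrows, g$ncols)
  for (j in seq_along(group$drivers)) {
    v <- stack[[group$drivers[j]]]$values
    mu <- mean(v[is.finite(v)]); sdv <- stats::sd(v[is.finite(v)])
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    z <- (v - mu) / sdv
    eta <- eta + group$beta[j] * z + group$beta2[j] * z^2
  }
  raster_layer(stats::plogis(eta), g,
               name = paste0("truth_", group$name))
}

#' Sample presence-only occurrence records
#'
#' Cells are drawn (with replacement) with probability proportional to
#' `suitability x effort`; the record coordinate is the cell center jittered
#' uniformly within the cell, emulating opportunistic reporting.
#'
#' @param true_suitability Suitability [raster_layer()] in `[0, 1]`.
#' @param n_target Number of records to draw (>= 1).
#' @param effort Optional nonnegative effort [raster_layer()] (observer
#'   bias); uniform when `NULL`.
#' @param seed Integer seed.
#' @param species,group Labels attached to the records.
#' @return Occurrence data.frame (`species`, `group`, `x`, `y`).
#' @export
sample_occurrences <- function(true_suitability, n_target, effort = NULL,
                               seed = 1, species = "sp1", group = NA) {
  stopifnot(n_target >= 1)
  g <- true_suitability$grid
  w <- as.vector(true_suitability$values)
  if (!is.null(effort)) {
    ev <- as.vector(effort$values)
    if (any(ev < 0, na.rm = TRUE)) stop("effort must be nonnegative")
    w <- w * ev
  }
  w[!is.finite(w)] <- 0
  if (all(w <= 0)) stop("all sampling weights are zero")
  with_seed(seed, {
    cells <- sample.int(length(w), n_target, replace = TRUE, prob = w)
    ctr <- cell_center(g, cells)
    data.frame(species = species, group = group,
               x = ctr$x + (stats::runif(n_target) - 0.5) * g$cellsize,
               y = ctr$y + (stats::runif(n_target) - 0.5) * g$cellsize)
  })
}

#' Random reserves and a regional partition
#'
#' Reserves are unions of random discs rasterized to the grid; regions are
#' the Voronoi partition of random seed cells (every cell labelled exactly
#' once, labels `1..n_regions`).
#'
#' @param grid Analysis grid.
#' @param n_reserves Number of reserve discs (0 allowed: empty mask).
#' @param n_regions Number of regions (>= 1).
#' @param seed Integer seed.
#' @return List with binary [raster_layer()] `reserves` and integer
#'   [raster_layer()] `regions`.
#' @export
generate_reserves_and_regions <- function(grid, n_reserves, n_regions,
                                          seed = 1) {
  stopifnot(n_reserves >= 0, n_regions >= 1)
  nr <- grid$nrows; nc <- grid$ncols
  rc <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  with_seed(seed, {
    mask <- rep(0, nr * nc)
    if (n_reserves >= 1) {
      for (i in seq_len(n_reserves)) {
        r0 <- stats::runif(1, 1, nr); c0 <- stats::runif(1, 1, nc)
        rad <- stats::runif(1, 0.03, 0.10) * min(nr, nc)
        mask[(rc$row - r0)^2 + (rc$col - c0)^2 <= rad^2] <- 1
      }
    }
    seeds <- sample.int(nr * nc, n_regions)
    srw <- cell_to_rowcol(grid, seeds)
    d <- vapply(seq_len(n_regions),
                function(i) (rc$row - srw$row[i])^2 + (rc$col - srw$col[i])^2,
                numeric(nr * nc))
    lab <- max.col(-d, ties.method = "first")
    list(reserves = raster_layer(matrix(mask, nr, nc), grid,
                                 name = "reserves", kind = "categorical"),
         regions = raster_layer(matrix(lab, nr, nc), grid,
                                name = "regions", kind = "categorical"))
  })
}

#' Generate a complete synthetic bundle
#'
#' The bundle carries everything the pipeline consumes, with known ground
#' truth: the environmental stack, group definitions with one dominant
#' climate driver each (standardized linear coefficient 2.0 and a weak
#' secondary driver 0.5), true suitability surfaces, presence-only
#' occurrences per species, a reserve mask and a regional partition.
#'
#' @param config A [landscape_config()].
#' @param groups Optional list of [true_group()]; a 3-group default (dominant
#'   drivers `bio1`, `bio2`, `bio3`) is built when `NULL`.
#' @param n_species_per_group Species per group (each species shares the
#'   group's truth surface but has its own sampling seed).
#' @param n_presences Presence records per species.
#' @param n_reserves,n_regions Passed to [generate_reserves_and_regions()].
#' @param effort Optional effort raster for biased sampling.
#' @return An `hs_bundle` list.
#' @export
simulate_bundle <- function(config, groups = NULL, n_species_per_group = 3,
                            n_presences = 300, n_reserves = 5, n_regions = 4,
                            effort = NULL) {
  stack <- generate_env_stack(config)
  if (is.null(groups)) {
    if (config$n_env_layers < 3)
      stop("default groups need at least 3 climate layers")
    # Specialist groups: a dominant climate driver (linear 2.0 with niche
    # curvature 1.0 on its standardized scale), a weak secondary climate
    # driver, and moderate vegetation/terrain structure; intercept -7 gives
    # landscape prevalence near 5%, typical of a wetland specialist.
    groups <- list(
      true_group("waders",    c("bio1", "bio2", "ndvi", "dem"),
                 beta = c(2, 0.5, 1, -1), beta2 = c(1, 0, 0, 0),
                 intercept = -7),
      true_group("waterfowl", c("bio2", "bio3", "dem", "ndvi"),
                 beta = c(2, 0.5, -1, 1), beta2 = c(1, 0, 0, 0),
                 intercept = -7),
      true_group("gulls",     c("bio3", "bio1", "ndvi", "dem"),
                 beta = c(2, 0.5, -1, -1), beta2 = c(1, 0, 0, 0),
                 intercept = -7))
  }
  truths <- lapply(groups, function(gr) make_true_suitability(stack, gr))
  names(truths) <- vapply(groups, `[[`, "", "name")
  occ <- do.call(rbind, lapply(seq_along(groups), function(gi) {
    do.call(rbind, lapply(seq_len(n_species_per_group), function(si) {
      sample_occurrences(truths[[gi]], n_presences, effort = effort,
                         seed = derive_seed(config$seed, "occ",
                                            groups[[gi]]$name, si),
                         species = sprintf("sp_%s_%02d",
                                           groups[[gi]]$name, si),
                         group = groups[[gi]]$name)
    }))
  }))
  rr <- generate_reserves_and_regions(stack$grid, n_reserves, n_regions,
                                      seed = derive_seed(config$seed, "rr"))
  structure(list(stack = stack, groups = groups, true_suitability = truths,
                 occurrences = occ, reserves = rr$reserves,
                 regions = rr$regions, config = config),
            class = "hs_bundle")
}
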