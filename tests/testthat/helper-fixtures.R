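# Shared fixtures built in code.

tiny_grid <- function(nrows = 4, ncols = 4, cellsize = 100) {
  make_grid(nrows, ncols, cellsize)
}

# A small continuous raster with reproducible values.
tiny_raster <- function(nrows = 4, ncols = 4, cellsize = 100, seed = 1,
                        name = "x") {
  g <- tiny_grid(nrows, ncols, cellsize)
  set.seed(seed)
  raster_layer(matrix(round(rnorm(nrows * ncols), 6), nrows, ncols), g,
               name = name)
}

# Small stack of named independent uniform layers.
tiny_stack <- function(nrows = 10, ncols = 10, nlayers = 3, seed = 1,
                       cellsize = 100) {
  g <- make_grid(nrows, ncols, cellsize)
  set.seed(seed)
  raster_stack(lapply(seq_len(nlayers), function(i)
    raster_layer(matrix(runif(nrows * ncols), nrows, ncols), g,
                 name = paste0("v", i))))
}

# Brute-force AUC by pair counting with 0.5 tie credit.
auc_brute <- function(p, b) {
  s <- 0
  for (x in p) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(p) * length(b))
}

# Exhaustive Fisher-Jenks oracle: enumerate all ordered partitions of the
# sorted values into k contiguous classes, minimize total within-class SSD.
jenks_oracle <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ssd <- function(x) sum((x - mean(x))^2)
  best <- NULL; best_cost <- Inf
  splits <- utils::combn(n - 1, k - 1, simplify = FALSE)
  for (sp in splits) {
    bounds <- c(0, sp, n)
    cost <- sum(vapply(seq_len(k), function(i)
      ssd(v[(bounds[i] + 1):bounds[i + 1]]), 0))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- v[sp]   # upper bounds of lower classes
    }
  }
  list(breaks = best, cost = best_cost)
}
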