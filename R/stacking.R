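# Natural-breaks classification, per-species binarization, richness stacking
# and hotspot/uniqueness derivation.

#' Fisher-Jenks natural breaks
#'
#' Exact dynamic-programming optimal 1-D partition into `k` classes
#' minimizing the total within-class sum of squared deviations. Breaks are
#' the upper bounds of the lower `k - 1` classes (a value belongs to the
#' lowest class whose break is `>=` it). Duplicated input values are handled
#' as weights, so complexity depends on the number of distinct values; above
#' `max_bins` distinct values the DP runs on quantile-binned weighted
#' representatives (breaks then are near-optimal rather than exact).
#'
#' @param values Numeric vector (at least `k` distinct finite values).
#' @param k Number of classes (>= 1).
#' @param max_bins Distinct-value cap before binning (default 4096).
#' @return Numeric vector of `k - 1` break values (empty for `k = 1`).
#' @export
jenks_breaks <- function(values, k, max_bins = 4096) {
  if (k < 1) stop("k must be >= 1")
  values <- values[is.finite(values)]
  vs <- sort(values)              # rle keeps exact doubles (no string round-trip)
  runs <- rle(vs)
  v <- runs$values
  w <- as.numeric(runs$lengths)
  if (length(v) < k)
    stop("need at least k distinct values (have ", length(v), ", k = ", k, ")")
  if (k == 1) return(numeric(0))
  if (length(v) > max_bins) {
    qs <- unique(stats::quantile(values, probs = seq(0, 1,
                                                     length.out = max_bins + 1),
                                 names = FALSE))
    bin <- findInterval(values, qs, rightmost.closed = TRUE)
    v <- as.numeric(tapply(values, bin, mean))
    w <- as.numeric(tapply(values, bin, length))
    o <- order(v)
    v <- v[o]; w <- w[o]
  }
  n <- length(v)
  cw <- cumsum(w)
  cwv <- cumsum(w * v)
  cwv2 <- cumsum(w * v^2)
  # ssd of v[i..j] weighted
  ssd <- function(i, j) {
    W <- cw[j] - ifelse(i > 1, cw[i - 1], 0)
    S <- cwv[j] - ifelse(i > 1, cwv[i - 1], 0)
    S2 <- cwv2[j] - ifelse(i > 1, cwv2[i - 1], 0)
    pmax(S2 - S^2 / W, 0)
  }
  D <- matrix(Inf, k, n)        # D[c, j]: best cost of v[1..j] in c classes
  B <- matrix(0L, k, n)         # start index of the last class
  D[1, ] <- ssd(1, seq_len(n))
  B[1, ] <- 1L
  if (k > 1) for (cl in 2:k) {
    for (j in cl:n) {
      i <- cl:j                 # candidate start of the last class
      cost <- D[cl - 1, i - 1] + ssd(i, j)
      best <- which.min(cost)
      D[cl, j] <- cost[best]
      B[cl, j] <- i[best]
    }
  }
  # backtrack class boundaries
  breaks <- numeric(k - 1)
  j <- n
  for (cl in k:2) {
    i <- B[cl, j]
    breaks[cl - 1] <- v[i - 1]  # upper bound of the class below
    j <- i - 1
  }
  breaks
}

# Assign class codes 1..k from breaks (value <= break -> lower class).
# Preserves the shape of x (matrix in, matrix out).
classify_by_breaks <- function(x, breaks) {
  cls <- x
  cls[] <- NA_real_
  ok <- is.finite(x)
  cls[ok] <- findInterval(x[ok], breaks, left.open = TRUE) + 1
  cls
}

#' Binarize a logistic suitability map
#'
#' `jenks3_top`: 3-class natural breaks on the map's finite values, top class
#' (high suitability) coded 1, others 0. `fixed_threshold`: cells with value
#' `>= threshold` coded 1.
#'
#' @param logistic_map [raster_layer()] in `[0, 1]`.
#' @param method `"jenks3_top"` or `"fixed_threshold"`.
#' @param threshold Required for `fixed_threshold`.
#' @return A binary [raster_layer()] (`NA` cells stay `NA`); the threshold
#'   actually applied is attached as attribute `"threshold"`.
#' @export
binarize_species <- function(logistic_map,
                             method = c("jenks3_top", "fixed_threshold"),
                             threshold = NULL) {
  method <- match.arg(method)
  v <- logistic_map$values
  fin <- v[is.finite(v)]
  if (method == "jenks3_top") {
    if (length(unique(fin)) < 3)
      stop("jenks3_top needs at least 3 distinct finite values")
    br <- jenks_breaks(fin, 3)
    thr <- br[2]
    bin <- ifelse(is.finite(v), as.numeric(v > thr), NA_real_)
  } else {
    if (is.null(threshold)) stop("fixed_threshold requires a threshold")
    thr <- threshold
    bin <- ifelse(is.finite(v), as.numeric(v >= thr), NA_real_)
  }
  out <- raster_layer(bin, logistic_map$grid,
                      name = paste0(logistic_map$name, "_bin"),
                      kind = "categorical")
  attr(out, "threshold") <- thr
  out
}

#' Stack binary maps into a richness surface
#'
#' @param binary_maps List of aligned binary [raster_layer()]s.
#' @param grid Grid to use when the list is empty.
#' @return Integer richness [raster_layer()] (cellwise sum; a cell that is
#'   nodata in any input map is nodata).
#' @export
stack_richness <- function(binary_maps, grid = NULL) {
  if (length(binary_maps) == 0) {
    if (is.null(grid)) stop("grid required for an empty map list")
    return(raster_layer(matrix(0, grid$nrows, grid$ncols), grid,
                        name = "richness"))
  }
  g <- binary_maps[[1]]$grid
  acc <- matrix(0, g$nrows, g$ncols)
  for (b in binary_maps) {
    if (!grid_equal(b$grid, g)) stop_grid_mismatch("binary maps")
    acc <- acc + b$values
  }
  raster_layer(acc, g, name = "richness")
}

#' Classify a richness surface into hotspot classes
#'
#' 3-class natural breaks on the richness values, coded 0 (non-suitable),
#' 1 (low suitability), 2 (high suitability / suitable habitat).
#'
#' @param richness Integer [raster_layer()].
#' @return Categorical [raster_layer()] coded 0/1/2 with attribute
#'   `"breaks"`. Fewer than 3 distinct values degrade gracefully (all class
#'   0, or a two-class coding) with a warning.
#' @export
classify_hotspots <- function(richness) {
  v <- richness$values
  fin <- v[is.finite(v)]
  nu <- length(unique(fin))
  if (nu < 3) {
    warning("fewer than 3 distinct richness values; degenerate hotspot coding")
    if (nu <= 1) {
      cls <- ifelse(is.finite(v), 0, NA_real_)
      br <- numeric(0)
    } else {
      br <- jenks_breaks(fin, 2)
      cls <- classify_by_breaks(v, br) - 1
    }
  } else {
    br <- jenks_breaks(fin, 3)
    cls <- classify_by_breaks(v, br) - 1
  }
  out <- raster_layer(cls, richness$grid, name = "hotspot3",
                      kind = "categorical")
  attr(out, "breaks") <- br
  out
}

# Windowed box sums with edge shrinkage via summed-area tables.
# Returns list(sum, count) over finite cells in the w x w window.
box_stats <- function(m, wcells) {
  half <- (wcells - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  fin <- is.finite(m)
  mz <- ifelse(fin, m, 0)
  sat <- function(x) {
    x <- apply(x, 2, cumsum)
    t(apply(x, 1, cumsum))
  }
  Sv <- sat(mz); Sc <- sat(fin + 0)
  idx <- function(S, r1, r2, c1, c2) {
    # inclusive rectangle sums, vectorized over equal-length index vectors
    g <- function(r, c) {
      out <- numeric(length(r))
      ok <- r >= 1 & c >= 1
      out[ok] <- S[cbind(r[ok], c[ok])]
      out
    }
    g(r2, c2) - g(r1 - 1, c2) - g(r2, c1 - 1) + g(r1 - 1, c1 - 1)
  }
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  r1 <- pmax(rows - half, 1); r2 <- pmin(rows + half, nr)
  c1 <- pmax(cols - half, 1); c2 <- pmin(cols + half, nc)
  list(sum = matrix(idx(Sv, r1, r2, c1, c2), nr, nc),
       count = matrix(idx(Sc, r1, r2, c1, c2), nr, nc))
}

window_cells <- function(window_edge, cellsize) {
  w <- max(1L, round(window_edge / cellsize))
  if (w %% 2 == 0) w <- w + 1L   # nearest odd count
  as.integer(w)
}

#' Moving-window density of a binary raster
#'
#' Mean of the binary values over a square window centred on each cell; at
#' the edges the window shrinks to in-bounds cells. Nodata cells are excluded
#' from both numerator and denominator.
#'
#' @param binary [raster_layer()] of 0/1 values.
#' @param window_edge Window edge length in map units (default 1000 m).
#' @return A [raster_layer()] of densities in `[0, 1]`.
#' @export
neighborhood_density <- function(binary, window_edge = 1000) {
  g <- binary$grid
  if (window_edge < g$cellsize) stop("window_edge must be >= cellsize")
  w <- window_cells(window_edge, g$cellsize)
  bs <- box_stats(binary$values, w)
  dens <- ifelse(bs$count > 0, bs$sum / bs$count, NA_real_)
  dens[!is.finite(binary$values)] <- NA_real_
  raster_layer(dens, g, name = paste0(binary$name, "_density"))
}

#' Cells suitable for exactly one group
#'
#' @param suitable_masks Named list of aligned binary [raster_layer()]s, one
#'   per ecological group.
#' @return Integer [raster_layer()]: the index (1-based, in list order) of
#'   the single group a cell is suitable for, 0 elsewhere; attribute
#'   `"groups"` carries the group names.
#' @export
unique_group_cells <- function(suitable_masks) {
  g <- suitable_masks[[1]]$grid
  cnt <- matrix(0, g$nrows, g$ncols)
  lab <- matrix(0, g$nrows, g$ncols)
  for (i in seq_along(suitable_masks)) {
    msk <- suitable_masks[[i]]
    if (!grid_equal(msk$grid, g)) stop_grid_mismatch("suitable masks")
    one <- is.finite(msk$values) & msk$values == 1
    cnt <- cnt + one
    lab[one] <- i
  }
  lab[cnt != 1] <- 0
  out <- raster_layer(lab, g, name = "unique_group", kind = "categorical")
  attr(out, "groups") <- names(suitable_masks)
  out
}
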