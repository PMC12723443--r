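# Moving-window Shannon diversity/evenness of land cover and
# disturbance-exposure summaries over group hotspots.

#' Moving-window Shannon diversity and evenness
#'
#' Per square window centred on each cell: class proportions `p_i` among the
#' finite cells, `SHDI = -sum p_i ln p_i`, and `SHEI = SHDI / ln(m)` with
#' `m` either the number of classes present in the window (default) or in
#' the whole map. Single-class windows score `SHDI = 0, SHEI = 0`; edge
#' windows shrink to the in-bounds cells; all-nodata windows are `NA`.
#'
#' @param landcover Categorical [raster_layer()].
#' @param window_edge Window edge in map units (default 900 m; the cell
#'   count is `window_edge / cellsize` rounded to the nearest odd integer).
#' @param shei_basis `"window"` or `"map"` basis for `m`.
#' @return List of [raster_layer()]s `shdi` and `shei` (the SHEI basis is
#'   recorded as attribute `"shei_basis"`).
#' @export
shannon_window <- function(landcover, window_edge = 900,
                           shei_basis = c("window", "map")) {
  shei_basis <- match.arg(shei_basis)
  g <- landcover$grid
  w <- window_cells(window_edge, g$cellsize)
  v <- landcover$values
  cls <- sort(unique(v[is.finite(v)]))
  nr <- g$nrows; nc <- g$ncols
  total <- matrix(0, nr, nc)
  counts <- vector("list", length(cls))
  for (i in seq_along(cls)) {
    ind <- matrix(NA_real_, nr, nc)
    ind[is.finite(v)] <- as.numeric(v[is.finite(v)] == cls[i])
    bs <- box_stats(ind, w)
    counts[[i]] <- bs$sum
    if (i == 1) total <- bs$count
  }
  shdi <- matrix(0, nr, nc)
  m_present <- matrix(0, nr, nc)
  for (i in seq_along(cls)) {
    p <- ifelse(total > 0, counts[[i]] / total, 0)
    pos <- p > 0
    shdi[pos] <- shdi[pos] - p[pos] * log(p[pos])
    m_present <- m_present + pos
  }
  m <- if (shei_basis == "window") m_present
  else matrix(length(cls), nr, nc)
  shei <- ifelse(m > 1, shdi / log(m), 0)
  empty <- total == 0
  shdi[empty] <- NA_real_; shei[empty] <- NA_real_
  out_shdi <- raster_layer(shdi, g, name = "shdi")
  out_shei <- raster_layer(shei, g, name = "shei")
  attr(out_shei, "shei_basis") <- shei_basis
  list(shdi = out_shdi, shei = out_shei)
}

#' Disturbance exposure summaries per group
#'
#' Quantile summaries (median, quartiles, deciles) of a disturbance raster
#' (e.g. nighttime lights or population density) over each group's suitable
#' cells, as a tidy table suitable for violin-style comparison.
#'
#' @param disturbance Continuous [raster_layer()].
#' @param suitable_masks Named list of binary [raster_layer()]s per group.
#' @return Data.frame: `group`, `n`, `q10`, `q25`, `median`, `q75`, `q90`;
#'   empty masks yield an `n = 0` row with `NA` summaries.
#' @export
exposure_summary <- function(disturbance, suitable_masks) {
  do.call(rbind, lapply(names(suitable_masks), function(gname) {
    msk <- suitable_masks[[gname]]
    if (!grid_equal(msk$grid, disturbance$grid))
      stop_grid_mismatch("masks and disturbance raster")
    x <- disturbance$values[is.finite(msk$values) & msk$values == 1]
    x <- x[is.finite(x)]
    if (length(x) == 0)
      return(data.frame(group = gname, n = 0, q10 = NA_real_, q25 = NA_real_,
                        median = NA_real_, q75 = NA_real_, q90 = NA_real_))
    qs <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7,
                          names = FALSE)
    data.frame(group = gname, n = length(x), q10 = qs[1], q25 = qs[2],
               median = qs[3], q75 = qs[4], q90 = qs[5])
  }))
}
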