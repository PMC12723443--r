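# Protected-area gap analysis: overlay of suitable habitat and reserve
# masks within biogeographic regions.

#' Coverage ratio as a percentage
#'
#' @param overlap_area Overlap area (>= 0).
#' @param denominator_area Denominator area (>= 0).
#' @return `100 * overlap / denominator`; `NA` when the denominator is 0.
#' @export
coverage_ratio <- function(overlap_area, denominator_area) {
  if (any(overlap_area < 0, na.rm = TRUE) ||
      any(denominator_area < 0, na.rm = TRUE))
    stop("areas must be nonnegative")
  ifelse(denominator_area > 0, 100 * overlap_area / denominator_area,
         NA_real_)
}

#' Regional overlay of suitable habitat and reserves
#'
#' Per region label: suitable, reserve and overlap areas (cell counts times
#' cell area, rescaled by `area_unit`) and both coverage percentages —
#' overlap/reserve (the reserve-referenced ratio) and overlap/suitable.
#'
#' @param suitable_mask,reserve_mask Binary [raster_layer()]s.
#' @param regions Integer-labelled [raster_layer()] partitioning the cells.
#' @param area_unit Divisor applied to areas (default `1e10`, i.e. map-unit
#'   m^2 reported in 10^4 km^2).
#' @return A `gap_report` data.frame: `region`, cell counts, areas,
#'   `coverage_pct_reserve`, `coverage_pct_suitable` (`NA` on zero
#'   denominators).
#' @export
regional_overlay <- function(suitable_mask, reserve_mask, regions,
                             area_unit = 1e10) {
  g <- regions$grid
  if (!grid_equal(suitable_mask$grid, g) || !grid_equal(reserve_mask$grid, g))
    stop_grid_mismatch("overlay rasters")
  cell_area <- g$cellsize^2
  lab <- as.vector(regions$values)
  suit <- is.finite(as.vector(suitable_mask$values)) &
    as.vector(suitable_mask$values) == 1
  res <- is.finite(as.vector(reserve_mask$values)) &
    as.vector(reserve_mask$values) == 1
  keep <- is.finite(lab)
  labs <- sort(unique(lab[keep]))
  out <- do.call(rbind, lapply(labs, function(L) {
    in_r <- keep & lab == L
    ns <- sum(in_r & suit); nr <- sum(in_r & res); no <- sum(in_r & suit & res)
    data.frame(region = L, n_suitable = ns, n_reserve = nr, n_overlap = no,
               suitable_area = ns * cell_area / area_unit,
               reserve_area = nr * cell_area / area_unit,
               overlap_area = no * cell_area / area_unit)
  }))
  out$coverage_pct_reserve <- coverage_ratio(out$overlap_area,
                                             out$reserve_area)
  out$coverage_pct_suitable <- coverage_ratio(out$overlap_area,
                                              out$suitable_area)
  class(out) <- c("gap_report", class(out))
  out
}
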