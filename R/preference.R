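# Use-availability land-use preference (relative preference index) and
# terrain/vegetation distribution profiles over suitable habitat.

#' Relative preference index over land-cover classes
#'
#' For an ecological group and each land class `l`, `U` is the area of
#' distinct suitable cells of class `l` occupied by at least one record of
#' the group, `S` the area of all suitable cells of class `l`, and
#' `RF = U / S x 10^4`. The index is computed within the predicted suitable
#' extent by default; `within_suitable_only = FALSE` counts occupied cells
#' of a class whether or not they are suitable (U may then exceed S).
#'
#' @param occ Occurrence data.frame for the group (snapped if needed).
#' @param suitable_mask Binary [raster_layer()] of the group's suitable
#'   habitat.
#' @param landcover Categorical [raster_layer()].
#' @param classes Optional named vector mapping class code -> label; default
#'   codes 1-6 as cropland, forest, grassland, water, barren, impervious.
#' @param within_suitable_only Restrict U to suitable cells (default TRUE).
#' @return Data.frame per class: `class`, `label`, `U_area`, `S_area`, `RF`
#'   (`NA` where `S = 0`), areas in squared map units.
#' @export
rf_index <- function(occ, suitable_mask, landcover, classes = NULL,
                     within_suitable_only = TRUE) {
  g <- landcover$grid
  if (!grid_equal(suitable_mask$grid, g)) stop_grid_mismatch("mask/landcover")
  if (is.null(classes))
    classes <- c(`1` = "cropland", `2` = "forest", `3` = "grassland",
                 `4` = "water", `5` = "barren", `6` = "impervious")
  if (is.null(occ$cell)) occ <- snap_occurrences(occ, g)
  cell_area <- g$cellsize^2
  lc <- as.vector(landcover$values)
  suit <- as.vector(suitable_mask$values) == 1 & is.finite(lc)
  occ_cells <- unique(occ$cell)
  occupied <- rep(FALSE, length(lc))
  occupied[occ_cells] <- TRUE
  use <- occupied & is.finite(lc) & (if (within_suitable_only) suit else TRUE)
  codes <- as.numeric(names(classes))
  out <- do.call(rbind, lapply(seq_along(codes), function(i) {
    in_class <- is.finite(lc) & lc == codes[i]
    S <- sum(suit & in_class) * cell_area
    U <- sum(use & in_class) * cell_area
    data.frame(class = codes[i], label = unname(classes[i]),
               U_area = U, S_area = S,
               RF = if (S > 0) U / S * 1e4 else NA_real_)
  }))
  out
}

#' Terrain and vegetation profiles over suitable cells
#'
#' Per group x variable: median, quartiles (linear-interpolation, type 7)
#' and whiskers at 1.5 x IQR capped at the data range, over the group's
#' suitable cells. Aspect is summarized only over cells with defined aspect.
#'
#' @param suitable_masks Named list of binary [raster_layer()]s per group.
#' @param terrain_stack Stack providing the profile layers.
#' @param variables Layer names to profile (default
#'   `c("dem", "slo", "asp", "ndvi")` intersected with the stack).
#' @return Tidy data.frame: `group`, `variable`, `n`, `q1`, `median`, `q3`,
#'   `lo_whisker`, `hi_whisker`; empty masks yield an `n = 0` row flagged by
#'   `NA` summaries.
#' @export
terrain_profiles <- function(suitable_masks, terrain_stack,
                             variables = NULL) {
  if (is.null(variables))
    variables <- intersect(c("dem", "slo", "asp", "ndvi"),
                           names(terrain_stack))
  do.call(rbind, lapply(names(suitable_masks), function(gname) {
    msk <- suitable_masks[[gname]]
    if (!grid_equal(msk$grid, terrain_stack$grid))
      stop_grid_mismatch("masks and terrain stack")
    cells <- which(is.finite(msk$values) & msk$values == 1)
    do.call(rbind, lapply(variables, function(v) {
      x <- terrain_stack[[v]]$values[cells]
      x <- x[is.finite(x)]
      if (length(x) == 0)
        return(data.frame(group = gname, variable = v, n = 0,
                          q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                          lo_whisker = NA_real_, hi_whisker = NA_real_))
      qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- qs[3] - qs[1]
      data.frame(group = gname, variable = v, n = length(x),
                 q1 = qs[1], median = qs[2], q3 = qs[3],
                 lo_whisker = max(min(x), qs[1] - 1.5 * iqr),
                 hi_whisker = min(max(x), qs[3] + 1.5 * iqr))
    }))
  }))
}
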