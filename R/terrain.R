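#' Slope and aspect from a DEM (Horn's method)
#'
#' Horn's 3x3 finite-difference gradient. Slope is `atan(|grad z|)` in
#' degrees. Aspect is the compass direction of steepest descent (0 = north,
#' 90 = east, clockwise); flat cells (zero gradient) have undefined aspect
#' and are returned as `NA`.
#'
#' @param dem Continuous [raster_layer()] of elevations, at least 3x3.
#' @param edge `"na"`: cells without a complete finite 3x3 neighbourhood are
#'   `NA`; `"replicate"`: the DEM border is replicated outward so edge cells
#'   get values (used by the synthetic generator to keep all cells finite).
#' @return A list with [raster_layer()] elements `slope` (degrees) and
#'   `aspect` (degrees).
#' @export
slope_aspect <- function(dem, edge = c("na", "replicate")) {
  edge <- match.arg(edge)
  g <- dem$grid
  if (g$nrows < 3 || g$ncols < 3) stop("DEM must be at least 3x3")
  z <- dem$values
  nr <- g$nrows; nc <- g$ncols
  # pad by one cell
  zp <- matrix(NA_real_, nr + 2, nc + 2)
  zp[2:(nr + 1), 2:(nc + 1)] <- z
  if (edge == "replicate") {
    zp[1, 2:(nc + 1)] <- z[1, ]; zp[nr + 2, 2:(nc + 1)] <- z[nr, ]
    zp[2:(nr + 1), 1] <- z[, 1]; zp[2:(nr + 1), nc + 2] <- z[, nc]
    zp[1, 1] <- z[1, 1]; zp[1, nc + 2] <- z[1, nc]
    zp[nr + 2, 1] <- z[nr, 1]; zp[nr + 2, nc + 2] <- z[nr, nc]
  }
  sh <- function(dr, dc) zp[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  # row - 1 is north; col + 1 is east
  nw <- sh(-1, -1); n_ <- sh(-1, 0); ne <- sh(-1, 1)
  w_ <- sh(0, -1);                   e_ <- sh(0, 1)
  sw <- sh(1, -1);  s_ <- sh(1, 0);  se <- sh(1, 1)
  cs <- g$cellsize
  gx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * cs)  # dz/dx (east)
  gy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * cs)  # dz/dy (north)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  # steepest descent direction; compass angle from north, clockwise
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  flat <- is.finite(gx) & is.finite(gy) & gx == 0 & gy == 0
  aspect[flat] <- NA_real_
  bad <- !is.finite(gx) | !is.finite(gy)
  slope[bad] <- NA_real_
  aspect[bad] <- NA_real_
  list(slope = raster_layer(slope, g, name = "slo"),
       aspect = raster_layer(aspect, g, name = "asp"))
}
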