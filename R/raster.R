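#' Define an analysis grid
#'
#' A grid describes a north-up, row-major raster lattice in a single planar
#' coordinate reference system (all inputs are assumed pre-projected; the
#' pipeline performs no reprojection). Cell (row 1, col 1) is the northwest
#' cell and cell extents are half-open `[x, x + cellsize)`.
#'
#' @param nrows,ncols Grid dimensions (>= 1).
#' @param cellsize Cell edge length in map units (> 0).
#' @param xmin,ymin Coordinates of the lower-left corner of the grid.
#' @param nodata Sentinel value used when serializing missing cells.
#' @return An object of class `hs_grid`.
#' @export
make_grid <- function(nrows, ncols, cellsize, xmin = 0, ymin = 0,
                      nodata = -9999) {
  stopifnot(nrows >= 1, ncols >= 1, cellsize > 0,
            is.finite(xmin), is.finite(ymin))
  structure(list(nrows = as.integer(nrows), ncols = as.integer(ncols),
                 cellsize = as.numeric(cellsize),
                 xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                 nodata = as.numeric(nodata)),
            class = "hs_grid")
}

#' @export
print.hs_grid <- function(x, ...) {
  cat(sprintf("<hs_grid> %d x %d cells, cellsize %g, origin (%g, %g)\n",
              x$nrows, x$ncols, x$cellsize, x$xmin, x$ymin))
  invisible(x)
}

grid_equal <- function(a, b, tol = 1e-9) {
  a$nrows == b$nrows && a$ncols == b$ncols &&
    abs(a$cellsize - b$cellsize) <= tol * max(1, abs(a$cellsize)) &&
    abs(a$xmin - b$xmin) <= tol * max(1, a$cellsize) &&
    abs(a$ymin - b$ymin) <= tol * max(1, a$cellsize)
}

stop_grid_mismatch <- function(what) {
  stop("grid mismatch: ", what, " must share one grid", call. = FALSE)
}

#' Construct a raster layer
#'
#' Values are held as an `nrows x ncols` matrix with row 1 the northernmost
#' row; missing cells are `NA` internally and only become the grid's nodata
#' sentinel on serialization.
#'
#' @param values Numeric matrix (`nrows x ncols`) or vector of length
#'   `nrows * ncols` filled row-major from the north.
#' @param grid An [make_grid()] object.
#' @param name Layer name (e.g. `"bio12"`, `"dem"`, `"ndvi"`, `"lc"`).
#' @param kind `"continuous"` or `"categorical"`.
#' @return An object of class `hs_raster`.
#' @export
raster_layer <- function(values, grid, name = "layer",
                         kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!inherits(grid, "hs_grid")) stop("grid must be an hs_grid")
  if (is.matrix(values)) {
    if (nrow(values) != grid$nrows || ncol(values) != grid$ncols)
      stop("values shape does not match grid")
    v <- values
  } else {
    if (length(values) != grid$nrows * grid$ncols)
      stop("values length does not match grid")
    v <- matrix(values, nrow = grid$nrows, ncol = grid$ncols, byrow = TRUE)
  }
  storage.mode(v) <- "double"
  structure(list(values = v, grid = grid, name = name, kind = kind),
            class = "hs_raster")
}

#' @export
print.hs_raster <- function(x, ...) {
  fin <- sum(is.finite(x$values))
  cat(sprintf("<hs_raster> '%s' (%s), %d x %d, %d finite cells, range [%g, %g]\n",
              x$name, x$kind, x$grid$nrows, x$grid$ncols, fin,
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Bundle aligned layers into a stack
#'
#' @param layers List of [raster_layer()] objects on one common grid.
#' @return An object of class `hs_stack`; layers are retrievable by name
#'   with `[[`.
#' @export
raster_stack <- function(layers) {
  if (length(layers) == 0) stop("empty stack")
  if (inherits(layers, "hs_raster")) layers <- list(layers)
  g <- layers[[1]]$grid
  for (l in layers) {
    if (!inherits(l, "hs_raster")) stop("all elements must be hs_raster")
    if (!grid_equal(l$grid, g)) stop_grid_mismatch("stack layers")
  }
  names(layers) <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(names(layers))) stop("duplicate layer names in stack")
  structure(list(layers = layers, grid = g), class = "hs_stack")
}

#' @export
`[[.hs_stack` <- function(x, i) x$layers[[i]]

#' @export
names.hs_stack <- function(x) names(x$layers)

#' @export
length.hs_stack <- function(x) length(x$layers)

#' @export
print.hs_stack <- function(x, ...) {
  cat(sprintf("<hs_stack> %d layers on %d x %d grid: %s\n",
              length(x$layers), x$grid$nrows, x$grid$ncols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

# ---- coordinate arithmetic ------------------------------------------------

# Map coordinates -> (row, col); NA outside the grid. Half-open cells.
xy_to_rowcol <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$cellsize) + 1
  row <- grid$nrows - floor((y - grid$ymin) / grid$cellsize)
  bad <- !is.finite(x) | !is.finite(y) |
    col < 1 | col > grid$ncols | row < 1 | row > grid$nrows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

# (row, col) -> linear index into the value matrix (column-major, as R).
rowcol_to_cell <- function(grid, row, col) (as.integer(col) - 1L) * grid$nrows + as.integer(row)

cell_to_rowcol <- function(grid, cell) {
  cell <- as.integer(cell)
  col <- (cell - 1L) %/% grid$nrows + 1L
  row <- cell - (col - 1L) * grid$nrows
  list(row = row, col = col)
}

#' Cell-center coordinates for linear cell indices
#' @param grid An [make_grid()] grid.
#' @param cell Integer linear cell indices.
#' @return A data.frame with columns `x`, `y`.
#' @export
cell_center <- function(grid, cell) {
  rc <- cell_to_rowcol(grid, cell)
  data.frame(x = grid$xmin + (rc$col - 0.5) * grid$cellsize,
             y = grid$ymin + (grid$nrows - rc$row + 0.5) * grid$cellsize)
}

#' Linear cell indices of map coordinates
#' @inheritParams cell_center
#' @param x,y Map coordinates.
#' @return Integer cell indices; `NA` for points outside the grid.
#' @export
cell_from_xy <- function(grid, x, y) {
  rc <- xy_to_rowcol(grid, x, y)
  out <- rowcol_to_cell(grid, rc$row, rc$col)
  out[is.na(rc$row)] <- NA_integer_
  out
}

#' Extract stack values at cells
#'
#' @param stack An [raster_stack()].
#' @param cells Integer linear cell indices.
#' @return Numeric matrix, one row per cell, one named column per layer.
#' @export
stack_values_at <- function(stack, cells) {
  out <- vapply(stack$layers, function(l) l$values[cells],
                numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1,
                                         dimnames = list(NULL, names(stack$layers)))
  out
}

#' Cells with finite values in every layer
#' @param stack An [raster_stack()].
#' @return Integer vector of linear cell indices.
#' @export
finite_cells <- function(stack) {
  ok <- rep(TRUE, stack$grid$nrows * stack$grid$ncols)
  for (l in stack$layers) ok <- ok & is.finite(l$values)
  which(ok)
}
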