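#' Read an ESRI ASCII grid
#'
#' Parses the standard six-key header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`; the last is optional) followed by
#' `nrows` rows of `ncols` values ordered north to south. Cells equal to the
#' declared nodata sentinel become `NA`.
#'
#' @param path Path to an `.asc` file.
#' @param name Layer name; defaults to the file name without extension.
#' @param kind `"continuous"` or `"categorical"`.
#' @return An [raster_layer()].
#' @export
read_raster <- function(path, name = NULL,
                        kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-+0-9.eE]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!is.null(hdr[[key]]))
      stop("parse error at line ", i, ": duplicate header key '", key, "'")
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) stop("parse error at line ", i, ": non-numeric header value")
    hdr[[key]] <- val
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("parse error: missing header key(s): ", paste(miss, collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- lines[i:length(lines)]
  if (length(body) != nr)
    stop("parse error: expected ", nr, " data rows, found ", length(body))
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(row) != nc)
      stop("parse error at data line ", i + r - 1L, ": expected ", nc,
           " values, found ", length(row))
    if (anyNA(row))
      stop("parse error at data line ", i + r - 1L, ": non-numeric cell")
    vals[r, ] <- row
  }
  vals[vals == nodata] <- NA_real_
  g <- make_grid(nr, nc, hdr$cellsize, hdr$xllcorner, hdr$yllcorner, nodata)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raster_layer(vals, g, name = name, kind = kind)
}

#' Write an ESRI ASCII grid
#'
#' Emits the header keys in the canonical order (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) then data rows north
#' to south; `NA` cells are serialized as the grid's nodata sentinel.
#'
#' @param layer An [raster_layer()].
#' @param path Output path.
#' @param digits Significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, digits = 10) {
  g <- layer$grid
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(c(
    paste("ncols", g$ncols),
    paste("nrows", g$nrows),
    paste("xllcorner", format(g$xmin, digits = 15)),
    paste("yllcorner", format(g$ymin, digits = 15)),
    paste("cellsize", format(g$cellsize, digits = 15)),
    paste("NODATA_value", format(g$nodata, digits = 15))), con)
  v <- layer$values
  v[!is.finite(v)] <- g$nodata
  for (r in seq_len(g$nrows))
    writeLines(paste(formatC(v[r, ], digits = digits, format = "g"),
                     collapse = " "), con)
  invisible(path)
}

#' Nearest-neighbour resampling onto a target grid
#'
#' Each target cell takes the value of the source cell containing the target
#' cell's center; target centers outside the source extent (and centers over
#' source nodata) become `NA`.
#'
#' @param layer Source [raster_layer()].
#' @param target Target [make_grid()] grid in the same units/CRS.
#' @return An [raster_layer()] on `target`.
#' @export
resample_nearest <- function(layer, target) {
  src <- layer$grid
  # quick disjointness check on extents
  if (target$xmin >= src$xmin + src$ncols * src$cellsize ||
      src$xmin >= target$xmin + target$ncols * target$cellsize ||
      target$ymin >= src$ymin + src$nrows * src$cellsize ||
      src$ymin >= target$ymin + target$nrows * target$cellsize)
    stop("source and target extents are disjoint")
  ctr <- cell_center(target, seq_len(target$nrows * target$ncols))
  rc <- xy_to_rowcol(src, ctr$x, ctr$y)
  out <- rep(NA_real_, target$nrows * target$ncols)
  ok <- !is.na(rc$row)
  out[ok] <- layer$values[cbind(rc$row[ok], rc$col[ok])]
  m <- matrix(NA_real_, target$nrows, target$ncols)
  m[seq_along(out)] <- out   # linear indices are column-major on the target
  raster_layer(m, target, name = layer$name, kind = layer$kind)
}

#' Read presence-only occurrence records
#'
#' @param path CSV with columns `species,group,x,y` (`group` optional).
#' @return A data.frame with columns `species`, `group`, `x`, `y`.
#' @export
read_occurrences <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "x", "y") %in% names(d)))
    stop("occurrence CSV must have columns species, x, y")
  if (is.null(d$group)) d$group <- NA_character_
  d[, c("species", "group", "x", "y")]
}

#' Write occurrence records
#' @param occ Occurrence data.frame (`species,group,x,y`).
#' @param path Output CSV path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ[, c("species", "group", "x", "y")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Grid de-duplication of occurrence records
#'
#' Retains a single record per species per de-duplication cell (the first in
#' input order), thinning densely reported localities before analysis.
#' Records with non-finite coordinates are rejected with a warning.
#'
#' @param occ Occurrence data.frame (`species,group,x,y`).
#' @param dedup_cellsize Edge length of the de-duplication cell in map units
#'   (default 1000, i.e. one record per species per km^2 for metre grids).
#' @param origin Lower-left corner anchoring the de-duplication lattice.
#' @return The thinned occurrence data.frame.
#' @export
dedup_grid <- function(occ, dedup_cellsize = 1000, origin = c(0, 0)) {
  stopifnot(dedup_cellsize > 0)
  bad <- !is.finite(occ$x) | !is.finite(occ$y)
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-finite coordinates rejected")
    occ <- occ[!bad, , drop = FALSE]
  }
  cx <- floor((occ$x - origin[1]) / dedup_cellsize)
  cy <- floor((occ$y - origin[2]) / dedup_cellsize)
  key <- paste(occ$species, cx, cy, sep = "\r")
  occ[!duplicated(key), , drop = FALSE]
}

#' Snap occurrences to grid cells
#'
#' @param occ Occurrence data.frame.
#' @param grid Analysis grid.
#' @param drop_outside Drop records outside the grid (default TRUE).
#' @return `occ` with an added integer `cell` column.
#' @export
snap_occurrences <- function(occ, grid, drop_outside = TRUE) {
  cell <- cell_from_xy(grid, occ$x, occ$y)
  occ$cell <- cell
  if (drop_outside) occ <- occ[!is.na(occ$cell), , drop = FALSE]
  occ
}

# ---- GeoJSON polygons -----------------------------------------------------

# Even-odd ray-casting point-in-polygon for one ring (matrix n x 2).
.ring_contains <- function(ring, px, py) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & is.finite(cross))
    j <- i
  }
  inside
}

.polygon_contains <- function(coords, px, py) {
  # coords: list of rings (first outer, rest holes); even-odd rule
  inside <- rep(FALSE, length(px))
  for (ring in coords) {
    m <- matrix(unlist(ring), ncol = 2, byrow = TRUE)
    inside <- xor(inside, .ring_contains(m, px, py))
  }
  inside
}

#' Rasterize GeoJSON polygons by cell-center containment
#'
#' Accepts a FeatureCollection (or single Feature/geometry) of Polygon or
#' MultiPolygon geometries in the grid's CRS. A cell belongs to a feature if
#' its center falls inside the polygon (even-odd rule, holes honoured).
#'
#' @param path Path to a GeoJSON file.
#' @param grid Target grid.
#' @param label_property Optional property name supplying integer labels;
#'   by default features are labelled 1, 2, ... in file order.
#' @param name Output layer name.
#' @return A categorical [raster_layer()]: feature label where covered, 0
#'   elsewhere (later features overwrite earlier ones where they overlap).
#' @export
rasterize_geojson <- function(path, grid, label_property = NULL,
                              name = "polygons") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- switch(gj$type %||% "",
                  FeatureCollection = gj$features,
                  Feature = list(gj),
                  list(list(geometry = gj)))
  ctr <- cell_center(grid, seq_len(grid$nrows * grid$ncols))
  lab <- rep(0, grid$nrows * grid$ncols)
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    geom <- f$geometry
    value <- if (!is.null(label_property) && !is.null(f$properties[[label_property]]))
      as.numeric(f$properties[[label_property]]) else k
    polys <- switch(geom$type,
                    Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates,
                    stop("unsupported geometry type: ", geom$type))
    for (p in polys) {
      inside <- .polygon_contains(p, ctr$x, ctr$y)
      lab[inside] <- value
    }
  }
  m <- matrix(0, grid$nrows, grid$ncols)
  m[seq_along(lab)] <- lab
  raster_layer(m, grid, name = name, kind = "categorical")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
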