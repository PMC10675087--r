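#' Georeferenced elevation / raster grid
#'
#' The geometric substrate of the lake twin: a regular square-celled raster in
#' projected map coordinates (metres), row 1 at the northern edge and y
#' increasing northward. Used both for watershed elevation models (DEM) and for
#' any derived single-band field.
#'
#' @param values numeric matrix of cell values (elevation in metres above the
#'   datum for a DEM). `NA` marks nodata.
#' @param origin length-2 numeric, map coordinates (x, y) of the *upper-left
#'   corner* of cell \[1, 1\].
#' @param cell_size cell edge length in metres (> 0); cells are square and
#'   half-open, covering \[x, x + cell_size).
#' @param nodata sentinel written to/read from files for missing cells;
#'   in-memory missing cells are always `NA`.
#' @param crs_label free-text tag for the projected coordinate system.
#' @return an object of class `elevation_grid`.
#' @export
elevation_grid <- function(values, origin, cell_size, nodata = -9999,
                           crs_label = "") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("grid must be at least 2x2 cells")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("`origin` must be finite (x, y) of the upper-left corner")
  if (any(is.infinite(values)))
    stop("grid values must be finite or NA")
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size), nodata = nodata,
         crs_label = crs_label),
    class = "elevation_grid"
  )
}

#' @export
print.elevation_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<elevation_grid> %d x %d cells @ %g m", d[1], d[2], x$cell_size),
      sprintf("| origin (%g, %g)", x$origin[1], x$origin[2]),
      if (nzchar(x$crs_label)) paste("|", x$crs_label) else "", "\n")
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.elevation_grid <- function(x) dim(x$values)

#' Cell-centre coordinates of a grid
#'
#' @param grid an [elevation_grid()] (or any object with the same geometry
#'   fields).
#' @return `grid_x`: x coordinates of the column centres (west to east);
#'   `grid_y`: y coordinates of the row centres (north to south, i.e.
#'   decreasing).
#' @keywords internal
grid_x <- function(grid) grid$origin[1] + (seq_len(ncol(grid$values)) - 0.5) * grid$cell_size

#' @rdname grid_x
#' @keywords internal
grid_y <- function(grid) grid$origin[2] - (seq_len(nrow(grid$values)) - 0.5) * grid$cell_size

#' Map coordinates -> (row, col) of the containing cell
#'
#' Cells are half-open `[x, x + cell_size)` eastward and `(y - cell_size, y]`
#' southward from the upper-left origin. Returns NA for points outside.
#' @keywords internal
xy_to_rowcol <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1L
  row <- floor((grid$origin[2] - y) / grid$cell_size) + 1L
  bad <- row < 1L | row > nrow(grid$values) | col < 1L | col > ncol(grid$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) <= tol &&
    all(abs(a$origin - b$origin) <= tol)
}

#' Read / write Esri ASCII grids
#'
#' Plain-text single-band raster exchange format (`ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value` header followed by row-major values,
#' northernmost row first). This is the package's on-disk grid format; a
#' sidecar is not needed because the header carries the full geometry.
#'
#' @param path file path (conventionally `.asc`).
#' @param grid an [elevation_grid()].
#' @param digits significant digits written (default 10).
#' @return `read_asc` returns an [elevation_grid()]; `write_asc` returns
#'   `path` invisibly.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- stats::setNames(
    vapply(kv, function(p) as.numeric(p[2]), 0),
    tolower(vapply(kv, `[`, "", 1))
  )
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an Esri ASCII grid (missing header keys): ", path)
  nodata <- if ("nodata_value" %in% names(hdr)) hdr[["nodata_value"]] else -9999
  vals <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(vals, nrow = hdr[["nrows"]], ncol = hdr[["ncols"]], byrow = TRUE)
  m[m == nodata] <- NA_real_
  elevation_grid(
    m,
    origin = c(hdr[["xllcorner"]],
               hdr[["yllcorner"]] + hdr[["nrows"]] * hdr[["cellsize"]]),
    cell_size = hdr[["cellsize"]], nodata = nodata
  )
}

#' @rdname read_asc
#' @export
write_asc <- function(grid, path, digits = 10) {
  stopifnot(inherits(grid, "elevation_grid"))
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2] - nrow(m) * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  rows <- apply(m, 1L, function(r) paste(formatC(r, digits = digits, format = "g"),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
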