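#' Planar raster grid
#'
#' A minimal in-memory raster: a matrix of values on a square-cell grid in
#' projected Cartesian metres.  Row 1 of `values` is the *southernmost* row
#' (row index increases northward); the centre of cell `(r, c)` is at
#' `(x_origin + (c - 0.5) * cell_size, y_origin + (r - 0.5) * cell_size)`.
#'
#' @param values numeric matrix (rows south to north).
#' @param x_origin,y_origin coordinates of the lower-left corner, m.
#' @param cell_size cell edge length, m (> 0).
#' @param nodata sentinel value; cells equal to it are stored as `NA`.
#' @return object of class `raster_grid` with fields `values`, `x_origin`,
#'   `y_origin`, `cell_size`, `n_rows`, `n_cols`, `nodata`.
#' @export
raster_grid <- function(values, x_origin = 0, y_origin = 0, cell_size = 1,
                        nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (nrow(values) < 1 || ncol(values) < 1) stop("grid must be at least 1x1")
  values[!is.na(values) & values == nodata] <- NA_real_
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite values in raster (only the nodata sentinel may be missing)")
  structure(
    list(values = values, x_origin = x_origin, y_origin = y_origin,
         cell_size = cell_size, n_rows = nrow(values), n_cols = ncol(values),
         nodata = nodata),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells of %g m, origin (%g, %g), %d nodata\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_origin, x$y_origin,
              sum(is.na(x$values))))
  invisible(x)
}

#' Cell-centre coordinates
#'
#' @param grid a [raster_grid()].
#' @param rows,cols integer vectors of equal length (1-based, row 1 = south).
#' @return two-column matrix of (x, y) centres.
#' @export
cell_centers <- function(grid, rows, cols) {
  cbind(x = grid$x_origin + (cols - 0.5) * grid$cell_size,
        y = grid$y_origin + (rows - 0.5) * grid$cell_size)
}

#' Extent of a raster
#' @param grid a [raster_grid()].
#' @return named vector `xmin, xmax, ymin, ymax`.
#' @export
raster_extent <- function(grid) {
  c(xmin = grid$x_origin,
    xmax = grid$x_origin + grid$n_cols * grid$cell_size,
    ymin = grid$y_origin,
    ymax = grid$y_origin + grid$n_rows * grid$cell_size)
}

#' Bilinear surface interpolation
#'
#' Interpolates the gridded surface at arbitrary points from the four
#' surrounding cell-centre values; fractional positions are clamped to the
#' centre lattice at the grid margin.  Returns `NA` where any contributing
#' corner is nodata.
#'
#' @param grid a [raster_grid()].
#' @param x,y numeric vectors of coordinates, m.
#' @return numeric vector of surface values.
#' @export
surface_at <- function(grid, x, y) {
  fr <- (y - grid$y_origin) / grid$cell_size - 0.5
  fc <- (x - grid$x_origin) / grid$cell_size - 0.5
  fr <- pmin(pmax(fr, 0), grid$n_rows - 1)
  fc <- pmin(pmax(fc, 0), grid$n_cols - 1)
  r0 <- pmin(floor(fr), grid$n_rows - 2); r0 <- pmax(r0, 0)
  c0 <- pmin(floor(fc), grid$n_cols - 2); c0 <- pmax(c0, 0)
  if (grid$n_rows == 1) r0 <- rep(0, length(fr))
  if (grid$n_cols == 1) c0 <- rep(0, length(fc))
  wr <- fr - r0
  wc <- fc - c0
  v <- grid$values
  nr <- grid$n_rows
  r1 <- pmin(r0 + 1, nr - 1)
  c1 <- pmin(c0 + 1, grid$n_cols - 1)
  i00 <- c0 * nr + r0 + 1          # linear (column-major) indices
  i01 <- c1 * nr + r0 + 1
  i10 <- c0 * nr + r1 + 1
  i11 <- c1 * nr + r1 + 1
  (1 - wr) * ((1 - wc) * v[i00] + wc * v[i01]) +
    wr * ((1 - wc) * v[i10] + wc * v[i11])
}

#' Read a raster file
#'
#' Reads an ESRI ASCII grid (`ncols/nrows/xllcorner/yllcorner/cellsize`
#' header, optional `NODATA_value`, rows stored north-to-south).
#'
#' @param path file path.
#' @param dialect raster format; only `"esri_ascii"` is implemented.
#' @return a [raster_grid()]; nodata cells are `NA`.
#' @export
read_raster <- function(path, dialect = "esri_ascii") {
  dialect <- match.arg(dialect, c("esri_ascii", "geotiff"))
  if (dialect == "geotiff")
    stop("geotiff dialect is not implemented; use esri_ascii")
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- list()
  body_start <- 1L
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value")) {
      if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2]))))
        stop(sprintf("malformed header line for key '%s' in %s", key, path))
      hdr[[key]] <- as.numeric(parts[2])
      body_start <- i + 1L
    } else break
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[key]]))
      stop(sprintf("missing required header key '%s' in %s", key, path))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- lines[body_start:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr)
    stop(sprintf("expected %d data rows, found %d in %s", nr, length(body), path))
  rows <- vector("list", nr)
  for (i in seq_len(nr)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body[[i]]), "\\s+")[[1]]))
    if (length(vals) != nc)
      stop(sprintf("row %d has %d values, expected %d in %s",
                   i, length(vals), nc, path))
    if (anyNA(vals))
      stop(sprintf("row %d contains non-numeric values in %s", i, path))
    rows[[i]] <- vals
  }
  m <- do.call(rbind, rows)
  m <- m[nr:1, , drop = FALSE]              # file is north-first; store south-first
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  raster_grid(m, x_origin = hdr$xllcorner, y_origin = hdr$yllcorner,
              cell_size = hdr$cellsize, nodata = nodata)
}

#' Write a raster file
#'
#' Writes an ESRI ASCII grid; [read_raster()] of the result reproduces the
#' grid exactly, and write-read-write round-trips byte-identically.
#'
#' @param grid a [raster_grid()].
#' @param path output path.
#' @param dialect only `"esri_ascii"`.
#' @export
write_raster <- function(grid, path, dialect = "esri_ascii") {
  dialect <- match.arg(dialect, c("esri_ascii", "geotiff"))
  if (dialect == "geotiff")
    stop("geotiff dialect is not implemented; use esri_ascii")
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  fmt <- function(x) {
    out <- format(x, trim = TRUE, scientific = FALSE, digits = 15)
    out
  }
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %s", fmt(grid$x_origin)),
           sprintf("yllcorner %s", fmt(grid$y_origin)),
           sprintf("cellsize %s", fmt(grid$cell_size)),
           sprintf("NODATA_value %s", fmt(grid$nodata)))
  body <- apply(v[grid$n_rows:1, , drop = FALSE], 1,
                function(row) paste(fmt(row), collapse = " "))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(NULL)
}
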