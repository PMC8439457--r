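#' Single-band raster grid
#'
#' A minimal in-memory raster used for elevation, land-cover, population,
#' mismanaged-plastic-waste and mask grids.  Values are stored as a numeric
#' matrix whose first row is the *northernmost* row (the ESRI ASCII grid
#' convention); the georeference is the lower-left corner of the grid and a
#' square cell size in metres.
#'
#' @param values numeric matrix (row 1 = top/north row).
#' @param cell_size_m positive cell edge length in metres.
#' @param origin numeric length-2, (x, y) of the lower-left corner.
#' @param nodata sentinel value marking missing cells (default -9999).
#' @return an object of class `mp_raster`.
#' @export
mp_raster <- function(values, cell_size_m = 25, origin = c(0, 0),
                      nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cell_size_m), length(cell_size_m) == 1,
            cell_size_m > 0, length(origin) == 2)
  if (any(values == nodata & !is.na(values)))
    values[values == nodata] <- NA_real_
  structure(list(values = values, cell_size_m = cell_size_m,
                 origin = as.numeric(origin), nodata = nodata),
            class = "mp_raster")
}

#' @export
print.mp_raster <- function(x, ...) {
  cat(sprintf("<mp_raster> %d x %d cells, %.6g m resolution, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size_m,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
dim.mp_raster <- function(x) dim(x$values)

raster_check_aligned <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      !isTRUE(all.equal(a$cell_size_m, b$cell_size_m)) ||
      !isTRUE(all.equal(a$origin, b$origin)))
    stop("rasters are not aligned (dimensions, cell size and origin must match)")
  invisible(TRUE)
}

#' Locate the grid cell containing a point
#'
#' Cells are half-open intervals `[x, x + cellsize)` in both axes; a point on
#' the lower/left boundary of a cell belongs to that cell.
#'
#' @param raster an [mp_raster].
#' @param x,y point coordinates in the raster's system.
#' @return integer vector `c(row, col)` or `NA` if outside the grid.
#' @export
raster_cell_at <- function(raster, x, y) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  cs <- raster$cell_size_m
  col <- floor((x - raster$origin[1]) / cs) + 1L
  row <- nr - floor((y - raster$origin[2]) / cs)
  if (is.na(col) || is.na(row) || col < 1L || col > nc || row < 1L || row > nr)
    return(c(NA_integer_, NA_integer_))
  c(as.integer(row), as.integer(col))
}

#' Read an ESRI ASCII grid
#'
#' @param path file path to a `.asc` grid.
#' @return an [mp_raster].
#' @export
read_asc <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows) || is.null(hdr$cellsize))
    stop("not an ESRI ASCII grid: ", path)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  mp_raster(m, cell_size_m = hdr$cellsize,
            origin = c(hdr$xllcorner %||% 0, hdr$yllcorner %||% 0),
            nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param raster an [mp_raster].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_asc <- function(raster, path) {
  v <- raster$values
  v[is.na(v)] <- raster$nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", raster$origin[1]),
           sprintf("yllcorner %.10g", raster$origin[2]),
           sprintf("cellsize %.10g", raster$cell_size_m),
           sprintf("NODATA_value %.10g", raster$nodata))
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE, digits = 15),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
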