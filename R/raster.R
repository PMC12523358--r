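# Gridded grazing-intensity surfaces (yak-hours per square metre) and their
# text serialization (ESRI ASCII grid + JSON metadata sidecar).

#' Construct a grazing-intensity raster
#'
#' A regular grid of intensity values in yak-hours per square metre. Rows
#' index y from south to north, columns x from west to east; `origin` is the
#' south-west corner of the grid (cell edges, not centres).
#'
#' @param values numeric matrix (`n_rows` x `n_cols`) of non-negative cell
#'   values; row 1 is the southernmost row.
#' @param origin numeric length-2 SW corner of the grid (m).
#' @param cell_size_m cell edge length (m), `> 0`.
#' @param period character period label, e.g. `"May"` or `"May-Jul"`.
#' @param meta optional named list of metadata (bandwidth, adjustment factor,
#'   ...).
#' @return An object of class `intensity_raster`.
#' @export
intensity_raster <- function(values, origin, cell_size_m = 1,
                             period = "unlabelled", meta = list()) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), length(origin) == 2)
  if (!is.finite(cell_size_m) || cell_size_m <= 0) stop("cell_size_m must be > 0")
  if (any(values < 0, na.rm = TRUE)) stop("intensity values must be >= 0")
  if (!is.character(period) || length(period) != 1L || is.na(period) ||
      !nzchar(period)) {
    stop("period label must be a non-empty string")
  }
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size_m = cell_size_m, n_rows = nrow(values),
         n_cols = ncol(values), period = period, meta = meta),
    class = "intensity_raster"
  )
}

#' Grid specification covering a pasture
#'
#' @param pasture a [pasture_geometry()].
#' @param cell_size_m cell edge length (m).
#' @return A list with `origin`, `cell_size_m`, `n_rows`, `n_cols` spanning
#'   the pasture bounding box.
#' @export
grid_from_pasture <- function(pasture, cell_size_m = 1) {
  stopifnot(inherits(pasture, "pasture_geometry"))
  xr <- range(pasture$boundary[, 1]); yr <- range(pasture$boundary[, 2])
  list(origin = c(xr[1], yr[1]), cell_size_m = cell_size_m,
       n_rows = ceiling((yr[2] - yr[1]) / cell_size_m),
       n_cols = ceiling((xr[2] - xr[1]) / cell_size_m))
}

#' @export
print.intensity_raster <- function(x, ...) {
  cat(sprintf("<intensity_raster> %d x %d cells @ %g m, period %s\n",
              x$n_rows, x$n_cols, x$cell_size_m, x$period))
  cat(sprintf("  total mass %.4g yak-hours, max %.4g yak-h/m2\n",
              raster_total(x), max(x$values)))
  invisible(x)
}

#' Integrated raster mass
#'
#' Sum of cell values times cell area: the total occupancy in yak-hours
#' represented by the surface.
#'
#' @param raster an [intensity_raster()].
#' @return Total mass (yak-hours).
#' @export
raster_total <- function(raster) {
  stopifnot(inherits(raster, "intensity_raster"))
  sum(raster$values) * raster$cell_size_m^2
}

# x (resp. y) coordinates of column (row) centres
raster_xcenters <- function(r) r$origin[1] + (seq_len(r$n_cols) - 0.5) * r$cell_size_m
raster_ycenters <- function(r) r$origin[2] + (seq_len(r$n_rows) - 0.5) * r$cell_size_m

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size_m - b$cell_size_m) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Writes the standard text grid format (readable by any GIS) with nodata
#' value -1, plus a JSON sidecar `<path>.json` carrying the period label and
#' any metadata (bandwidth, adjustment factor, cell size).
#'
#' @param raster an [intensity_raster()].
#' @param path output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "intensity_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", raster$n_cols),
    sprintf("nrows %d", raster$n_rows),
    sprintf("xllcorner %.10g", raster$origin[1]),
    sprintf("yllcorner %.10g", raster$origin[2]),
    sprintf("cellsize %.10g", raster$cell_size_m),
    "NODATA_value -1"
  ), con)
  # ASCII grids are written north to south
  for (r in rev(seq_len(raster$n_rows))) {
    writeLines(paste(format(raster$values[r, ], digits = 10, trim = TRUE,
                            scientific = TRUE), collapse = " "), con)
  }
  meta <- c(list(period = raster$period, cell_size_m = raster$cell_size_m),
            raster$meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#'
#' @param path path to the `.asc` file; the JSON sidecar is read if present.
#' @return An [intensity_raster()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(i) as.numeric(strsplit(trimws(hdr[i]), "\\s+")[[1]][2])
  ncols <- as.integer(val(1)); nrows <- as.integer(val(2))
  x0 <- val(3); y0 <- val(4); cell <- val(5)
  body <- lines[-(1:6)]
  rows <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  values <- do.call(rbind, rev(rows))
  period <- "unlabelled"; meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    m <- jsonlite::read_json(side, simplifyVector = TRUE)
    period <- m$period %||% period
    meta <- m[setdiff(names(m), c("period", "cell_size_m"))]
  }
  intensity_raster(values, c(x0, y0), cell, period = period, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
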