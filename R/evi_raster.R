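# Lightweight single-band geographic raster container and plain-text I/O.

#' Construct a single-band geographic raster
#'
#' A minimal container for a monthly greenness (EVI) layer: a value matrix
#' on a regular WGS84 lat/lon grid. Row 1 is the southernmost row and
#' column 1 the westernmost; `values[r, c]` covers the cell whose center is
#' `(ymin + (r - 0.5) * res, xmin + (c - 0.5) * res)`. Missing data are
#' `NA`.
#'
#' @param values Numeric matrix (rows south to north, columns west to east).
#' @param xmin,ymin Western/southern edge of the grid (degrees).
#' @param resolution Degrees per pixel (default 0.05).
#' @param month Optional month stamp (1--12).
#' @return An `evi_raster` object.
#' @export
evi_raster <- function(values, xmin, ymin, resolution = 0.05, month = NA_integer_) {
  stopifnot(is.matrix(values), resolution > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, res = resolution,
         xmax = xmin + ncol(values) * resolution,
         ymax = ymin + nrow(values) * resolution,
         month = as.integer(month)),
    class = "evi_raster"
  )
}

#' @export
print.evi_raster <- function(x, ...) {
  cat(sprintf("evi_raster: %d x %d pixels at %.4g deg, lon [%g, %g], lat [%g, %g]%s\n",
              nrow(x$values), ncol(x$values), x$res, x$xmin, x$xmax,
              x$ymin, x$ymax,
              if (is.na(x$month)) "" else sprintf(", month %d", x$month)))
  cat(sprintf("  values: mean %.4g, %d NA of %d\n",
              mean(x$values, na.rm = TRUE), sum(is.na(x$values)),
              length(x$values)))
  invisible(x)
}

# Center coordinates of every row / column.
raster_row_lats <- function(r) r$ymin + (seq_len(nrow(r$values)) - 0.5) * r$res
raster_col_lons <- function(r) r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$res

#' Look up raster values at point locations
#'
#' @param raster An [evi_raster()].
#' @param lat,lon Coordinate vectors (degrees).
#' @return Numeric vector of pixel values; `NA` outside the extent or at
#'   no-data pixels.
#' @export
evi_at <- function(raster, lat, lon) {
  r <- pmin(pmax(ceiling((lat - raster$ymin) / raster$res), 1L), nrow(raster$values))
  c <- pmin(pmax(ceiling((lon - raster$xmin) / raster$res), 1L), ncol(raster$values))
  out <- raster$values[cbind(r, c)]
  outside <- lat < raster$ymin | lat > raster$ymax |
    lon < raster$xmin | lon > raster$xmax
  out[outside | is.na(lat) | is.na(lon)] <- NA_real_
  out
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` dialect: a 6-line header then rows north to south.
#'
#' @param raster An [evi_raster()].
#' @param path Output path.
#' @param nodata No-data marker written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_evi_asc <- function(raster, path, nodata = -9999) {
  v <- raster$values
  v[is.na(v)] <- nodata
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(raster$xmin, digits = 15)),
    paste("yllcorner", format(raster$ymin, digits = 15)),
    paste("cellsize", format(raster$res, digits = 15)),
    paste("NODATA_value", nodata)
  ), con)
  # ASCII grids store the north row first; our matrix is south-first.
  for (r in rev(seq_len(nrow(v)))) {
    writeLines(paste(format(v[r, ], trim = TRUE, digits = 9), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path Path to a `.asc` file.
#' @param month Optional month stamp to attach.
#' @return An [evi_raster()].
#' @export
read_evi_asc <- function(path, month = NA_integer_) {
  if (!file.exists(path)) abort(paste0("raster file not found: ", path))
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  nrows <- as.integer(hdr$nrows)
  ncols <- as.integer(hdr$ncols)
  body <- lines[i:(i + nrows - 1)]
  vals <- vapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                 numeric(ncols), USE.NAMES = FALSE)
  # vapply gives columns-per-line; transpose, then flip to south-first rows.
  m <- t(vals)[rev(seq_len(nrows)), , drop = FALSE]
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  evi_raster(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
             resolution = hdr$cellsize, month = month)
}
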