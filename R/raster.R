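#' A single-band raster grid with a nodata mask
#'
#' Values are stored as a matrix whose first row is the top of the grid
#' (the ESRI ASCII grid convention).  The georeference is a lower-left
#' corner plus a square cell size in the same planar units as the region
#' geometry.
#'
#' @param values numeric matrix (row 1 = top row).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize square cell edge length.
#' @param variable,timepoint optional labels.
#' @param nodata logical matrix of masked cells; defaults to non-finite
#'   cells.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                        variable = "", timepoint = "", nodata = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(nodata)) nodata <- !is.finite(values)
  nodata <- matrix(as.logical(nodata), nrow(values), ncol(values))
  if (!all(dim(nodata) == dim(values)))
    stop("values and nodata mask differ in shape")
  values[nodata] <- NA_real_
  structure(list(values = values, nodata = nodata,
                 xll = as.numeric(xll), yll = as.numeric(yll),
                 cellsize = as.numeric(cellsize),
                 variable = as.character(variable),
                 timepoint = as.character(timepoint)),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat("raster_grid:", x$variable, x$timepoint, "-", nrow(x$values), "x",
      ncol(x$values), "cells, cellsize", x$cellsize, ";",
      sum(x$nodata), "nodata\n")
  invisible(x)
}

#' Cell-center coordinates of every raster cell
#'
#' @param raster a [raster_grid()].
#' @return List with matrices `x` and `y` of the same shape as the values.
#' @export
raster_cell_centers <- function(raster) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  cx <- raster$xll + (seq_len(nc) - 0.5) * raster$cellsize
  cy <- raster$yll + (nr - seq_len(nr) + 0.5) * raster$cellsize
  list(x = matrix(cx, nr, nc, byrow = TRUE), y = matrix(cy, nr, nc))
}

#' Read an ESRI ASCII grid
#'
#' Plain-text raster: `NCOLS`, `NROWS`, `XLLCORNER`, `YLLCORNER`,
#' `CELLSIZE`, `NODATA_VALUE` header lines, then rows of values from the
#' top of the grid down.
#'
#' @param path file path.
#' @param variable,timepoint labels to attach.
#' @return A [raster_grid()].
#' @export
read_ascii_grid <- function(path, variable = "", timepoint = "") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[toupper(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("NCOLS", "NROWS")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header must contain NCOLS and NROWS: ", path)
  nc <- as.integer(hdr$NCOLS); nr <- as.integer(hdr$NROWS)
  nod <- if (!is.null(hdr$NODATA_VALUE)) hdr$NODATA_VALUE else NA_real_
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  mask <- if (is.na(nod)) !is.finite(m) else (m == nod | !is.finite(m))
  raster_grid(m, xll = if (!is.null(hdr$XLLCORNER)) hdr$XLLCORNER else 0,
              yll = if (!is.null(hdr$YLLCORNER)) hdr$YLLCORNER else 0,
              cellsize = if (!is.null(hdr$CELLSIZE)) hdr$CELLSIZE else 1,
              variable = variable, timepoint = timepoint, nodata = mask)
}

#' Write an ESRI ASCII grid
#'
#' @param raster a [raster_grid()].
#' @param path output file path.
#' @param nodata_value value written for masked cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path, nodata_value = -9999) {
  stopifnot(inherits(raster, "raster_grid"))
  v <- raster$values
  v[raster$nodata] <- nodata_value
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("NCOLS", ncol(v)), paste("NROWS", nrow(v)),
               sprintf("XLLCORNER %.17g", raster$xll),
               sprintf("YLLCORNER %.17g", raster$yll),
               sprintf("CELLSIZE %.17g", raster$cellsize),
               sprintf("NODATA_VALUE %.17g", nodata_value)), con)
  writeLines(apply(v, 1L, function(r) paste(sprintf("%.17g", r),
                                            collapse = " ")), con)
  invisible(path)
}
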