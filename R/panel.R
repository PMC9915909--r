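#' Region-by-timepoint panel of one variable
#'
#' A `panel_table` holds one variable (an indicator, the CEI, or life
#' expectancy) as a regions x timepoints numeric matrix together with a
#' missingness mask and a provenance mask marking interpolated cells.
#' Timepoint labels carry numeric year values so that lag arithmetic
#' (e.g. a 5- or 10-year offset) is explicit rather than positional.
#'
#' @param values numeric matrix, one row per region, one column per timepoint.
#' @param region_ids character vector of unique region ids (row order).
#' @param years numeric vector of strictly increasing timepoint values.
#' @param variable variable name, e.g. `"NDVI"` or `"LE"`.
#' @param missing logical matrix flagging missing cells; defaults to
#'   non-finite cells of `values`.
#' @param filled logical matrix flagging cells produced by interpolation.
#' @return An object of class `panel_table`.
#' @export
panel_table <- function(values, region_ids, years, variable,
                        missing = NULL, filled = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  region_ids <- as.character(region_ids)
  years <- as.numeric(years)
  if (nrow(values) != length(region_ids))
    stop("values has ", nrow(values), " rows but ", length(region_ids),
         " region ids were given")
  if (ncol(values) != length(years))
    stop("values has ", ncol(values), " columns but ", length(years),
         " timepoints were given")
  if (anyDuplicated(region_ids))
    stop("duplicate region id: ",
         region_ids[duplicated(region_ids)][1L])
  if (length(years) > 1L && any(diff(years) <= 0))
    stop("timepoints must be strictly increasing")
  if (is.null(missing)) missing <- !is.finite(values)
  missing <- matrix(as.logical(missing), nrow(values), ncol(values))
  if (any(!missing & !is.finite(values)))
    stop("non-finite cell not flagged missing")
  values[missing] <- NA_real_
  if (is.null(filled)) filled <- matrix(FALSE, nrow(values), ncol(values))
  dimnames(values) <- dimnames(missing) <- dimnames(filled) <-
    list(region_ids, as.character(years))
  structure(
    list(variable = as.character(variable), region_ids = region_ids,
         years = years, values = values, missing = missing, filled = filled),
    class = "panel_table")
}

#' @export
print.panel_table <- function(x, ...) {
  cat("panel_table:", x$variable, "-", length(x$region_ids), "regions x",
      length(x$years), "timepoints (", paste(x$years, collapse = ", "), ")\n")
  if (any(x$missing)) cat("  missing cells:", sum(x$missing), "\n")
  if (any(x$filled)) cat("  interpolated cells:", sum(x$filled), "\n")
  invisible(x)
}

#' Read a panel CSV
#'
#' Expects a first column of region ids and one column per timepoint, the
#' column names being (or containing) the numeric year.  Empty cells are
#' flagged missing; any non-numeric non-empty cell is an error.
#'
#' @param path CSV file path.
#' @param variable variable name to attach to the panel.
#' @return A [panel_table()].
#' @export
read_panel_csv <- function(path, variable) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  if (nrow(raw) == 0L)
    stop("panel CSV has no data rows: ", path)
  if (ncol(raw) < 2L)
    stop("panel CSV needs a region-id column plus timepoint columns: ", path)
  ids <- trimws(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate region id in ", path, ": ", ids[duplicated(ids)][1L])
  tp_names <- names(raw)[-1L]
  years <- suppressWarnings(as.numeric(gsub("[^0-9.+-]", "", tp_names)))
  if (anyNA(years))
    stop("cannot parse a numeric year from column name(s): ",
         paste(tp_names[is.na(years)], collapse = ", "))
  vals <- matrix(NA_real_, nrow(raw), length(tp_names))
  miss <- matrix(FALSE, nrow(raw), length(tp_names))
  for (j in seq_along(tp_names)) {
    cell <- trimws(raw[[j + 1L]])
    empty <- !nzchar(cell) | toupper(cell) %in% c("NA", "NAN")
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(num))
    if (length(bad))
      stop("non-numeric cell in ", path, " at row ", bad[1L],
           ", column '", tp_names[j], "': '", cell[bad[1L]], "'")
    vals[, j] <- num
    miss[, j] <- empty
  }
  panel_table(vals, ids, years, variable, missing = miss)
}

#' Write a panel CSV
#'
#' Finite cells are written with 17 significant digits so that a
#' read/write round-trip reproduces them bit-exactly; missing cells are
#' written as empty strings.
#'
#' @param panel a [panel_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "panel_table"))
  fmt <- function(v, m) ifelse(m, "", sprintf("%.17g", v))
  out <- data.frame(region_id = panel$region_ids, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_along(panel$years))
    out[[as.character(panel$years[j])]] <-
      fmt(panel$values[, j], panel$missing[, j])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Fill missing panel cells by linear interpolation in time
#'
#' Interior gaps are filled by piecewise-linear interpolation against the
#' numeric year; leading/trailing gaps are filled by linear extrapolation
#' from the two nearest observed points.  A region with a single observed
#' timepoint is filled with that constant.  Observed cells are never
#' changed, and every filled cell is flagged in the `filled` mask.
#'
#' @param panel a [panel_table()] where each region has at least one
#'   observed timepoint.
#' @return A [panel_table()] with no missing cells.
#' @export
interpolate_missing <- function(panel) {
  stopifnot(inherits(panel, "panel_table"))
  vals <- panel$values
  miss <- panel$missing
  filled <- panel$filled
  t <- panel$years
  for (i in seq_along(panel$region_ids)) {
    mi <- miss[i, ]
    if (!any(mi)) next
    obs <- which(!mi)
    if (length(obs) == 0L)
      stop("region '", panel$region_ids[i], "' has no observed timepoint")
    y <- vals[i, ]
    to <- t[obs]; yo <- y[obs]
    for (j in which(mi)) {
      if (length(obs) == 1L) {
        y[j] <- yo[1L]
      } else if (t[j] < to[1L]) {
        s <- (yo[2L] - yo[1L]) / (to[2L] - to[1L])
        y[j] <- yo[1L] + s * (t[j] - to[1L])
      } else if (t[j] > to[length(to)]) {
        k <- length(to)
        s <- (yo[k] - yo[k - 1L]) / (to[k] - to[k - 1L])
        y[j] <- yo[k] + s * (t[j] - to[k])
      } else {
        y[j] <- stats::approx(to, yo, xout = t[j])$y
      }
    }
    vals[i, ] <- y
    filled[i, mi] <- TRUE
    miss[i, ] <- FALSE
  }
  panel_table(vals, panel$region_ids, panel$years, panel$variable,
              missing = miss, filled = filled)
}
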