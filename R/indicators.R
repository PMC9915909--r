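#' Scale/offset conversion spec for a raster indicator
#'
#' MODIS-style products store physical quantities as scaled integers; a
#' `scale_spec` describes the affine conversion and the physically valid
#' range after conversion.  The shipped defaults follow the standard
#' MODIS conventions (e.g. LST: digital number x 0.02 Kelvin, then
#' -273.15 to degrees Celsius; NDVI and surface reflectance: x 1e-4).
#'
#' @param scale multiplicative factor (non-zero).
#' @param offset additive term applied after scaling.
#' @param valid_range length-2 inclusive (min, max) after conversion, or
#'   `NULL` for no range screening.
#' @return An object of class `scale_spec`.
#' @export
scale_spec <- function(scale = 1, offset = 0, valid_range = NULL) {
  if (scale == 0) stop("scale must be non-zero")
  if (!is.null(valid_range)) {
    valid_range <- as.numeric(valid_range)
    if (length(valid_range) != 2L || valid_range[1L] > valid_range[2L])
      stop("valid_range must be (min, max) with min <= max")
  }
  structure(list(scale = as.numeric(scale), offset = as.numeric(offset),
                 valid_range = valid_range), class = "scale_spec")
}

#' Default conversion specs for the five study indicators
#'
#' @return Named list of [scale_spec()]s for NDVI, LAI, GPP, LST (to
#'   degrees Celsius, screened to 0-69) and surface reflectance.
#' @export
default_scale_specs <- function() {
  list(NDVI = scale_spec(1e-4, 0, c(-1, 1)),
       LAI = scale_spec(0.1, 0, c(0, 10)),
       GPP = scale_spec(1e-4, 0, c(0, Inf)),
       LST = scale_spec(0.02, -273.15, c(0, 69)),
       reflectance = scale_spec(1e-4, 0, c(-0.01, 1.6)))
}

#' Apply a scale/offset conversion to a raster
#'
#' `out = in * scale + offset`; cells falling outside `valid_range`
#' become nodata, so the mask can only grow.
#'
#' @param raster a [raster_grid()].
#' @param spec a [scale_spec()].
#' @return A converted [raster_grid()].
#' @export
apply_scale <- function(raster, spec) {
  stopifnot(inherits(raster, "raster_grid"), inherits(spec, "scale_spec"))
  v <- raster$values * spec$scale + spec$offset
  mask <- raster$nodata
  if (!is.null(spec$valid_range))
    mask <- mask | (!is.na(v) &
                      (v < spec$valid_range[1L] | v > spec$valid_range[2L]))
  raster_grid(v, raster$xll, raster$yll, raster$cellsize,
              raster$variable, raster$timepoint, nodata = mask)
}

#' MODIS tasseled-cap wetness coefficients
#'
#' Seven-band coefficient set for MODIS surface reflectance (bands 1-7),
#' the standard wetness axis of the tasseled-cap transformation for that
#' sensor.
#'
#' @return Numeric vector of length 7.
#' @export
tct_wetness_coefficients <- function() {
  c(b1 = 0.1147, b2 = 0.2489, b3 = 0.2408, b4 = 0.3132,
    b5 = -0.3122, b6 = -0.6416, b7 = -0.5087)
}

#' Tasseled-cap wetness from reflectance bands
#'
#' Pixelwise dot product of the reflectance bands with the wetness
#' coefficients; a pixel is nodata if any band is nodata.
#'
#' @param bands list of [raster_grid()]s sharing shape and georeference.
#' @param coefficients numeric vector, one per band.
#' @return A [raster_grid()] named `"Wet"`.
#' @export
tct_wetness <- function(bands, coefficients = tct_wetness_coefficients()) {
  if (length(bands) == 0L) stop("no bands given")
  if (length(coefficients) != length(bands))
    stop(length(coefficients), " coefficients for ", length(bands), " bands")
  ref <- bands[[1L]]
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  mask <- matrix(FALSE, nrow(ref$values), ncol(ref$values))
  for (k in seq_along(bands)) {
    b <- bands[[k]]
    if (!all(dim(b$values) == dim(ref$values)))
      stop("band ", k, " shape differs from band 1")
    v <- b$values
    v[b$nodata] <- 0
    acc <- acc + coefficients[k] * v
    mask <- mask | b$nodata
  }
  raster_grid(acc, ref$xll, ref$yll, ref$cellsize, "Wet", ref$timepoint,
              nodata = mask)
}

#' Assign raster cells to regions by pixel-center membership
#'
#' Regions are visited in order and claim still-unassigned cells whose
#' centers fall inside them, so a cell belongs to at most one region and
#' boundary ties break by region order.
#'
#' @param raster a [raster_grid()].
#' @param regions a [region_set()] with geometry.
#' @return Integer matrix of region indices (NA = no region).
#' @export
raster_region_assignment <- function(raster, regions) {
  ctr <- raster_cell_centers(raster)
  assign <- matrix(NA_integer_, nrow(raster$values), ncol(raster$values))
  px <- as.vector(ctr$x); py <- as.vector(ctr$y)
  free <- rep(TRUE, length(px))
  idx <- rep(NA_integer_, length(px))
  for (k in seq_along(regions$ids)) {
    if (!any(free)) break
    hit <- points_in_geometry(px[free], py[free], regions$geometry[[k]])
    idx[which(free)[hit]] <- k
    free[which(free)[hit]] <- FALSE
  }
  assign[] <- idx
  assign
}

#' Per-region mean of a raster
#'
#' Mean over unmasked cells whose centers fall in each region; regions
#' with no valid cell get `NA`.
#'
#' @param raster a [raster_grid()].
#' @param regions a [region_set()] with geometry.
#' @return Named numeric vector of region means.
#' @export
zonal_mean <- function(raster, regions) {
  assign <- raster_region_assignment(raster, regions)
  if (all(is.na(assign)))
    stop("no region intersects the raster extent")
  out <- rep(NA_real_, length(regions$ids))
  names(out) <- regions$ids
  ok <- !is.na(assign) & !raster$nodata
  if (any(ok)) {
    sums <- tapply(raster$values[ok], assign[ok], mean)
    out[as.integer(names(sums))] <- as.numeric(sums)
  }
  out
}

#' Annual observation bookkeeping for composited satellite products
#'
#' A product composited every `interval_days` days yields
#' `ceiling(365 / interval_days)` layers per year (46 for 8-day, 23 for
#' 16-day products); across `n_regions` regions the per-year observation
#' total is their product (736 and 368 for a 16-region study).
#'
#' @param interval_days compositing interval in days (e.g. 8 or 16).
#' @param n_regions number of regions observed.
#' @return List with `composites_per_year` and `total_observations`.
#' @export
annual_observations <- function(interval_days, n_regions = 16L) {
  if (interval_days <= 0) stop("interval_days must be positive")
  k <- as.integer(ceiling(365 / interval_days))
  list(composites_per_year = k,
       total_observations = k * as.integer(n_regions))
}
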