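#' Configuration for the synthetic study generator
#'
#' The generator emulates the study design the package is built for: a
#' small set of contiguous regions (default 16) observed at three
#' 5-yearly timepoints, five ecological indicators with a single shared
#' "greenness" factor (GPP, LAI, NDVI and Wet load together; LST loads
#' weakly and negatively), spatial autocorrelation injected by a
#' simultaneous-autoregressive (SAR) filter, and life expectancy driven
#' by the ecological index of an earlier timepoint.
#'
#' @param n_side regions grid dimension (n_side^2 regions; default 4).
#' @param years numeric timepoints (default 2010, 2015, 2020).
#' @param rho spatial autoregression strength in \[0, 1) (default 0.8).
#' @param lag_m true lag of the LE dependence, in timepoint steps
#'   (default 1, i.e. 5 years at the default spacing).
#' @param beta_le effect of the lagged, z-scored CEI on LE, in years per
#'   standard deviation (default 2).
#' @param noise_sd_le LE noise standard deviation in years (default 0.1).
#' @param noise_ind multiplier on the indicators' idiosyncratic noise
#'   (default 1; 0 gives noise-free affine maps of the latent field).
#' @param seed integer random seed (default 1).
#' @param pixels_per_region raster cells per region side (default 4).
#' @param raster_noise_sd within-region pixel noise s.d. for
#'   [generate_rasters()] (default 0).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_side = 4L, years = c(2010, 2015, 2020),
                             rho = 0.8, lag_m = 1L, beta_le = 2,
                             noise_sd_le = 0.1, noise_ind = 1,
                             seed = 1L, pixels_per_region = 4L,
                             raster_noise_sd = 0) {
  if (n_side < 2L) stop("n_side must be at least 2")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (lag_m < 0L || lag_m >= length(years))
    stop("lag_m must be smaller than the number of timepoints")
  if (noise_sd_le < 0 || raster_noise_sd < 0 || noise_ind < 0)
    stop("noise levels must be non-negative")
  if (any(diff(years) <= 0)) stop("years must be strictly increasing")
  structure(list(n_side = as.integer(n_side), years = as.numeric(years),
                 rho = rho, lag_m = as.integer(lag_m), beta_le = beta_le,
                 noise_sd_le = noise_sd_le, noise_ind = noise_ind,
                 seed = as.integer(seed),
                 pixels_per_region = as.integer(pixels_per_region),
                 raster_noise_sd = raster_noise_sd),
            class = "synthetic_config")
}

#' Generate a grid of square study regions
#'
#' `n_side^2` unit squares tiling \[0, n_side\]^2, ids `r00`, `r01`, ...
#' (row, column); deterministic given the config.
#'
#' @param config a [synthetic_config()].
#' @return A [region_set()].
#' @export
generate_regions <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_side
  ids <- character(n * n)
  geo <- vector("list", n * n)
  k <- 0L
  for (r in seq_len(n) - 1L) for (c in seq_len(n) - 1L) {
    k <- k + 1L
    ids[k] <- sprintf("r%d%d", r, c)
    ring <- rbind(c(c, r), c(c + 1, r), c(c + 1, r + 1), c(c, r + 1))
    geo[[k]] <- list(type = "Polygon", rings = list(ring))
  }
  region_set(ids, geometry = geo)
}

# Latent spatially autocorrelated field: g = (I - rho W)^-1 eps,
# standardized to population mean 0 / s.d. 1 across regions.
sar_field <- function(n, rho, Wmat) {
  eps <- stats::rnorm(n)
  g <- solve(diag(n) - rho * Wmat, eps)
  m <- mean(g)
  s <- sqrt(mean((g - m)^2))
  (g - m) / s
}

# Affine maps of the latent greenness field; intercept/slope/noise chosen
# so marginal ranges respect the published per-indicator envelopes.
indicator_params <- function() {
  list(NDVI = list(a = 0.27, b = 0.12, s = 0.06, lo = -0.19, hi = 0.999),
       LAI = list(a = 0.75, b = 0.45, s = 0.22, lo = 0, hi = 7),
       GPP = list(a = 0.013, b = 0.005, s = 0.0025, lo = 0, hi = 0.102),
       Wet = list(a = 0.05, b = 0.10, s = 0.05, lo = -0.6, hi = 0.91),
       LST = list(a = 45, b = -1.2, s = 8, lo = 0, hi = 69))
}

#' Generate the five spatially autocorrelated indicator panels
#'
#' Per timepoint an independent latent greenness field g is drawn through
#' the SAR filter `g = (I - rho W)^-1 eps` (eps i.i.d. standard normal).
#' GPP, LAI, NDVI and Wet are positive affine functions of g plus
#' independent noise; LST is a weakly negative affine function of g with
#' a dominant independent component (so it decorrelates from the
#' greenness factor, as in arid-region data).  Values are clipped to the
#' published marginal envelopes (NDVI in \[-0.19, 1\], LST in \[0, 69\]
#' degrees C, GPP >= 0).
#'
#' @param config a [synthetic_config()].
#' @param weights row-standardized [spatial_weights()] over the generated
#'   regions.
#' @return Named list of five [panel_table()]s (NDVI, LAI, GPP, LST, Wet).
#' @export
generate_indicator_panels <- function(config, weights) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(weights, "spatial_weights"))
  if (weights$standardized != "row")
    stop("weights must be row-standardized")
  n <- length(weights$ids)
  Wmat <- weights_matrix(weights)
  n_t <- length(config$years)
  pars <- indicator_params()
  set.seed(config$seed)
  vals <- lapply(pars, function(p) matrix(NA_real_, n, n_t))
  for (t in seq_len(n_t)) {
    g <- sar_field(n, config$rho, Wmat)
    for (nm in names(pars)) {
      p <- pars[[nm]]
      x <- p$a + p$b * g +
        config$noise_ind * p$s * stats::rnorm(n)
      vals[[nm]][, t] <- pmin(pmax(x, p$lo), p$hi)
    }
  }
  out <- lapply(names(pars), function(nm)
    panel_table(vals[[nm]], weights$ids, config$years, nm))
  names(out) <- names(pars)
  out[c("NDVI", "LAI", "GPP", "LST", "Wet")]
}

#' Generate life expectancy with a known lagged CEI dependence
#'
#' `LE_i(t) = 73 + beta_le * zscore(CEI_i(t - lag_m)) + noise`, clipped
#' to \[65, 85\] years; timepoints with no lagged predecessor use the
#' earliest available CEI.
#'
#' @param config a [synthetic_config()].
#' @param cei the CEI [panel_table()] covering all timepoints.
#' @return A [panel_table()] named `"LE"`.
#' @export
generate_le_panel <- function(config, cei) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(cei, "panel_table"))
  n_t <- length(cei$years)
  if (config$lag_m >= n_t)
    stop("lag_m must be smaller than the number of timepoints")
  n <- length(cei$region_ids)
  set.seed(config$seed + 10007L)
  le <- matrix(NA_real_, n, n_t)
  for (t in seq_len(n_t)) {
    src <- max(1L, t - config$lag_m)
    z <- as.vector(scale(cei$values[, src]))
    le[, t] <- 73 + config$beta_le * z +
      stats::rnorm(n, sd = config$noise_sd_le)
  }
  le <- pmin(pmax(le, 65), 85)
  panel_table(le, cei$region_ids, cei$years, "LE")
}

#' Generate per-timepoint rasters consistent with a panel
#'
#' Each region becomes a `pixels_per_region` x `pixels_per_region` block
#' whose cells equal the region's panel value plus i.i.d. noise, so a
#' zonal mean over the raster recovers the panel up to Monte-Carlo error
#' (exactly, at zero noise).
#'
#' @param config a [synthetic_config()].
#' @param panel a [panel_table()] over the generated grid regions.
#' @return List of [raster_grid()]s, one per timepoint.
#' @export
generate_rasters <- function(config, panel) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(panel, "panel_table"))
  if (config$pixels_per_region < 1L)
    stop("pixels_per_region must be at least 1")
  ns <- config$n_side
  p <- config$pixels_per_region
  if (length(panel$region_ids) != ns * ns)
    stop("panel does not match the generated grid")
  set.seed(config$seed + 20011L)
  out <- vector("list", length(panel$years))
  for (t in seq_along(panel$years)) {
    m <- matrix(NA_real_, ns * p, ns * p)
    k <- 0L
    for (r in seq_len(ns) - 1L) for (c in seq_len(ns) - 1L) {
      k <- k + 1L
      rows <- (ns - r - 1L) * p + seq_len(p)  # matrix row 1 = top
      cols <- c * p + seq_len(p)
      m[rows, cols] <- panel$values[k, t] +
        stats::rnorm(p * p, sd = config$raster_noise_sd)
    }
    out[[t]] <- raster_grid(m, xll = 0, yll = 0, cellsize = 1 / p,
                            variable = panel$variable,
                            timepoint = as.character(panel$years[t]))
  }
  out
}

#' Simulate a full synthetic study
#'
#' One-stop generation of regions, queen-contiguity weights, the five
#' indicator panels, the CEI (via [build_cei()]) and the lag-dependent
#' life-expectancy panel.
#'
#' @param config a [synthetic_config()].
#' @return List with `regions`, `weights` (row-standardized queen),
#'   `panels`, `cei` (panel), `pca` (per-year [cei_pca()]s) and `le`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  regions <- generate_regions(config)
  w <- suppressWarnings(row_standardize(queen_contiguity(regions)))
  panels <- generate_indicator_panels(config, w)
  cei <- build_cei(panels)
  le <- generate_le_panel(config, cei$panel)
  list(regions = regions, weights = w, panels = panels,
       cei = cei$panel, pca = cei$pca, le = le)
}

#' Write a synthetic dataset to disk
#'
#' Writes `regions.geojson`, one CSV per indicator, `cei.csv` and
#' `le.csv` into a directory, plus optional per-indicator ASCII-grid
#' rasters.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @param rasters also write per-timepoint rasters for each indicator.
#' @return Invisible character vector of the files written.
#' @export
write_synthetic_dataset <- function(config, dir, rasters = FALSE) {
  sim <- simulate_study(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, "regions.geojson")
  write_regions_geojson(sim$regions, files[1L])
  for (nm in names(sim$panels)) {
    f <- file.path(dir, paste0(tolower(nm), ".csv"))
    write_panel_csv(sim$panels[[nm]], f)
    files <- c(files, f)
  }
  f <- file.path(dir, "cei.csv"); write_panel_csv(sim$cei, f)
  files <- c(files, f)
  f <- file.path(dir, "le.csv"); write_panel_csv(sim$le, f)
  files <- c(files, f)
  if (rasters) {
    for (nm in names(sim$panels)) {
      rs <- generate_rasters(config, sim$panels[[nm]])
      for (t in seq_along(rs)) {
        f <- file.path(dir, sprintf("%s_%s.asc", tolower(nm),
                                    config$years[t]))
        write_ascii_grid(rs[[t]], f)
        files <- c(files, f)
      }
    }
  }
  invisible(files)
}
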