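#' Theil-Sen slope of a time series
#'
#' Median of all pairwise slopes (x_j - x_i) / (t_j - t_i) over j > i,
#' using the actual time spacing (years), not index spacing, so a panel
#' observed every 5 years yields a slope per year.
#'
#' @param x numeric series.
#' @param times strictly increasing numeric times (defaults to 1..n).
#' @return The Sen slope (variable units per time unit).
#' @export
sen_slope <- function(x, times = seq_along(x)) {
  n <- length(x)
  if (n < 2L) stop("sen_slope needs at least 2 observations")
  if (length(times) != n || any(diff(times) <= 0))
    stop("times must be strictly increasing and match the series length")
  dx <- outer(x, x, "-")
  dt <- outer(times, times, "-")
  stats::median(dx[lower.tri(dx)] / dt[lower.tri(dt)])
}

#' Mann-Kendall trend test
#'
#' The sign statistic S = sum_{i<j} sign(x_j - x_i) with the
#' tie-corrected variance
#' Var(S) = \[n(n-1)(2n+5) - sum_k t_k(t_k-1)(2t_k+5)\] / 18 and the
#' continuity-corrected normal deviate Z ((S-1)/sqrt(Var) for S > 0, 0
#' for S = 0, (S+1)/sqrt(Var) for S < 0).  The normal approximation is
#' used at all n >= 3.
#'
#' @param x numeric series in time order (n >= 3).
#' @param times optional strictly increasing times, used only for the
#'   accompanying Sen slope.
#' @param z_crit absolute-Z significance gate for the direction label
#'   (default 1.96).
#' @return List of class `trend_result`: `beta` (Sen slope), `S`,
#'   `var_S`, `Z`, `p_value` (two-sided) and `direction` in
#'   `"up"`/`"down"`/`"none"`.
#' @export
mk_test <- function(x, times = seq_along(x), z_crit = 1.96) {
  n <- length(x)
  if (n < 3L) stop("mk_test needs at least 3 observations")
  diffs <- outer(x, x, "-")            # [i, j] = x_i - x_j
  S <- sum(sign(diffs[lower.tri(diffs)]))  # i > j: later minus earlier
  ties <- table(x)
  ties <- ties[ties > 1L]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  Z <- if (S > 0) (S - 1) / sqrt(var_S) else
    if (S < 0) (S + 1) / sqrt(var_S) else 0
  p <- 2 * stats::pnorm(-abs(Z))
  direction <- if (abs(Z) >= z_crit) (if (Z > 0) "up" else "down") else "none"
  structure(list(beta = sen_slope(x, times), S = as.integer(S),
                 var_S = var_S, Z = Z, p_value = p, direction = direction),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("trend: beta = %.4g, S = %d, Z = %.3f, p = %.4g (%s)\n",
              x$beta, x$S, x$Z, x$p_value, x$direction))
  invisible(x)
}

#' Per-region trends of a panel
#'
#' @param panel a fully observed [panel_table()] with >= 3 timepoints.
#' @param z_crit significance gate passed to [mk_test()].
#' @return data.frame with one row per region: `region_id`, `beta`, `S`,
#'   `Z`, `p_value`, `direction`.
#' @export
trend_panel <- function(panel, z_crit = 1.96) {
  stopifnot(inherits(panel, "panel_table"))
  if (any(panel$missing)) stop("panel has missing cells; interpolate first")
  rows <- lapply(seq_along(panel$region_ids), function(i) {
    tr <- mk_test(panel$values[i, ], panel$years, z_crit = z_crit)
    data.frame(region_id = panel$region_ids[i], beta = tr$beta, S = tr$S,
               Z = tr$Z, p_value = tr$p_value, direction = tr$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-pixel trends of a raster time stack
#'
#' @param stack list of >= 3 aligned [raster_grid()]s in time order.
#' @param times numeric times of the layers (defaults to 1..n).
#' @return List of two [raster_grid()]s, `beta` and `Z`; pixels with
#'   fewer than 3 valid layers are nodata.
#' @export
trend_raster <- function(stack, times = seq_along(stack)) {
  if (length(stack) < 3L) stop("trend_raster needs at least 3 layers")
  ref <- stack[[1L]]
  for (k in seq_along(stack))
    if (!all(dim(stack[[k]]$values) == dim(ref$values)))
      stop("layer ", k, " shape differs from layer 1")
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  cube <- vapply(stack, function(r) r$values, matrix(0, nr, nc))
  beta <- z <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    series <- cube[i, j, ]
    ok <- is.finite(series)
    if (sum(ok) < 3L) next
    tr <- mk_test(series[ok], times[ok])
    beta[i, j] <- tr$beta
    z[i, j] <- tr$Z
  }
  list(beta = raster_grid(beta, ref$xll, ref$yll, ref$cellsize,
                          paste0(ref$variable, "_sen_beta")),
       Z = raster_grid(z, ref$xll, ref$yll, ref$cellsize,
                       paste0(ref$variable, "_mk_z")))
}
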