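#' @keywords internal
zscore_pop <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("constant variable")
  (x - m) / s
}

check_cross_inputs <- function(y, x_lagged, w) {
  stopifnot(inherits(w, "spatial_weights"))
  n <- length(w$ids)
  if (length(y) != n || length(x_lagged) != n)
    stop("variable length != number of units")
  if (w$standardized != "row")
    stop("cross-Moran statistics expect row-standardized weights")
  non_iso <- lengths(w$neighbors) > 0L
  if (sum(non_iso) < 3L) stop("need at least 3 non-isolated units")
  if (any(!is.finite(y)) || any(!is.finite(x_lagged)))
    stop("non-finite variable value")
  non_iso
}

#' Global bivariate (lagged) Moran's I
#'
#' The spatial cross-product statistic relating variable y at each
#' location to variable x at its neighbours:
#' `I = sum_ij w_ij z_y,i z_x,j / S0`, with both variables standardized
#' by their population standard deviation and `S0 = sum_ij w_ij`.  In
#' the spatiotemporal-lag analysis y is life expectancy at time t and x
#' the ecological index at time t - m; with `x_lagged = y` the statistic
#' reduces to univariate Moran's I.
#'
#' @param y per-unit response values (e.g. LE at time t).
#' @param x_lagged per-unit covariate values (e.g. CEI at time t - m).
#' @param w row-standardized [spatial_weights()].
#' @return Scalar global I.
#' @export
global_cross_moran <- function(y, x_lagged, w) {
  check_cross_inputs(y, x_lagged, w)
  W <- weights_matrix(w)
  S0 <- sum(W)
  zy <- zscore_pop(y)
  zx <- zscore_pop(x_lagged)
  sum(zy * as.vector(W %*% zx)) / S0
}

#' Local bivariate (lagged) Moran's I
#'
#' `I_i = z_y,i * sum_j w_ij z_x,j`.  With row-standardized weights and
#' no isolates the mean of the local values equals the global statistic.
#'
#' @inheritParams global_cross_moran
#' @return Named per-unit numeric vector of local I values.
#' @export
local_cross_moran <- function(y, x_lagged, w) {
  check_cross_inputs(y, x_lagged, w)
  W <- weights_matrix(w)
  zy <- zscore_pop(y)
  zx <- zscore_pop(x_lagged)
  out <- zy * as.vector(W %*% zx)
  names(out) <- w$ids
  out
}

#' Permutation inference for the lagged cross-Moran statistics
#'
#' Global: the covariate is permuted over all units `n_perm` times and
#' the pseudo p-value is `(#\{|I_perm| >= |I_obs|\} + 1) / (n_perm + 1)`.
#' Local: GeoDa-style conditional permutation -- unit i's own value is
#' held fixed while its neighbours draw (without replacement) from the
#' covariate values of the remaining units.  Deterministic given `seed`.
#' Isolated units get `NA` local p-values.
#'
#' @inheritParams global_cross_moran
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed optional integer seed.
#' @param alternative `"two.sided"` (by |I|) or `"greater"`.
#' @param local also run the (slower) local conditional permutations.
#' @return List with `global_I`, `expected_I` (permutation mean),
#'   `p_value`, `local_I`, `local_p`, `z_y` and `lag_zx` (the spatial
#'   lag of standardized x).
#' @export
permutation_inference <- function(y, x_lagged, w, n_perm = 999, seed = NULL,
                                  alternative = c("two.sided", "greater"),
                                  local = TRUE) {
  alternative <- match.arg(alternative)
  if (n_perm < 99L) stop("n_perm must be at least 99")
  non_iso <- check_cross_inputs(y, x_lagged, w)
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  W <- weights_matrix(w)
  S0 <- sum(W)
  zy <- zscore_pop(y)
  zx <- zscore_pop(x_lagged)
  lag_obs <- as.vector(W %*% zx)
  I_obs <- sum(zy * lag_obs) / S0
  perm_idx <- vapply(seq_len(n_perm), function(k) sample.int(n), integer(n))
  Ip <- colSums(zy * (W %*% matrix(zx[perm_idx], n, n_perm))) / S0
  exceed <- if (alternative == "two.sided") abs(Ip) >= abs(I_obs) else
    Ip >= I_obs
  p_global <- (sum(exceed) + 1) / (n_perm + 1)
  I_loc <- zy * lag_obs
  names(I_loc) <- w$ids
  local_p <- rep(NA_real_, n)
  names(local_p) <- w$ids
  if (local) {
    for (i in which(non_iso)) {
      nb <- w$neighbors[[i]]
      wt <- w$weights[[i]]
      pool <- zx[-i]
      k <- length(nb)
      draws <- matrix(0, n_perm, k)
      for (b in seq_len(n_perm))
        draws[b, ] <- pool[sample.int(n - 1L, k)]
      Iip <- zy[i] * as.vector(draws %*% wt)
      ex <- if (alternative == "two.sided") abs(Iip) >= abs(I_loc[i]) else
        Iip >= I_loc[i]
      local_p[i] <- (sum(ex) + 1) / (n_perm + 1)
    }
  }
  list(global_I = I_obs, expected_I = mean(Ip), p_value = p_global,
       local_I = I_loc, local_p = local_p, z_y = zy, lag_zx = lag_obs)
}

#' LISA cluster labels for the lagged cross-Moran
#'
#' Significant units are labelled by the quadrant of
#' (z_y,i, sum_j w_ij z_x,j): (+,+) high-high, (-,-) low-low, (+,-)
#' high-low, (-,+) low-high; all other units are `not_significant`.
#'
#' @inheritParams global_cross_moran
#' @param local_p per-unit pseudo p-values from
#'   [permutation_inference()].
#' @param alpha significance level (default 0.05).
#' @return Named character vector of cluster labels.
#' @export
lisa_classify <- function(y, x_lagged, w, local_p, alpha = 0.05) {
  check_cross_inputs(y, x_lagged, w)
  zy <- zscore_pop(y)
  lag_zx <- as.vector(weights_matrix(w) %*% zscore_pop(x_lagged))
  lab <- rep("not_significant", length(zy))
  sig <- !is.na(local_p) & local_p <= alpha
  lab[sig & zy > 0 & lag_zx > 0] <- "high-high"
  lab[sig & zy < 0 & lag_zx < 0] <- "low-low"
  lab[sig & zy > 0 & lag_zx < 0] <- "high-low"
  lab[sig & zy < 0 & lag_zx > 0] <- "low-high"
  names(lab) <- w$ids
  lab
}

#' Moran scatter values
#'
#' Per-unit pairs of z_y against the spatial lag of z_x, plus the
#' least-squares through-origin slope of the lag on z_y, which equals
#' the global cross-Moran statistic under row-standardized weights.
#'
#' @inheritParams global_cross_moran
#' @return List with `scatter` (data.frame `region_id`, `z_y`,
#'   `lag_z_x`) and `slope`.
#' @export
moran_scatter <- function(y, x_lagged, w) {
  check_cross_inputs(y, x_lagged, w)
  zy <- zscore_pop(y)
  lag_zx <- as.vector(weights_matrix(w) %*% zscore_pop(x_lagged))
  list(scatter = data.frame(region_id = w$ids, z_y = zy, lag_z_x = lag_zx,
                            stringsAsFactors = FALSE),
       slope = sum(zy * lag_zx) / sum(zy^2))
}

#' Full lagged cross-Moran analysis for one variable pair
#'
#' Bundles the global statistic, permutation inference, local values,
#' LISA cluster labels and Moran scatter values.
#'
#' @inheritParams permutation_inference
#' @param alpha local significance level for the cluster labels.
#' @return An object of class `cross_moran_result`.
#' @export
cross_moran <- function(y, x_lagged, w, n_perm = 999, seed = NULL,
                        alpha = 0.05,
                        alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  inf <- permutation_inference(y, x_lagged, w, n_perm = n_perm, seed = seed,
                               alternative = alternative)
  sc <- moran_scatter(y, x_lagged, w)
  structure(list(global_I = inf$global_I, expected_I = inf$expected_I,
                 p_value = inf$p_value, local_I = inf$local_I,
                 local_p = inf$local_p,
                 cluster = lisa_classify(y, x_lagged, w, inf$local_p, alpha),
                 scatter = sc$scatter, slope = sc$slope,
                 n_perm = n_perm, alpha = alpha),
            class = "cross_moran_result")
}

#' @export
print.cross_moran_result <- function(x, ...) {
  cat(sprintf("bivariate Moran's I = %.4f (perm. mean %.4f, pseudo p = %.4g, %d perms)\n",
              x$global_I, x$expected_I, x$p_value, x$n_perm))
  sig <- x$cluster[x$cluster != "not_significant"]
  if (length(sig))
    cat("  clusters:", paste(names(sig), sig, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Pearson lag-correlation table between indicators and a response panel
#'
#' For each requested (x variable, x time, y time) pair, the sample
#' Pearson correlation across regions; cells missing in either panel are
#' pairwise-deleted.
#'
#' @param x_panels named list of [panel_table()]s (indicators, CEI).
#' @param y_panel response [panel_table()] (life expectancy).
#' @param pairs data.frame with columns `x_variable`, `x_time`, `y_time`
#'   (numeric years present in the panels).
#' @return data.frame `x_variable`, `x_time`, `y_time`, `lag_years`,
#'   `pearson_r`, `n_used`.
#' @export
pearson_lag_matrix <- function(x_panels, y_panel, pairs) {
  stopifnot(inherits(y_panel, "panel_table"))
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    xv <- as.character(pairs$x_variable[r])
    xt <- as.numeric(pairs$x_time[r])
    yt <- as.numeric(pairs$y_time[r])
    xp <- x_panels[[xv]]
    if (is.null(xp)) stop("unknown x variable: ", xv)
    jx <- match(xt, xp$years)
    jy <- match(yt, y_panel$years)
    if (is.na(jx)) stop("x time ", xt, " not in panel '", xv, "'")
    if (is.na(jy)) stop("y time ", yt, " not in the response panel")
    x <- xp$values[, jx]
    y <- y_panel$values[, jy]
    ok <- !xp$missing[, jx] & !y_panel$missing[, jy]
    if (sum(ok) < 3L)
      stop("fewer than 3 complete pairs for ", xv, " ", xt, " vs ", yt)
    data.frame(x_variable = xv, x_time = xt, y_time = yt,
               lag_years = yt - xt,
               pearson_r = stats::cor(x[ok], y[ok]),
               n_used = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
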