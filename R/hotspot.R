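#' Getis-Ord Gi* cold/hot-spot statistic
#'
#' The Gi* z-score with self-inclusion (w_ii = 1 is added internally):
#' for unit i with binary weights w_ij over the t units,
#' `z_i = (sum_j w_ij x_j - xbar W_i) / (S sqrt((t S1_i - W_i^2)/(t-1)))`
#' where `W_i = sum_j w_ij`, `S1_i = sum_j w_ij^2`, and xbar and S are
#' the global mean and population standard deviation (all units,
#' including i).  Positive z marks hot spots (clustering of high
#' values), negative z cold spots.
#'
#' @param x per-unit attribute values (finite, non-constant).
#' @param w binary [spatial_weights()] (row-standardized weights are
#'   refused; Gi* is defined on binary neighbourhoods by default).
#' @return List of class `gi_star_result` with `z` (named per-unit
#'   z-scores) and `category` (see [classify_gi()]).
#' @export
gi_star <- function(x, w) {
  stopifnot(inherits(w, "spatial_weights"))
  if (w$standardized != "binary")
    stop("gi_star expects binary weights; got row-standardized")
  t <- length(x)
  if (t != length(w$ids)) stop("attribute length != number of units")
  if (t < 3L) stop("gi_star needs at least 3 units")
  if (any(!is.finite(x))) stop("non-finite attribute value")
  xbar <- mean(x)
  S <- sqrt(mean(x^2) - xbar^2)          # population s.d.
  if (S == 0) stop("attribute has zero variance")
  W <- weights_matrix(w)
  diag(W) <- 1                           # self-inclusion
  Wi <- rowSums(W)
  S1 <- rowSums(W^2)
  num <- as.vector(W %*% x) - xbar * Wi
  den <- S * sqrt(pmax(t * S1 - Wi^2, 0) / (t - 1))
  z <- ifelse(den > 0, num / den, 0)
  names(z) <- w$ids
  structure(list(z = z, category = classify_gi(z)),
            class = "gi_star_result")
}

#' Tiered cold/hot classification of Gi* z-scores
#'
#' Three confidence tiers at |z| >= 1.65, 1.96 and 2.58 (roughly 90, 95
#' and 99 percent), signed: positive z yields hot tiers, negative z cold
#' tiers.
#'
#' @param z numeric z-scores.
#' @return Character vector with levels `cold99`, `cold95`, `cold90`,
#'   `not_significant`, `hot90`, `hot95`, `hot99`.
#' @export
classify_gi <- function(z) {
  if (any(!is.finite(z))) stop("non-finite z-score")
  tier <- findInterval(abs(z), c(1.65, 1.96, 2.58))
  out <- rep("not_significant", length(z))
  hot <- z > 0
  out[tier == 1] <- ifelse(hot[tier == 1], "hot90", "cold90")
  out[tier == 2] <- ifelse(hot[tier == 2], "hot95", "cold95")
  out[tier == 3] <- ifelse(hot[tier == 3], "hot99", "cold99")
  names(out) <- names(z)
  out
}
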