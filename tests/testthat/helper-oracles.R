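# Independent brute-force oracles: literal double-loop implementations of
# each statistic, kept free of any package internals so they can certify
# the vectorized implementations.

oracle_sen_slope <- function(x, times = seq_along(x)) {
  slopes <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    slopes <- c(slopes, (x[j] - x[i]) / (times[j] - times[i]))
  median(slopes)
}

oracle_mk <- function(x) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    S <- S + sign(x[j] - x[i])
  tie_term <- 0
  for (v in unique(x)) {
    tk <- sum(x == v)
    if (tk > 1) tie_term <- tie_term + tk * (tk - 1) * (2 * tk + 5)
  }
  var_S <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  Z <- if (S > 0) (S - 1) / sqrt(var_S) else if (S < 0) (S + 1) / sqrt(var_S) else 0
  list(S = S, var_S = var_S, Z = Z)
}

# W is a dense binary matrix WITHOUT self-links; self-inclusion added here.
oracle_gi_star <- function(x, W) {
  t <- length(x)
  W <- W + diag(t)
  xbar <- mean(x)
  S <- sqrt(sum((x - xbar)^2) / t)
  z <- numeric(t)
  for (i in seq_len(t)) {
    Wi <- sum(W[i, ])
    S1 <- sum(W[i, ]^2)
    num <- sum(W[i, ] * x) - xbar * Wi
    den <- S * sqrt((t * S1 - Wi^2) / (t - 1))
    z[i] <- if (den > 0) num / den else 0
  }
  z
}

oracle_zscore <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

oracle_global_moran <- function(y, x, W) {
  zy <- oracle_zscore(y); zx <- oracle_zscore(x)
  n <- length(y)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * zy[i] * zx[j]
  num / sum(W)
}

oracle_local_moran <- function(y, x, W) {
  zy <- oracle_zscore(y); zx <- oracle_zscore(x)
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + W[i, j] * zx[j]
    out[i] <- zy[i] * acc
  }
  out
}

# Random connected binary weights on n units: a ring plus random chords,
# built independently of the package's contiguity code.
random_binary_weights <- function(n, p_extra = 0.3) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    A[i, j] <- A[j, i] <- 1
  }
  extra <- which(upper.tri(A) & A == 0)
  on <- extra[runif(length(extra)) < p_extra]
  A[on] <- 1
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

weights_from_matrix <- function(A, standardize = FALSE) {
  nb <- lapply(seq_len(nrow(A)), function(i) which(A[i, ] != 0))
  w <- spatial_weights(paste0("u", seq_len(nrow(A))), nb)
  if (standardize) suppressWarnings(row_standardize(w)) else w
}

grid_regions <- function(n_side) generate_regions(synthetic_config(n_side = n_side))
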