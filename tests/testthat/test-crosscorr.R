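test_that("with x = y the bivariate statistic reduces to univariate Moran's I", {
  set.seed(26)
  w <- row_standardize(queen_contiguity(grid_regions(4)))
  y <- rnorm(16)
  I <- global_cross_moran(y, y, w)
  # classic univariate Moran's I: (n/S0) * sum_ij w_ij (y_i-ybar)(y_j-ybar) / sum (y_i-ybar)^2
  W <- weights_matrix(w)
  yc <- y - mean(y)
  I_uni <- (length(y) / sum(W)) * sum(W * outer(yc, yc)) / sum(yc^2)
  expect_equal(I, I_uni, tolerance = 1e-12)
})

test_that("global and local statistics match the brute-force double loops", {
  set.seed(27)
  for (rep in 1:30) {
    n <- sample(5:12, 1)
    A <- random_binary_weights(n)
    w <- weights_from_matrix(A, standardize = TRUE)
    W <- weights_matrix(w)
    y <- rnorm(n); x <- rnorm(n)
    expect_equal(global_cross_moran(y, x, w), oracle_global_moran(y, x, W),
                 tolerance = 1e-12)
    expect_equal(unname(local_cross_moran(y, x, w)),
                 oracle_local_moran(y, x, W), tolerance = 1e-12)
  }
})

test_that("mean local I equals global I under row-standardized weights", {
  set.seed(28)
  w <- row_standardize(queen_contiguity(grid_regions(4)))
  for (rep in 1:20) {
    y <- rnorm(16); x <- rnorm(16)
    expect_equal(mean(local_cross_moran(y, x, w)),
                 global_cross_moran(y, x, w), tolerance = 1e-10)
  }
})

test_that("the Moran scatter slope through the origin equals global I", {
  set.seed(29)
  w <- row_standardize(queen_contiguity(grid_regions(4)))
  y <- rnorm(16); x <- rnorm(16)
  sc <- moran_scatter(y, x, w)
  expect_equal(sc$slope, global_cross_moran(y, x, w), tolerance = 1e-10)
  expect_equal(nrow(sc$scatter), 16L)
  # with x = y this is the univariate Moran scatter
  sy <- moran_scatter(y, y, w)
  expect_equal(sy$slope, global_cross_moran(y, y, w), tolerance = 1e-10)
})

test_that("permutation of the covariate centres I near zero", {
  set.seed(30)
  w <- row_standardize(queen_contiguity(grid_regions(4)))
  y <- rnorm(16); x <- rnorm(16)
  inf <- permutation_inference(y, x, w, n_perm = 2000, seed = 77,
                               local = FALSE)
  # the permutation null is exactly centred (z-scores sum to zero), so the
  # empirical mean over 2000 permutations sits within Monte-Carlo error of 0
  expect_lt(abs(inf$expected_I), 0.02)
})

test_that("permutation inference is deterministic given the seed", {
  w <- row_standardize(queen_contiguity(grid_regions(4)))
  set.seed(31)
  y <- rnorm(16); x <- rnorm(16)
  a <- permutation_inference(y, x, w, n_perm = 199, seed = 5)
  b <- permutation_inference(y, x, w, n_perm = 199, seed = 5)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$local_p, b$local_p)
  expect_error(permutation_inference(y, x, w, n_perm = 50), "at least 99")
})

test_that("LISA quadrant labels follow the sign pattern of (z_y, lag z_x)", {
  w <- row_standardize(queen_contiguity(grid_regions(4)))
  set.seed(32)
  y <- rnorm(16); x <- rnorm(16)
  zy <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  lag <- as.vector(weights_matrix(w) %*%
                     ((x - mean(x)) / sqrt(mean((x - mean(x))^2))))
  p_all <- rep(0.01, 16)
  lab <- lisa_classify(y, x, w, p_all, alpha = 0.05)
  expect_identical(unname(lab[zy > 0 & lag > 0][1]), "high-high")
  expected <- ifelse(zy > 0 & lag > 0, "high-high",
              ifelse(zy < 0 & lag < 0, "low-low",
              ifelse(zy > 0 & lag < 0, "high-low", "low-high")))
  expect_identical(unname(lab), expected)

  none <- lisa_classify(y, x, w, rep(0.99, 16), alpha = 0.05)
  expect_true(all(none == "not_significant"))
})

test_that("a planted low-low region is labelled low-low on a 5x5 grid", {
  regions <- grid_regions(5)
  w <- row_standardize(queen_contiguity(regions))
  coord <- do.call(rbind, lapply(w$ids, function(id)
    as.integer(c(substr(id, 2, 2), substr(id, 3, 3)))))
  target <- which(coord[, 1] == 1 & coord[, 2] == 1)  # r11
  nbrs <- w$neighbors[[target]]
  y <- rep(1, 25); x <- rep(1, 25)
  y[target] <- -3                      # low response at the target
  x[nbrs] <- -3                        # low covariate at its neighbours
  set.seed(33)
  y <- y + rnorm(25, sd = 0.05)
  x <- x + rnorm(25, sd = 0.05)
  cm <- cross_moran(y = y, x_lagged = x, w = w, n_perm = 999, seed = 9)
  expect_identical(unname(cm$cluster[target]), "low-low")
})

test_that("Pearson lag tables handle identity, inversion, and missing cells", {
  vals <- matrix(rnorm(48), 16, 3)
  x <- panel_table(vals, paste0("r", 1:16), c(2010, 2015, 2020), "CEI")
  y_same <- panel_table(vals, paste0("r", 1:16), c(2010, 2015, 2020), "LE")
  y_neg <- panel_table(-vals, paste0("r", 1:16), c(2010, 2015, 2020), "LE")
  pairs <- data.frame(x_variable = "CEI", x_time = 2010, y_time = 2010)
  expect_equal(pearson_lag_matrix(list(CEI = x), y_same, pairs)$pearson_r, 1)
  expect_equal(pearson_lag_matrix(list(CEI = x), y_neg, pairs)$pearson_r, -1)

  vals2 <- vals; vals2[1:14, 1] <- NA
  xm <- panel_table(vals2, paste0("r", 1:16), c(2010, 2015, 2020), "CEI")
  expect_error(pearson_lag_matrix(list(CEI = xm), y_same, pairs),
               "fewer than 3")
  pairs2 <- data.frame(x_variable = "CEI", x_time = 2015, y_time = 2020)
  out <- pearson_lag_matrix(list(CEI = xm), y_same, pairs2)
  expect_equal(out$lag_years, 5)
  expect_equal(out$n_used, 16L)
})

test_that("the lagged design out-correlates the contemporaneous one on ground truth", {
  wins_pearson <- wins_moran <- logical(60)
  for (k in seq_len(60)) {
    sim <- simulate_study(synthetic_config(seed = 40000 + k))
    le20 <- sim$le$values[, 3]
    wins_pearson[k] <- cor(le20, sim$cei$values[, 2]) >
      cor(le20, sim$cei$values[, 3])
    r <- rank_lags(sim, 2020, c(2015, 2020))
    wins_moran[k] <- r$lag_years[1] == 5
  }
  expect_gt(mean(wins_pearson), 0.7)
  # a single 16-region design is noisy; the spec'd property is a majority
  expect_gt(mean(wins_moran), 0.5)
})

test_that("constant variables and bad weights are rejected", {
  w <- row_standardize(queen_contiguity(grid_regions(4)))
  y <- rnorm(16)
  expect_error(global_cross_moran(y, rep(1, 16), w), "constant")
  expect_error(global_cross_moran(y, y, queen_contiguity(grid_regions(4))),
               "row-standardized")
})
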