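test_that("standardization gives mean-0, sd-1 columns and flags degeneracy", {
  expect_equal(unname(standardize(cbind(x = c(1, 2, 3)))[, 1]), c(-1, 0, 1))

  set.seed(4)
  m <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, letters[1:5]))
  z <- standardize(m)
  expect_equal(unname(colMeans(z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 5), tolerance = 1e-12)
  expect_equal(unname(standardize(z)), unname(z), tolerance = 1e-12)

  m[, 3] <- 2
  expect_error(standardize(m), "'c' has zero variance")
})

test_that("correlation-matrix PCA has unit-trace eigenstructure and fixed signs", {
  set.seed(9)
  for (rep in 1:10) {
    m <- matrix(rnorm(16 * 5), 16, 5)
    fit <- cei_pca(standardize(m))
    expect_equal(sum(fit$eigenvalues), 5, tolerance = 1e-8)
    expect_true(all(diff(fit$contribution) <= 1e-9))
    expect_true(all(diff(fit$cumulative) >= -1e-12))
    expect_equal(fit$cumulative[5], 100, tolerance = 1e-8)
    # sign convention: each component's largest-|.| loading is positive
    for (j in 1:5)
      expect_gt(fit$loadings[j, which.max(abs(fit$loadings[j, ]))], 0)
    # scores reproduce the matrix-times-loadings definition
    expect_equal(fit$scores, standardize(m) %*% t(fit$loadings),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("two perfectly correlated indicators collapse to one component", {
  x <- rnorm(10)
  fit <- cei_pca(standardize(cbind(a = x, b = 2 * x + 1)))
  expect_equal(fit$eigenvalues, c(2, 0), tolerance = 1e-10)
  expect_equal(fit$contribution, c(100, 0), tolerance = 1e-8)
  expect_equal(fit$n_selected, 1L)
})

test_that("independent indicators at large n approach equal contributions", {
  set.seed(10)
  fit <- cei_pca(standardize(matrix(rnorm(4000 * 5), 4000, 5)))
  expect_true(all(abs(fit$eigenvalues - 1) < 0.15))
  expect_true(all(abs(fit$contribution - 20) < 3))
  expect_equal(fit$n_selected, 4L)  # ~20% each: 4 components reach 80%
})

test_that("component selection reproduces the published per-year decisions", {
  path <- system.file("extdata", "pca_contribution_rates.csv",
                      package = "ecolag")
  tab <- read.csv(path)
  by_year <- split(tab$contribution_pct, tab$year)
  expect_equal(select_components(by_year[["2010"]]), 2L)
  expect_equal(select_components(by_year[["2015"]]), 2L)
  expect_equal(select_components(by_year[["2020"]]), 3L)
  # the 2020 selection is forced by the first two reaching only 75.758
  expect_lt(sum(by_year[["2020"]][1:2]), 80)
  expect_equal(select_components(100), 1L)
  expect_error(select_components(numeric(0)), "empty")
})

test_that("composite score equals the first-principles weighted sum", {
  set.seed(13)
  m <- standardize(matrix(rnorm(16 * 5), 16, 5))
  fit <- cei_pca(m)
  cs <- composite_score(fit)
  # independent recomputation from the correlation matrix up
  eig <- eigen(cor(m), symmetric = TRUE)
  V <- eig$vectors
  for (j in 1:5) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  contrib <- 100 * eig$values / sum(eig$values)
  n <- which(cumsum(contrib) >= 80)[1]
  P <- as.vector((m %*% V[, 1:n]) %*% (contrib[1:n] / 100))
  expect_equal(unname(cs$P), P, tolerance = 1e-10)
  expect_equal(cs$n_components, n)

  one <- composite_score(fit, n = 1)
  expect_equal(unname(one$P),
               unname(fit$scores[, 1] * fit$contribution[1] / 100))
})

test_that("permuting unit order permutes the composite score identically", {
  set.seed(14)
  m <- standardize(matrix(rnorm(16 * 5), 16, 5))
  P <- composite_score(cei_pca(m))$P
  perm <- sample(16)
  P2 <- composite_score(cei_pca(m[perm, ]))$P
  expect_equal(unname(P2), unname(P[perm]), tolerance = 1e-10)
})

test_that("a one-factor synthetic panel mirrors the published loading pattern", {
  sim <- simulate_study(synthetic_config(seed = 17))
  fit <- sim$pca[["2010"]]
  ld <- fit$scaled_loadings["PC1", ]
  expect_gt(ld["GPP"], 0.5)
  expect_gt(ld["LAI"], 0.5)
  expect_gt(ld["NDVI"], 0.5)
  expect_gt(ld["Wet"], 0.5)
  expect_lt(ld["LST"], 0.3)  # LST stays off the greenness component
})
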