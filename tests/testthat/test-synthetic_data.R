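test_that("region generation tiles the unit grid deterministically", {
  cfg <- synthetic_config(n_side = 4)
  r1 <- generate_regions(cfg)
  r2 <- generate_regions(cfg)
  expect_length(r1$ids, 16L)
  expect_identical(r1, r2)
  expect_length(generate_regions(synthetic_config(n_side = 2))$ids, 4L)
  # unit squares: area 1 each
  areas <- vapply(r1$geometry, function(g)
    abs(ecolag:::ring_area_centroid(g$rings[[1]])$area), numeric(1))
  expect_equal(areas, rep(1, 16))
})

test_that("generated artifacts are fully deterministic given the seed", {
  cfg <- synthetic_config(seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$panels, s2$panels)
  expect_identical(s1$le, s2$le)
  expect_identical(s1$cei, s2$cei)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_dataset(cfg, d1)
  write_synthetic_dataset(cfg, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("indicator panels respect the published marginal envelopes", {
  cfg <- synthetic_config(seed = 5)
  sim <- simulate_study(cfg)
  expect_true(all(sim$panels$NDVI$values >= -0.2 &
                    sim$panels$NDVI$values <= 1))
  expect_true(all(sim$panels$LST$values >= 0 & sim$panels$LST$values <= 69))
  expect_true(all(sim$panels$GPP$values >= 0))
  expect_true(all(sim$le$values >= 65 & sim$le$values <= 85))
})

test_that("rho = 0 gives the i.i.d. Moran null; rho = 0.8 gives positive Moran", {
  n_rep <- 200
  I0 <- Ipos <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    s0 <- simulate_study(synthetic_config(rho = 0, seed = 5000 + k))
    sp <- simulate_study(synthetic_config(rho = 0.8, seed = 5000 + k))
    w <- s0$weights
    I0[k] <- global_cross_moran(s0$panels$NDVI$values[, 1],
                                s0$panels$NDVI$values[, 1], w)
    Ipos[k] <- global_cross_moran(sp$panels$NDVI$values[, 1],
                                  sp$panels$NDVI$values[, 1], w)
  }
  # null expectation of univariate Moran's I is -1/(n-1) = -1/15
  expect_lt(abs(mean(I0) - (-1 / 15)), 0.03)
  expect_gt(mean(Ipos > 0), 0.5)
})

test_that("the factor structure orients GPP with NDVI and against LST", {
  cfg <- synthetic_config(n_side = 10, seed = 11)
  sim <- simulate_study(cfg)
  # GPP shares the greenness factor with NDVI; LST is only weakly
  # (negatively) coupled, so across timepoints its correlation stays low
  r_ndvi <- r_lst <- numeric(3)
  for (t in 1:3) {
    gpp <- sim$panels$GPP$values[, t]
    r_ndvi[t] <- cor(gpp, sim$panels$NDVI$values[, t])
    r_lst[t] <- cor(gpp, sim$panels$LST$values[, t])
  }
  expect_true(all(r_ndvi > r_lst))
  expect_true(all(r_ndvi > 0.5))
  expect_lt(mean(r_lst), 0.15)
})

test_that("LE tracks the lagged CEI at the analytic correlation strength", {
  # with LE = 73 + beta * z(CEI_lag) + noise, r = beta / sqrt(beta^2 + sd^2)
  cfg <- synthetic_config(beta_le = 2, noise_sd_le = 0.1, lag_m = 1, seed = 21)
  sim <- simulate_study(cfg)
  r <- cor(sim$le$values[, 3], sim$cei$values[, 2])
  expect_gt(r, 0.9)

  cfg0 <- synthetic_config(beta_le = 0, noise_sd_le = 0, seed = 22)
  sim0 <- simulate_study(cfg0)
  expect_true(all(sim0$le$values == 73))
})

test_that("lag_m at or beyond the number of timepoints is rejected", {
  expect_error(synthetic_config(lag_m = 3), "lag_m")
  cfg <- synthetic_config(lag_m = 1)
  cfg$lag_m <- 5L
  sim <- simulate_study(synthetic_config(seed = 1))
  expect_error(generate_le_panel(cfg, sim$cei), "lag_m")
})

test_that("rasters reproduce the panel under zonal means", {
  cfg <- synthetic_config(seed = 31, pixels_per_region = 3,
                          raster_noise_sd = 0)
  sim <- simulate_study(cfg)
  rs <- generate_rasters(cfg, sim$panels$NDVI)
  zm <- zonal_mean(rs[[1]], sim$regions)
  expect_equal(unname(zm), unname(sim$panels$NDVI$values[, 1]),
               tolerance = 1e-12)

  # noisy pixels: zonal-mean error shrinks as s / sqrt(p^2)
  cfgn <- synthetic_config(seed = 32, pixels_per_region = 8,
                           raster_noise_sd = 0.5)
  simn <- simulate_study(cfgn)
  rsn <- generate_rasters(cfgn, simn$panels$NDVI)
  errs <- zonal_mean(rsn[[1]], simn$regions) - simn$panels$NDVI$values[, 1]
  expect_lt(sd(errs), 3 * 0.5 / 8)  # s.e. = s / sqrt(64)
})

test_that("nodata pixels leave zonal means finite", {
  cfg <- synthetic_config(seed = 33, pixels_per_region = 5)
  sim <- simulate_study(cfg)
  r <- generate_rasters(cfg, sim$panels$GPP)[[1]]
  set.seed(1)
  kill <- sample(length(r$values), round(0.1 * length(r$values)))
  mask <- r$nodata
  mask[kill] <- TRUE
  r2 <- raster_grid(r$values, r$xll, r$yll, r$cellsize, nodata = mask)
  zm <- zonal_mean(r2, sim$regions)
  expect_true(all(is.finite(zm)))
})
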