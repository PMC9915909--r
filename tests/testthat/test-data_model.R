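test_that("panel CSV reading ingests the published LE table", {
  path <- system.file("extdata", "le_study_cities.csv", package = "ecolag")
  le <- read_panel_csv(path, "LE")
  expect_s3_class(le, "panel_table")
  expect_length(le$region_ids, 16L)
  expect_equal(le$years, c(2010, 2015, 2020))
  expect_false(any(le$missing))
  expect_equal(unname(le$values["Wuwei City", ]), c(71.34, 73.50, 75.66))
})

test_that("panel CSV round-trips finite cells bit-exactly and keeps masks", {
  set.seed(42)
  vals <- matrix(rnorm(12) * 1000, 4, 3)
  vals[2, 3] <- NA
  p <- panel_table(vals, paste0("g", 1:4), c(2000, 2005, 2010), "X")
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(p, f)
  p2 <- read_panel_csv(f, "X")
  expect_identical(p2$values[!p2$missing], p$values[!p$missing])
  expect_identical(p2$missing, p$missing)
  expect_identical(p2$region_ids, p$region_ids)
})

test_that("panel CSV errors on degenerate input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), f)
  expect_error(read_panel_csv(f, "X"))

  writeLines(c("region_id,2010,2015", "a,1,2", "a,3,4"), f)
  expect_error(read_panel_csv(f, "X"), "duplicate region id.*a")

  writeLines(c("region_id,2010,2015", "a,1,two"), f)
  expect_error(read_panel_csv(f, "X"), "row 1.*2015")
})

test_that("blank cells become missing-mask entries, not zeros", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("region_id,2010,2015,2020", "a,70,,74", "b,71,72,73"), f)
  p <- read_panel_csv(f, "LE")
  expect_true(p$missing[1, 2])
  expect_equal(sum(p$missing), 1L)
  expect_true(all(is.finite(p$values[!p$missing])))
})

test_that("interpolation fills interior gaps linearly and edges by extrapolation", {
  p <- panel_table(matrix(c(70, NA, 74,
                            NA, 73.5, 75.66), 2, 3, byrow = TRUE),
                   c("mid", "lead"), c(2010, 2015, 2020), "LE")
  out <- interpolate_missing(p)
  expect_equal(unname(out$values["mid", "2015"]), 72)
  # backward extrapolation with slope (75.66 - 73.5)/5 lands on 71.34,
  # matching the published Wuwei series
  expect_equal(unname(out$values["lead", "2010"]), 71.34)
  expect_false(any(out$missing))
  expect_identical(unname(out$filled["mid", ]), c(FALSE, TRUE, FALSE))
  expect_identical(unname(out$filled["lead", ]), c(TRUE, FALSE, FALSE))
})

test_that("interpolation is idempotent, exact on affine ramps, and errors on empty regions", {
  # affine ramp: any missing pattern with >= 2 observations recovers exactly
  t <- c(2000, 2004, 2010, 2018)
  set.seed(7)
  for (rep in 1:20) {
    a <- rnorm(1); b <- rnorm(1)
    y <- a + b * t
    miss <- sample(c(TRUE, FALSE), 4, replace = TRUE)
    if (sum(!miss) < 2) miss[sample(4, 2)] <- FALSE
    v <- y; v[miss] <- NA
    p <- panel_table(matrix(v, 1), "r", t, "X")
    out <- interpolate_missing(p)
    expect_equal(unname(out$values[1, ]), y, tolerance = 1e-12)
  }

  full <- panel_table(matrix(1:6, 2), c("a", "b"), c(1, 2, 3), "X")
  again <- interpolate_missing(interpolate_missing(full))
  expect_equal(again$values, full$values)
  expect_false(any(again$filled))

  empty <- panel_table(matrix(NA_real_, 1, 3), "ghost", c(1, 2, 3), "X")
  expect_error(interpolate_missing(empty), "ghost")
})

test_that("single observed timepoint fills with a constant", {
  p <- panel_table(matrix(c(NA, 72, NA), 1), "r", c(2010, 2015, 2020), "LE")
  out <- interpolate_missing(p)
  expect_equal(unname(out$values[1, ]), c(72, 72, 72))
})

test_that("GeoJSON regions round-trip with geometry and ids preserved", {
  regions <- grid_regions(4)
  expect_length(regions$ids, 16L)
  f <- withr::local_tempfile(fileext = ".geojson")
  write_regions_geojson(regions, f)
  back <- read_regions_geojson(f)
  expect_identical(back$ids, regions$ids)
  expect_equal(back$geometry[[1]]$rings[[1]], regions$geometry[[1]]$rings[[1]])
})

test_that("GeoJSON reader rejects malformed inputs", {
  f <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(),
         geometry = list(type = "Polygon",
                         coordinates = list(list(c(0, 0), c(1, 0), c(0, 1))))))),
    f, auto_unbox = TRUE, digits = NA)
  expect_error(read_regions_geojson(f), "id")

  jsonlite::write_json(list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(id = "p"),
         geometry = list(type = "Point", coordinates = c(0, 0))))),
    f, auto_unbox = TRUE, digits = NA)
  expect_error(read_regions_geojson(f), "non-polygon")

  # a single triangle feature is a valid one-region set
  jsonlite::write_json(list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(id = "tri"),
         geometry = list(type = "Polygon",
                         coordinates = list(list(c(0, 0), c(1, 0), c(0, 1),
                                                 c(0, 0))))))),
    f, auto_unbox = TRUE, digits = NA)
  tri <- read_regions_geojson(f)
  expect_identical(tri$ids, "tri")
})

test_that("ASCII grid raster round-trips values and nodata", {
  set.seed(3)
  m <- matrix(rnorm(20), 4, 5)
  m[2, 2] <- NA
  r <- raster_grid(m, xll = 10, yll = -3, cellsize = 0.5, variable = "LST")
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, f)
  r2 <- read_ascii_grid(f, variable = "LST")
  expect_identical(r2$values[!r2$nodata], r$values[!r$nodata])
  expect_identical(r2$nodata, r$nodata)
  expect_equal(r2$cellsize, 0.5)
  expect_equal(r2$xll, 10)
})
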