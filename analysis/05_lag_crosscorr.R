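#!/usr/bin/env Rscript
# The headline analysis: Pearson lag correlations and global/local
# bivariate Moran's I between life expectancy and each ecological index,
# with the covariate taken from the same year (lag 0) or an earlier year
# (5- and 10-year spatiotemporal lags), plus LISA cluster labels for the
# CEI designs and the pooled lag ranking.
suppressPackageStartupMessages(library(ecolag))

regions <- read_regions_geojson("results/data/regions.geojson")
w <- suppressWarnings(row_standardize(queen_contiguity(regions)))
le <- read_panel_csv("results/data/le.csv", "LE")
x_panels <- c(
  sapply(c("NDVI", "LAI", "GPP", "LST", "Wet"), function(nm)
    read_panel_csv(file.path("results/data", paste0(tolower(nm), ".csv")), nm),
    simplify = FALSE),
  list(CEI = read_panel_csv("results/cei.csv", "CEI")))

pairs <- default_lag_pairs(le$years)
rows <- list(); lisa_rows <- list()
for (nm in names(x_panels)) {
  xp <- x_panels[[nm]]
  for (r in seq_len(nrow(pairs))) {
    xt <- pairs$x_time[r]; yt <- pairs$y_time[r]
    x <- xp$values[, match(xt, xp$years)]
    y <- le$values[, match(yt, le$years)]
    cm <- cross_moran(y = y, x_lagged = x, w = w, n_perm = 999,
                      seed = 1000L + 100L * match(nm, names(x_panels)) + r)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = nm, x_time = xt, y_time = yt, lag_years = yt - xt,
      pearson_r = cor(x, y), moran_I = cm$global_I, p_value = cm$p_value)
    if (nm == "CEI")
      lisa_rows[[length(lisa_rows) + 1L]] <- data.frame(
        x_time = xt, y_time = yt, region_id = w$ids,
        local_I = unname(cm$local_I), local_p = unname(cm$local_p),
        cluster = unname(cm$cluster))
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/crosscorr.csv", row.names = FALSE)
write.csv(do.call(rbind, lisa_rows), "results/lisa.csv", row.names = FALSE)

cat("strongest lagged associations with LE (|Moran I|):\n")
lag_tab <- tab[tab$lag_years > 0, ]
print(head(lag_tab[order(-abs(lag_tab$moran_I)),
                   c("variable", "x_time", "y_time", "pearson_r",
                     "moran_I", "p_value")], 6), row.names = FALSE)

sim <- simulate_study(synthetic_config())  # same defaults as 01_simulate
rk <- lag_recovery_rank(sim)
cat("\npooled |I| lag ranking (CEI):\n")
print(rk, row.names = FALSE)
cat(sprintf("-> the %d-year lag ranks first (true lag: 5 years)\n",
            rk$lag_years[1]))
cat("tables written to results/crosscorr.csv and results/lisa.csv\n")
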