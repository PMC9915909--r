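#!/usr/bin/env Rscript
# Getis-Ord Gi* cold/hot-spot z-scores per region, indicator and year,
# on binary queen-contiguity weights with self-inclusion.
suppressPackageStartupMessages(library(ecolag))

regions <- read_regions_geojson("results/data/regions.geojson")
w <- queen_contiguity(regions)

vars <- c(NDVI = "results/data/ndvi.csv", LAI = "results/data/lai.csv",
          GPP = "results/data/gpp.csv", LST = "results/data/lst.csv",
          Wet = "results/data/wet.csv", CEI = "results/cei.csv")

tab <- do.call(rbind, lapply(names(vars), function(nm) {
  p <- read_panel_csv(vars[[nm]], nm)
  do.call(rbind, lapply(seq_along(p$years), function(t) {
    gs <- gi_star(p$values[, t], w)
    data.frame(variable = nm, year = p$years[t], region_id = w$ids,
               z = unname(gs$z), category = unname(gs$category))
  }))
}))
write.csv(tab, "results/hotspots.csv", row.names = FALSE)

sig <- tab[tab$category != "not_significant", ]
cat(nrow(sig), "of", nrow(tab), "region-year cells are significant cold/hot spots\n")
if (nrow(sig)) print(table(sig$variable, sig$category))
cat("hotspot table written to results/hotspots.csv\n")
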