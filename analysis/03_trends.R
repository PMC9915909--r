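#!/usr/bin/env Rscript
# Theil-Sen slopes and Mann-Kendall tests per region for every indicator,
# the CEI, and life expectancy (3 timepoints, slopes in units per year).
suppressPackageStartupMessages(library(ecolag))

vars <- c("NDVI", "LAI", "GPP", "LST", "Wet", "CEI", "LE")
paths <- file.path("results",
                   c(rep("data", 5), ".", "data"),
                   c("ndvi.csv", "lai.csv", "gpp.csv", "lst.csv", "wet.csv",
                     "cei.csv", "le.csv"))

tab <- do.call(rbind, Map(function(nm, p) {
  cbind(variable = nm, trend_panel(read_panel_csv(p, nm)))
}, vars, paths))
write.csv(tab, "results/trends.csv", row.names = FALSE)

for (nm in vars) {
  sub <- tab[tab$variable == nm, ]
  cat(sprintf("%-4s median Sen slope %+.4g per year; %d/%d regions rising\n",
              nm, median(sub$beta), sum(sub$beta > 0), nrow(sub)))
}
cat("per-region trends written to results/trends.csv\n")
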