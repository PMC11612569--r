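#!/usr/bin/env Rscript
# Simulate the study landscape: three dates of land use on a 100x100 km
# grid (east forest belt, central cropland/urban core, western
# grassland/saline mix) plus the seven driver covariate rasters for the
# first date. Everything downstream (02-05) reads these files.

suppressMessages(library(habiquant))
set.seed(2026)

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lp <- landscape_params(nrows = 100, ncols = 100, cell_size = 1, seed = 2026)
series <- generate_landscape_series(lp, n_dates = 3)
dates <- c("t0", "t1", "t2")
for (k in seq_along(series))
  write_ascii_grid(series[[k]], file.path(out, sprintf("landuse_%s.asc", dates[k])))

covs <- generate_covariate_stack(series[[1]], sem_truth(seed = 2026), seed = 2026)
for (nm in names(covs))
  write_ascii_grid(covs[[nm]], file.path(out, sprintf("cov_%s.asc", nm)))

cat("Simulated", length(series), "dates of land use on a",
    lp$nrows, "x", lp$ncols, "km grid, and", length(covs),
    "covariate rasters, under", out, "\n")
cat("Per-step conversions (probability/cell):",
    paste(sprintf("%s: %.3f", names(lp$conversions), lp$conversions),
          collapse = ", "), "\n")
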