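#!/usr/bin/env Rscript
# Land-use change accounting: per-date class percentages and the
# transition matrices (areas and row-normalized conversion rates) between
# consecutive simulated dates.

suppressMessages(library(habiquant))

sim <- "results/sim"; out <- "results/landuse"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
legend <- default_parameter_tables()$legend
dates <- c("t0", "t1", "t2")
lus <- lapply(dates, function(d)
  read_ascii_grid(file.path(sim, sprintf("landuse_%s.asc", d))))
names(lus) <- dates

for (d in dates) {
  ap <- area_percentages(lus[[d]], legend)
  write.csv(ap[order(-ap$percent), ],
            file.path(out, sprintf("areas_%s.csv", d)), row.names = FALSE)
}
cat("Class percentages at", dates[1], "(top 4):\n")
ap0 <- area_percentages(lus[[1]], legend)
print(head(ap0[order(-ap0$percent), ], 4), row.names = FALSE)

for (k in 1:2) {
  a <- dates[k]; b <- dates[k + 1]
  tm <- transition_matrix(lus[[a]], lus[[b]], legend)
  write.csv(cbind(from = rownames(tm$areas), as.data.frame(tm$areas)),
            file.path(out, sprintf("transitions_%s_%s.csv", a, b)),
            row.names = FALSE)
  cr <- conversion_rates(tm)
  write.csv(cbind(from = rownames(cr), as.data.frame(round(cr, 2))),
            file.path(out, sprintf("conversion_rates_%s_%s.csv", a, b)),
            row.names = FALSE)
  moved <- 100 * (1 - sum(diag(tm$areas)) / sum(tm$areas))
  cat(sprintf("%s -> %s: %.1f%% of the landscape changed class\n", a, b, moved))
}
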