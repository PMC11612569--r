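#!/usr/bin/env Rscript
# Habitat quality per date: degradation D, quality Q, the five-grade
# area table, and improved/unchanged/degraded change maps between dates.

suppressMessages(library(habiquant))

sim <- "results/sim"; out <- "results/hq"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
p <- default_parameter_tables()
cfg <- hq_config(z = 2.5, k = 0.5)
dates <- c("t0", "t1", "t2")

qs <- list()
for (d in dates) {
  lu <- read_ascii_grid(file.path(sim, sprintf("landuse_%s.asc", d)))
  D <- degradation(lu, p$threats, p$legend, cfg)
  Q <- quality(lu, D, p$legend, cfg)
  qs[[d]] <- Q
  write_ascii_grid(D, file.path(out, sprintf("D_%s.asc", d)))
  write_ascii_grid(Q, file.path(out, sprintf("Q_%s.asc", d)))
  gr <- classify_quality(Q)
  write.csv(gr$table, file.path(out, sprintf("grades_%s.csv", d)),
            row.names = FALSE)
  cat(sprintf("%s: mean HQ %.3f | grades %s\n", d,
              mean(Q$values, na.rm = TRUE),
              paste(sprintf("%s %.1f%%", gr$table$grade, gr$table$percent),
                    collapse = ", ")))
}

for (k in 1:2) {
  a <- dates[k]; b <- dates[k + 1]
  cm <- change_map(qs[[a]], qs[[b]], eps = 0.01)
  write.csv(cm$table, file.path(out, sprintf("change_%s_%s.csv", a, b)),
            row.names = FALSE)
  cat(sprintf("%s -> %s: improved %.1f%%, unchanged %.1f%%, degraded %.1f%%\n",
              a, b, cm$table$percent[1], cm$table$percent[2],
              cm$table$percent[3]))
}
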