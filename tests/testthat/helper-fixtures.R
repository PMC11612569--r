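# Shared fixtures and independent brute-force oracles.

# minimal legend: classes 1 (habitat) and 9 (urban-like source, H = 0)
tiny_legend <- function(S1 = 0.5, S9 = 0) {
  landuse_legend(
    data.frame(code = c(1, 9), name = c("habitat", "urban"),
               H = c(0.8, 0), stringsAsFactors = FALSE),
    matrix(c(S1, S9), 2, 1, dimnames = list(NULL, "urban"))
  )
}

tiny_threat <- function(d_rmax = 2, weight = 1, decay = "exponential") {
  threat_spec("urban", 9, d_rmax = d_rmax, weight = weight, decay = decay)
}

# quadruple loop over (cell x, source y, threat r): the reference
# implementation of the degradation sum
brute_degradation <- function(lu, threats, legend, beta = 1) {
  v <- lu$values
  nr <- nrow(v); nc <- ncol(v)
  wsum <- sum(vapply(threats, `[[`, numeric(1), "weight"))
  D <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(v[i, j])) next
    acc <- 0
    for (tr in threats) {
      S <- sensitivity_to(legend, v[i, j], tr$name)
      for (yi in seq_len(nr)) for (yj in seq_len(nc)) {
        if (is.na(v[yi, yj]) || !(v[yi, yj] %in% tr$source_codes)) next
        d <- lu$cell_size * sqrt((i - yi)^2 + (j - yj)^2)
        if (d > tr$d_rmax) next
        irxy <- if (tr$decay == "linear") max(0, 1 - d / tr$d_rmax)
                else exp(-2.99 * d / tr$d_rmax)
        acc <- acc + (tr$weight / wsum) * irxy * beta * S
      }
    }
    D[i, j] <- acc
  }
  D
}

lattice_nbrs <- function(nr, nc, i, j, scheme) {
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (scheme == "queen")
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  out <- list()
  for (o in offs) {
    ii <- i + o[1]; jj <- j + o[2]
    if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
      out[[length(out) + 1]] <- c(ii, jj)
  }
  out
}

# double sum over all cell pairs
brute_moran <- function(vals, scheme = "queen", row_standardized = TRUE) {
  nr <- nrow(vals); nc <- ncol(vals)
  cells <- which(!is.na(vals), arr.ind = TRUE)
  n <- nrow(cells)
  x <- vals[cells]
  z <- x - mean(x)
  key <- paste(cells[, 1], cells[, 2])
  deg <- numeric(n); cross <- 0; S0 <- 0
  for (a in seq_len(n)) {
    nb <- lattice_nbrs(nr, nc, cells[a, 1], cells[a, 2], scheme)
    nb <- Filter(function(p) !is.na(vals[p[1], p[2]]), nb)
    deg[a] <- length(nb)
  }
  for (a in seq_len(n)) {
    nb <- lattice_nbrs(nr, nc, cells[a, 1], cells[a, 2], scheme)
    for (p in nb) {
      b <- match(paste(p[1], p[2]), key)
      if (is.na(b)) next
      w <- if (row_standardized) 1 / deg[a] else 1
      cross <- cross + w * z[a] * z[b]
      S0 <- S0 + w
    }
  }
  (n / S0) * cross / sum(z^2)
}

# per-cell Gi* statistic, self included, binary weights
brute_gi_z <- function(vals, scheme = "queen") {
  nr <- nrow(vals); nc <- ncol(vals)
  cells <- which(!is.na(vals), arr.ind = TRUE)
  n <- nrow(cells)
  x <- vals[cells]
  xbar <- mean(x); s <- sqrt(sum(x^2) / n - xbar^2)
  z <- matrix(NA_real_, nr, nc)
  for (a in seq_len(n)) {
    i <- cells[a, 1]; j <- cells[a, 2]
    nb <- lattice_nbrs(nr, nc, i, j, scheme)
    nb <- Filter(function(p) !is.na(vals[p[1], p[2]]), nb)
    xs <- vals[i, j] + sum(vapply(nb, function(p) vals[p[1], p[2]], numeric(1)))
    Wi <- length(nb) + 1
    z[i, j] <- (xs - xbar * Wi) / (s * sqrt((n * Wi - Wi^2) / (n - 1)))
  }
  z
}

checkerboard <- function(nr, nc) {
  outer(seq_len(nr), seq_len(nc), function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
}

sample_skewness <- function(x) {
  z <- (x - mean(x)) / sd(x)
  mean(z^3)
}

random_landuse <- function(nr, nc, codes = c(1, 9), p_na = 0,
                           cell_size = 1) {
  v <- matrix(sample(codes, nr * nc, replace = TRUE), nr, nc)
  if (p_na > 0) v[runif(nr * nc) < p_na] <- NA
  hq_grid(v, cell_size = cell_size)
}
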