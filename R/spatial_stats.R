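#' Lattice spatial weights specification
#'
#' Contiguity weights on the raster lattice. Nodata cells are removed from
#' the graph entirely; no neighbor relation crosses them. Moran's I
#' conventionally uses row-standardized weights; Gi* uses binary weights
#' with the cell itself included in its neighborhood.
#'
#' @param scheme `"queen"` (8 neighbors, default) or `"rook"` (4).
#' @param row_standardized standardize each row of W to sum 1?
#' @param include_self include the focal cell (used by Gi*)?
#' @return a `spatial_weights` specification.
#' @export
spatial_weights <- function(scheme = c("queen", "rook"),
                            row_standardized = TRUE,
                            include_self = FALSE) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme, row_standardized = row_standardized,
                 include_self = include_self),
            class = "spatial_weights")
}

# directed edge list (i, j) over valid (non-NA) cells; both directions
# present; ids index the vector of valid cells in column-major order
lattice_edges <- function(valid, scheme) {
  nr <- nrow(valid); nc <- ncol(valid)
  ids <- matrix(NA_integer_, nr, nc)
  ids[valid] <- seq_len(sum(valid))
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (scheme == "queen")
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  ii <- integer(0); jj <- integer(0)
  for (o in offs) {
    di <- o[1]; dj <- o[2]
    it <- max(1, 1 - di):min(nr, nr - di)
    jt <- max(1, 1 - dj):min(nc, nc - dj)
    a <- ids[it, jt, drop = FALSE]
    b <- ids[it + di, jt + dj, drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    ii <- c(ii, a[keep]); jj <- c(jj, b[keep])
  }
  list(i = ii, j = jj, n = sum(valid))
}

#' Global Moran's I of a gridded surface
#'
#' \deqn{I = \frac{n}{S_0}\,
#'   \frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x)}{\sum_i (x_i-\bar x)^2}}
#' with expectation \eqn{E[I] = -1/(n-1)} and a z standard score from the
#' randomization-assumption variance. Positive I indicates spatial
#' clustering of like values, negative I dispersion.
#'
#' @param values an [hq_grid()]; NA cells are excluded from the graph.
#' @param weights a [spatial_weights()]; default queen, row-standardized.
#' @return list with elements `I`, `expectation`, `variance`, `z`, `n`.
#' @export
morans_i <- function(values, weights = spatial_weights()) {
  v <- values$values
  valid <- !is.na(v)
  n <- sum(valid)
  if (n < 2) stop("need at least 2 valid cells")
  x <- v[valid]
  z <- x - mean(x)
  m2 <- sum(z^2)
  if (m2 == 0) stop("zero variance: constant surface")
  ed <- lattice_edges(valid, weights$scheme)
  if (!length(ed$i)) stop("no neighbor pairs on this grid")
  deg <- tabulate(ed$i, nbins = n)
  w <- if (weights$row_standardized) 1 / deg[ed$i] else rep(1, length(ed$i))
  S0 <- sum(w)
  cross <- sum(w * z[ed$i] * z[ed$j])
  I <- (n / S0) * cross / m2
  EI <- -1 / (n - 1)
  # randomization variance (S1, S2 from the weight structure, b2 kurtosis)
  wji <- if (weights$row_standardized) 1 / deg[ed$j] else rep(1, length(ed$j))
  S1 <- 0.5 * sum((w + wji)^2)
  rs <- vapply(split(w, ed$i), sum, numeric(1))
  row_sum <- numeric(n); row_sum[as.integer(names(rs))] <- rs
  cs <- vapply(split(w, ed$j), sum, numeric(1))
  col_sum <- numeric(n); col_sum[as.integer(names(cs))] <- cs
  S2 <- sum((row_sum + col_sum)^2)
  b2 <- n * sum(z^4) / m2^2
  num <- n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
    b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)
  VarI <- num / ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  list(I = I, expectation = EI, variance = VarI,
       z = (I - EI) / sqrt(VarI), n = n)
}

hotspot_class_names <- c("coldspot99", "coldspot95", "coldspot90",
                         "not_significant",
                         "hotspot90", "hotspot95", "hotspot99")

classify_gi_z <- function(z) {
  cls <- numeric(length(z))
  cls[z >= 1.645] <- 1; cls[z >= 1.960] <- 2; cls[z >= 2.576] <- 3
  cls[z <= -1.645] <- -1; cls[z <= -1.960] <- -2; cls[z <= -2.576] <- -3
  cls
}

#' Getis-Ord Gi* hot/cold-spot classification
#'
#' Per-cell Gi* standard score with the focal cell included in its own
#' neighborhood:
#' \deqn{G_i^* = \frac{\sum_j w_{ij} x_j - \bar X W_i}
#'   {S \sqrt{\left(n S_{1i} - W_i^2\right)/(n-1)}}}
#' where \eqn{W_i = \sum_j w_{ij}}, \eqn{S_{1i} = \sum_j w_{ij}^2}, and
#' \eqn{\bar X}, \eqn{S} are the mean and population sd over all valid
#' cells. Cells are classed by |z| thresholds 1.645 / 1.960 / 2.576
#' (90 / 95 / 99% confidence), sign separating hotspots from coldspots.
#'
#' @param values an [hq_grid()].
#' @param weights a [spatial_weights()]; the default for Gi* is queen,
#'   binary, self-included.
#' @return list with `z_grid` (Gi* scores), `class_grid` (codes -3..3),
#'   `table` (7-row percent table over valid cells, summing to 100), and
#'   `classes` (the class labels in code order).
#' @export
gi_star <- function(values,
                    weights = spatial_weights(row_standardized = FALSE,
                                              include_self = TRUE)) {
  v <- values$values
  valid <- !is.na(v)
  n <- sum(valid)
  if (n < 2) stop("need at least 2 valid cells")
  x <- v[valid]
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  if (s == 0) stop("zero variance: constant surface")
  ed <- lattice_edges(valid, weights$scheme)
  nbr_sum <- numeric(n); cnt <- numeric(n)
  sl <- vapply(split(x[ed$j], ed$i), sum, numeric(1))
  nbr_sum[as.integer(names(sl))] <- sl
  cnt <- tabulate(ed$i, nbins = n)
  if (weights$include_self) {
    nbr_sum <- nbr_sum + x
    cnt <- cnt + 1
  }
  Wi <- cnt                       # binary weights: W_i = S_1i = #neighbors
  S1i <- cnt
  zscore <- (nbr_sum - xbar * Wi) /
    (s * sqrt(pmax(n * S1i - Wi^2, 0) / (n - 1)))
  cls <- classify_gi_z(zscore)
  zg <- matrix(NA_real_, nrow(v), ncol(v)); zg[valid] <- zscore
  cg <- matrix(NA_real_, nrow(v), ncol(v)); cg[valid] <- cls
  counts <- vapply(-3:3, function(k) sum(cls == k), numeric(1))
  tab <- data.frame(class = hotspot_class_names,
                    percent = counts / n * 100,
                    stringsAsFactors = FALSE)
  list(z_grid = hq_grid(zg, cell_size = values$cell_size,
                        origin = values$origin, nodata = values$nodata),
       class_grid = hq_grid(cg, cell_size = values$cell_size,
                            origin = values$origin, nodata = values$nodata),
       table = tab, classes = hotspot_class_names)
}
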