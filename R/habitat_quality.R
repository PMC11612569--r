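#' Habitat-quality model configuration
#'
#' Parameters of the saturating quality response: the exponent `z`
#' (dimensionless shape of the degradation penalty), the half-saturation
#' constant `k` (the degradation level at which quality is halved, on the
#' same scale as D), and the accessibility `beta` in \[0,1\] (scalar, or an
#' [hq_grid()] for spatially varying accessibility). Defaults follow the
#' InVEST habitat-quality convention: z = 2.5, k = 0.5, beta = 1.
#'
#' @param z exponent, > 0.
#' @param k half-saturation constant, > 0, or the string `"half_max"` to
#'   use half the maximum observed degradation (the common alternative
#'   calibration when D's scale is landscape-dependent).
#' @param beta accessibility, scalar in \[0,1\] or a grid of such values.
#' @return an `hq_config` list.
#' @export
hq_config <- function(z = 2.5, k = 0.5, beta = 1) {
  stopifnot(is.numeric(z), length(z) == 1, z > 0)
  if (is.character(k)) {
    if (!identical(k, "half_max")) stop("k must be > 0 or \"half_max\"")
  } else stopifnot(is.numeric(k), length(k) == 1, k > 0)
  if (inherits(beta, "hq_grid")) {
    b <- beta$values
    if (any(b[!is.na(b)] < 0 | b[!is.na(b)] > 1))
      stop("beta grid values must lie in [0,1]")
  } else {
    stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0, beta <= 1)
  }
  structure(list(z = z, k = k, beta = beta), class = "hq_config")
}

#' Binary presence grid of a threat's source cells
#'
#' @param lu land-use grid.
#' @param threat a [threat_spec()].
#' @param legend a [landuse_legend()] used to validate codes.
#' @return an [hq_grid()] with 1 on source cells, 0 elsewhere, NA where the
#'   land use is nodata.
#' @export
threat_presence <- function(lu, threat, legend) {
  v <- lu$values
  suitability(legend, unique(v[!is.na(v)]))  # errors on unknown codes
  p <- matrix(as.numeric(v %in% threat$source_codes), nrow(v), ncol(v))
  p[is.na(v)] <- NA_real_
  hq_grid(p, cell_size = lu$cell_size, origin = lu$origin, nodata = lu$nodata)
}

#' Distance-decay kernel weight
#'
#' Impact of a threat source at distance `d` km: linear decay
#' \eqn{\max(0, 1 - d/d_{r,max})}, exponential decay
#' \eqn{\exp(-2.99\, d/d_{r,max})}. Both kernels are truncated to 0
#' strictly beyond the maximum influence distance, and both equal 1 at
#' d = 0.
#'
#' @param d distance(s) in km, >= 0 (vectorized).
#' @param threat a [threat_spec()] supplying `d_rmax` and `decay`.
#' @return weight(s) in \[0,1\].
#' @export
decay_factor <- function(d, threat) {
  if (any(d < 0)) stop("distance must be non-negative")
  w <- if (threat$decay == "linear") {
    pmax(0, 1 - d / threat$d_rmax)
  } else {
    exp(-2.99 * d / threat$d_rmax)
  }
  w[d > threat$d_rmax] <- 0
  w
}

# decay weights over all integer cell offsets within d_rmax; returns a
# data.frame of (di, dj, w) with the zero offset included at weight 1
kernel_offsets <- function(threat, cell_size) {
  r <- floor(threat$d_rmax / cell_size)
  off <- expand.grid(di = -r:r, dj = -r:r)
  d <- cell_size * sqrt(off$di^2 + off$dj^2)
  w <- decay_factor(d, threat)
  keep <- w > 0
  data.frame(di = off$di[keep], dj = off$dj[keep], w = w[keep])
}

# sum over source cells of the decay kernel: L[x] = sum_y P[y] * i(d_xy),
# computed by shift-and-accumulate over kernel offsets
threat_load <- function(presence, threat, cell_size) {
  p <- presence
  p[is.na(p)] <- 0
  nr <- nrow(p); nc <- ncol(p)
  off <- kernel_offsets(threat, cell_size)
  L <- matrix(0, nr, nc)
  for (k in seq_len(nrow(off))) {
    di <- off$di[k]; dj <- off$dj[k]; w <- off$w[k]
    # target rows i receive from source rows i + di
    it <- max(1, 1 - di):min(nr, nr - di)
    jt <- max(1, 1 - dj):min(nc, nc - dj)
    if (!length(it) || !length(jt)) next
    L[it, jt] <- L[it, jt] + w * p[it + di, jt + dj]
  }
  L
}

#' Habitat degradation surface D
#'
#' Accumulates, for every cell x, the distance-decayed pressure of all
#' threat-source cells:
#' \deqn{D_x = \sum_r \sum_{y \in Y_r} \frac{\omega_r}{\sum_r \omega_r}
#'   \; i_r(d_{xy}) \; \beta_x \; S_{j(x),r}}
#' with \eqn{i_r} the threat's decay kernel ([decay_factor()]) on the
#' center-to-center Euclidean distance, truncated at \eqn{d_{r,max}}.
#' Weights are normalized by their sum, so rescaling all weights by a
#' common positive factor leaves D unchanged. A source cell whose own class
#' is sensitive to its threat receives that threat at distance 0.
#'
#' @param lu land-use grid.
#' @param threats list of [threat_spec()].
#' @param legend a [landuse_legend()].
#' @param config an [hq_config()] (supplies beta).
#' @return degradation grid D >= 0, NA where land use is nodata.
#' @export
degradation <- function(lu, threats, legend, config = hq_config()) {
  if (!length(threats)) stop("at least one threat is required")
  wsum <- sum(vapply(threats, `[[`, numeric(1), "weight"))
  if (wsum <= 0) stop("all threat weights are zero")
  v <- lu$values
  D <- matrix(0, nrow(v), ncol(v))
  for (tr in threats) {
    pres <- threat_presence(lu, tr, legend)
    L <- threat_load(pres$values, tr, lu$cell_size)
    S <- matrix(sensitivity_to(legend, as.vector(v), tr$name),
                nrow(v), ncol(v))
    S[is.na(S)] <- 0
    D <- D + (tr$weight / wsum) * S * L
  }
  if (inherits(config$beta, "hq_grid")) {
    stop_geometry(lu, config$beta, "land use and beta grids")
    D <- D * config$beta$values
  } else {
    D <- D * config$beta
  }
  D[is.na(v)] <- NA_real_
  hq_grid(D, cell_size = lu$cell_size, origin = lu$origin, nodata = lu$nodata)
}

#' Habitat quality surface Q
#'
#' Converts degradation into quality through a saturating penalty on the
#' class's intrinsic suitability:
#' \deqn{Q_x = H_{j(x)} \left(1 - \frac{D_x^z}{D_x^z + k^z}\right)}
#' so Q = H at D = 0, Q = H/2 at D = k, and Q decreases monotonically in D.
#'
#' @param lu land-use grid (supplies the class, hence H).
#' @param D degradation grid from [degradation()].
#' @param legend a [landuse_legend()].
#' @param config an [hq_config()] (supplies z and k).
#' @return quality grid with values in \[0, 1\].
#' @export
quality <- function(lu, D, legend, config = hq_config()) {
  stop_geometry(lu, D, "land use and degradation grids")
  v <- lu$values
  H <- matrix(suitability(legend, as.vector(v)), nrow(v), ncol(v))
  d <- D$values
  if (any(d[!is.na(d)] < 0)) stop("degradation must be non-negative")
  k <- if (identical(config$k, "half_max")) {
    km <- max(d, na.rm = TRUE) / 2
    if (km <= 0) 0.5 else km
  } else config$k
  q <- H * (1 - d^config$z / (d^config$z + k^config$z))
  q[is.na(v) | is.na(d)] <- NA_real_
  hq_grid(q, cell_size = lu$cell_size, origin = lu$origin, nodata = lu$nodata)
}

hq_grade_names <- c("lowest", "lower", "medium", "higher", "highest")

#' Five-grade classification of a quality surface
#'
#' Grades are assigned by the half-open bins \[0, 0.2), \[0.2, 0.4),
#' \[0.4, 0.6), \[0.6, 0.8), \[0.8, 1\] (left-closed, with 1 included in
#' "highest").
#'
#' @param Q quality grid with values in \[0,1\].
#' @return list with `grid` (grade codes 1..5 as an [hq_grid()]) and
#'   `table` (data.frame grade/percent over valid cells, summing to 100).
#' @export
classify_quality <- function(Q) {
  q <- Q$values
  val <- q[!is.na(q)]
  if (!length(val)) stop("empty valid area")
  if (any(val < 0 | val > 1)) stop("quality values outside [0,1]")
  g <- findInterval(q, c(0, 0.2, 0.4, 0.6, 0.8), rightmost.closed = FALSE)
  g[!is.na(q) & q >= 1] <- 5L
  g <- matrix(as.numeric(g), nrow(q), ncol(q))
  counts <- tabulate(g[!is.na(q)], nbins = 5)
  tab <- data.frame(grade = hq_grade_names,
                    percent = counts / sum(counts) * 100,
                    stringsAsFactors = FALSE)
  list(grid = hq_grid(g, cell_size = Q$cell_size, origin = Q$origin,
                      nodata = Q$nodata),
       table = tab)
}

#' Habitat-quality change map between two dates
#'
#' Cells are classed improved when quality rose by more than `eps`,
#' degraded when it fell by more than `eps`, unchanged otherwise.
#'
#' @param Q_a,Q_b quality grids at the earlier and later date.
#' @param eps tolerance below which a change counts as unchanged
#'   (default 0.01, one quality unit at reporting precision).
#' @return list with `grid` (-1 degraded / 0 unchanged / +1 improved) and
#'   `table` (percent improved/unchanged/degraded, summing to 100).
#' @export
change_map <- function(Q_a, Q_b, eps = 0.01) {
  stop_geometry(Q_a, Q_b, "quality grids")
  if (eps < 0) stop("eps must be >= 0")
  d <- Q_b$values - Q_a$values
  cls <- matrix(0, nrow(d), ncol(d))
  cls[d > eps] <- 1
  cls[d < -eps] <- -1
  cls[is.na(d)] <- NA_real_
  n <- sum(!is.na(d))
  if (!n) stop("empty valid area")
  tab <- data.frame(
    trend = c("improved", "unchanged", "degraded"),
    percent = c(sum(cls == 1, na.rm = TRUE),
                sum(cls == 0, na.rm = TRUE),
                sum(cls == -1, na.rm = TRUE)) / n * 100,
    stringsAsFactors = FALSE)
  list(grid = hq_grid(cls, cell_size = Q_a$cell_size, origin = Q_a$origin,
                      nodata = Q_a$nodata),
       table = tab)
}
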