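# Synthetic landscapes and driver tables with known structure.
#
# The generators state a small world that mirrors the qualitative
# structure of the plain the package's default parameters describe:
# an eastern forest belt, a central cropland core carrying the urban and
# rural patches, and a western grassland/saline mix; later dates apply
# cell-independent Bernoulli conversions (cropland expansion). Covariates
# are smooth fields plus class-linked effects so a known driver signal is
# recoverable end-to-end.

# white noise smoothed by repeated box blur; marginal sd normalized to 1
smooth_field <- function(nr, nc, radius = max(2L, round(min(nr, nc) / 10)),
                         passes = 2) {
  f <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- 2 * radius + 1
  box <- function(m) {
    # running mean along rows then columns (reflecting edges)
    pad <- function(x, r) c(rev(x[seq_len(r)]), x, rev(x[length(x) - seq_len(r) + 1]))
    sm_vec <- function(x) {
      cs <- cumsum(pad(x, radius))
      (cs[(k):(k + length(x) - 1)] - c(0, cs[seq_len(length(x) - 1)])) / k
    }
    m <- apply(m, 2, sm_vec)
    t(apply(t(m), 2, sm_vec))
  }
  for (i in seq_len(passes)) f <- box(f)
  (f - mean(f)) / stats::sd(f)
}

#' Parameters of the synthetic landscape generator
#'
#' Class proportions default to the composition of the plain the packaged
#' legend describes (dry-farmland dominated, ~12% woodland); the spatial
#' layout places woodland in an eastern belt, cropland with urban/rural
#' patches in the center and grassland/saline in the west. Codes refer to
#' the packaged legend ([default_parameter_tables()]).
#'
#' @param nrows,ncols grid size.
#' @param cell_size cell edge km.
#' @param proportions named numeric vector of class proportions (names are
#'   legend codes as characters); must sum to <= 1, remainder goes to dry
#'   farmland (code 2).
#' @param conversions named numeric vector of per-step conversion
#'   probabilities, names `"from->to"` in legend codes. Defaults emulate a
#'   decade of cropland expansion (paddy->dry 0.09, woodland->dry 0.025,
#'   grassland->dry 0.045, wetland->dry 0.015, paddy->urban 0.01).
#' @param east_width fraction of columns forming the eastern forest belt.
#' @param noise_weight weight of the smooth-noise texture against the
#'   zonal affinity.
#' @param seed RNG seed: generators are pure functions of (params, seed).
#' @return a `landscape_params` list.
#' @export
landscape_params <- function(nrows = 120, ncols = 120, cell_size = 1,
                             proportions = c("1" = 0.06, "3" = 0.12,
                                             "7" = 0.08, "10" = 0.04,
                                             "14" = 0.03, "15" = 0.015,
                                             "18" = 0.05, "19" = 0.06),
                             conversions = c("1->2" = 0.09, "3->2" = 0.025,
                                             "7->2" = 0.045, "19->2" = 0.015,
                                             "1->14" = 0.01),
                             east_width = 0.25, noise_weight = 0.8,
                             seed = 1) {
  stopifnot(all(proportions >= 0), sum(proportions) <= 1,
            all(conversions >= 0 & conversions <= 1))
  structure(list(nrows = nrows, ncols = ncols, cell_size = cell_size,
                 proportions = proportions, conversions = conversions,
                 east_width = east_width, noise_weight = noise_weight,
                 seed = seed),
            class = "landscape_params")
}

# zonal affinity of each generated class: east belt, central core, west
zone_affinity <- function(code, u) {
  east <- u; west <- 1 - u; center <- 1 - abs(u - 0.5) * 2
  switch(code,
         "3" = 2.5 * east,                    # woodland: eastern belt
         "7" = 2.0 * west,                    # grassland: west
         "18" = 1.8 * west,                   # saline-alkali: west
         "19" = 1.2 * west,                   # wetlands: west
         "1" = 1.2 * center,                  # paddy: central core
         "14" = 1.6 * center,                 # urban: central core
         "15" = 1.3 * center,                 # rural settlements
         "10" = 0.6 * center,                 # river: noise-driven
         0)
}

#' Generate a land-use raster series with known dynamics
#'
#' Date 1 realizes the east-forest / central-cropland / west-grassland
#' layout by allocating exactly the requested cell counts per class to the
#' cells with the highest class affinity (zonal preference plus smoothed
#' noise, so classes form patches). Every later date applies the
#' per-step conversion probabilities independently per cell.
#'
#' @param params a [landscape_params()].
#' @param n_dates number of dates (>= 1).
#' @return list of land-use [hq_grid()]s.
#' @export
generate_landscape_series <- function(params, n_dates = 3) {
  stopifnot(inherits(params, "landscape_params"), n_dates >= 1)
  nr <- params$nrows; nc <- params$ncols
  ncell <- nr * nc
  counts <- round(params$proportions * ncell)
  if (sum(counts) > ncell) stop("class proportions infeasible for grid size")
  set.seed(params$seed)
  u <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  lu <- matrix(2, nr, nc)  # dry farmland background takes the remainder
  assigned <- matrix(FALSE, nr, nc)
  # small built classes first so their patches are coherent
  order_codes <- c("14", "15", "10", "18", "19", "1", "3", "7")
  order_codes <- order_codes[order_codes %in% names(counts)]
  for (code in order_codes) {
    aff <- zone_affinity(code, u) +
      params$noise_weight * smooth_field(nr, nc)
    aff[assigned] <- -Inf
    take <- order(aff, decreasing = TRUE)[seq_len(counts[[code]])]
    lu[take] <- as.numeric(code)
    assigned[take] <- TRUE
  }
  out <- list(hq_grid(lu, cell_size = params$cell_size))
  conv <- params$conversions
  for (d in seq_len(n_dates - 1)) {
    prev <- out[[d]]$values
    nxt <- prev
    for (key in names(conv)) {
      ft <- as.numeric(strsplit(key, "->", fixed = TRUE)[[1]])
      idx <- which(prev == ft[1])
      if (!length(idx)) next
      flip <- idx[stats::runif(length(idx)) < conv[[key]]]
      nxt[flip] <- ft[2]
    }
    out[[d + 1]] <- hq_grid(nxt, cell_size = params$cell_size)
  }
  out
}

#' Known-truth generating model for the driver analysis
#'
#' States the standardized loadings and structural coefficients of the
#' three-latent driver model (Topography, Climate, HumanDisturbance ->
#' NDVI -> HQ) used to generate test data and assess parameter recovery.
#' All variables have unit variance under the truth; residual variances
#' are solved from the standardized coefficients.
#'
#' @param loadings named numeric vector `indicator = loading` (sign of
#'   temperature's loading is negative: warmer lowlands, cooler uplands).
#' @param structural data.frame from/to/coef of standardized structural
#'   edges.
#' @param latent_cov covariance between the exogenous Topography and
#'   Climate latents.
#' @param n default sample size for [generate_sem_table()].
#' @param seed RNG seed.
#' @return a `sem_truth` list with the model, the full parameter table and
#'   the implied observed covariance (positive-definite by construction).
#' @export
sem_truth <- function(loadings = c(elevation = 0.9, slope = 0.8,
                                   precipitation = 0.8, temperature = -0.7,
                                   nightlight = 0.85, popdensity = 0.8),
                      structural = data.frame(
                        from = c("Topography", "Topography", "Climate",
                                 "HumanDisturbance", "Topography", "Climate",
                                 "HumanDisturbance", "NDVI"),
                        to = c("HumanDisturbance", "NDVI", "NDVI", "NDVI",
                               "HQ", "HQ", "HQ", "HQ"),
                        coef = c(-0.3, 0.4, 0.3, -0.2, 0.2, 0.2, -0.3, 0.3),
                        stringsAsFactors = FALSE),
                      latent_cov = 0.3, n = 5000, seed = 1) {
  model <- path_model(hq_driver_model())
  pt <- param_table(model)
  # set loadings and structural coefficients
  for (k in seq_len(nrow(pt))) {
    if (pt$type[k] == "loading" && pt$to[k] %in% names(loadings))
      pt$value[k] <- loadings[[pt$to[k]]]
    if (pt$type[k] == "reg") {
      hit <- structural$from == pt$from[k] & structural$to == pt$to[k]
      pt$value[k] <- if (any(hit)) structural$coef[hit][1] else 0
    }
    if (pt$type[k] == "cov") pt$value[k] <- latent_cov
  }
  pt <- solve_unit_variances(model, pt)
  Sigma <- implied_covariance(model, pt)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("truth implies a non-positive-definite covariance")
  structure(list(model = model, pt = pt, Sigma = Sigma,
                 loadings = loadings, structural = structural,
                 latent_cov = latent_cov, n = n, seed = seed),
            class = "sem_truth")
}

# choose residual variances so every variable has unit variance under the
# truth (standardized metric); processes variables in topological order
solve_unit_variances <- function(model, pt) {
  edges <- pt[pt$type %in% c("loading", "reg"), c("from", "to", "value")]
  names(edges) <- c("from", "to", "coef")
  ord <- topological_order(model$vars,
                           stats::setNames(edges[c("from", "to")],
                                           c("from", "to")))
  if (is.null(ord)) stop("cyclic graph")
  Sig <- matrix(0, length(model$vars), length(model$vars),
                dimnames = list(model$vars, model$vars))
  covs <- pt[pt$type == "cov", , drop = FALSE]
  done <- character(0)
  for (v in ord) {
    par_e <- edges[edges$to == v, , drop = FALSE]
    if (!nrow(par_e)) {
      Sig[v, v] <- 1
      pt$value[pt$type == "var" & pt$to == v] <- 1
    } else {
      a <- par_e$coef
      P <- par_e$from
      expl <- as.numeric(t(a) %*% Sig[P, P, drop = FALSE] %*% a)
      resid <- 1 - expl
      if (resid <= 0)
        stop(sprintf("structural coefficients leave no residual variance for %s", v))
      pt$value[pt$type == "var" & pt$to == v] <- resid
      Sig[v, v] <- 1
      for (u in done) {
        cv <- as.numeric(Sig[u, P, drop = FALSE] %*% a)
        Sig[u, v] <- cv; Sig[v, u] <- cv
      }
    }
    done <- c(done, v)
    # exogenous covariances once both ends exist
    for (k in seq_len(nrow(covs))) {
      if (covs$from[k] %in% done && covs$to[k] %in% done) {
        Sig[covs$from[k], covs$to[k]] <- covs$value[k]
        Sig[covs$to[k], covs$from[k]] <- covs$value[k]
      }
    }
  }
  pt
}

#' Draw an observed-variable table from a known truth
#'
#' Multivariate normal draws with the truth's implied covariance,
#' deterministic given the truth's seed.
#'
#' @param truth a [sem_truth()].
#' @param n rows to draw (default `truth$n`).
#' @return data.frame with one column per observed variable.
#' @export
generate_sem_table <- function(truth, n = truth$n) {
  stopifnot(inherits(truth, "sem_truth"))
  set.seed(truth$seed)
  p <- ncol(truth$Sigma)
  Z <- matrix(stats::rnorm(n * p), n, p)
  X <- Z %*% chol(truth$Sigma)
  colnames(X) <- colnames(truth$Sigma)
  as.data.frame(X)
}

#' Covariate rasters with class-linked driver signal
#'
#' Builds the seven observed driver covariates over a landscape as smooth
#' fields plus class-linked effects: elevation rises eastward (under the
#' forest belt) and slope follows its local relief; temperature falls and
#' precipitation rises with elevation; NDVI carries a per-class greenness
#' level (woodland high, built land low) plus a positive elevation link;
#' nightlight and population density concentrate over built cells and are
#' reduced at elevation. The built-in links give the pipeline a known,
#' recoverable signal: positive topography -> NDVI, negative topography ->
#' human disturbance.
#'
#' @param landscape a land-use [hq_grid()].
#' @param truth a [sem_truth()] (its structural coefficients scale the
#'   topography links).
#' @param seed RNG seed.
#' @return named list of [hq_grid()]s: elevation, slope, temperature,
#'   precipitation, ndvi, nightlight, popdensity.
#' @export
generate_covariate_stack <- function(landscape, truth = sem_truth(),
                                     seed = 1) {
  v <- landscape$values
  nr <- nrow(v); nc <- ncol(v)
  set.seed(seed)
  u <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  lat <- matrix(rep((seq_len(nr) - 0.5) / nr, nc), nr, nc)  # 0 north, 1 south
  topo_ndvi <- truth$structural$coef[truth$structural$from == "Topography" &
                                       truth$structural$to == "NDVI"]
  topo_hum <- truth$structural$coef[truth$structural$from == "Topography" &
                                      truth$structural$to == "HumanDisturbance"]
  if (!length(topo_ndvi)) topo_ndvi <- 0.4
  if (!length(topo_hum)) topo_hum <- -0.3
  elev <- 200 + 300 * u^2 + 60 * smooth_field(nr, nc) +
    80 * (v == 3)  # forest belt sits on the uplands
  gx <- cbind(elev[, -1], elev[, nc]) - cbind(elev[, 1], elev[, -nc])
  gy <- rbind(elev[-1, ], elev[nr, ]) - rbind(elev[1, ], elev[-nr, ])
  slope <- sqrt(gx^2 + gy^2) / 2 + 3 * abs(smooth_field(nr, nc))
  ez <- (elev - mean(elev)) / stats::sd(elev)
  temp <- 4 - 2.5 * ez - 1.5 * lat + 0.8 * smooth_field(nr, nc)
  precip <- 500 + 60 * ez + 40 * u + 25 * smooth_field(nr, nc)
  green <- c("1" = 0.55, "2" = 0.50, "3" = 0.85, "7" = 0.60, "10" = 0.10,
             "14" = 0.15, "15" = 0.25, "18" = 0.30, "19" = 0.65)
  g0 <- green[as.character(v)]
  g0[is.na(g0)] <- 0.4
  ndvi <- matrix(g0, nr, nc) + 0.15 * topo_ndvi * ez +
    0.05 * smooth_field(nr, nc)
  built <- matrix(as.numeric(v %in% c(14, 15, 16)), nr, nc)
  spread <- threat_load(built, threat_spec("built", c(14, 15, 16),
                                           d_rmax = 5 * landscape$cell_size,
                                           weight = 1, decay = "exponential"),
                        landscape$cell_size)
  spread <- spread / max(spread, 1e-9)
  human_base <- spread + 0.3 * topo_hum * ez
  nightlight <- pmax(60 * human_base + 3 * abs(smooth_field(nr, nc)), 0)
  popdens <- pmax(800 * human_base + 30 * abs(smooth_field(nr, nc)), 0)
  wrap <- function(m) {
    m[is.na(v)] <- NA_real_
    hq_grid(m, cell_size = landscape$cell_size, origin = landscape$origin,
            nodata = landscape$nodata)
  }
  list(elevation = wrap(elev), slope = wrap(slope), temperature = wrap(temp),
       precipitation = wrap(precip), ndvi = wrap(ndvi),
       nightlight = wrap(nightlight), popdensity = wrap(popdens))
}
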