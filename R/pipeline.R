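#' Read a pipeline run configuration
#'
#' Configurations are JSON with an explicit `seed`: per-date land-use
#' raster paths, parameter-table paths (defaults to the packaged Songnen
#' tables), habitat-quality parameters, the spatial-weights scheme, the
#' change tolerance, and an optional SEM block naming per-date covariate
#' rasters.
#'
#' @param path JSON file path.
#' @return the configuration list.
#' @export
run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(cfg$seed)) stop("config must state an explicit seed")
  cfg
}

write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full habitat-quality analysis pipeline
#'
#' Orchestrates: land-use ingestion -> per-date class areas -> transition
#' matrices between consecutive dates -> degradation and quality surfaces
#' -> five-grade tables -> Moran's I and Gi* hotspot tables -> change maps
#' -> (optionally) the SEM driver analysis on a seeded sample of valid
#' cells. All outputs are plain CSV or ASCII grids under `out_dir`; a run
#' log records parameters and the seed, and identical config + seed yields
#' byte-identical outputs.
#'
#' @param config a configuration list (see [run_config()]); `landuse` may
#'   map dates either to `.asc` paths or directly to [hq_grid()] objects,
#'   and the SEM block's covariates likewise.
#' @return data.frame manifest of produced files (stage, file).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- run_config(config)
  if (is.null(config$seed)) stop("config must state an explicit seed")
  out_dir <- config$out_dir %||% stop("config must name out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- c(sprintf("habiquant run, seed %d", config$seed),
                 sprintf("z=%g k=%g eps=%g scheme=%s",
                         config$z %||% 2.5, config$k %||% 0.5,
                         config$eps %||% 0.01, config$scheme %||% "queen"))
  manifest <- list()
  add <- function(stage, file) manifest[[length(manifest) + 1]] <<-
    data.frame(stage = stage, file = file, stringsAsFactors = FALSE)
  fail <- function(stage, msg) stop(sprintf("stage '%s' failed: %s", stage, msg),
                                    call. = FALSE)

  params <- tryCatch({
    if (!is.null(config$legend_csv))
      read_parameter_tables(config$legend_csv, config$threats_csv)
    else default_parameter_tables()
  }, error = function(e) fail("parameters", conditionMessage(e)))
  legend <- params$legend; threats <- params$threats
  cfg_hq <- hq_config(z = config$z %||% 2.5, k = config$k %||% 0.5)
  eps <- config$eps %||% 0.01
  w_moran <- spatial_weights(scheme = config$scheme %||% "queen")
  w_gi <- spatial_weights(scheme = config$scheme %||% "queen",
                          row_standardized = FALSE, include_self = TRUE)

  dates <- names(config$landuse)
  if (is.null(dates) || !length(dates)) fail("ingest", "no land-use inputs")
  lus <- lapply(config$landuse, function(x)
    if (inherits(x, "hq_grid")) x else
      tryCatch(read_ascii_grid(x),
               error = function(e) fail("ingest", conditionMessage(e))))

  qs <- list(); moran_rows <- list()
  for (d in dates) {
    lu <- lus[[d]]
    ap <- tryCatch(area_percentages(lu, legend),
                   error = function(e) fail("areas", conditionMessage(e)))
    add("areas", write_table_csv(ap, file.path(out_dir,
                                               sprintf("lu_area_%s.csv", d))))
    D <- tryCatch(degradation(lu, threats, legend, cfg_hq),
                  error = function(e) fail("degradation", conditionMessage(e)))
    Q <- quality(lu, D, legend, cfg_hq)
    qs[[d]] <- Q
    add("degradation", write_ascii_grid(D, file.path(out_dir,
                                                     sprintf("D_%s.asc", d))))
    add("quality", write_ascii_grid(Q, file.path(out_dir,
                                                 sprintf("Q_%s.asc", d))))
    gr <- classify_quality(Q)
    add("grades", write_table_csv(gr$table,
                                  file.path(out_dir, sprintf("grades_%s.csv", d))))
    mi <- tryCatch(morans_i(Q, w_moran),
                   error = function(e) fail("morans_i", conditionMessage(e)))
    moran_rows[[d]] <- data.frame(date = d, I = mi$I,
                                  expectation = mi$expectation, z = mi$z,
                                  n = mi$n, stringsAsFactors = FALSE)
    hs <- tryCatch(gi_star(Q, w_gi),
                   error = function(e) fail("gi_star", conditionMessage(e)))
    add("hotspots", write_ascii_grid(hs$class_grid,
                                     file.path(out_dir, sprintf("hotspots_%s.asc", d))))
    add("hotspots", write_table_csv(hs$table,
                                    file.path(out_dir, sprintf("hotspots_%s.csv", d))))
    log_lines <- c(log_lines, sprintf("date %s: mean Q %.4f, Moran's I %.4f",
                                      d, mean(Q$values, na.rm = TRUE), mi$I))
  }
  add("morans_i", write_table_csv(do.call(rbind, moran_rows),
                                  file.path(out_dir, "morans_i.csv")))

  if (length(dates) > 1) {
    for (k in seq_len(length(dates) - 1)) {
      a <- dates[k]; b <- dates[k + 1]
      tm <- tryCatch(transition_matrix(lus[[a]], lus[[b]], legend),
                     error = function(e) fail("transitions", conditionMessage(e)))
      mat <- as.data.frame(tm$areas)
      mat <- cbind(from = rownames(mat), mat)
      add("transitions", write_table_csv(mat,
        file.path(out_dir, sprintf("transitions_%s_%s.csv", a, b))))
      cm <- change_map(qs[[a]], qs[[b]], eps = eps)
      add("change", write_table_csv(cm$table,
        file.path(out_dir, sprintf("change_%s_%s.csv", a, b))))
      add("change", write_ascii_grid(cm$grid,
        file.path(out_dir, sprintf("change_%s_%s.asc", a, b))))
    }
  }

  if (!is.null(config$sem)) {
    sem_cfg <- config$sem
    model <- path_model(if (!is.null(sem_cfg$model)) {
      if (file.exists(sem_cfg$model)) paste(readLines(sem_cfg$model),
                                            collapse = "\n")
      else sem_cfg$model
    } else hq_driver_model())
    sample_n <- sem_cfg$sample_n %||% 10000
    for (d in names(sem_cfg$covariates)) {
      covs <- lapply(sem_cfg$covariates[[d]], function(x)
        if (inherits(x, "hq_grid")) x else read_ascii_grid(x))
      tab <- tryCatch(
        sem_sample_table(qs[[d]], covs, sample_n = sample_n,
                         seed = config$seed),
        error = function(e) fail("sem_sample", conditionMessage(e)))
      fit <- tryCatch(
        fit_ml(stats::cov(tab), nrow(tab), model, seed = config$seed),
        error = function(e) fail("sem_fit", conditionMessage(e)))
      add("sem", write_table_csv(
        data.frame(index = names(fit$fit),
                   value = unlist(fit$fit), row.names = NULL),
        file.path(out_dir, sprintf("sem_fit_%s.csv", d))))
      drivers <- c("Topography", "Climate", "HumanDisturbance", "NDVI")
      drivers <- intersect(drivers, c(fit$model$latents, fit$model$observed))
      add("sem", write_table_csv(effects_table(fit, drivers, "HQ"),
        file.path(out_dir, sprintf("sem_effects_%s.csv", d))))
      log_lines <- c(log_lines,
                     sprintf("sem %s: chisq %.3f df %d CFI %.3f SRMR %.3f",
                             d, fit$fit$chisq, fit$fit$df, fit$fit$CFI,
                             fit$fit$SRMR))
    }
  }

  writeLines(log_lines, log_path)
  out <- do.call(rbind, manifest)
  out$file <- as.character(out$file)
  out
}

#' Sample valid cells into an SEM input table
#'
#' Draws a seeded uniform sample of cells valid in the quality surface and
#' every covariate, then applies the rank-based inverse-normal transform
#' per column ([rank_normalize()]).
#'
#' @param Q quality grid (becomes column `HQ`).
#' @param covariates named list of covariate grids; names must include
#'   elevation, slope, temperature, precipitation, ndvi, nightlight,
#'   popdensity (the `ndvi` column is renamed `NDVI`).
#' @param sample_n cells to sample (capped at the number of valid cells).
#' @param seed RNG seed.
#' @return data.frame of transformed columns.
#' @export
sem_sample_table <- function(Q, covariates, sample_n = 10000, seed = 1) {
  need <- c("elevation", "slope", "temperature", "precipitation", "ndvi",
            "nightlight", "popdensity")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stop(sprintf("missing covariate raster(s): %s", paste(miss, collapse = ", ")))
  for (nm in need) stop_geometry(Q, covariates[[nm]], nm)
  stack <- c(list(HQ = Q$values), lapply(covariates[need], `[[`, "values"))
  valid <- Reduce(`&`, lapply(stack, function(m) !is.na(m)))
  idx <- which(valid)
  if (length(idx) < 10) stop("fewer than 10 jointly valid cells")
  set.seed(seed)
  take <- if (length(idx) > sample_n) sort(sample(idx, sample_n)) else idx
  tab <- as.data.frame(lapply(stack, function(m) m[take]))
  names(tab) <- c("HQ", "elevation", "slope", "temperature", "precipitation",
                  "NDVI", "nightlight", "popdensity")
  as.data.frame(lapply(tab, rank_normalize))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
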