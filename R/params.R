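#' Land-use legends and threat specifications
#'
#' The legend carries, per land-use class, its habitat suitability
#' \eqn{H_j \in [0,1]} (intrinsic quality absent threats) and its
#' sensitivity \eqn{S_{jr} \in [0,1]} to every threat factor. A threat
#' specification names a threat factor, the land-use codes that act as its
#' sources, the maximum influence distance \eqn{d_{r,max}} in km, its
#' relative weight \eqn{\omega_r} and the decay type of its kernel.
#'
#' @param classes data.frame with columns `code` (integer, unique), `name`,
#'   `H` (in \[0,1\]).
#' @param sensitivity numeric matrix, rows in the order of `classes`,
#'   one named column per threat, entries in \[0,1\].
#' @return a `landuse_legend` object.
#' @export
landuse_legend <- function(classes, sensitivity) {
  stopifnot(is.data.frame(classes),
            all(c("code", "name", "H") %in% names(classes)))
  sensitivity <- as.matrix(sensitivity)
  if (nrow(sensitivity) != nrow(classes))
    stop("sensitivity must have one row per legend class")
  if (is.null(colnames(sensitivity)) || any(!nzchar(colnames(sensitivity))))
    stop("sensitivity columns must be named after threats")
  if (anyDuplicated(classes$code))
    stop(sprintf("duplicate land-use code(s): %s",
                 paste(unique(classes$code[duplicated(classes$code)]), collapse = ", ")))
  bad_h <- which(classes$H < 0 | classes$H > 1 | is.na(classes$H))
  if (length(bad_h))
    stop(sprintf("habitat suitability outside [0,1] in row(s): %s",
                 paste(bad_h, collapse = ", ")))
  bad_s <- which(apply(sensitivity, 1, function(r) any(is.na(r) | r < 0 | r > 1)))
  if (length(bad_s))
    stop(sprintf("sensitivity outside [0,1] in row(s): %s",
                 paste(bad_s, collapse = ", ")))
  rownames(sensitivity) <- classes$code
  structure(list(classes = classes, sensitivity = sensitivity),
            class = "landuse_legend")
}

#' @export
print.landuse_legend <- function(x, ...) {
  cat(sprintf("<landuse_legend> %d classes, %d threats (%s)\n",
              nrow(x$classes), ncol(x$sensitivity),
              paste(colnames(x$sensitivity), collapse = ", ")))
  invisible(x)
}

#' @rdname landuse_legend
#' @param legend a `landuse_legend`.
#' @export
legend_codes <- function(legend) legend$classes$code

#' Habitat suitability H for a vector of class codes
#'
#' @param legend a [landuse_legend()].
#' @param codes integer class codes (NA passes through as NA).
#' @return numeric vector of H values.
#' @export
suitability <- function(legend, codes) {
  idx <- match(codes, legend$classes$code)
  unknown <- unique(codes[!is.na(codes) & is.na(idx)])
  if (length(unknown))
    stop(sprintf("unknown land-use code(s): %s", paste(unknown, collapse = ", ")))
  legend$classes$H[idx]
}

#' Sensitivity S of class codes to one threat
#'
#' @inheritParams suitability
#' @param threat threat name (a sensitivity column of the legend).
#' @export
sensitivity_to <- function(legend, codes, threat) {
  if (!threat %in% colnames(legend$sensitivity))
    stop(sprintf("legend has no sensitivity column for threat '%s'", threat))
  idx <- match(codes, legend$classes$code)
  unknown <- unique(codes[!is.na(codes) & is.na(idx)])
  if (length(unknown))
    stop(sprintf("unknown land-use code(s): %s", paste(unknown, collapse = ", ")))
  legend$sensitivity[idx, threat]
}

#' @rdname landuse_legend
#' @param name threat factor name.
#' @param source_codes land-use codes whose cells emit this threat.
#' @param d_rmax maximum influence distance in km.
#' @param weight relative threat weight \eqn{\omega_r \ge 0}.
#' @param decay `"linear"` or `"exponential"`.
#' @export
threat_spec <- function(name, source_codes, d_rmax, weight,
                        decay = c("linear", "exponential")) {
  decay <- match.arg(decay)
  if (!is.numeric(d_rmax) || d_rmax <= 0) stop("d_rmax must be > 0")
  if (!is.numeric(weight) || weight < 0) stop("weight must be >= 0")
  structure(list(name = name, source_codes = unique(as.integer(source_codes)),
                 d_rmax = d_rmax, weight = weight, decay = decay),
            class = "threat_spec")
}

#' @export
print.threat_spec <- function(x, ...) {
  cat(sprintf("<threat_spec> %s: codes {%s}, d_rmax %.2f km, weight %.2f, %s decay\n",
              x$name, paste(x$source_codes, collapse = ","), x$d_rmax,
              x$weight, x$decay))
  invisible(x)
}

#' Read legend and threat parameter tables
#'
#' The legend CSV has columns `code,name,H` plus one sensitivity column per
#' threat; the threats CSV has `name,codes,d_rmax_km,weight,decay` with
#' `codes` a `;`-separated list of source land-use codes. Threat names must
#' match the legend's sensitivity columns exactly. The packaged defaults
#' (`legend_songnen.csv`, `threats_songnen.csv`) carry the Songnen Plain
#' parameterization: six threat factors (industrial/mining, arable, urban,
#' rural settlement, saline-alkali, bare ground) over 21 land-use classes.
#'
#' @param legend_path path to the legend CSV.
#' @param threats_path path to the threats CSV.
#' @return list with elements `legend` ([landuse_legend()]) and `threats`
#'   (list of [threat_spec()]).
#' @export
read_parameter_tables <- function(legend_path, threats_path) {
  leg <- utils::read.csv(legend_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!all(c("code", "name", "H") %in% names(leg)))
    stop("legend CSV must have columns code,name,H plus one per threat")
  sens_cols <- setdiff(names(leg), c("code", "name", "H"))
  if (!length(sens_cols)) stop("legend CSV has no sensitivity columns")
  legend <- landuse_legend(leg[c("code", "name", "H")],
                           as.matrix(leg[sens_cols]))
  th <- utils::read.csv(threats_path, stringsAsFactors = FALSE)
  need <- c("name", "codes", "d_rmax_km", "weight", "decay")
  if (!all(need %in% names(th)))
    stop("threats CSV must have columns name,codes,d_rmax_km,weight,decay")
  threats <- lapply(seq_len(nrow(th)), function(i) {
    codes <- as.integer(strsplit(as.character(th$codes[i]), ";")[[1]])
    threat_spec(th$name[i], codes, th$d_rmax_km[i], th$weight[i],
                tolower(th$decay[i]))
  })
  t_names <- vapply(threats, `[[`, character(1), "name")
  if (!setequal(t_names, sens_cols) || length(t_names) != length(sens_cols))
    stop(sprintf(
      "threat names and legend sensitivity columns disagree: threats {%s} vs legend {%s}",
      paste(t_names, collapse = ", "), paste(sens_cols, collapse = ", ")))
  bad <- unlist(lapply(threats, function(tr)
    setdiff(tr$source_codes, legend$classes$code)))
  if (length(bad))
    stop(sprintf("threat source code(s) absent from legend: %s",
                 paste(unique(bad), collapse = ", ")))
  list(legend = legend, threats = threats)
}

#' Packaged Songnen Plain parameter tables
#'
#' @return as [read_parameter_tables()].
#' @export
default_parameter_tables <- function() {
  read_parameter_tables(
    system.file("extdata", "legend_songnen.csv", package = "habiquant",
                mustWork = TRUE),
    system.file("extdata", "threats_songnen.csv", package = "habiquant",
                mustWork = TRUE)
  )
}
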