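#' Specify a latent-variable path model
#'
#' Models are written in a compact text syntax, one statement per line:
#' \itemize{
#'   \item `Latent =~ ind1 + ind2` — measurement: a latent variable and
#'     its observed indicators (the first indicator's loading is fixed to
#'     1 for identification);
#'   \item `y ~ x1 + x2` — structural regression (latent or observed on
#'     either side);
#'   \item `a ~~ b` — free covariance between two exogenous variables.
#' }
#' Lines starting with `#` are comments. Only declared `~~` covariances
#' are freed. The structural graph must be acyclic.
#'
#' The driver analysis this package was built around uses three latents —
#' Topography (elevation, slope), Climate (precipitation, temperature),
#' HumanDisturbance (nightlight, population density) — with observed NDVI
#' as mediator and observed HQ as the response; see
#' [hq_driver_model()].
#'
#' @param spec model syntax as a single string or character vector of
#'   lines.
#' @return a `path_model` object.
#' @export
path_model <- function(spec) {
  lines <- unlist(strsplit(spec, "\n"))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  loadings <- list(); regressions <- list(); covariances <- list()
  split_rhs <- function(rhs) trimws(strsplit(rhs, "\\+")[[1]])
  for (ln in lines) {
    if (grepl("=~", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "=~", fixed = TRUE)[[1]])
      for (ind in split_rhs(parts[2]))
        loadings[[length(loadings) + 1]] <- c(parts[1], ind)
    } else if (grepl("~~", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "~~", fixed = TRUE)[[1]])
      covariances[[length(covariances) + 1]] <- c(parts[1], parts[2])
    } else if (grepl("~", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "~", fixed = TRUE)[[1]])
      for (x in split_rhs(parts[2]))
        regressions[[length(regressions) + 1]] <- c(x, parts[1])
    } else stop(sprintf("cannot parse model line: '%s'", ln))
  }
  to_df <- function(lst, nm) {
    if (!length(lst)) return(stats::setNames(
      data.frame(a = character(0), b = character(0),
                 stringsAsFactors = FALSE), nm))
    stats::setNames(as.data.frame(do.call(rbind, lst),
                                  stringsAsFactors = FALSE), nm)
  }
  load_df <- to_df(loadings, c("latent", "indicator"))
  reg_df <- to_df(regressions, c("from", "to"))
  cov_df <- to_df(covariances, c("a", "b"))
  latents <- unique(load_df$latent)
  if (any(load_df$indicator %in% latents))
    stop("an indicator cannot also be a latent variable")
  dup <- load_df$indicator[duplicated(load_df$indicator)]
  if (length(dup))
    stop(sprintf("indicator(s) loading on more than one latent: %s",
                 paste(unique(dup), collapse = ", ")))
  cnt <- table(load_df$latent)
  if (any(cnt < 2))
    stop(sprintf("latent(s) with fewer than 2 indicators: %s",
                 paste(names(cnt)[cnt < 2], collapse = ", ")))
  observed <- unique(c(load_df$indicator,
                       setdiff(c(reg_df$from, reg_df$to,
                                 cov_df$a, cov_df$b), latents)))
  allv <- c(observed, latents)
  # acyclicity of the structural graph
  edges <- reg_df
  if (nrow(edges)) {
    order_ok <- topological_order(unique(c(edges$from, edges$to)), edges)
    if (is.null(order_ok)) stop("structural graph contains a cycle")
  }
  structure(list(observed = observed, latents = latents,
                 loadings = load_df, regressions = reg_df,
                 covariances = cov_df, vars = allv),
            class = "path_model")
}

# Kahn's algorithm; NULL if cyclic
topological_order <- function(nodes, edges) {
  indeg <- stats::setNames(rep(0L, length(nodes)), nodes)
  for (t in edges$to) indeg[t] <- indeg[t] + 1L
  queue <- nodes[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    hit <- edges$from == v
    for (t in edges$to[hit]) {
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) queue <- c(queue, t)
    }
    edges <- edges[!hit, , drop = FALSE]
  }
  if (length(out) == length(nodes)) out else NULL
}

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("<path_model> %d observed, %d latents, %d structural paths\n",
              length(x$observed), length(x$latents), nrow(x$regressions)))
  invisible(x)
}

#' Default habitat-quality driver model
#'
#' Three latents measured by two indicators each, with NDVI mediating and
#' HQ as the terminal response. Structural edges can be added or removed
#' per analysis year by editing the returned syntax.
#'
#' @param extra optional extra syntax lines appended to the base model.
#' @return model syntax string (feed to [path_model()]).
#' @export
hq_driver_model <- function(extra = NULL) {
  base <- c(
    "Topography =~ elevation + slope",
    "Climate =~ precipitation + temperature",
    "HumanDisturbance =~ nightlight + popdensity",
    "NDVI ~ Topography + Climate + HumanDisturbance",
    "HumanDisturbance ~ Topography",
    "HQ ~ Topography + Climate + HumanDisturbance + NDVI",
    "Topography ~~ Climate"
  )
  paste(c(base, extra), collapse = "\n")
}
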