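#' Direct, indirect and total effects along the structural graph
#'
#' Decomposes the standardized effect of a driver on a response over the
#' acyclic structural graph: the direct effect is the coefficient on the
#' edge driver -> response (0 if absent), each indirect contribution is
#' the product of coefficients along one simple directed path of length
#' >= 2, and the total is their sum — the convention in which, e.g.,
#' topography acts on habitat quality directly, through vegetation (NDVI)
#' and through human disturbance.
#'
#' @param fit a [fit_ml()] result, or a data.frame of standardized
#'   structural edges with columns `from`, `to`, `coef`.
#' @param driver name of the driver variable.
#' @param response name of the response variable.
#' @return list with `direct`, `indirect` (data.frame path/contribution),
#'   `total`.
#' @export
effect_decomposition <- function(fit, driver, response) {
  edges <- structural_edges(fit)
  if (is.null(topological_order(unique(c(edges$from, edges$to)), edges)))
    stop("structural graph contains a cycle")
  paths <- enumerate_paths(edges, driver, response)
  direct <- 0
  ind <- list()
  for (p in paths) {
    coefs <- vapply(seq_len(length(p) - 1), function(k)
      edges$coef[edges$from == p[k] & edges$to == p[k + 1]][1], numeric(1))
    contrib <- prod(coefs)
    if (length(p) == 2) direct <- contrib
    else ind[[length(ind) + 1]] <- data.frame(
      path = paste(p, collapse = " -> "), contribution = contrib,
      stringsAsFactors = FALSE)
  }
  indirect <- if (length(ind)) do.call(rbind, ind) else
    data.frame(path = character(0), contribution = numeric(0),
               stringsAsFactors = FALSE)
  list(direct = direct, indirect = indirect,
       total = direct + sum(indirect$contribution))
}

structural_edges <- function(fit) {
  if (is.data.frame(fit)) {
    stopifnot(all(c("from", "to", "coef") %in% names(fit)))
    return(fit[c("from", "to", "coef")])
  }
  pt <- fit$params
  e <- pt[pt$type == "reg", c("from", "to", "std")]
  names(e)[3] <- "coef"
  rownames(e) <- NULL
  e
}

# all simple directed paths driver -> response (DFS; graph is acyclic)
enumerate_paths <- function(edges, from, to) {
  out <- list()
  walk <- function(node, path) {
    if (node == to) { out[[length(out) + 1]] <<- path; return(invisible()) }
    for (nxt in edges$to[edges$from == node]) walk(nxt, c(path, nxt))
  }
  walk(from, from)
  out
}

#' Effect table for several drivers at once
#'
#' @inheritParams effect_decomposition
#' @param drivers character vector of driver names.
#' @return data.frame with columns driver, direct, indirect (summed),
#'   total.
#' @export
effects_table <- function(fit, drivers, response = "HQ") {
  rows <- lapply(drivers, function(d) {
    dec <- effect_decomposition(fit, d, response)
    data.frame(driver = d, direct = dec$direct,
               indirect = sum(dec$indirect$contribution),
               total = dec$total, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Total-effects matrix by matrix-series summation
#'
#' Independent route to the same totals as [effect_decomposition()]: with
#' B the standardized structural coefficient matrix (B\[to, from\]) of an
#' acyclic graph, the matrix of total effects is
#' \eqn{(I - B)^{-1} - I = B + B^2 + \dots}.
#'
#' @inheritParams effect_decomposition
#' @return square matrix, entry \[response, driver\] = total effect.
#' @export
total_effects_matrix <- function(fit) {
  edges <- structural_edges(fit)
  vars <- unique(c(edges$from, edges$to))
  B <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  for (k in seq_len(nrow(edges))) B[edges$to[k], edges$from[k]] <- edges$coef[k]
  solve(diag(length(vars)) - B) - diag(length(vars))
}
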