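#' Land-use transition matrix between two dates
#'
#' Cross-tabulates the areas moving between land-use classes across two
#' dates: entry (i, j) is the area (km^2) of cells carrying class i at the
#' first date and class j at the second. Cells that are nodata at either
#' date are excluded entirely, so the row sums equal the per-class areas at
#' the first date, the column sums those at the second, and the grand total
#' the area valid at both dates.
#'
#' @param lu_a,lu_b land-use grids ([hq_grid()]) on the same geometry.
#' @param legend a [landuse_legend()]; all codes present must be known.
#' @return a `transition_matrix`: list with `classes` (codes, in legend
#'   order restricted to codes present at either date) and `areas`
#'   (named square matrix, km^2).
#' @export
transition_matrix <- function(lu_a, lu_b, legend) {
  stop_geometry(lu_a, lu_b, "land-use grids")
  a <- as.vector(lu_a$values); b <- as.vector(lu_b$values)
  ok <- !is.na(a) & !is.na(b)
  suitability(legend, unique(c(a[ok], b[ok])))  # errors on unknown codes
  present <- legend$classes$code[legend$classes$code %in% c(a[ok], b[ok])]
  fa <- factor(a[ok], levels = present)
  fb <- factor(b[ok], levels = present)
  counts <- table(from = fa, to = fb)
  areas <- unclass(counts) * lu_a$cell_size^2
  structure(list(classes = present, areas = areas), class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d classes, total area %g km^2\n",
              length(x$classes), sum(x$areas)))
  print(round(x$areas, 3))
  invisible(x)
}

#' Row-normalized conversion rates
#'
#' Expresses each transition as a percentage of the origin class's area
#' (the "x% of class i converted to class j" reading).
#'
#' @param tm a [transition_matrix()].
#' @return matrix of percentages; rows sum to 100 for non-empty classes.
#' @export
conversion_rates <- function(tm) {
  rs <- rowSums(tm$areas)
  out <- sweep(tm$areas, 1, ifelse(rs > 0, rs, 1), "/") * 100
  out[rs == 0, ] <- 0
  out
}

#' Percentage of valid area per land-use class (or class group)
#'
#' @param lu land-use grid.
#' @param legend a [landuse_legend()].
#' @param grouping optional named character vector mapping code -> group
#'   name (names are codes); codes absent from it keep their class name.
#' @return data.frame with columns `group` and `percent`; percentages sum
#'   to 100 over the valid area.
#' @export
area_percentages <- function(lu, legend, grouping = NULL) {
  v <- as.vector(lu$values)
  v <- v[!is.na(v)]
  if (!length(v)) stop("empty valid area: all cells are nodata")
  suitability(legend, unique(v))  # errors on unknown codes
  labels <- legend$classes$name[match(v, legend$classes$code)]
  if (!is.null(grouping)) {
    hit <- match(as.character(v), names(grouping))
    labels[!is.na(hit)] <- grouping[hit[!is.na(hit)]]
  }
  tab <- table(labels)
  data.frame(group = names(tab),
             percent = as.numeric(tab) / length(v) * 100,
             row.names = NULL, stringsAsFactors = FALSE)
}
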