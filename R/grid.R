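#' Gridded raster surfaces
#'
#' A `hq_grid` is the package's carrier for every raster: categorical land
#' use, habitat degradation D, habitat quality Q, covariates. It is a plain
#' list holding a numeric matrix (`values`, row 1 = northernmost row),
#' the cell edge length in km (`cell_size`), the lower-left corner of the
#' grid in map units (`origin`), and the sentinel written for missing cells
#' on disk (`nodata`). In memory missing cells are `NA`; the sentinel is
#' only used at the file boundary.
#'
#' @param values numeric matrix, row-major north-up; `NA` marks nodata.
#' @param cell_size cell edge length in km; must be positive.
#' @param origin numeric length-2, (x, y) of the lower-left corner.
#' @param nodata sentinel value used when writing; must not collide with a
#'   finite value present in `values`.
#' @return an object of class `hq_grid`.
#' @examples
#' g <- hq_grid(matrix(1:6, nrow = 2, byrow = TRUE), cell_size = 1)
#' dim(g$values)
#' @export
hq_grid <- function(values, cell_size = 1, origin = c(0, 0), nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  g <- structure(
    list(values = values, cell_size = cell_size,
         origin = as.numeric(origin), nodata = nodata),
    class = "hq_grid"
  )
  validate_grid(g)
  g
}

validate_grid <- function(g) {
  stopifnot(inherits(g, "hq_grid"))
  if (!is.matrix(g$values)) stop("grid values must be a matrix")
  if (!is.numeric(g$cell_size) || length(g$cell_size) != 1 || g$cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (length(g$origin) != 2) stop("origin must be (x, y)")
  if (any(g$values[is.finite(g$values)] == g$nodata))
    stop("nodata sentinel collides with a finite cell value")
  invisible(g)
}

#' @export
print.hq_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<hq_grid> %d x %d cells, cell_size %g km, %d nodata\n",
              nrow(v), ncol(v), x$cell_size, sum(is.na(v))))
  rng <- range(v, na.rm = TRUE)
  cat(sprintf("  values in [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Number of rows/columns of a grid
#' @param g an `hq_grid`.
#' @return integer count.
#' @export
grid_nrow <- function(g) nrow(g$values)

#' @rdname grid_nrow
#' @export
grid_ncol <- function(g) ncol(g$values)

# TRUE where two grids share shape and cell size
same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size))
}

stop_geometry <- function(a, b, what = "grids") {
  if (!same_geometry(a, b))
    stop(sprintf("%s differ in geometry: %dx%d (cell %g) vs %dx%d (cell %g)",
                 what, nrow(a$values), ncol(a$values), a$cell_size,
                 nrow(b$values), ncol(b$values), b$cell_size))
  invisible(TRUE)
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard `.asc` dialect: a header with keys `ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize` and optionally `NODATA_value`,
#' followed by `nrows` rows of `ncols` whitespace-separated values, first
#' row northernmost. Cells equal to the declared nodata sentinel become
#' `NA`.
#'
#' The header `cellsize` is interpreted as km (the package's length unit
#' throughout; threat distances are given in km).
#'
#' @param path path to the `.asc` file.
#' @return an [hq_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop(sprintf("'%s': too short for an ASCII grid", path))
  hdr <- list()
  i <- 1
  repeat {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) == 2 && grepl("^[A-Za-z_]+$", toks[1])) {
      val <- suppressWarnings(as.numeric(toks[2]))
      if (is.na(val))
        stop(sprintf("line %d: non-numeric header value '%s'", i, toks[2]))
      hdr[[tolower(toks[1])]] <- val
      i <- i + 1
    } else break
    if (i > length(lines)) stop("file contains only header lines")
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop(sprintf("malformed header: missing key(s) %s", paste(miss, collapse = ", ")))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr)
    stop(sprintf("line %d: expected %d value rows, found %d", i, nr, length(body)))
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    toks <- strsplit(trimws(body[r]), "\\s+")[[1]]
    if (length(toks) != nc)
      stop(sprintf("line %d: expected %d values, found %d",
                   i + r - 1, nc, length(toks)))
    row <- suppressWarnings(as.numeric(toks))
    if (anyNA(row))
      stop(sprintf("line %d: non-numeric cell value '%s'",
                   i + r - 1, toks[which(is.na(row))[1]]))
    vals[r, ] <- row
  }
  vals[vals == nodata] <- NA_real_
  hq_grid(vals, cell_size = hdr$cellsize,
          origin = c(hdr$xllcorner, hdr$yllcorner), nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [read_ascii_grid()]: integer-valued grids round-trip
#' bit-exactly, floating grids to 15 significant digits. `NA` cells are
#' serialized as the grid's nodata sentinel.
#'
#' @param grid an [hq_grid()].
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_ascii_grid <- function(grid, path) {
  validate_grid(grid)
  v <- grid$values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  fmt <- function(x) {
    out <- vapply(x, function(xx) {
      if (is.na(xx)) return(format(grid$nodata, scientific = FALSE))
      if (xx == round(xx) && abs(xx) < 1e15)
        sprintf("%.0f", xx)
      else format(xx, digits = 15, scientific = FALSE)
    }, character(1))
    paste(out, collapse = " ")
  }
  rows <- apply(v, 1, fmt)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
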