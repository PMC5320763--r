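#' Regular planar grid raster
#'
#' A lightweight single-band raster on a regular planar grid (coordinates in
#' metres, no geodesy). Values are stored as a matrix whose first row is the
#' northernmost row of cells; `NA` encodes NODATA. Categorical layers store
#' integer category codes.
#'
#' @param values numeric or integer matrix; row 1 is the northern edge.
#' @param xll,yll coordinates of the lower-left (south-west) corner of the
#'   grid, in metres.
#' @param cellsize cell edge length in metres (> 0).
#' @param categorical logical; `TRUE` for category-code layers.
#' @param nodata value used to represent NODATA when the grid is written to
#'   disk; internally NODATA is always `NA`.
#' @return An object of class `grid_raster`.
#' @examples
#' g <- grid_raster(matrix(1:12, 3, 4), xll = 0, yll = 0, cellsize = 10)
#' dim(g$values)
#' @export
grid_raster <- function(values, xll, yll, cellsize, categorical = FALSE,
                        nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is_scalar_number(cellsize) || cellsize <= 0)
    stopf("cellsize must be a positive number")
  if (!is_scalar_number(xll) || !is_scalar_number(yll))
    stopf("xll and yll must be finite numbers")
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, categorical = isTRUE(categorical),
                 nodata = nodata),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster: %d rows x %d cols, cell %g m, origin (%g, %g)%s\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
              if (x$categorical) ", categorical" else ""))
  nd <- sum(is.na(x$values))
  cat(sprintf("  NODATA cells: %d / %d\n", nd, length(x$values)))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

grid_ytop <- function(g) g$yll + nrow(g$values) * g$cellsize
grid_xmax <- function(g) g$xll + ncol(g$values) * g$cellsize

#' Locate the cell containing a point
#'
#' Half-open cell convention: a point on a shared vertical edge belongs to
#' the cell to the east; a point on a shared horizontal edge to the cell to
#' the south. Vectorised over `x` and `y`.
#'
#' @param g a [grid_raster].
#' @param x,y point coordinates in metres.
#' @return A two-column integer matrix (`row`, `col`); `NA` rows for points
#'   outside the grid.
#' @export
cell_of <- function(g, x, y) {
  col <- floor((x - g$xll) / g$cellsize) + 1
  row <- floor((grid_ytop(g) - y) / g$cellsize) + 1
  bad <- !is.finite(col) | !is.finite(row) |
    col < 1 | col > ncol(g$values) | row < 1 | row > nrow(g$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Coordinates of cell centers
#'
#' @param g a [grid_raster].
#' @param row,col cell indices (vectorised).
#' @return Two-column matrix of center coordinates (`x`, `y`).
#' @export
cell_center <- function(g, row, col) {
  cbind(x = g$xll + (col - 0.5) * g$cellsize,
        y = grid_ytop(g) - (row - 0.5) * g$cellsize)
}

#' Sample a raster value at point locations
#'
#' Point-on-raster lookup using the half-open cell convention of [cell_of()].
#' NODATA cells and out-of-bounds points return `NA` (out-of-bounds points
#' additionally raise a warning).
#'
#' @inheritParams cell_of
#' @return Vector of cell values (`NA` for NODATA or out-of-bounds).
#' @export
sample_feature_at <- function(g, x, y) {
  rc <- cell_of(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc[, 1])
  if (any(!ok)) warnf("%d point(s) fall outside the grid; returning NA", sum(!ok))
  if (any(ok)) out[ok] <- g$values[rc[ok, , drop = FALSE]]
  out
}

#' Modal category within a radius
#'
#' Most frequent non-NODATA category among cells whose centers lie within
#' `radius` of the point (Euclidean, inclusive). Ties are broken by the
#' smallest category code. If no cell center falls within the radius the
#' value of the cell containing the point is returned; if every candidate
#' cell is NODATA the result is `NA`.
#'
#' @param g a categorical [grid_raster].
#' @param x,y center point (scalars).
#' @param radius neighbourhood radius in metres.
#' @return The modal category code, or `NA`.
#' @export
modal_category <- function(g, x, y, radius) {
  if (!isTRUE(g$categorical)) stopf("modal_category requires a categorical grid")
  if (!is_scalar_number(radius) || radius <= 0) stopf("radius must be positive")
  cs <- g$cellsize
  # candidate window in cell indices
  rc <- cell_of(g, x, y)
  span <- ceiling(radius / cs) + 1L
  r0 <- max(1L, ifelse(is.na(rc[1, 1]), 1L, rc[1, 1]) - span)
  r1 <- min(nrow(g$values), ifelse(is.na(rc[1, 1]), nrow(g$values), rc[1, 1]) + span)
  c0 <- max(1L, ifelse(is.na(rc[1, 2]), 1L, rc[1, 2]) - span)
  c1 <- min(ncol(g$values), ifelse(is.na(rc[1, 2]), ncol(g$values), rc[1, 2]) + span)
  rows <- r0:r1; cols <- c0:c1
  cx <- g$xll + (cols - 0.5) * cs
  cy <- grid_ytop(g) - (rows - 0.5) * cs
  dx2 <- outer(rep(1, length(rows)), (cx - x)^2)
  dy2 <- outer((cy - y)^2, rep(1, length(cols)))
  inside <- (dx2 + dy2) <= radius^2
  vals <- g$values[rows, cols, drop = FALSE][inside]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    # degenerate radius: fall back to the containing cell
    if (!is.na(rc[1, 1])) return(g$values[rc])
    return(NA_real_)
  }
  tab <- table(vals)
  codes <- as.numeric(names(tab))
  codes[tab == max(tab)][1]  # names(table) sort ascending: smallest code wins ties
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard single-band plain-text raster format (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value` header
#' followed by rows north to south). NODATA cells become `NA`.
#'
#' @param path file path.
#' @param categorical logical; mark the layer as categorical.
#' @return A [grid_raster].
#' @export
read_ascii_grid <- function(path, categorical = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stopf("'%s' is not an ASCII grid (too short)", path)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && tolower(parts[1]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stopf("'%s': missing header keys: %s", path,
          paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stopf("'%s': expected %d values, found %d", path, nr * nc, length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  grid_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
              categorical = categorical, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [read_ascii_grid()]; the round trip is value-identical,
#' including NODATA cells.
#'
#' @param g a [grid_raster].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(g, path) {
  stopifnot(inherits(g, "grid_raster"))
  m <- g$values
  m[is.na(m)] <- g$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(g$values)),
    sprintf("nrows %d", nrow(g$values)),
    sprintf("xllcorner %s", format(g$xll, digits = 17)),
    sprintf("yllcorner %s", format(g$yll, digits = 17)),
    sprintf("cellsize %s", format(g$cellsize, digits = 17)),
    sprintf("NODATA_value %s", format(g$nodata, digits = 17))), con)
  apply(m, 1, function(r)
    writeLines(paste(format(r, digits = 17, trim = TRUE), collapse = " "), con))
  invisible(path)
}

#' Aggregate a raster to a coarser cell size
#'
#' Blocks of `fact` x `fact` cells become one output cell: the modal
#' category (ties to the smallest code, NODATA ignored) for categorical
#' layers, the mean for numeric layers. Used to derive the 100 m output
#' grid from 10 m feature layers. Rows/cols not divisible by `fact` are
#' truncated at the south/east edge.
#'
#' @param g a [grid_raster].
#' @param fact integer aggregation factor (> 1).
#' @return A coarser [grid_raster].
#' @export
aggregate_raster <- function(g, fact) {
  stopifnot(inherits(g, "grid_raster"))
  fact <- as.integer(fact)
  if (fact < 1) stopf("fact must be >= 1")
  if (fact == 1) return(g)
  nr <- nrow(g$values) %/% fact
  nc <- ncol(g$values) %/% fact
  if (nr < 1 || nc < 1) stopf("grid too small to aggregate by %d", fact)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    rows <- ((i - 1) * fact + 1):(i * fact)
    for (j in seq_len(nc)) {
      block <- g$values[rows, ((j - 1) * fact + 1):(j * fact)]
      block <- block[!is.na(block)]
      if (length(block) == 0) next
      out[i, j] <- if (g$categorical) {
        tab <- table(block)
        as.numeric(names(tab)[tab == max(tab)][1])
      } else mean(block)
    }
  }
  # the aggregated grid shares the NW corner; the S/E remainder is dropped
  yll_new <- grid_ytop(g) - nr * fact * g$cellsize
  grid_raster(out, g$xll, yll_new, g$cellsize * fact,
              categorical = g$categorical, nodata = g$nodata)
}

# Check two grids share origin, cell size and dimensions.
grids_aligned <- function(a, b, tol = 1e-9) {
  abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol &&
    all(dim(a$values) == dim(b$values))
}
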