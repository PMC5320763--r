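#' Spatially thin observation records
#'
#' Enforces a minimum pairwise distance between retained records to level
#' out observation density. Presence records (coverage > 0, or
#' `source == "active"` presences) are processed before track-derived
#' absences, so a presence is never discarded in favour of a nearby track
#' point; within each class the greedy pass follows input order.
#'
#' @param records data.frame with columns `x`, `y` (planar metres),
#'   `coverage` in [0, 1] and optionally `source`
#'   (`"active"`/`"track"`).
#' @param min_dist minimum accepted pairwise distance in metres (default 50).
#' @return The accepted subset of `records` (original row order restored
#'   within the output). Re-thinning the output changes nothing.
#' @examples
#' r <- data.frame(x = c(0, 40, 80), y = 0, coverage = c(0.2, 0, 0))
#' thin_records(r, 50)  # keeps the 1st and 3rd
#' @export
thin_records <- function(records, min_dist = 50) {
  if (!is_scalar_number(min_dist) || min_dist <= 0) stopf("min_dist must be positive")
  check_records(records)
  n <- nrow(records)
  if (n == 0) return(records)
  presence <- records$coverage > 0
  ord <- c(which(presence), which(!presence))
  x <- records$x[ord]; y <- records$y[ord]
  keep <- logical(n)
  ax <- numeric(0); ay <- numeric(0)
  d2 <- min_dist^2
  for (i in seq_len(n)) {
    if (length(ax) == 0 || all((ax - x[i])^2 + (ay - y[i])^2 >= d2)) {
      keep[i] <- TRUE
      ax <- c(ax, x[i]); ay <- c(ay, y[i])
    }
  }
  records[sort(ord[keep]), , drop = FALSE]
}

check_records <- function(records) {
  need <- c("x", "y", "coverage")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stopf("records must be a data.frame with columns x, y, coverage")
  if (any(!is.finite(records$x)) || any(!is.finite(records$y)))
    stopf("record coordinates must be finite")
  if (any(is.na(records$coverage) | records$coverage < 0 | records$coverage > 1))
    stopf("coverage must lie in [0, 1]")
  invisible(records)
}

# indices of records within `radius` of (cx, cy); optionally excluding one
# focal record index (the autocovariate leakage guard).
in_radius <- function(records, cx, cy, radius, exclude = NULL) {
  idx <- which((records$x - cx)^2 + (records$y - cy)^2 <= radius^2)
  if (!is.null(exclude)) idx <- setdiff(idx, exclude)
  idx
}

#' Proportion of presence records within a radius
#'
#' Spatial autocovariate: the share of records within `radius` of the point
#' that are presences (coverage > 0). Returns `NA` when no record falls in
#' the neighbourhood, so downstream similarity computation skips the
#' feature rather than treating absence of data as absence of the species.
#'
#' @param records thinned observation records (see [thin_records()]).
#' @param cx,cy neighbourhood centre (scalars).
#' @param radius radius in metres.
#' @param exclude optional record row index to leave out (the focal record
#'   itself, when computing the feature at an observation site).
#' @return Fraction in [0, 1], or `NA`.
#' @export
proportion_presences <- function(records, cx, cy, radius, exclude = NULL) {
  if (!is_scalar_number(radius) || radius <= 0) stopf("radius must be positive")
  idx <- in_radius(records, cx, cy, radius, exclude)
  if (length(idx) == 0) return(NA_real_)
  mean(records$coverage[idx] > 0)
}

#' Mean coverage within a radius
#'
#' Spatial autocovariate: the arithmetic mean of observed coverages within
#' `radius` of the point; `NA` when the neighbourhood is empty.
#'
#' @inheritParams proportion_presences
#' @return Fraction in [0, 1], or `NA`.
#' @export
mean_coverage <- function(records, cx, cy, radius, exclude = NULL) {
  if (!is_scalar_number(radius) || radius <= 0) stopf("radius must be positive")
  idx <- in_radius(records, cx, cy, radius, exclude)
  if (length(idx) == 0) return(NA_real_)
  mean(records$coverage[idx])
}

#' Distance-weighted mean coverage within a radius
#'
#' Inverse-distance-weighted mean of observed coverages within `radius`:
#' weights `1 / max(d, floor_dist)^power`, with the distance floored (by
#' default at half a 10 m cell) so a record at the centre does not dominate
#' with an infinite weight.
#'
#' @inheritParams proportion_presences
#' @param power inverse-distance exponent (> 0; default 1).
#' @param floor_dist minimum distance used in the weights, metres.
#' @return Fraction in [0, 1], or `NA`.
#' @export
idw_mean_coverage <- function(records, cx, cy, radius, power = 1,
                              floor_dist = 5, exclude = NULL) {
  if (!is_scalar_number(radius) || radius <= 0) stopf("radius must be positive")
  if (!is_scalar_number(power) || power <= 0) stopf("power must be positive")
  idx <- in_radius(records, cx, cy, radius, exclude)
  if (length(idx) == 0) return(NA_real_)
  d <- sqrt((records$x[idx] - cx)^2 + (records$y[idx] - cy)^2)
  w <- 1 / pmax(d, floor_dist)^power
  sum(w * records$coverage[idx]) / sum(w)
}

#' Build the autocovariate site features at point locations
#'
#' Computes the neighbourhood autocovariates of the predictive sets —
#' proportion of presences (radii 100 and 1000 m), mean coverage (100 and
#' 1000 m) and distance-weighted mean coverage (10 000 m) — at arbitrary
#' points, from the thinned record set. When the evaluation points are the
#' records themselves (`self = TRUE`), each record is excluded from its own
#' neighbourhood so the feature never leaks the record's own coverage.
#'
#' @param records thinned observation records.
#' @param points data.frame with `x`, `y` of evaluation points; defaults to
#'   the records themselves (with `self = TRUE`).
#' @param self logical: exclude the focal record from its neighbourhood
#'   (row-wise identity between `points` and `records` assumed).
#' @param radii_prop,radii_mean,radius_idw radii (m) for the three feature
#'   families.
#' @param power inverse-distance exponent for the distance-weighted mean.
#' @return data.frame with one column per autocovariate, e.g.
#'   `prop_presence_100`, `mean_coverage_1000`, `idw_coverage_10000`.
#' @export
build_autocovariates <- function(records, points = records, self = missing(points),
                                 radii_prop = c(100, 1000),
                                 radii_mean = c(100, 1000),
                                 radius_idw = 10000, power = 1) {
  check_records(records)
  np <- nrow(points)
  out <- list()
  for (r in radii_prop)
    out[[sprintf("prop_presence_%g", r)]] <- vapply(seq_len(np), function(i)
      proportion_presences(records, points$x[i], points$y[i], r,
                           exclude = if (self) i else NULL), numeric(1))
  for (r in radii_mean)
    out[[sprintf("mean_coverage_%g", r)]] <- vapply(seq_len(np), function(i)
      mean_coverage(records, points$x[i], points$y[i], r,
                    exclude = if (self) i else NULL), numeric(1))
  for (r in radius_idw)
    out[[sprintf("idw_coverage_%g", r)]] <- vapply(seq_len(np), function(i)
      idw_mean_coverage(records, points$x[i], points$y[i], r, power = power,
                        exclude = if (self) i else NULL), numeric(1))
  as.data.frame(out)
}

#' Autocovariate layers on a grid
#'
#' Evaluates [build_autocovariates()] at every cell centre of a template
#' grid, returning one [grid_raster] per autocovariate. Cell centres are
#' not observation sites, so no neighbourhood exclusion applies.
#'
#' @param records thinned observation records.
#' @param template a [grid_raster] defining the output cells.
#' @param ... passed to [build_autocovariates()] (radii, power).
#' @return Named list of numeric [grid_raster] layers.
#' @export
autocovariate_grids <- function(records, template, ...) {
  stopifnot(inherits(template, "grid_raster"))
  nr <- nrow(template$values); nc <- ncol(template$values)
  idx <- cbind(rep(seq_len(nr), times = nc), rep(seq_len(nc), each = nr))
  ctr <- cell_center(template, idx[, 1], idx[, 2])
  ac <- build_autocovariates(records, data.frame(x = ctr[, 1], y = ctr[, 2]),
                             self = FALSE, ...)
  lapply(ac, function(v)
    grid_raster(matrix(v, nr, nc), template$xll, template$yll,
                template$cellsize))
}

#' Sample raster site features at point locations
#'
#' Looks up each layer of a named list of [grid_raster]s at the given
#' points ([sample_feature_at()]), returning a feature data.frame whose
#' categorical layers become character columns.
#'
#' @param grids named list of [grid_raster] layers.
#' @param points data.frame with `x`, `y`.
#' @return data.frame with one column per layer.
#' @export
sample_site_features <- function(grids, points) {
  out <- lapply(grids, function(g) {
    v <- sample_feature_at(g, points$x, points$y)
    if (isTRUE(g$categorical)) ifelse(is.na(v), NA_character_, as.character(v)) else v
  })
  as.data.frame(out, optional = TRUE)
}
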