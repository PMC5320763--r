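#' Predict coverage, certainty and mean similarity over the output grid
#'
#' Runs the per-partition inference over every cell of the partition map:
#' proved-absence cells are fixed at coverage 0 (no decision is computed);
#' probable-presence cells get a coverage decision from that partition's
#' predictive set; unclear cells get a two-stage decision — presence/absence
#' first, then coverage only where presence was predicted (absence-predicted
#' cells get coverage 0). Cell features are evaluated at cell centres:
#' raster layers by point lookup, autocovariates from the thinned records.
#'
#' @param pmap partition label [grid_raster] from [classify_cells()]; also
#'   defines the output grid.
#' @param fits named list of fitted [simfit] models:
#'   `probable_presence` (coverage), `unclear` (presence/absence) and
#'   optionally `unclear_coverage` (coverage for predicted presence sites in
#'   the unclear partition; falls back to `probable_presence`).
#' @param feature_grids named list of [grid_raster] site-feature layers
#'   (sampled at cell centres under their layer names).
#' @param records thinned observation records used for the autocovariate
#'   features; `NULL` to skip autocovariates.
#' @param autocov_args arguments passed to [build_autocovariates()] (radii,
#'   power).
#' @return Named list of [grid_raster] layers: `coverage` in [0, 1] (0 in
#'   proved absence), `certainty` in (0, 1] where a class decision was made,
#'   `mean_similarity` in [0, 1] for the decision that produced each cell's
#'   value. Cells with no usable similarity stay NODATA.
#' @export
predict_grid <- function(pmap, fits, feature_grids = list(), records = NULL,
                         autocov_args = list()) {
  stopifnot(inherits(pmap, "grid_raster"))
  lab <- as.vector(pmap$values)
  ncell <- length(lab)
  nr <- nrow(pmap$values); nc <- ncol(pmap$values)
  idx <- cbind(row = rep(seq_len(nr), times = nc),
               col = rep(seq_len(nc), each = nr))
  ctr <- cell_center(pmap, idx[, 1], idx[, 2])
  pts <- data.frame(x = ctr[, 1], y = ctr[, 2])
  feats <- NULL
  if (length(feature_grids) > 0) {
    for (g in feature_grids)
      if (!grids_aligned(pmap, g) && g$cellsize > pmap$cellsize)
        stopf("feature grids must cover the output grid")
    feats <- sample_site_features(feature_grids, pts)
  }
  if (!is.null(records)) {
    ac <- do.call(build_autocovariates,
                  c(list(records = records, points = pts, self = FALSE),
                    autocov_args))
    feats <- if (is.null(feats)) ac else cbind(feats, ac)
  }
  if (is.null(feats)) stopf("no site features available for prediction")

  coverage <- rep(NA_real_, ncell)
  certainty <- rep(NA_real_, ncell)
  meansim <- rep(NA_real_, ncell)

  coverage[lab == 1] <- 0  # proved absence is the partition's definition

  i_pp <- which(lab == 2)
  if (length(i_pp) > 0) {
    fit <- fits$probable_presence
    if (is.null(fit)) stopf("no predictive set for the probable_presence partition")
    p <- predict(fit, feats[i_pp, , drop = FALSE], type = "full")
    coverage[i_pp] <- p$value
    meansim[i_pp] <- p$mean_similarity
  }
  i_un <- which(lab == 3)
  if (length(i_un) > 0) {
    fit <- fits$unclear
    if (is.null(fit)) stopf("no predictive set for the unclear partition")
    p <- predict(fit, feats[i_un, , drop = FALSE], type = "full")
    certainty[i_un] <- p$certainty
    meansim[i_un] <- p$mean_similarity
    pres <- !is.na(p$value) & p$value == "presence"
    coverage[i_un[!is.na(p$value) & p$value == "absence"]] <- 0
    if (any(pres)) {
      cfit <- fits$unclear_coverage
      if (is.null(cfit)) cfit <- fits$probable_presence
      if (is.null(cfit)) stopf("no coverage predictive set for predicted presence sites")
      ii <- i_un[pres]
      pc <- predict(cfit, feats[ii, , drop = FALSE], type = "full")
      coverage[ii] <- pc$value
      # report the similarity of the decision that set the cell's coverage
      meansim[ii] <- ifelse(is.na(pc$mean_similarity), meansim[ii],
                            pc$mean_similarity)
    }
  }
  n_nodata <- sum(is.na(coverage) & lab != 1)
  if (n_nodata > 0)
    message(sprintf("predict_grid: %d cell(s) with no usable similarity stay NODATA",
                    n_nodata))
  as_layer <- function(v) grid_raster(matrix(v, nr, nc), pmap$xll, pmap$yll,
                                      pmap$cellsize)
  list(coverage = as_layer(coverage), certainty = as_layer(certainty),
       mean_similarity = as_layer(meansim))
}

#' Overlay observed records onto a predicted coverage layer
#'
#' Field records are taken to be more reliable than calculated values: every
#' cell containing at least one record is replaced by the mean observed
#' coverage of its records; all other cells are unchanged. The number of
#' replaced cells is recorded in attribute `"cells_modified"`.
#'
#' @param coverage a coverage [grid_raster].
#' @param records observation records (`x`, `y`, `coverage`).
#' @return The modified [grid_raster].
#' @export
overlay_observations <- function(coverage, records) {
  check_records(records)
  rc <- cell_of(coverage, records$x, records$y)
  ok <- !is.na(rc[, 1])
  out <- coverage
  n_mod <- 0L
  if (any(ok)) {
    key <- paste(rc[ok, 1], rc[ok, 2])
    means <- tapply(records$coverage[ok], key, mean)
    cells <- do.call(rbind, strsplit(names(means), " "))
    cells <- cbind(as.integer(cells[, 1]), as.integer(cells[, 2]))
    out$values[cells] <- as.numeric(means)
    n_mod <- nrow(cells)
  }
  attr(out, "cells_modified") <- n_mod
  out
}

#' Summarise a mapping run
#'
#' Collects the run-level quantities a mapping report needs: per-partition
#' validation objectives of the fitted predictive sets, exemplars retained,
#' specificity against the observed records (share of zero-coverage truths
#' predicted zero at their cells, before overlay), and histograms of the
#' predicted coverage and mean-similarity layers.
#'
#' @param layers layer list from [predict_grid()].
#' @param records observation records.
#' @param fits the fitted [simfit] models used for the run.
#' @param zero_tol predictions at or below this count as zero coverage for
#'   the specificity share (default 0.05 on the 0-1 scale).
#' @return A list of class `casemap_report`.
#' @export
summarize_run <- function(layers, records, fits, zero_tol = 0.05) {
  check_records(records)
  cov <- layers$coverage
  pred_at_rec <- sample_feature_at(cov, records$x, records$y)
  truth_zero <- records$coverage == 0
  ok <- !is.na(pred_at_rec)
  spec_share <- if (any(ok & truth_zero))
    mean(pred_at_rec[ok & truth_zero] <= zero_tol) else NA_real_
  breaks <- seq(0, 1, 0.1)
  hist_of <- function(v) {
    v <- v[!is.na(v)]
    h <- hist(pmin(pmax(v, 0), 1), breaks = breaks, plot = FALSE)
    stats::setNames(h$counts, paste0("(", utils::head(breaks, -1), ",",
                                     utils::tail(breaks, -1), "]"))
  }
  objectives <- lapply(fits, function(f)
    if (inherits(f, "simfit"))
      stats::setNames(f$objective, f$objective_name) else NULL)
  exemplars <- vapply(fits, function(f)
    if (inherits(f, "simfit")) length(f$base$ids) else NA_integer_, integer(1))
  structure(list(objectives = objectives,
                 exemplars_retained = exemplars,
                 specificity_zero_coverage = spec_share,
                 n_records = nrow(records),
                 coverage_histogram = hist_of(as.vector(cov$values)),
                 similarity_histogram = hist_of(as.vector(layers$mean_similarity$values)),
                 n_cells = length(cov$values),
                 n_cells_predicted = sum(!is.na(cov$values))),
            class = "casemap_report")
}

#' @export
print.casemap_report <- function(x, ...) {
  cat("Similarity-based mapping run\n")
  for (nm in names(x$objectives)) {
    o <- x$objectives[[nm]]
    if (!is.null(o))
      cat(sprintf("  %s: validation %s = %.4f (%d exemplars)\n", nm,
                  toupper(names(o)), o, x$exemplars_retained[[nm]]))
  }
  if (!is.na(x$specificity_zero_coverage))
    cat(sprintf("  zero-coverage records predicted zero: %.1f%%\n",
                100 * x$specificity_zero_coverage))
  cat(sprintf("  cells predicted: %d of %d\n", x$n_cells_predicted, x$n_cells))
  invisible(x)
}
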