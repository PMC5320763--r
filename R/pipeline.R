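#' Default partition rules based on neighbourhood autocovariates
#'
#' The four most firm presence predictors default to the spatial
#' autocovariates of the species' own records — the feature family that
#' carries most of the predictive weight in this kind of mapping — with
#' presence indicated where the local share of presences or the local mean
#' coverage is clearly above the background. The 1000 m features carry
#' higher thresholds than the 100 m ones: at the kilometre scale they
#' approach the study-wide prevalence, and a firm presence indication must
#' stand clearly above that background.
#'
#' @param absence_share_threshold,min_predictors_agreeing see
#'   [partition_rules()].
#' @return A [partition_rules] object.
#' @export
default_partition_rules <- function(absence_share_threshold = 0.01,
                                    min_predictors_agreeing = 2) {
  partition_rules(
    top_predictors = list(
      list(feature = "prop_presence_100", op = "ge", value = 0.2),
      list(feature = "prop_presence_1000", op = "ge", value = 0.5),
      list(feature = "mean_coverage_100", op = "ge", value = 0.05),
      list(feature = "mean_coverage_1000", op = "ge", value = 0.2)),
    absence_share_threshold = absence_share_threshold,
    min_predictors_agreeing = min_predictors_agreeing)
}

fit_pool <- function(pool_name, data, target_type, control) {
  n <- nrow(data)
  if (n < 20) {
    warnf("partition '%s': only %d record(s); predictive set not fitted",
          pool_name, n)
    return(NULL)
  }
  if (target_type == "class") {
    data$.target <- factor(ifelse(data$coverage > 0, "presence", "absence"))
    if (length(unique(data$.target)) < 2) {
      warnf("partition '%s': single-class records; class set not fitted",
            pool_name)
      return(NULL)
    }
  } else {
    data$.target <- data$coverage
  }
  feats <- setdiff(names(data), c("x", "y", "coverage", "source", ".target"))
  f <- stats::reformulate(feats, response = ".target")
  suppressWarnings(simfit(f, data, control = control))
}

#' Run the full similarity-based mapping workflow
#'
#' Orchestrates the whole pipeline on point records and fine feature
#' rasters: thin the records to the minimum spacing; aggregate the
#' categorical layers to the output grid and combine them into strata;
#' derive the autocovariate layers; classify the area into proved-absence /
#' probable-presence / unclear partitions; route the records into per-
#' partition learning pools; learn a predictive set per partition (coverage
#' in the probable-presence partition; presence/absence, then coverage at
#' predicted presence sites, in the unclear partition); predict the output
#' grid; overlay the observed records; and summarise the run.
#'
#' @param records observation records (`x`, `y`, `coverage`, `source`).
#' @param fine_grids named list of categorical [grid_raster] feature layers
#'   at the fine (input) resolution.
#' @param rules a [partition_rules]; default [default_partition_rules()].
#' @param output_cellsize output grid interval in metres (default 100).
#' @param thin_dist minimum record spacing in metres (default 50).
#' @param control a [simfit_control]; `control$seed` drives all learning
#'   randomness (per-partition fits use consecutive derived seeds).
#' @param autocov_args arguments for [build_autocovariates()].
#' @return List with `records` (thinned), `pmap`, `pools`, `fits`,
#'   `layers` (coverage / certainty / mean_similarity), `coverage_final`
#'   (after record overlay) and `report`.
#' @export
run_mapping <- function(records, fine_grids, rules = default_partition_rules(),
                        output_cellsize = 100, thin_dist = 50,
                        control = simfit_control(), autocov_args = list()) {
  check_records(records)
  if (length(fine_grids) == 0 || is.null(names(fine_grids)))
    stopf("fine_grids must be a named list of rasters")
  rec <- thin_records(records, thin_dist)

  fact <- output_cellsize / fine_grids[[1]]$cellsize
  if (abs(fact - round(fact)) > 1e-9)
    stopf("output_cellsize must be a multiple of the input cell size")
  coarse <- lapply(fine_grids, aggregate_raster, fact = round(fact))
  strata <- combine_strata(coarse[vapply(coarse, function(g) g$categorical,
                                         logical(1))])
  acov <- do.call(autocovariate_grids,
                  c(list(records = rec, template = strata), autocov_args))
  pmap <- classify_cells(rec, c(coarse, acov), rules, strata)
  pools <- route_records(rec, pmap)

  # per-record training features: fine layers at the record points plus
  # self-excluded autocovariates
  site <- sample_site_features(fine_grids, rec)
  ac <- do.call(build_autocovariates,
                c(list(records = rec, points = rec, self = TRUE),
                  autocov_args))
  rec_feats <- cbind(rec, site, ac)
  pool_feats <- lapply(pools, function(p) rec_feats[rownames(p), , drop = FALSE])

  ctrl_for <- function(offset) {
    c2 <- control; c2$seed <- as.integer(control$seed + offset); c2
  }
  fits <- list(
    probable_presence = fit_pool("probable_presence",
                                 pool_feats$probable_presence, "numeric",
                                 ctrl_for(1)),
    unclear = fit_pool("unclear", pool_feats$unclear, "class", ctrl_for(2)),
    unclear_coverage = fit_pool("unclear_coverage", pool_feats$unclear,
                                "numeric", ctrl_for(3)))
  # a partition with cells but no fitted set falls back to the pooled data
  needs <- table(factor(as.vector(pmap$values), levels = 1:3))
  if ((needs[["2"]] > 0 && is.null(fits$probable_presence)) ||
      (needs[["3"]] > 0 && is.null(fits$unclear_coverage))) {
    fallback <- fit_pool("all", rec_feats, "numeric", ctrl_for(4))
    if (is.null(fits$probable_presence)) fits$probable_presence <- fallback
    if (is.null(fits$unclear_coverage)) fits$unclear_coverage <- fallback
  }
  if (needs[["3"]] > 0 && is.null(fits$unclear))
    fits$unclear <- fit_pool("all", rec_feats, "class", ctrl_for(5))

  layers <- predict_grid(pmap, fits, feature_grids = fine_grids,
                         records = rec, autocov_args = autocov_args)
  final <- overlay_observations(layers$coverage, rec)
  report <- summarize_run(layers, rec, fits)
  list(records = rec, pmap = pmap, pools = pools, fits = fits,
       layers = layers, coverage_final = final, report = report)
}
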