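#' Partition rule configuration
#'
#' Rules for pre-classifying the study area into proved-absence,
#' probable-presence and unclear regions. A stratum (land-cover x soil
#' category combination) proves absence when it holds more than
#' `absence_share_threshold` of all observation records and none of them is
#' a presence. A cell indicates probable presence when at least
#' `min_predictors_agreeing` of the declared top presence predictors hold
#' there. Probable presence takes precedence over proved absence.
#'
#' @param top_predictors list of predicates, each a list with `feature`
#'   (layer or feature name), `op` (`"in"`, `"ge"`, `"le"`) and `value`
#'   (category set, or numeric threshold). Typically the four most firm
#'   presence predictors identified by an upstream feature screening.
#' @param absence_share_threshold record share a stratum must exceed to
#'   prove absence (default 0.01).
#' @param min_predictors_agreeing predictors that must agree for probable
#'   presence (default 2).
#' @return A list of class `partition_rules`.
#' @export
partition_rules <- function(top_predictors = list(),
                            absence_share_threshold = 0.01,
                            min_predictors_agreeing = 2) {
  if (!is_scalar_number(absence_share_threshold) ||
      absence_share_threshold <= 0 || absence_share_threshold >= 1)
    stopf("absence_share_threshold must be in (0, 1)")
  if (min_predictors_agreeing > max(length(top_predictors), 0) &&
      length(top_predictors) > 0)
    stopf("min_predictors_agreeing exceeds the number of predictors")
  structure(list(top_predictors = top_predictors,
                 absence_share_threshold = absence_share_threshold,
                 min_predictors_agreeing = as.integer(min_predictors_agreeing)),
            class = "partition_rules")
}

eval_predicate <- function(pred, values) {
  v <- values[[pred$feature]]
  if (is.null(v)) stopf("predicate refers to unknown feature '%s'", pred$feature)
  out <- switch(pred$op,
                "in" = as.character(v) %in% as.character(pred$value),
                "ge" = !is.na(v) & as.numeric(v) >= pred$value,
                "le" = !is.na(v) & as.numeric(v) <= pred$value,
                stopf("unknown predicate op '%s'", pred$op))
  out & !is.na(v)
}

#' Combine categorical layers into a stratum grid
#'
#' Each distinct combination of the input layers' categories becomes one
#' stratum code; cells with NODATA in any layer are NODATA.
#'
#' @param grids named list of categorical [grid_raster]s, mutually aligned.
#' @return A categorical [grid_raster] of stratum codes, with the
#'   combination labels in attribute `"strata"`.
#' @export
combine_strata <- function(grids) {
  stopifnot(length(grids) >= 1)
  ref <- grids[[1]]
  for (g in grids) if (!grids_aligned(ref, g)) stopf("stratum layers are not aligned")
  key <- do.call(paste, c(lapply(grids, function(g) as.vector(g$values)), sep = "|"))
  key[Reduce(`|`, lapply(grids, function(g) is.na(g$values)))] <- NA
  levels <- sort(unique(key[!is.na(key)]))
  codes <- matrix(match(key, levels), nrow(ref$values), ncol(ref$values))
  out <- grid_raster(codes, ref$xll, ref$yll, ref$cellsize, categorical = TRUE)
  attr(out, "strata") <- levels
  out
}

#' Classify output cells into spatial partitions
#'
#' Labels every cell of the output grid as proved absence (1), probable
#' presence (2) or unclear (3). Absence is proved per stratum: a category
#' combination with more than the configured share of all records and zero
#' presences. Probable presence is declared cell-wise where enough of the
#' top presence predictors agree, and overrides proved absence. Everything
#' else is unclear.
#'
#' @param records thinned observation records (`x`, `y`, `coverage`).
#' @param feature_grids named list of [grid_raster] layers referenced by
#'   the rule predicates (must align with `strata`).
#' @param rules a [partition_rules].
#' @param strata categorical [grid_raster] of stratum codes (e.g. from
#'   [combine_strata()]), defining the output grid.
#' @return A [grid_raster] of partition labels with the label legend in
#'   attribute `"labels"`.
#' @export
classify_cells <- function(records, feature_grids, rules, strata) {
  check_records(records)
  stopifnot(inherits(rules, "partition_rules"), inherits(strata, "grid_raster"))
  for (g in feature_grids)
    if (!grids_aligned(strata, g)) stopf("feature grids must align with the stratum grid")
  # per-record stratum
  rec_stratum <- sample_feature_at(strata, records$x, records$y)
  n_rec <- nrow(records)
  tab <- table(rec_stratum)
  share <- as.numeric(tab) / n_rec
  has_presence <- vapply(as.numeric(names(tab)), function(s)
    any(records$coverage[!is.na(rec_stratum) & rec_stratum == s] > 0), logical(1))
  absent_strata <- as.numeric(names(tab))[share > rules$absence_share_threshold &
                                            !has_presence]
  lab <- matrix(3L, nrow(strata$values), ncol(strata$values))  # unclear
  lab[strata$values %in% absent_strata] <- 1L                  # proved absence
  if (length(rules$top_predictors) > 0) {
    vals <- lapply(feature_grids, function(g) {
      v <- as.vector(g$values)
      if (isTRUE(g$categorical)) as.character(v) else v
    })
    agree <- Reduce(`+`, lapply(rules$top_predictors, function(p)
      as.integer(eval_predicate(p, vals))))
    lab[matrix(agree >= rules$min_predictors_agreeing,
               nrow(lab), ncol(lab))] <- 2L                    # probable presence
  }
  out <- grid_raster(lab, strata$xll, strata$yll, strata$cellsize,
                     categorical = TRUE)
  attr(out, "labels") <- c("proved_absence", "probable_presence", "unclear")
  out
}

#' Route records to partition learning pools
#'
#' Assigns each record to the pool of the partition whose cell contains it.
#' A separate set of learning data is used in each partition, so the pools
#' partition the record set exactly.
#'
#' @param records observation records.
#' @param pmap partition label [grid_raster] from [classify_cells()].
#' @return Named list of record data.frames (`proved_absence`,
#'   `probable_presence`, `unclear`); empty partitions yield empty
#'   data.frames with a warning when learning is later skipped.
#' @export
route_records <- function(records, pmap) {
  check_records(records)
  lab <- sample_feature_at(pmap, records$x, records$y)
  if (anyNA(lab)) {
    bad <- which(is.na(lab))
    stopf("record(s) outside the partition grid: rows %s",
          paste(utils::head(bad, 10), collapse = ", "))
  }
  labels <- attr(pmap, "labels")
  if (is.null(labels)) labels <- c("proved_absence", "probable_presence", "unclear")
  out <- lapply(seq_along(labels), function(i) records[lab == i, , drop = FALSE])
  names(out) <- labels
  out
}
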