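#' Read observation records from CSV
#'
#' Expects a header with at least `x`, `y`, `coverage` and optionally
#' `source` (`"active"`/`"track"`; defaults to `"active"`). Every row is
#' validated; malformed rows are reported with their row number and field.
#'
#' @param path CSV file path.
#' @return data.frame of validated records.
#' @export
read_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "coverage")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stopf("'%s': missing column(s): %s", path, paste(miss, collapse = ", "))
  if (!"source" %in% names(df)) df$source <- rep("active", nrow(df))
  for (col in c("x", "y", "coverage")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad) > 0)
      stopf("'%s': non-numeric or missing '%s' in data row %d", path, col, bad[1])
    df[[col]] <- v
  }
  bad <- which(df$coverage < 0 | df$coverage > 1)
  if (length(bad) > 0)
    stopf("'%s': coverage out of [0, 1] in data row %d (value %g)",
          path, bad[1], df$coverage[bad[1]])
  bad <- which(!df$source %in% c("active", "track"))
  if (length(bad) > 0)
    stopf("'%s': source must be 'active' or 'track' (data row %d)", path, bad[1])
  df[c("x", "y", "coverage", "source")]
}

#' Write observation records to CSV
#'
#' @param records data.frame with `x`, `y`, `coverage` (and `source`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_points <- function(records, path) {
  check_records(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_defaults <- function() {
  list(
    points = NULL,             # path to the observation CSV
    rasters = list(),          # named list of layer name -> .asc path
    categorical = character(), # layer names that are categorical
    thin_distance = 50,        # m
    radii_proportion = c(100, 1000),
    radii_mean_coverage = c(100, 1000),
    radius_idw = 10000,
    idw_power = 1,
    output_cellsize = 100,     # m, prediction grid interval
    train_size = 500,
    val_size = 1000,
    initial_k = 5,
    iterations = 200,
    seed = 1,
    absence_share_threshold = 0.01,
    min_predictors_agreeing = 2,
    top_predictors = list(),
    output_dir = "."
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, fills in the documented defaults
#' (thinning distance 50 m; autocovariate radii 100/1000 m, distance
#' weighted at 10 000 m; modal radii per layer; training sample 500,
#' validation sample 1000, initial similarity budget 5, 200 iterations;
#' output grid 100 m) and rejects unknown keys.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Named list of configuration values.
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stopf("unknown configuration key(s): %s\nvalid keys: %s",
          paste(unknown, collapse = ", "),
          paste(names(defaults), collapse = ", "))
  out <- utils::modifyList(defaults, user)
  if (!is_scalar_number(out$thin_distance) || out$thin_distance <= 0)
    stopf("thin_distance must be positive")
  if (out$iterations < 0) stopf("iterations must be >= 0")
  out
}

#' Serialise a learned weight state to a key-value file
#'
#' Writes the feature weights and similarity budget as YAML and the
#' exemplar weights as a CSV table next to it.
#'
#' @param fit a [simfit] object.
#' @param path output path for the YAML file; the exemplar table goes to
#'   `<path>_exemplars.csv`.
#' @return `path`, invisibly.
#' @export
write_weight_state <- function(fit, path) {
  stopifnot(inherits(fit, "simfit"))
  yaml::write_yaml(list(k = fit$k,
                        objective = fit$objective_name,
                        best_objective = fit$objective,
                        feature_weights = as.list(
                          stats::setNames(fit$specs$weight, fit$specs$name))),
                   path)
  utils::write.csv(data.frame(id = fit$base$ids, weight = fit$base$weights,
                              target = fit$base$target),
                   paste0(path, "_exemplars.csv"), row.names = FALSE)
  invisible(path)
}
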