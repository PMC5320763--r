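#' Feature specifications for similarity computation
#'
#' Builds the per-feature metadata the similarity metric needs: the feature
#' kind (numeric or categorical), a non-negative feature weight `wf`, and,
#' for numeric features, the standard deviation used to scale differences.
#' Standard deviations are computed once from the supplied (training) data
#' and frozen; prediction-time data never changes them.
#'
#' @param data data.frame of feature columns. Factor, character and logical
#'   columns become categorical features; numeric columns numeric features.
#' @param weights named or unnamed numeric vector of initial feature weights
#'   (default all 1). Non-negative.
#' @return A data.frame of class `feature_specs` with columns `name`,
#'   `kind`, `weight`, `sd`.
#' @examples
#' d <- data.frame(elev = rnorm(10), soil = factor(sample(letters[1:3], 10, TRUE)))
#' feature_specs(d)
#' @export
feature_specs <- function(data, weights = NULL) {
  stopifnot(is.data.frame(data), ncol(data) > 0)
  nm <- names(data)
  if (anyDuplicated(nm)) stopf("feature names must be unique")
  kind <- vapply(data, function(col) {
    if (is.numeric(col)) "numeric" else "categorical"
  }, character(1))
  if (is.null(weights)) weights <- rep(1, ncol(data))
  if (!is.null(names(weights))) weights <- weights[nm]
  if (length(weights) != ncol(data) || anyNA(weights) || any(weights < 0))
    stopf("weights must be non-negative, one per feature")
  sds <- rep(NA_real_, ncol(data))
  for (j in which(kind == "numeric")) {
    s <- stats::sd(data[[j]], na.rm = TRUE)
    if (!is.finite(s) || s <= 0) {
      if (weights[j] > 0) {
        warnf("numeric feature '%s' has zero variance; its weight is set to 0", nm[j])
        weights[j] <- 0
      }
      s <- NA_real_
    }
    sds[j] <- s
  }
  structure(data.frame(name = nm, kind = kind, weight = as.numeric(weights),
                       sd = sds, stringsAsFactors = FALSE),
            class = c("feature_specs", "data.frame"))
}

#' Exemplar base
#'
#' The case base used for similarity-based inference: one row per exemplar
#' site, with its feature vector, target (coverage fraction in [0, 1] or a
#' presence/absence class) and a non-negative exemplar weight `we`.
#'
#' @param features data.frame of feature columns (one row per exemplar).
#'   Missing values are allowed and are skipped feature-wise at inference.
#' @param target numeric coverage fractions in [0, 1], or a factor/character
#'   vector with values `"absence"`/`"presence"`.
#' @param ids unique exemplar identifiers (default row numbers).
#' @param weights non-negative exemplar weights (default all 1).
#' @return An object of class `exemplar_base`.
#' @export
exemplar_base <- function(features, target, ids = NULL, weights = NULL) {
  stopifnot(is.data.frame(features))
  n <- nrow(features)
  if (length(target) != n) stopf("target length must match feature rows")
  if (is.numeric(target)) {
    if (any(!is.na(target) & (target < 0 | target > 1)))
      stopf("coverage targets must lie in [0, 1]")
    type <- "numeric"
  } else {
    target <- as.character(target)
    if (!all(target %in% c("absence", "presence")))
      stopf("class targets must be 'absence' or 'presence'")
    type <- "class"
  }
  if (is.null(ids)) ids <- seq_len(n)
  if (anyDuplicated(ids)) stopf("exemplar ids must be unique")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) stopf("weights must be non-negative, one per exemplar")
  structure(list(features = features, target = target, ids = ids,
                 weights = as.numeric(weights), target_type = type),
            class = "exemplar_base")
}

#' @export
print.exemplar_base <- function(x, ...) {
  cat(sprintf("exemplar_base: %d exemplars (%d active), %d features, %s target\n",
              length(x$ids), sum(x$weights > 0), ncol(x$features), x$target_type))
  invisible(x)
}

check_finite_scalar <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) stopf("%s must be finite", what)
}

#' Partial similarity for a numeric feature
#'
#' Weighted partial similarity between an observation value and an exemplar
#' value for a single numeric feature:
#' `PS = wf * we * (1 - |Fe - Fo| / (k * SD * wf * we))`,
#' with negative values clamped to zero. A feature with a larger weight
#' tolerates a wider value difference before its contribution reaches zero.
#'
#' @param obs_value,ex_value feature values (vectorised).
#' @param wf feature weight (> 0; zero-weight features are skipped upstream).
#' @param sd standard deviation of the feature over the training data (> 0).
#' @param we exemplar weight (> 0).
#' @param k similarity budget scaling the accepted difference (> 0).
#' @return Partial similarity in `[0, wf * we]`; equals `wf * we` iff the
#'   values are equal.
#' @examples
#' partial_similarity_numeric(0.4, 0.0, wf = 0.5, sd = 1, k = 2)  # 0.3
#' @export
partial_similarity_numeric <- function(obs_value, ex_value, wf, sd, we = 1, k = 2) {
  check_finite_scalar(obs_value, "obs_value"); check_finite_scalar(ex_value, "ex_value")
  if (!is_scalar_number(sd) || sd <= 0) stopf("sd must be a positive number")
  if (!is_scalar_number(wf) || wf <= 0) stopf("wf must be positive (zero-weight features are skipped)")
  if (!is_scalar_number(we) || we <= 0) stopf("we must be positive (zero-weight exemplars are skipped)")
  if (!is_scalar_number(k) || k <= 0) stopf("k must be positive")
  # wf*we*(1 - |d|/(k*sd*wf*we)) simplifies to wf*we - |d|/(k*sd)
  pmax(0, wf * we - abs(obs_value - ex_value) / (k * sd))
}

#' Partial similarity for a categorical feature
#'
#' Matching categories have similarity one, different categories zero,
#' scaled by the feature and exemplar weights: `PS = Sc * wf * we` with
#' `Sc` the 0/1 category match indicator.
#'
#' @param obs_cat,ex_cat category codes or labels (vectorised).
#' @param wf feature weight.
#' @param we exemplar weight.
#' @return `wf * we` where the categories match, 0 otherwise.
#' @export
partial_similarity_categorical <- function(obs_cat, ex_cat, wf, we = 1) {
  ifelse(!is.na(obs_cat) & !is.na(ex_cat) & obs_cat == ex_cat, wf * we, 0)
}

#' Total similarity between an observation and an exemplar
#'
#' Weight-normalised mean of partial similarities over usable features:
#' `TS = sum_f PS(Of, Ef) / sum_f (wf * we)`. Zero-weight features are
#' skipped, as are features missing on either side, so data absence reduces
#' the evidence base rather than blocking the comparison. The result lies
#' in [0, 1] and equals 1 for identical usable feature vectors.
#'
#' @param obs named list or one-row data.frame of observation feature values.
#' @param ex named list or one-row data.frame of exemplar feature values.
#' @param specs a [feature_specs] table.
#' @param we exemplar weight (> 0).
#' @param k similarity budget.
#' @return Total similarity in [0, 1].
#' @section Errors: if no feature is usable (all missing or zero-weight) a
#'   condition of class `casemap_no_usable_features` is signalled so callers
#'   can skip the exemplar.
#' @export
total_similarity <- function(obs, ex, specs, we = 1, k = 2) {
  if (is.data.frame(obs)) obs <- as.list(obs)
  if (is.data.frame(ex)) ex <- as.list(ex)
  num <- 0; den <- 0
  for (i in seq_len(nrow(specs))) {
    wf <- specs$weight[i]
    if (wf <= 0) next
    nm <- specs$name[i]
    o <- obs[[nm]]; e <- ex[[nm]]
    if (is.null(o) || is.null(e) || is.na(o) || is.na(e)) next
    ps <- if (specs$kind[i] == "numeric")
      partial_similarity_numeric(as.numeric(o), as.numeric(e), wf, specs$sd[i], we, k)
    else
      partial_similarity_categorical(o, e, wf, we)
    num <- num + ps
    den <- den + wf * we
  }
  if (den == 0)
    stopf("no usable feature shared by observation and exemplar",
          class = "casemap_no_usable_features")
  num / den
}

# Encode a feature data.frame as a double matrix for the C++ kernel:
# categorical columns become integer level codes against the union of levels
# seen in `ref` (so observation and exemplar coding agree); NA preserved.
encode_features <- function(data, specs, levels_map) {
  m <- matrix(NA_real_, nrow(data), nrow(specs))
  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[i]
    col <- data[[nm]]
    if (is.null(col)) next
    if (specs$kind[i] == "numeric") {
      m[, i] <- as.numeric(col)
    } else {
      m[, i] <- as.numeric(match(as.character(col), levels_map[[nm]]))
    }
  }
  m
}

category_levels <- function(data, specs) {
  out <- list()
  for (i in which(specs$kind == "categorical")) {
    nm <- specs$name[i]
    out[[nm]] <- sort(unique(as.character(data[[nm]][!is.na(data[[nm]])])))
  }
  out
}

#' Total-similarity matrix between observations and an exemplar base
#'
#' Computes `TS` for every observation/exemplar pair. Exemplars with weight
#' zero yield `NA` (they are skipped from inference), as do pairs with no
#' usable shared feature.
#'
#' @param obs data.frame of observation feature vectors.
#' @param base an [exemplar_base].
#' @param specs a [feature_specs] table.
#' @param k similarity budget.
#' @return A `nrow(obs)` x `n exemplars` numeric matrix.
#' @export
similarity_matrix <- function(obs, base, specs, k = 2) {
  stopifnot(inherits(base, "exemplar_base"))
  if (!is_scalar_number(k) || k <= 0) stopf("k must be positive")
  lv <- category_levels(rbind_features(obs, base$features, specs), specs)
  om <- encode_features(obs, specs, lv)
  em <- encode_features(base$features, specs, lv)
  kindcode <- as.integer(specs$kind == "categorical")
  ts <- cpp_ts_matrix(om, em, kindcode, specs$sd, specs$weight, base$weights, k)
  ts[, base$weights <= 0] <- NA_real_
  ts
}

# bind two feature frames on the spec's columns only (types may differ in
# unused columns)
rbind_features <- function(a, b, specs) {
  cols <- specs$name
  a2 <- a[intersect(cols, names(a))]
  b2 <- b[intersect(cols, names(b))]
  for (nm in cols) {
    if (is.null(a2[[nm]])) a2[[nm]] <- NA
    if (is.null(b2[[nm]])) b2[[nm]] <- NA
  }
  rbind(as.data.frame(lapply(a2[cols], as.character), stringsAsFactors = FALSE),
        as.data.frame(lapply(b2[cols], as.character), stringsAsFactors = FALSE))
}

#' Assemble a decision set under a similarity budget
#'
#' Ranks exemplars by total similarity (descending; ties broken by exemplar
#' id, so the ranking is deterministic and seed-independent) and accumulates
#' them until the summed similarity reaches the budget `k`, always including
#' the exemplar that crosses the threshold. Exemplars with zero or undefined
#' similarity carry no evidence and are excluded. If the available
#' similarity is exhausted before reaching `k`, all usable exemplars are
#' included and the set is flagged as exhausted.
#'
#' @param ts numeric vector of total similarities (NA = unusable pair).
#' @param k similarity budget (> 0).
#' @param ids exemplar identifiers aligned with `ts`.
#' @return An object of class `decision_set`: list with `ids`, `ts`
#'   (descending), `cumulative`, `exhausted`.
#' @section Errors: if no exemplar has positive similarity a condition of
#'   class `casemap_no_decision` is signalled.
#' @export
decision_set <- function(ts, k, ids = seq_along(ts)) {
  if (!is_scalar_number(k) || k <= 0) stopf("k must be positive")
  usable <- which(!is.na(ts) & ts > 0)
  if (length(usable) == 0)
    stopf("no exemplar with positive similarity: no decision possible",
          class = "casemap_no_decision")
  o <- usable[order(-ts[usable], ids[usable])]
  tso <- ts[o]
  cs <- cumsum(tso)
  m <- which(cs >= k)[1]
  exhausted <- is.na(m)
  if (exhausted) m <- length(tso)
  structure(list(ids = ids[o[seq_len(m)]], ts = tso[seq_len(m)],
                 cumulative = cs[m], exhausted = exhausted),
            class = "decision_set")
}

#' @export
print.decision_set <- function(x, ...) {
  cat(sprintf("decision_set: %d exemplars, cumulative similarity %.3f%s\n",
              length(x$ids), x$cumulative,
              if (x$exhausted) " (base exhausted)" else ""))
  invisible(x)
}

#' Numeric (coverage) decision from a decision set
#'
#' The predicted coverage is the similarity-weighted mean of the exemplar
#' coverages in the decision set; the mean similarity of the set is reported
#' alongside as a reliability indicator.
#'
#' @param ds a [decision_set].
#' @param targets named/aligned coverage values: either a vector indexed by
#'   the full base (with `ids` giving the alignment) or a function of id.
#' @param ids identifiers aligned with `targets` (default positions).
#' @return List with `value` (coverage), `mean_similarity`, `n`.
#' @export
decide_numeric <- function(ds, targets, ids = seq_along(targets)) {
  idx <- match(ds$ids, ids)
  cov <- targets[idx]
  if (!is.numeric(cov) || anyNA(cov)) stopf("decision-set exemplars must carry numeric coverage targets")
  list(value = sum(ds$ts * cov) / sum(ds$ts),
       mean_similarity = mean(ds$ts),
       n = length(ds$ts))
}

#' Class (presence/absence) decision from a decision set
#'
#' The predicted class is the one holding the largest accumulated similarity
#' in the decision set. Certainty is the share of the set's accumulated
#' similarity belonging to the predicted class: 1 means the set contains
#' only the predicted class; values near 0.5 mean nearly equal similarity to
#' both classes. An exact tie is resolved to absence (the conservative call
#' for a protected species) with certainty 0.5.
#'
#' @param ds a [decision_set].
#' @param targets class labels (`"absence"`/`"presence"`) aligned with `ids`.
#' @param ids identifiers aligned with `targets`.
#' @return List with `class`, `certainty`, `mean_similarity`, `shares`
#'   (per-class similarity shares), `n`.
#' @export
decide_class <- function(ds, targets, ids = seq_along(targets)) {
  idx <- match(ds$ids, ids)
  cls <- as.character(targets[idx])
  if (anyNA(cls)) stopf("decision-set exemplars must carry class targets")
  tot <- sum(ds$ts)
  s_pres <- sum(ds$ts[cls == "presence"])
  s_abs <- tot - s_pres
  pred <- if (s_pres > s_abs) "presence" else "absence"
  share <- max(s_pres, s_abs) / tot
  list(class = pred, certainty = share, mean_similarity = mean(ds$ts),
       shares = c(absence = s_abs / tot, presence = s_pres / tot),
       n = length(ds$ts))
}
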