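#' Fit a similarity-based predictive set
#'
#' Fits the case-based prediction model: a weighted variant of Gower's
#' similarity over mixed numeric/categorical site features, whose feature
#' weights, exemplar weights and similarity budget `k` are machine-learned
#' by stochastic hill-climbing against a validation objective. A numeric
#' response (coverage fraction in [0, 1]) is learned against RMSE; a
#' two-class factor/character/logical response (presence/absence) against
#' the True Skill Statistic. Inference retrieves, for each new site, the
#' most similar exemplars up to the similarity budget and aggregates their
#' targets (similarity-weighted mean for coverage; largest similarity share
#' for classes, with a decision certainty).
#'
#' Exemplars whose learned weight reaches zero are dropped from the stored
#' base. Numeric feature standard deviations are computed from the training
#' data and frozen into the model.
#'
#' @param formula model formula, `response ~ feature1 + feature2 + ...`.
#' @param data data.frame holding the response and feature columns; missing
#'   feature values are allowed (skipped feature-wise at inference).
#' @param objective `"auto"` (default; by response type), `"tss"` or `"rmse"`.
#' @param weights optional initial exemplar weights.
#' @param control a [simfit_control] with learning parameters.
#' @return An object of class `simfit` with methods [print.simfit()],
#'   [summary.simfit()], [coef.simfit()], [predict.simfit()],
#'   [plot.simfit()], [fitted.simfit()] and [residuals.simfit()].
#' @examples
#' set.seed(42)
#' d <- data.frame(habitat = factor(sample(c("alvar", "forest"), 80, TRUE)),
#'                 wetness = rnorm(80))
#' d$occ <- factor(ifelse(d$habitat == "alvar", "presence", "absence"))
#' fit <- simfit(occ ~ habitat + wetness, d,
#'               control = simfit_control(train_size = 40, val_size = 40,
#'                                        iterations = 20, seed = 7))
#' coef(fit)
#' predict(fit, d[1:3, ])
#' @export
simfit <- function(formula, data, objective = c("auto", "tss", "rmse"),
                   weights = NULL, control = simfit_control()) {
  objective <- match.arg(objective)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  target <- stats::model.response(mf)
  feats <- mf[, -1, drop = FALSE]
  if (ncol(feats) == 0) stopf("the model needs at least one feature")
  if (is.numeric(target)) {
    if (any(!is.na(target) & (target < 0 | target > 1)))
      stopf("numeric responses are coverage fractions and must lie in [0, 1]")
    if (anyNA(target)) stopf("the response may not contain missing values")
    target_type <- "numeric"
  } else {
    target <- as_class_label(target)
    if (anyNA(target) || !all(target %in% c("absence", "presence")))
      stopf("class responses must be two-level ('absence'/'presence' or logical)")
    target_type <- "class"
  }
  if (objective == "auto") objective <- if (target_type == "class") "tss" else "rmse"
  specs <- feature_specs(feats)
  res <- learn_weights(feats, target, specs, control = control,
                       objective = objective, exemplar_weights = weights)
  wf <- res$state$feature_weights
  we <- res$state$exemplar_weights
  keep <- we > 0
  specs$weight <- as.numeric(wf[specs$name])
  base <- exemplar_base(feats[keep, , drop = FALSE], target[keep],
                        ids = which(keep), weights = we[keep])
  obj <- structure(list(call = match.call(), formula = formula,
                        specs = specs, base = base, k = res$state$k,
                        objective_name = res$objective_name,
                        objective = res$objective, trace = res$trace,
                        control = control, n_records = nrow(feats),
                        target_type = target_type),
                   class = "simfit")
  obj
}

#' @export
print.simfit <- function(x, ...) {
  cat("Similarity-based predictive set\n")
  cat("Call: "); print(x$call)
  cat(sprintf("Response: %s (%s objective)\n", x$target_type, x$objective_name))
  cat(sprintf("Exemplars retained: %d of %d; similarity budget k = %.3g\n",
              length(x$base$ids), x$n_records, x$k))
  if (!is.na(x$objective))
    cat(sprintf("Best validation %s: %.4f\n", toupper(x$objective_name), x$objective))
  invisible(x)
}

#' Model coefficients: learned feature weights and similarity budget
#'
#' @param object a [simfit] object.
#' @param ... unused.
#' @return Named numeric vector of feature weights, with the similarity
#'   budget appended as `k`.
#' @export
coef.simfit <- function(object, ...) {
  c(stats::setNames(object$specs$weight, object$specs$name), k = object$k)
}

#' Summarise a fitted similarity model
#'
#' @param object a [simfit] object.
#' @param ... unused.
#' @return An object of class `summary.simfit`.
#' @export
summary.simfit <- function(object, ...) {
  tr <- object$trace
  structure(list(call = object$call, specs = object$specs, k = object$k,
                 objective_name = object$objective_name,
                 objective = object$objective,
                 n_exemplars = length(object$base$ids),
                 n_records = object$n_records,
                 n_accepted = sum(tr$accepted),
                 iterations = nrow(tr),
                 target_type = object$target_type),
            class = "summary.simfit")
}

#' @export
print.summary.simfit <- function(x, ...) {
  cat("Similarity-based predictive set\n")
  cat("Call: "); print(x$call)
  cat("\nLearned feature weights:\n")
  tab <- x$specs
  tab$sd <- signif(tab$sd, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("\nSimilarity budget k: %.4g\n", x$k))
  cat(sprintf("Exemplars retained: %d of %d records\n", x$n_exemplars, x$n_records))
  cat(sprintf("Accepted proposals: %d of %d iterations\n", x$n_accepted, x$iterations))
  if (!is.na(x$objective))
    cat(sprintf("Best validation %s: %.4f\n", toupper(x$objective_name), x$objective))
  invisible(x)
}

# internal: run decisions for a feature data.frame against the stored base,
# chunked so the similarity matrix never exceeds a few million entries
simfit_decide <- function(object, newdata, k = object$k, exclude_ids = NULL,
                          chunk = 4000L) {
  base <- object$base
  n <- nrow(newdata)
  excl <- rep(-1L, n)
  if (!is.null(exclude_ids)) {
    excl <- match(exclude_ids, base$ids) - 1L
    excl[is.na(excl)] <- -1L
  }
  starts <- seq(1L, n, by = chunk)
  parts <- lapply(starts, function(s) {
    rows <- s:min(s + chunk - 1L, n)
    ts <- similarity_matrix(newdata[rows, , drop = FALSE], base,
                            object$specs, k = k)
    cpp_decide_rows(ts, encode_target(base$target),
                    object$target_type == "class", k, excl[rows])
  })
  out <- list()
  for (nm in c("value", "certainty", "mean_similarity", "cumulative",
               "n_used", "exhausted"))
    out[[nm]] <- do.call(c, lapply(parts, `[[`, nm))
  out$contrib <- Reduce(`+`, lapply(parts, `[[`, "contrib"))
  out
}

#' Predict from a fitted similarity model
#'
#' For each new site the most similar exemplars are accumulated up to the
#' similarity budget and aggregated. Sites with no usable similarity to any
#' exemplar (all shared features missing, or zero similarity throughout)
#' yield `NA`.
#'
#' @param object a [simfit] object.
#' @param newdata data.frame with the model's feature columns.
#' @param type `"response"` for the predicted coverage (numeric models) or
#'   class label (class models); `"full"` for a data.frame with the value,
#'   decision certainty (class models), mean similarity of the decision set,
#'   number of exemplars used and an exhaustion flag.
#' @param k override the learned similarity budget.
#' @param ... unused.
#' @return Vector or data.frame, see `type`.
#' @export
predict.simfit <- function(object, newdata, type = c("response", "full"),
                           k = object$k, ...) {
  type <- match.arg(type)
  dec <- simfit_decide(object, newdata, k = k)
  value <- if (object$target_type == "class")
    ifelse(is.na(dec$value), NA_character_,
           ifelse(dec$value > 0, "presence", "absence"))
  else dec$value
  if (type == "response") return(value)
  data.frame(value = value, certainty = dec$certainty,
             mean_similarity = dec$mean_similarity,
             n_used = dec$n_used, exhausted = dec$exhausted)
}

#' Leave-one-out fitted values over the exemplar base
#'
#' Each retained exemplar is predicted from the rest of the base (itself
#' excluded from its decision set).
#'
#' @param object a [simfit] object.
#' @param ... unused.
#' @return Numeric vector: coverage, or presence share 0/1 for class models.
#' @export
fitted.simfit <- function(object, ...) {
  dec <- simfit_decide(object, object$base$features,
                       exclude_ids = object$base$ids)
  dec$value
}

#' Leave-one-out residuals over the exemplar base
#'
#' Observed minus leave-one-out predicted target (classes coded 0/1).
#'
#' @param object a [simfit] object.
#' @param ... unused.
#' @return Numeric vector.
#' @export
residuals.simfit <- function(object, ...) {
  encode_target(object$base$target) - fitted(object)
}

#' Plot the learning trace
#'
#' Per-iteration validation objective and the best-so-far envelope.
#'
#' @param x a [simfit] object.
#' @param ... passed to [plot()].
#' @export
plot.simfit <- function(x, ...) {
  tr <- x$trace
  if (nrow(tr) == 0) {
    warnf("no learning iterations to plot")
    return(invisible(x))
  }
  graphics::plot(tr$iteration, tr$objective, type = "l", col = "grey50",
                 xlab = "iteration",
                 ylab = sprintf("validation %s", toupper(x$objective_name)), ...)
  graphics::lines(tr$iteration, tr$best, col = "firebrick", lwd = 2)
  graphics::legend("bottomright", c("per-iteration", "best so far"),
                   col = c("grey50", "firebrick"), lwd = c(1, 2), bty = "n")
  invisible(x)
}
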