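#' True Skill Statistic for presence/absence predictions
#'
#' TSS = sensitivity + specificity - 1, ranging from -1 to +1; zero is the
#' expected value for random decisions and the statistic is insensitive to
#' prevalence. If one class is absent from the truths, the corresponding
#' term is undefined; it is treated as 0 and the result flagged degenerate.
#'
#' @param predictions,truths vectors of `"absence"`/`"presence"` labels (or
#'   logicals, `TRUE` = presence) of equal length.
#' @return List with `tss`, `sensitivity`, `specificity`, confusion counts
#'   (`tp`, `fp`, `tn`, `fn`) and `degenerate`.
#' @examples
#' evaluate_tss(c("presence", "absence"), c("presence", "absence"))$tss  # 1
#' @export
evaluate_tss <- function(predictions, truths) {
  predictions <- as_class_label(predictions)
  truths <- as_class_label(truths)
  if (length(predictions) == 0) stopf("empty input")
  if (length(predictions) != length(truths)) stopf("length mismatch")
  keep <- !is.na(predictions) & !is.na(truths)
  predictions <- predictions[keep]; truths <- truths[keep]
  if (length(predictions) == 0) stopf("no non-missing prediction/truth pairs")
  tp <- sum(predictions == "presence" & truths == "presence")
  fn <- sum(predictions == "absence" & truths == "presence")
  tn <- sum(predictions == "absence" & truths == "absence")
  fp <- sum(predictions == "presence" & truths == "absence")
  degenerate <- (tp + fn) == 0 || (tn + fp) == 0
  sens <- if ((tp + fn) > 0) tp / (tp + fn) else 0
  spec <- if ((tn + fp) > 0) tn / (tn + fp) else 0
  list(tss = sens + spec - 1, sensitivity = sens, specificity = spec,
       tp = tp, fp = fp, tn = tn, fn = fn, degenerate = degenerate)
}

as_class_label <- function(x) {
  if (is.logical(x)) return(ifelse(x, "presence", "absence"))
  if (is.numeric(x)) return(ifelse(is.na(x), NA_character_,
                                   ifelse(x > 0, "presence", "absence")))
  as.character(x)
}

#' Root mean squared error of coverage predictions
#'
#' RMSE on the 0-1 coverage scale, the objective for numeric (coverage)
#' learning; ranges from 0 upwards.
#'
#' @param predicted,observed numeric vectors of equal nonzero length.
#' @return List with `rmse` and `n`.
#' @export
evaluate_rmse <- function(predicted, observed) {
  if (length(predicted) == 0) stopf("empty input")
  if (length(predicted) != length(observed)) stopf("length mismatch")
  keep <- !is.na(predicted) & !is.na(observed)
  if (!any(keep)) stopf("no non-missing prediction/truth pairs")
  d <- predicted[keep] - observed[keep]
  list(rmse = sqrt(mean(d^2)), n = sum(keep))
}
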