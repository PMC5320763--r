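#' Learning configuration
#'
#' Bundles the tunables of the iterative weight search. Defaults follow the
#' study conditions: training sample 500, validation sample 1000, initial
#' similarity budget 5, 200 iterations.
#'
#' @param train_size exemplar (training) sample drawn per iteration.
#' @param val_size validation sample drawn per iteration.
#' @param initial_k starting similarity budget; `k` itself is learnable.
#' @param iterations number of search iterations (one proposal each).
#' @param seed master RNG seed; every sampling and proposal draw derives
#'   from it, so reruns are bit-identical.
#' @param factors multiplicative step sizes for weight/budget proposals.
#' @param coverage_breaks cut points defining exemplar-weight blocks for
#'   coverage targets (weights are perturbed per block to keep the search
#'   tractable; class targets use the two classes as blocks).
#' @return A list of class `simfit_control`.
#' @export
simfit_control <- function(train_size = 500, val_size = 1000, initial_k = 5,
                           iterations = 200, seed = 1,
                           factors = c(0.5, 0.8, 1.25, 2),
                           coverage_breaks = c(-Inf, 0, 0.3, 0.6, 1)) {
  stopifnot(train_size >= 1, val_size >= 1, initial_k > 0, iterations >= 0)
  structure(list(train_size = as.integer(train_size),
                 val_size = as.integer(val_size),
                 initial_k = initial_k, iterations = as.integer(iterations),
                 seed = seed, factors = factors,
                 coverage_breaks = coverage_breaks),
            class = "simfit_control")
}

# encode target for the kernel: coverage as-is, classes as 0/1 (presence=1)
encode_target <- function(target) {
  if (is.numeric(target)) target else as.numeric(target == "presence")
}

# evaluate a weight state on given train/validation index draws.
# Returns the objective, per-exemplar contributions (aligned with
# train_idx) and the share of validation rows with a decision.
eval_state <- function(X, kindcode, sds, target_enc, is_class,
                       wf, we, k, train_idx, val_idx, objective) {
  ts <- cpp_ts_matrix(X[val_idx, , drop = FALSE], X[train_idx, , drop = FALSE],
                      kindcode, sds, wf, we[train_idx], k)
  excl <- match(val_idx, train_idx) - 1L
  excl[is.na(excl)] <- -1L
  dec <- cpp_decide_rows(ts, target_enc[train_idx], is_class, k, excl)
  pred <- dec$value
  truth <- target_enc[val_idx]
  ok <- !is.na(pred)
  obj <- if (!any(ok)) NA_real_
  else if (objective == "tss")
    evaluate_tss(pred[ok] > 0, truth[ok] > 0)$tss
  else evaluate_rmse(pred[ok], truth[ok])$rmse
  # class-separation margin for tie-breaking: mean, over validation rows,
  # of the whole-base similarity share belonging to the row's true class
  # (the "similarity to a given category" quantity). Unlike decision-set
  # certainty it does not saturate once decision sets are pure.
  margin <- NA_real_
  if (is_class) {
    ts0 <- ts; ts0[is.na(ts0)] <- 0
    sp <- rowSums(ts0[, target_enc[train_idx] == 1, drop = FALSE])
    st <- rowSums(ts0)
    m <- ifelse(st > 0, ifelse(truth > 0, sp / st, 1 - sp / st), NA)
    if (any(!is.na(m))) margin <- mean(m, na.rm = TRUE)
  }
  list(objective = obj, margin = margin, contrib = dec$contrib,
       decided = mean(ok))
}

obj_better <- function(a, b, objective, strict = TRUE) {
  # is a better than (or, strict = FALSE, at least as good as) b?
  # NA counts as worst.
  if (is.na(a)) return(FALSE)
  if (is.na(b)) return(TRUE)
  if (strict) { if (objective == "tss") a > b else a < b }
  else { if (objective == "tss") a >= b else a <= b }
}

# parsimony measure used to direct tie acceptance: summed feature weights
# and active exemplar count. On an objective plateau only non-complexifying
# feature/exemplar proposals are accepted, so uninformative feature weights
# shrink and redundant exemplars get pruned while informative weights are
# protected by the objective itself. Budget (k) moves always require strict
# improvement: a different k is not a simpler model, just a differently
# smoothed one, so it must earn its change.
state_complexity <- function(wf, we, k) sum(wf) + sum(we > 0)

#' Learn feature weights, exemplar weights and the similarity budget
#'
#' Iterative stochastic hill-climbing over the full tunable state of a
#' predictive set. Each iteration draws fresh training and validation
#' subsamples (without replacement), evaluates the current state and one
#' proposed perturbation on them, and accepts the proposal if it improves
#' the validation objective (TSS for presence/absence, RMSE for coverage).
#' An exact objective tie is accepted only when the proposal does not
#' increase model complexity (summed feature weights, budget, active
#' exemplar count), so on a plateau the search keeps pruning redundant
#' exemplars and shrinking uninformative feature weights without ever
#' worsening the objective.
#' Proposals multiply one feature weight, one exemplar-weight block, or the
#' budget `k` by a step factor, or zero out the least-contributing exemplar
#' (redundant cases are thereby removed from the base). A validation record
#' that is also in the iteration's exemplar base is excluded from its own
#' decision set. Class proportions in the samples are never rebalanced.
#'
#' The state with the best validation objective seen is returned; the trace
#' records the per-iteration and best-so-far objectives.
#'
#' @param features data.frame of candidate-exemplar feature vectors.
#' @param target coverage fractions in [0, 1] or `"absence"`/`"presence"`
#'   labels.
#' @param specs a [feature_specs] table holding the initial feature weights
#'   and frozen numeric SDs.
#' @param control a [simfit_control].
#' @param objective `"tss"` or `"rmse"`; defaults by target type.
#' @param exemplar_weights optional initial exemplar weights (default 1).
#' @return List with `state` (`feature_weights`, `exemplar_weights`, `k`),
#'   `objective` (best validation value), `trace` (data.frame), `objective_name`.
#' @export
learn_weights <- function(features, target, specs, control = simfit_control(),
                          objective = NULL, exemplar_weights = NULL) {
  n <- nrow(features)
  if (n < 2) stopf("need at least 2 records")
  is_class <- !is.numeric(target)
  if (is_class) target <- as_class_label(target)
  if (is.null(objective)) objective <- if (is_class) "tss" else "rmse"
  if (objective == "tss") {
    if (!is_class) stopf("objective 'tss' needs class targets")
    if (length(unique(target)) < 2)
      stopf("objective 'tss' needs both classes present in the records")
  }
  train_size <- control$train_size
  val_size <- control$val_size
  if (train_size > n) { warnf("train_size capped at %d available records", n); train_size <- n }
  if (val_size > n) { warnf("val_size capped at %d available records", n); val_size <- n }

  lv <- category_levels(features, specs)
  X <- encode_features(features, specs, lv)
  kindcode <- as.integer(specs$kind == "categorical")
  target_enc <- encode_target(target)

  wf <- stats::setNames(specs$weight, specs$name)
  we <- if (is.null(exemplar_weights)) rep(1, n) else as.numeric(exemplar_weights)
  k <- control$initial_k
  if (all(wf <= 0)) stopf("at least one feature weight must be positive")

  blocks <- if (is_class) factor(target)
  else cut(target_enc, control$coverage_breaks, include.lowest = TRUE)

  best <- list(wf = wf, we = we, k = k)
  best_obj <- NA_real_
  trace <- vector("list", control$iterations)

  with_rng_seed(control$seed, {
    for (it in seq_len(control$iterations)) {
      train_idx <- sample.int(n, train_size)
      val_idx <- sample.int(n, val_size)
      cur <- eval_state(X, kindcode, specs$sd, target_enc, is_class,
                        wf, we, k, train_idx, val_idx, objective)
      # propose a perturbation
      move <- sample(c("feature", "block", "budget", "drop"), 1,
                     prob = c(0.45, 0.2, 0.15, 0.2))
      wf2 <- wf; we2 <- we; k2 <- k
      if (move == "feature") {
        j <- sample.int(length(wf), 1)
        wf2[j] <- wf[j] * sample(control$factors, 1)
      } else if (move == "block") {
        b <- sample(levels(blocks), 1)
        we2[blocks == b] <- we[blocks == b] * sample(control$factors, 1)
      } else if (move == "budget") {
        k2 <- k * sample(control$factors, 1)
      } else {
        # zero the least-contributing exemplar of this draw, but keep the
        # base workable: never below 10 active exemplars overall nor below
        # 2 active exemplars of the candidate's target block
        active <- train_idx[we[train_idx] > 0]
        if (length(active) > 1 && sum(we > 0) > 10) {
          ctb <- cur$contrib[match(active, train_idx)]
          cand <- active[which.min(ctb)]
          if (sum(we > 0 & blocks == blocks[cand]) > 2) we2[cand] <- 0
        }
      }
      prop <- eval_state(X, kindcode, specs$sd, target_enc, is_class,
                         wf2, we2, k2, train_idx, val_idx, objective)
      accepted <- obj_better(prop$objective, cur$objective, objective)
      tie <- !is.na(prop$objective) && !is.na(cur$objective) &&
        prop$objective == cur$objective
      if (!accepted && tie && move != "budget") {
        # secondary criterion on an objective plateau: larger class
        # separation margin first, then lower complexity
        if (!is.na(prop$margin) && !is.na(cur$margin) &&
            prop$margin != cur$margin) {
          accepted <- prop$margin > cur$margin
        } else {
          accepted <- state_complexity(wf2, we2, k2) <= state_complexity(wf, we, k)
        }
      }
      if (accepted) { wf <- wf2; we <- we2; k <- k2 }
      obj_now <- if (accepted) prop$objective else cur$objective
      if (obj_better(obj_now, best_obj, objective, strict = FALSE)) {
        best <- list(wf = wf, we = we, k = k)
        best_obj <- obj_now
      }
      trace[[it]] <- data.frame(iteration = it, move = move,
                                accepted = accepted,
                                objective = obj_now, best = best_obj)
    }
  })

  trace <- if (control$iterations > 0) do.call(rbind, trace)
  else data.frame(iteration = integer(), move = character(),
                  accepted = logical(), objective = numeric(), best = numeric())
  list(state = list(feature_weights = best$wf,
                    exemplar_weights = best$we, k = best$k),
       objective = best_obj, objective_name = objective, trace = trace)
}
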