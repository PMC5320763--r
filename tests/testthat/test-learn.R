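small_ctrl <- function(iterations = 40, seed = 3)
  simfit_control(train_size = 80, val_size = 120,
                 iterations = iterations, seed = seed)

test_that("zero iterations return the initial uniform state unchanged", {
  d <- make_class_data(60, seed = 1)
  specs <- feature_specs(d[setdiff(names(d), "occ")])
  suppressWarnings(
    res <- learn_weights(d[setdiff(names(d), "occ")], d$occ, specs,
                         control = simfit_control(train_size = 40, val_size = 40,
                                                  iterations = 0, seed = 1)))
  expect_equal(unname(res$state$feature_weights), rep(1, 5))
  expect_equal(res$state$exemplar_weights, rep(1, 60))
  expect_equal(res$state$k, 5)
  expect_equal(nrow(res$trace), 0)
})

test_that("reruns with the same seed are bit-identical", {
  d <- make_class_data(150, seed = 2)
  feats <- d[setdiff(names(d), "occ")]
  specs <- feature_specs(feats)
  r1 <- learn_weights(feats, d$occ, specs, control = small_ctrl())
  r2 <- learn_weights(feats, d$occ, specs, control = small_ctrl())
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$state, r2$state)
  # a different seed changes the trajectory
  r3 <- learn_weights(feats, d$occ, specs, control = small_ctrl(seed = 99))
  expect_false(identical(r1$trace$objective, r3$trace$objective))
})

test_that("learning does not disturb the caller's RNG stream", {
  d <- make_class_data(120, seed = 4)
  feats <- d[setdiff(names(d), "occ")]
  specs <- feature_specs(feats)
  set.seed(77); before <- runif(3)
  set.seed(77); invisible(learn_weights(feats, d$occ, specs,
                                        control = small_ctrl()))
  expect_identical(runif(3), before)
})

test_that("the best-so-far objective never worsens along the trace", {
  d <- make_class_data(200, seed = 5)
  feats <- d[setdiff(names(d), "occ")]
  res <- learn_weights(feats, d$occ, feature_specs(feats),
                       control = small_ctrl(iterations = 60))
  expect_true(all(diff(res$trace$best) >= 0))
  expect_equal(res$objective, max(res$trace$best))
  # coverage task: best RMSE is non-increasing
  cov <- ifelse(d$sig == "A", pmin(abs(rnorm(200, 0.4, 0.2)), 1), 0)
  resr <- learn_weights(feats, cov, feature_specs(feats),
                        control = small_ctrl(iterations = 60))
  expect_true(all(diff(resr$trace$best) <= 0))
})

test_that("a perfectly discriminating feature is recovered from noise", {
  d <- make_class_data(400, seed = 6)
  feats <- d[setdiff(names(d), "occ")]
  res <- learn_weights(feats, d$occ, feature_specs(feats),
                       control = simfit_control(train_size = 150, val_size = 200,
                                                iterations = 80, seed = 11))
  wf <- res$state$feature_weights
  expect_equal(names(which.max(wf)), "sig")
  expect_gte(res$objective, 0.9)
  # redundant exemplars got pruned along the way
  expect_lt(sum(res$state$exemplar_weights > 0), 400)
})

test_that("sample sizes are capped with a warning and class checks enforced", {
  d <- make_class_data(30, seed = 7)
  feats <- d[setdiff(names(d), "occ")]
  specs <- feature_specs(feats)
  # both the train and the validation size get capped, one warning each
  expect_warning(expect_warning(
    learn_weights(feats, d$occ, specs,
                  control = simfit_control(train_size = 500, val_size = 1000,
                                           iterations = 2, seed = 1)),
    "capped"), "capped")
  expect_error(learn_weights(feats, rep("absence", 30), specs,
                             control = small_ctrl(), objective = "tss"),
               "both classes")
  expect_error(learn_weights(feats[1, , drop = FALSE], "absence", specs,
                             control = small_ctrl()), "at least 2")
})
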