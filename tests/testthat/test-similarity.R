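test_that("numeric partial similarity follows the weighted, clamped form", {
  # identity: equal values give the full weight product
  expect_equal(partial_similarity_numeric(3.2, 3.2, wf = 1, sd = 1), 1)
  expect_equal(partial_similarity_numeric(0, 0, wf = 0.5, sd = 2, we = 0.4), 0.2)
  # hand-evaluated: wf*we*(1 - |d|/(k*sd*wf*we)) = 0.5*(1 - 0.4/1) = 0.3
  expect_equal(partial_similarity_numeric(0.4, 0, wf = 0.5, sd = 1, k = 2), 0.3)
  # negative raw values are clamped to zero (|d| = 3 SD, raw -0.5)
  expect_equal(partial_similarity_numeric(3, 0, wf = 1, sd = 1, k = 2), 0)
  # result never exceeds wf*we and decreases with |d|
  d <- seq(0, 5, 0.25)
  ps <- partial_similarity_numeric(d, 0, wf = 1.3, sd = 1, we = 0.9, k = 2)
  expect_true(all(ps <= 1.3 * 0.9 + 1e-12))
  expect_true(all(diff(ps) <= 0))
  # a larger feature weight widens the accepted difference: at fixed d > 0
  # (inside the unclamped range) similarity grows with wf
  d0 <- 0.8
  ps_w <- vapply(c(0.6, 1, 1.5, 2.5), function(w)
    partial_similarity_numeric(d0, 0, wf = w, sd = 1, k = 2), numeric(1))
  expect_true(all(diff(ps_w) > 0))
  # invalid inputs
  expect_error(partial_similarity_numeric(Inf, 0, wf = 1, sd = 1), "finite")
  expect_error(partial_similarity_numeric(1, 0, wf = 1, sd = 0), "positive")
  expect_error(partial_similarity_numeric(1, 0, wf = 0, sd = 1), "positive")
})

test_that("categorical partial similarity is the weighted match indicator", {
  expect_equal(partial_similarity_categorical("x", "x", wf = 1), 1)
  expect_equal(partial_similarity_categorical("x", "y", wf = 1), 0)
  expect_equal(partial_similarity_categorical("x", "y", wf = 5, we = 3), 0)
  expect_equal(partial_similarity_categorical("x", "x", wf = 0.8, we = 0.5), 0.4)
  expect_equal(partial_similarity_categorical(NA, "x", wf = 1), 0)
})

test_that("total similarity normalises over usable features and skips missing", {
  specs <- make_specs()
  obs <- list(num_a = 0, cat_b = "p")
  # identical vectors reach 1 regardless of weights
  expect_equal(total_similarity(obs, obs, specs), 1)
  specs2 <- specs; specs2$weight <- c(2.5, 0.3)
  expect_equal(total_similarity(obs, obs, specs2, we = 0.7), 1)
  # categorical match (PS 1) + numeric |d| = SD (PS 0.5): TS = 1.5/2
  ex <- list(num_a = 1, cat_b = "p")
  expect_equal(total_similarity(obs, ex, specs), 0.75)
  # missing numeric on one side: computed on the categorical alone
  expect_equal(total_similarity(list(num_a = NA, cat_b = "p"), ex, specs), 1)
  expect_equal(total_similarity(obs, list(num_a = NA, cat_b = "q"), specs), 0)
  # zero-weight feature is identical to deleting the feature
  specs_zero <- specs; specs_zero$weight[1] <- 0
  obs2 <- list(num_a = 99, cat_b = "p")
  expect_equal(total_similarity(obs2, ex, specs_zero),
               total_similarity(list(cat_b = "p"), list(cat_b = "p"),
                                specs_zero))
  # no usable feature raises a typed condition
  expect_error(total_similarity(list(num_a = NA, cat_b = NA), ex, specs),
               class = "casemap_no_usable_features")
  expect_error(total_similarity(obs, ex, transform(specs, weight = 0)),
               class = "casemap_no_usable_features")
})

test_that("total similarity is bounded and maximal at identity on random vectors", {
  set.seed(11)
  for (rep in 1:25) {
    d <- data.frame(a = rnorm(8), b = sample(letters[1:3], 8, TRUE),
                    c = runif(8, 0, 10))
    specs <- feature_specs(d, weights = runif(3, 0.2, 3))
    for (i in 1:4) {
      ts <- total_similarity(d[i, ], d[i + 4, ], specs,
                             we = runif(1, 0.3, 2), k = runif(1, 0.5, 5))
      expect_gte(ts, 0); expect_lte(ts, 1)
      expect_equal(total_similarity(d[i, ], d[i, ], specs), 1)
    }
  }
})

test_that("the similarity matrix agrees with scalar total similarity", {
  set.seed(21)
  d <- data.frame(a = rnorm(30), b = sample(letters[1:4], 30, TRUE),
                  c = runif(30))
  d$a[sample(30, 4)] <- NA; d$b[sample(30, 5)] <- NA
  specs <- feature_specs(d, weights = c(1.2, 0.8, 0.5))
  base <- exemplar_base(d[1:20, ], runif(20, 0, 1),
                        weights = runif(20, 0.2, 2))
  obs <- d[21:30, ]
  ts <- similarity_matrix(obs, base, specs, k = 2)
  for (i in 1:10) for (j in 1:20) {
    ref <- tryCatch(total_similarity(obs[i, ], base$features[j, ], specs,
                                     we = base$weights[j], k = 2),
                    casemap_no_usable_features = function(e) NA_real_)
    expect_equal(ts[i, j], ref, tolerance = 1e-12)
  }
  # zero-weight exemplars are skipped (NA column)
  base0 <- exemplar_base(d[1:20, ], runif(20, 0, 1),
                         weights = c(0, runif(19, 0.2, 2)))
  expect_true(all(is.na(similarity_matrix(obs, base0, specs)[, 1])))
})

test_that("decision sets accumulate similarity up to the budget", {
  ds <- decision_set(c(0.9, 0.8, 0.7, 0.1), k = 2)
  expect_equal(ds$ts, c(0.9, 0.8, 0.7))
  expect_equal(ds$cumulative, 2.4)
  expect_false(ds$exhausted)
  # a single exemplar cannot reach k = 2: all included, flagged exhausted
  ds1 <- decision_set(1.0, k = 2)
  expect_equal(length(ds1$ids), 1)
  expect_true(ds1$exhausted)
  # small budget stops at the first exemplar
  expect_equal(length(decision_set(c(0.9, 0.8), k = 0.5)$ids), 1)
  # ties are ranked by exemplar id
  ds_tie <- decision_set(c(0.5, 0.5, 0.5), k = 1, ids = c(30, 10, 20))
  expect_equal(ds_tie$ids, c(10, 20))
  # zero/NA similarities are excluded; nothing usable is an error
  expect_equal(length(decision_set(c(0.6, 0, NA), k = 10)$ids), 1)
  expect_error(decision_set(c(0, NA), k = 1), class = "casemap_no_decision")
})

test_that("numeric decisions are the similarity-weighted mean of coverages", {
  ds <- decision_set(1.0, k = 2)
  expect_equal(decide_numeric(ds, 0.4)$value, 0.4)
  ds2 <- structure(list(ids = c(1, 2), ts = c(0.6, 0.3), cumulative = 0.9,
                        exhausted = TRUE), class = "decision_set")
  out <- decide_numeric(ds2, c(0.8, 0.2))
  expect_equal(out$value, 0.6)  # (0.48 + 0.06) / 0.9
  expect_equal(out$mean_similarity, 0.45)
  expect_equal(decide_numeric(ds2, c(0, 0))$value, 0)
  # value stays within the contributing coverages
  set.seed(5)
  for (r in 1:20) {
    ts <- runif(6); cov <- runif(6)
    ds_r <- decision_set(ts, k = 1.5)
    v <- decide_numeric(ds_r, cov)$value
    idx <- match(ds_r$ids, seq_along(cov))
    expect_gte(v, min(cov[idx])); expect_lte(v, max(cov[idx]))
  }
})

test_that("numeric decisions are invariant to splitting an exemplar's similarity", {
  ds <- structure(list(ids = 1:3, ts = c(0.8, 0.6, 0.4), cumulative = 1.8,
                       exhausted = TRUE), class = "decision_set")
  cov <- c(0.9, 0.1, 0.5)
  # duplicate exemplar 1 with its similarity split in half
  ds_dup <- structure(list(ids = c(1, 4, 2, 3), ts = c(0.4, 0.4, 0.6, 0.4),
                           cumulative = 1.8, exhausted = TRUE),
                      class = "decision_set")
  expect_equal(decide_numeric(ds_dup, c(cov, cov[1]))$value,
               decide_numeric(ds, cov)$value)
})

test_that("class decisions report the majority-similarity class and certainty", {
  mk <- function(ts) structure(list(ids = seq_along(ts), ts = ts,
                                    cumulative = sum(ts), exhausted = FALSE),
                               class = "decision_set")
  # single-class set: certainty exactly 1
  out <- decide_class(mk(c(0.9, 0.7)), c("presence", "presence"))
  expect_equal(out$class, "presence"); expect_equal(out$certainty, 1)
  # presence 1.2 vs absence 0.8: certainty is the similarity share
  out2 <- decide_class(mk(c(0.7, 0.5, 0.8)),
                       c("presence", "presence", "absence"))
  expect_equal(out2$class, "presence"); expect_equal(out2$certainty, 0.6)
  expect_equal(unname(out2$shares["absence"]), 0.4)
  # exact tie resolves to absence with certainty 0.5
  out3 <- decide_class(mk(c(1, 1)), c("presence", "absence"))
  expect_equal(out3$class, "absence"); expect_equal(out3$certainty, 0.5)
})

test_that("feature specs freeze SDs and reject degenerate numeric features", {
  d <- data.frame(a = c(1, 2, 3, 4), b = c("x", "x", "y", "y"),
                  const = rep(2, 4))
  expect_warning(sp <- feature_specs(d), "zero variance")
  expect_equal(sp$weight[sp$name == "const"], 0)
  expect_equal(sp$sd[sp$name == "a"], sd(d$a))
  expect_equal(sp$kind, c("numeric", "categorical", "numeric"))
  expect_error(feature_specs(d, weights = c(-1, 1, 1)), "non-negative")
})

test_that("exemplar bases validate targets and weights", {
  d <- data.frame(a = 1:3)
  expect_error(exemplar_base(d, c(0.2, 1.5, 0)), "\\[0, 1\\]")
  expect_error(exemplar_base(d, c("presence", "maybe", "absence")), "absence")
  expect_error(exemplar_base(d, c(0.1, 0.2, 0.3), ids = c(1, 1, 2)), "unique")
  b <- exemplar_base(d, c("presence", "absence", "absence"))
  expect_equal(b$target_type, "class")
})
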