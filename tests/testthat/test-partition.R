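# a 4x4, 100 m stratum grid with two strata: west (code 1) and east (code 2)
make_partition_fixture <- function() {
  strata <- grid_raster(matrix(rep(c(1, 1, 2, 2), 4), 4, 4, byrow = TRUE),
                        0, 0, 100, categorical = TRUE)
  # presence indicator layer: top predictor fires in the NE quadrant
  ind <- grid_raster(matrix(c(0, 0, 1, 1,
                              0, 0, 1, 1,
                              0, 0, 0, 0,
                              0, 0, 0, 0), 4, 4, byrow = TRUE),
                     0, 0, 100, categorical = TRUE)
  list(strata = strata, grids = list(indicator = ind, strata_lc = strata))
}

test_that("cells are classified by the absence-stratum and predictor rules", {
  fx <- make_partition_fixture()
  set.seed(1)
  # 100 records: 20 in stratum 1 (all absences), 80 in stratum 2 (presences)
  rec <- rbind(
    data.frame(x = runif(20, 10, 190), y = runif(20, 10, 390), coverage = 0),
    data.frame(x = runif(80, 210, 390), y = runif(80, 10, 390),
               coverage = 0.5))
  rules <- partition_rules(
    top_predictors = list(
      list(feature = "indicator", op = "in", value = 1),
      list(feature = "strata_lc", op = "in", value = 2)),
    min_predictors_agreeing = 2)
  pmap <- classify_cells(rec, fx$grids, rules, fx$strata)
  lab <- pmap$values
  # west stratum: 20% of records, no presences -> proved absence
  expect_true(all(lab[, 1:2] == 1))
  # NE quadrant: both predicates hold -> probable presence
  expect_true(all(lab[1:2, 3:4] == 2))
  # SE: only one predicate -> unclear
  expect_true(all(lab[3:4, 3:4] == 3))
  # every cell is labelled
  expect_true(all(lab %in% 1:3))
})

test_that("probable presence takes precedence over proved absence", {
  fx <- make_partition_fixture()
  set.seed(3)
  rec <- data.frame(x = runif(50, 10, 390), y = runif(50, 10, 390),
                    coverage = 0)
  rules <- partition_rules(
    top_predictors = list(list(feature = "strata_lc", op = "in", value = 1)),
    min_predictors_agreeing = 1)
  pmap <- classify_cells(rec, fx$grids, rules, fx$strata)
  # stratum 1 proves absence (all records absences) but the predicate also
  # fires there: presence wins
  expect_true(all(pmap$values[, 1:2] == 2))
})

test_that("a rare stratum cannot prove absence and thresholds are monotone", {
  fx <- make_partition_fixture()
  set.seed(4)
  # stratum 1 holds only 0.5% of records
  rec <- rbind(
    data.frame(x = 50, y = 50, coverage = 0),
    data.frame(x = runif(199, 210, 390), y = runif(199, 10, 390),
               coverage = rep(c(0, 0.4), length.out = 199)))
  rules <- partition_rules(absence_share_threshold = 0.01)
  pmap <- classify_cells(rec, fx$grids, rules, fx$strata)
  expect_true(all(pmap$values == 3))
  # raising the threshold never grows the proved-absence area
  rec2 <- rbind(
    data.frame(x = runif(30, 10, 190), y = runif(30, 10, 390), coverage = 0),
    data.frame(x = runif(70, 210, 390), y = runif(70, 10, 390),
               coverage = 0.3))
  areas <- vapply(c(0.01, 0.2, 0.5), function(th) {
    pm <- classify_cells(rec2, fx$grids, partition_rules(
      absence_share_threshold = th), fx$strata)
    sum(pm$values == 1)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("routed pools partition the record set", {
  fx <- make_partition_fixture()
  set.seed(2)
  rec <- data.frame(x = runif(120, 5, 395), y = runif(120, 5, 395),
                    coverage = ifelse(runif(120) < 0.3, 0.5, 0))
  rules <- partition_rules(
    top_predictors = list(list(feature = "indicator", op = "in", value = 1)),
    min_predictors_agreeing = 1)
  pmap <- classify_cells(rec, fx$grids, rules, fx$strata)
  pools <- route_records(rec, pmap)
  expect_named(pools, c("proved_absence", "probable_presence", "unclear"))
  expect_equal(sum(vapply(pools, nrow, integer(1))), nrow(rec))
  # no record appears in two pools
  all_rows <- unlist(lapply(pools, rownames))
  expect_false(any(duplicated(all_rows)))
  # a record outside the grid is a routing error naming the offender
  bad <- rbind(rec, data.frame(x = 999, y = 999, coverage = 0))
  expect_error(suppressWarnings(route_records(bad, pmap)), "outside")
})

test_that("stratum combination requires aligned layers and codes combinations", {
  a <- grid_raster(matrix(c(1, 1, 2, 2), 2, 2), 0, 0, 10, categorical = TRUE)
  b <- grid_raster(matrix(c(1, 2, 1, 2), 2, 2), 0, 0, 10, categorical = TRUE)
  s <- combine_strata(list(a, b))
  # 2x2 distinct combinations
  expect_equal(length(attr(s, "strata")), 4)
  expect_equal(length(unique(as.vector(s$values))), 4)
  c_bad <- grid_raster(matrix(1, 3, 3), 0, 0, 10, categorical = TRUE)
  expect_error(combine_strata(list(a, c_bad)), "aligned")
})
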