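test_that("thinning enforces the minimum distance with presence priority", {
  # three collinear points 40 m apart: first and third survive
  r <- data.frame(x = c(0, 40, 80), y = 0, coverage = c(0.2, 0.1, 0.3))
  expect_equal(thin_records(r, 50)$x, c(0, 80))
  # a single record is kept
  expect_equal(nrow(thin_records(r[1, ], 50)), 1)
  # a presence is never discarded in favour of a nearby track absence,
  # regardless of input order
  r2 <- data.frame(x = c(30, 0), y = 0, coverage = c(0, 0.5),
                   source = c("track", "active"))
  out <- thin_records(r2, 50)
  expect_equal(nrow(out), 1)
  expect_equal(out$coverage, 0.5)
  expect_error(thin_records(r, -5), "positive")
})

test_that("thinned sets are fixed points with all pairs separated", {
  set.seed(41)
  for (rep in 1:5) {
    r <- data.frame(x = runif(300, 0, 500), y = runif(300, 0, 500),
                    coverage = ifelse(runif(300) < 0.3, runif(300, 0, 0.9), 0))
    th <- thin_records(r, 50)
    d <- as.matrix(dist(th[c("x", "y")]))
    diag(d) <- Inf
    expect_true(all(d >= 50))
    expect_identical(thin_records(th, 50), th)
    # every rejected record is within 50 m of an accepted one
    rej <- r[!rownames(r) %in% rownames(th), ]
    if (nrow(rej) > 0) {
      dmin <- apply(rej, 1, function(p)
        min(sqrt((th$x - as.numeric(p["x"]))^2 + (th$y - as.numeric(p["y"]))^2)))
      expect_true(all(dmin < 50))
    }
  }
})

test_that("neighbourhood statistics match their definitions", {
  r <- data.frame(x = c(0, 10, 20, 500), y = 0,
                  coverage = c(0.4, 0, 0, 0.8))
  # 2 presences? no: coverages 0.4,0,0 in radius -> 1/3 presences
  expect_equal(proportion_presences(r, 5, 0, 30), 1 / 3)
  expect_equal(proportion_presences(r, 5, 0, 1), NA_real_)
  expect_equal(proportion_presences(r[2:3, ], 10, 0, 30), 0)
  expect_equal(mean_coverage(r, 5, 0, 30), mean(c(0.4, 0, 0)))
  expect_equal(mean_coverage(r, 1000, 0, 10), NA_real_)
  # distance-weighted mean: coverages {0,1} at 100 and 200 m, power 1 -> 1/3
  r2 <- data.frame(x = c(100, 200), y = 0, coverage = c(0, 1))
  expect_equal(idw_mean_coverage(r2, 0, 0, 300, power = 1), 1 / 3)
  # a single record returns its coverage regardless of distance
  expect_equal(idw_mean_coverage(r2[2, ], 0, 0, 300), 1)
  expect_equal(idw_mean_coverage(r2, 0, 0, 50), NA_real_)
})

test_that("neighbourhood statistics agree with brute-force oracles", {
  set.seed(42)
  r <- data.frame(x = runif(400, 0, 1000), y = runif(400, 0, 1000),
                  coverage = ifelse(runif(400) < 0.4, runif(400, 0, 0.9), 0))
  centers <- data.frame(x = runif(30, 0, 1000), y = runif(30, 0, 1000))
  for (i in seq_len(nrow(centers))) {
    cx <- centers$x[i]; cy <- centers$y[i]
    for (rad in c(60, 150)) {
      d <- sqrt((r$x - cx)^2 + (r$y - cy)^2)
      inside <- d <= rad
      exp_prop <- if (any(inside)) mean(r$coverage[inside] > 0) else NA_real_
      exp_mean <- if (any(inside)) mean(r$coverage[inside]) else NA_real_
      exp_idw <- if (any(inside)) {
        w <- 1 / pmax(d[inside], 5)
        sum(w * r$coverage[inside]) / sum(w)
      } else NA_real_
      expect_equal(proportion_presences(r, cx, cy, rad), exp_prop)
      expect_equal(mean_coverage(r, cx, cy, rad), exp_mean)
      expect_equal(idw_mean_coverage(r, cx, cy, rad), exp_idw)
    }
  }
  # reordering records never changes the statistics
  perm <- sample(400)
  expect_equal(proportion_presences(r[perm, ], 500, 500, 200),
               proportion_presences(r, 500, 500, 200))
  expect_equal(mean_coverage(r[perm, ], 500, 500, 200),
               mean_coverage(r, 500, 500, 200))
})

test_that("autocovariates exclude the focal record at observation sites", {
  r <- data.frame(x = c(0, 30), y = 0, coverage = c(0.8, 0))
  ac <- build_autocovariates(r, radii_prop = 100, radii_mean = 100,
                             radius_idw = 100)
  # at record 1 the neighbourhood is only record 2, and vice versa
  expect_equal(ac$prop_presence_100, c(0, 1))
  expect_equal(ac$mean_coverage_100, c(0, 0.8))
  # at an arbitrary point both records count
  ac2 <- build_autocovariates(r, points = data.frame(x = 15, y = 0),
                              radii_prop = 100, radii_mean = 100,
                              radius_idw = 100)
  expect_equal(ac2$prop_presence_100, 0.5)
  expect_equal(ac2$mean_coverage_100, 0.4)
})

test_that("autocovariate grids evaluate the features at cell centres", {
  r <- data.frame(x = c(25, 75), y = c(25, 75), coverage = c(0.6, 0))
  tpl <- grid_raster(matrix(0, 2, 2), 0, 0, 50)
  g <- autocovariate_grids(r, tpl, radii_prop = 40, radii_mean = 40,
                           radius_idw = 40)
  # cell (row 2, col 1) centre is (25, 25): only the presence record inside
  expect_equal(g$prop_presence_40$values[2, 1], 1)
  expect_equal(g$mean_coverage_40$values[2, 1], 0.6)
  # cell (row 1, col 2) centre is (75, 75): only the absence record
  expect_equal(g$prop_presence_40$values[1, 2], 0)
})
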