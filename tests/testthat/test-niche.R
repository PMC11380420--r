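test_that("Julian-day weights equalise daily mass", {
  w <- julian_day_weights(c(5, 5, 5, 5))
  expect_equal(w, rep(0.25, 4))
  # two days with 1 and 99 records contribute equal total mass
  jd <- c(1, rep(2, 99))
  w2 <- julian_day_weights(jd)
  expect_equal(sum(w2[jd == 1]), 0.5)
  expect_equal(sum(w2[jd == 2]), 0.5)
  expect_equal(sum(w2), 1)
})

test_that("reference bandwidth follows the normal-reference rule", {
  set.seed(40)
  x <- rnorm(100)
  h <- reference_bandwidth(x)
  iqr <- unname(diff(quantile(x, c(0.25, 0.75))))
  expect_equal(h, 4 * 1.06 * min(sd(x), iqr / 1.34) * 100^(-1 / 5))
  # for sd = 1 and IQR = 1.34 at n = 100 the rule gives ~1.688
  expect_equal(4 * 1.06 * 1 * 100^(-1 / 5), 1.68797, tolerance = 1e-5)
  # scale equivariance and shrinkage with n
  expect_equal(reference_bandwidth(5 * x), 5 * h, tolerance = 1e-12)
  set.seed(41)
  big <- rnorm(10000)
  expect_lt(reference_bandwidth(big), reference_bandwidth(big[1:500]))
  expect_error(reference_bandwidth(rep(3, 10)), "spread")
})

test_that("reference bandwidth agrees with the MASS implementation", {
  skip_if_not_installed("MASS")
  set.seed(42)
  for (x in list(rnorm(50), rexp(200), runif(1000) * 30)) {
    expect_equal(reference_bandwidth(x), MASS::bandwidth.nrd(x))
  }
})

test_that("weighted KDE integrates to one and peaks at a lone point", {
  set.seed(43)
  d <- c(rnorm(500, 50, 10), rnorm(500, 200, 20))
  t <- c(rnorm(500, 12, 1), rnorm(500, 8, 0.5))
  est <- weighted_kde2d(d, t)
  cell <- diff(est$depth_grid[1:2]) * diff(est$temp_grid[1:2])
  expect_equal(sum(est$density) * cell, 1, tolerance = 0.01)

  one <- weighted_kde2d(rep(c(10, 10, 10, 10.1), 3), rep(c(8, 8, 8, 8.1), 3),
                        bandwidths = c(4, 4))
  peak <- which(one$density == max(one$density), arr.ind = TRUE)
  expect_lt(abs(one$depth_grid[peak[1]] - 10), 1)
  expect_lt(abs(one$temp_grid[peak[2]] - 8), 1)
  expect_error(weighted_kde2d(d, t, bandwidths = c(0, 1)), "bandwidth")
})

test_that("duplicating records leaves the normalised density unchanged", {
  set.seed(44)
  d <- rnorm(300, 100, 30)
  t <- rnorm(300, 10, 2)
  w <- julian_day_weights(rep(1:30, 10))
  e1 <- weighted_kde2d(d, t, weights = w, bandwidths = c(20, 1))
  e2 <- weighted_kde2d(rep(d, 2), rep(t, 2),
                       weights = rep(w, 2), bandwidths = c(20, 1))
  expect_equal(e1$density, e2$density, tolerance = 1e-12)
})

test_that("day weighting removes seasonal imbalance", {
  set.seed(45)
  d <- rnorm(200, 100, 30)
  t <- rnorm(200, 10, 2)
  jd <- rep(1:20, each = 10)
  e1 <- weighted_kde2d(d, t, weights = julian_day_weights(jd),
                       bandwidths = c(20, 1))
  # duplicate every record of Julian day 3
  dup <- which(jd == 3)
  e2 <- weighted_kde2d(c(d, d[dup]), c(t, t[dup]),
                       weights = julian_day_weights(c(jd, jd[dup])),
                       bandwidths = c(20, 1))
  expect_equal(e1$density, e2$density, tolerance = 1e-12)
})

test_that("isopleth levels are nested and behave on flat densities", {
  flat <- matrix(1, 10, 10)
  lv <- isopleth_levels(flat)
  expect_equal(unname(lv[["0.5"]]), 1)
  expect_equal(unname(lv[["0.95"]]), 1)
  set.seed(46)
  est <- weighted_kde2d(rnorm(500, 100, 20), rnorm(500, 10, 1))
  expect_gte(est$isopleth_levels[["0.5"]], est$isopleth_levels[["0.95"]])
  expect_error(isopleth_levels(flat, mass_fractions = 1.2), "mass_fractions")

  # two point masses: the 50% region covers only the heavier mode's cell
  two <- matrix(0, 10, 10)
  two[3, 3] <- 0.6
  two[8, 8] <- 0.4
  lv2 <- isopleth_levels(two, mass_fractions = 0.5)
  expect_equal(sum(two >= lv2), 1)
})

test_that("occupancy fractions sum to 100% and aggregate across animals", {
  h <- data.frame(animal_id = rep(c("a", "b"), each = 4),
                  julian_day = rep(1:4, 2),
                  median_depth_m = c(10, 10, 60, 60, 10, 10, 10, 10))
  occ <- occupancy_fractions(h, breaks = c(0, 50, 100))
  # a: 50/50, b: 100/0 -> means 75/25, SE 25/25
  expect_equal(occ$bins$mean_pct, c(75, 25))
  expect_equal(occ$bins$se_pct, c(25, 25))
  expect_equal(colSums(occ$per_individual), c(a = 100, b = 100))
  # everything shallow: zones
  expect_equal(occ$zones$mean_pct[occ$zones$zone == "epipelagic"], 100)

  single <- occupancy_fractions(
    data.frame(animal_id = "a", julian_day = 1:5,
               median_depth_m = rep(30, 5)), breaks = c(25, 50))
  expect_equal(single$bins$mean_pct, 100)
  expect_equal(single$bins$se_pct, 0)
  expect_error(occupancy_fractions(h, breaks = 10), "bin")
})
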