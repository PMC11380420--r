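# Builders for aggregated-series-like frames used by the statistics layer.
agg_frame <- function(animal_id, date, diel2, depth,
                      vspeed = 0, fs = 0L, diel4 = diel2,
                      temp = 8, light = 50) {
  data.frame(animal_id = animal_id, date = as.Date(date), diel2 = diel2,
             diel4 = diel4, median_depth_m = depth,
             median_temp_C = temp, median_light = light,
             mean_vspeed_m_s = vspeed, n_fast_starts = fs)
}

test_that("identical day/night medians give p = 1 at the null centre", {
  n <- 10
  x <- rbind(
    agg_frame("a", as.Date("2021-11-01") + rep(1:n, each = 1), "day", 100),
    agg_frame("a", as.Date("2021-11-01") + rep(1:n, each = 1), "night", 100))
  out <- compare_day_night_depth(x)
  expect_equal(out$p_value, 1)
  expect_equal(out$statistic, n * (n + 1) / 4)
  expect_equal(out$n, n)
})

test_that("a consistent 100 m day-night difference is highly significant", {
  n <- 20
  dates <- as.Date("2021-11-01") + 1:n
  x <- rbind(agg_frame("a", dates, "day", 200),
             agg_frame("a", dates, "night", 100))
  out <- compare_day_night_depth(x)
  expect_lt(out$p_value, 0.001)
  expect_equal(out$direction, "day deeper")
  # DVM flag restriction drops unflagged days from the pairing
  flags <- data.frame(animal_id = "a", date = dates,
                      dvm_flag = rep(c(TRUE, FALSE), n / 2))
  out2 <- compare_day_night_depth(x, flags)
  expect_equal(out2$n, n / 2)
  few <- compare_day_night_depth(x[c(1, 2, n + 1, n + 2), ])
  expect_true(grepl("insufficient", few$note))
})

test_that("vertical-speed t-tests detect crepuscular ascent/descent", {
  zero <- agg_frame("a", "2021-11-01", "day", 100, vspeed = 0,
                    diel4 = "day")
  out0 <- test_vspeed_nonzero(rbind(zero, zero, zero), periods = "day")
  expect_equal(out0$p_value, 1)

  set.seed(60)
  dusk <- agg_frame("a", "2021-11-01", "night",
                    100, vspeed = rnorm(100, 0.2, 0.05), diel4 = "dusk")
  dawn <- agg_frame("a", "2021-11-01", "night",
                    100, vspeed = rnorm(100, -0.2, 0.05), diel4 = "dawn")
  out <- test_vspeed_nonzero(rbind(dusk, dawn))
  dusk_row <- out[out$grouping == "vspeed_dusk", ]
  dawn_row <- out[out$grouping == "vspeed_dawn", ]
  expect_lt(dusk_row$p_value, 1e-6)
  expect_equal(dusk_row$direction, "ascent")
  expect_lt(dawn_row$p_value, 1e-6)
  expect_equal(dawn_row$direction, "descent")
})

test_that("fast starts are compared between DVM and non-DVM hours", {
  set.seed(61)
  dates <- as.Date("2021-11-01") + 1:40
  mk <- function(id, counts_dvm, counts_non) {
    rbind(
      agg_frame(id, rep(dates[1:20], each = 2), rep(c("day", "night"), 20),
                100, fs = counts_dvm),
      agg_frame(id, rep(dates[21:40], each = 2), rep(c("day", "night"), 20),
                100, fs = counts_non))
  }
  flags <- data.frame(animal_id = rep(c("a", "b"), each = 40),
                      date = rep(dates, 2),
                      dvm_flag = rep(rep(c(TRUE, FALSE), each = 20), 2))
  # identical distributions: one-sided p around 0.5
  x_same <- rbind(mk("a", rpois(40, 5), rpois(40, 5)),
                  mk("b", rpois(40, 5), rpois(40, 5)))
  p_same <- compare_fast_starts_by_dvm(x_same, flags)$pooled$p_value
  expect_gt(p_same, 0.1)
  # stochastically larger during DVM
  x_more <- rbind(mk("a", rpois(40, 20), rpois(40, 4)),
                  mk("b", rpois(40, 20), rpois(40, 4)))
  res <- compare_fast_starts_by_dvm(x_more, flags)
  expect_lt(res$pooled$p_value, 0.01)
  expect_equal(res$pooled$direction, "dvm higher")
  expect_equal(nrow(res$per_individual), 2)
})

test_that("environmental correlations recover sign and degeneracy", {
  set.seed(62)
  depth <- sample(10:300, 500, replace = TRUE)
  x <- agg_frame("a", "2021-11-01", "day", depth, fs = depth)
  out <- faststart_environment_correlations(x)
  expect_equal(out$statistic[out$grouping == "fast_starts_vs_depth"], 1)
  # temperature column is constant -> missing r
  expect_true(is.na(out$statistic[out$grouping ==
                                    "fast_starts_vs_temperature"]))
  # independent noise: |r| small at n = 1000
  y <- agg_frame("a", "2021-11-01", "day", rnorm(1000, 100, 30),
                 fs = rpois(1000, 5), temp = rnorm(1000, 9),
                 light = rnorm(1000, 60, 10))
  outn <- faststart_environment_correlations(y)
  expect_true(all(abs(outn$statistic) < 0.1))
})

test_that("tests are invariant to row permutation", {
  set.seed(63)
  dates <- as.Date("2021-11-01") + 1:15
  x <- rbind(agg_frame("a", dates, "day", 150 + rnorm(15)),
             agg_frame("a", dates, "night", 60 + rnorm(15)))
  perm <- x[sample(nrow(x)), ]
  expect_equal(compare_day_night_depth(x), compare_day_night_depth(perm))
})
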