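test_that("configuration invariants are enforced", {
  expect_error(wavelet_config(omega0 = -1))
  expect_error(wavelet_config(dj = 0))
  expect_error(wavelet_config(lower_period = 1, dt = 1))
  expect_error(wavelet_config(n_sim = 0))
  expect_error(morlet_cwt(rnorm(10)), "too short")
  x <- rnorm(100)
  x[1:20] <- NA
  expect_error(morlet_cwt(x), "missing")
})

test_that("a constant series has zero power at all scales", {
  res <- morlet_cwt(rep(7, 64))
  expect_lt(max(res$power), 1e-20)
})

test_that("power scales quadratically with amplitude", {
  set.seed(3)
  x <- rnorm(64)
  p1 <- morlet_cwt(x)$power
  p3 <- morlet_cwt(3 * x)$power
  expect_equal(p3, 9 * p1, tolerance = 1e-10)
})

test_that("FFT transform equals direct time-domain convolution", {
  set.seed(11)
  x <- rnorm(64) + sin(2 * pi * (1:64) / 12)
  res <- morlet_cwt(x)
  sub <- seq(1, length(res$scales), by = 10)
  oracle <- direct_morlet_power(x, res$scales[sub])
  for (k in seq_along(sub)) {
    expect_lt(max(abs(oracle[k, ] - res$power[sub[k], ])) /
                max(oracle[k, ]), 1e-8)
  }
})

test_that("the period grid is geometric and the spectrum localises a tone", {
  x <- sin(2 * pi * (1:240) / 24)
  res <- morlet_cwt(x)
  expect_true(all(diff(res$periods) > 0))
  expect_equal(diff(log2(res$periods)), rep(1 / 20, length(res$periods) - 1),
               tolerance = 1e-10)
  pk <- res$periods[which.max(res$global_power)]
  expect_lte(abs(log2(pk / 24)), 1 / 20)
})

test_that("time-shift covariance holds away from the edges", {
  set.seed(13)
  base <- rnorm(400)
  k <- 32
  x1 <- base[1:256]
  x2 <- base[(1 + k):(256 + k)]
  r1 <- morlet_cwt(x1)
  r2 <- morlet_cwt(x2)
  rows <- which(r1$periods <= 16)   # small scales: support well inside
  cols <- 120:136
  rel <- abs(r2$power[rows, cols - k] - r1$power[rows, cols]) /
    max(r1$power[rows, cols])
  expect_lt(max(rel), 1e-6)
})

test_that("surrogate p-values are valid and saturate for a flat series", {
  res <- morlet_cwt(rep(1, 64), wavelet_config(upper_period = 16))
  res <- ar1_surrogate_pvalues(res, wavelet_config(upper_period = 16,
                                                   n_sim = 19, seed = 1))
  expect_true(all(res$pvalues == 1))
  expect_true(all(res$global_pvalues == 1))

  set.seed(2)
  x <- rnorm(128)
  r <- morlet_cwt(x, wavelet_config(upper_period = 32))
  r <- ar1_surrogate_pvalues(r, wavelet_config(upper_period = 32,
                                               n_sim = 39, seed = 3))
  expect_true(all(r$pvalues > 0 & r$pvalues <= 1))
  expect_gte(min(r$pvalues), 1 / 40)  # add-one correction floor
  expect_error(ar1_surrogate_pvalues(r, wavelet_config(upper_period = 32,
                                                       n_sim = 10)),
               "seed")
})

test_that("surrogate p-values are reproducible for a fixed seed", {
  set.seed(4)
  x <- ar1_series(128)
  r <- morlet_cwt(x, wavelet_config(upper_period = 32))
  cfg <- wavelet_config(upper_period = 32, n_sim = 50, seed = 17)
  expect_identical(ar1_surrogate_pvalues(r, cfg)$pvalues,
                   ar1_surrogate_pvalues(r, cfg)$pvalues)
})

test_that("a strong diel tone is significant against the red-noise null", {
  set.seed(6)
  x <- sin(2 * pi * (1:720) / 24) + 0.1 * rnorm(720)
  r <- morlet_cwt(x)
  r <- ar1_surrogate_pvalues(r, wavelet_config(n_sim = 100, seed = 7))
  j24 <- which.min(abs(r$periods - 24))
  expect_lte(r$global_pvalues[j24], 0.05)
})

test_that("band summary reports significant diel bands and unresolved bands", {
  set.seed(8)
  x <- sin(2 * pi * (1:720) / 24) + 0.5 * sin(2 * pi * (1:720) / 12) +
    0.1 * rnorm(720)
  r <- morlet_cwt(x)
  r <- ar1_surrogate_pvalues(r, wavelet_config(n_sim = 100, seed = 9))
  s <- summarize_periodicity(r)
  expect_true(s$significant[s$band == "24h"])
  expect_true(s$significant[s$band == "12h"])
  # 28-day band is not resolvable on a 720 h series (upper period 240 h)
  expect_false(s$resolved[s$band == "28d"])
  expect_true(is.na(s$significant[s$band == "28d"]))
})

test_that("missing values under 10% are interpolated and recorded", {
  set.seed(10)
  x <- sin(2 * pi * (1:240) / 24) + 0.2 * rnorm(240)
  x[c(50:54, 120)] <- NA
  r <- morlet_cwt(x)
  expect_equal(r$interp_idx, c(50:54, 120))
  expect_false(anyNA(r$power))
})
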