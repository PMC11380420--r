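test_that("archive write/read round-trips a generated archive", {
  arc <- tiny_sim(days = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_archive(arc, path)
  back <- read_archive(path, animal_id = attr(arc, "animal_id"))
  expect_equal(nrow(back), nrow(arc))
  expect_equal(back$timestamp, arc$timestamp)
  for (ch in c("depth", "temp", "light", "ax", "ay", "az")) {
    expect_equal(back[[ch]], arc[[ch]], tolerance = 1e-9)
  }
  expect_equal(attr(back, "interval_s"), 5)
})

test_that("malformed archive files are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,depth,temp,light,ax,ay,az",
               "2021-11-01T00:00:00Z,10,8,0,0,0,0",
               "2021-11-01T00:00:05Z,11,8,0,0,0,0",
               "2021-11-01T00:00:10Z,12,8,0,0,0,0"), path)
  expect_equal(nrow(read_archive(path)), 3)

  no_depth <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,temp,light,ax,ay,az",
               "2021-11-01T00:00:00Z,8,0,0,0,0"), no_depth)
  expect_error(read_archive(no_depth), "depth")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,depth,temp,light,ax,ay,az",
               "2021-11-01T00:00:00Z,10,8,0,0,0,0",
               "2021-11-01T00:00:00Z,11,8,0,0,0,0"), dup)
  expect_error(read_archive(dup), "increasing")
  expect_error(read_archive(withr::local_tempfile()), "not found")
})

test_that("cleaning removes the first 24 h and is idempotent", {
  arc <- make_archive(depth = 100 + sin(seq_len(48 * 60) / 10) * 20)
  cl <- clean_track(arc)
  expect_equal(nrow(cl$archive), 24 * 60)
  expect_equal(cl$report$samples_removed_head, 24 * 60)
  expect_false(cl$report$mortality_flag)
  # idempotence: cleaning the cleaned track changes nothing
  cl2 <- clean_track(cl$archive)
  expect_equal(cl2$archive, cl$archive)
  expect_equal(cl2$report$samples_removed_head, 0)
  expect_error(clean_track(make_archive(depth = rep(10, 60))), "shorter")
})

test_that("terminal surface drifting is excised", {
  depth <- c(100 + sin(seq_len(42 * 60) / 7) * 30, rep(0.5, 6 * 60))
  cl <- clean_track(make_archive(depth = depth))
  expect_equal(cl$report$samples_removed_tail, 6 * 60)
  expect_false(cl$report$mortality_flag)
  expect_true(all(cl$archive$depth > 1))
})

test_that("terminal constant-depth segment triggers the mortality flag", {
  set.seed(7)
  depth <- c(150 + sin(seq_len(72 * 60) / 9) * 60 + rnorm(72 * 60),
             rep(300, 48 * 60))
  cl <- clean_track(make_archive(depth = depth))
  expect_true(cl$report$mortality_flag)
  expect_gte(cl$report$samples_removed_tail, 48 * 60)
  expect_lt(max(cl$archive$timestamp),
            make_archive(depth = depth)$timestamp[72 * 60 + 1])
})

test_that("mortality detector follows the windowed depth-SD rule", {
  int <- 60
  flat <- rep(200, 48 * 60)
  expect_gt(nrow(detect_mortality(flat, interval_s = int)), 0)
  sine <- 200 + 50 * sin(seq_len(96 * 60) * 2 * pi / (24 * 60))
  expect_equal(nrow(detect_mortality(sine, interval_s = int)), 0)
  set.seed(1)
  noisy <- 150 + rnorm(48 * 60, sd = 1)
  expect_gt(nrow(detect_mortality(noisy, interval_s = int)), 0)
  surface <- rep(0.5, 48 * 60)  # shallow constant: not mortality
  expect_equal(nrow(detect_mortality(surface, interval_s = int)), 0)
  expect_error(detect_mortality(rep(1, 10), interval_s = 60), "shorter")
})

test_that("vertical speed uses the ascent-positive sign convention", {
  expect_equal(vertical_speed(c(100, 90), dt = 60), 1 / 6,
               tolerance = 1e-12)
  expect_equal(vertical_speed(rep(50, 10), dt = 5), rep(0, 9))
  # reversing the depth trace negates and reverses the speed trace
  set.seed(2)
  d <- cumsum(rnorm(50))
  expect_equal(vertical_speed(rev(d), dt = 5),
               -rev(vertical_speed(d, dt = 5)))
  expect_error(vertical_speed(c(1, 2, 3), dt = c(5, 6)), "dt")
})

test_that("light calibration reproduces the printed reference points", {
  expect_equal(light_to_irradiance(150), 1e-5)
  expect_equal(light_to_irradiance(110), 1e-7)
  expect_equal(light_to_irradiance(70), 1e-9)
})

test_that("aggregation uses medians, conserves fast starts, flags misalignment", {
  # 3 samples per hour (interval 1200 s) so all intervals are complete
  depth <- c(1, 2, 100, 5, 6, 7)
  arc <- make_archive(depth = depth, interval_s = 1200)
  agg <- aggregate_archive(arc, interval = "hour")
  expect_equal(agg$median_depth_m[1], 2)
  expect_equal(agg$n_samples, c(3, 3))

  flags <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  agg2 <- aggregate_archive(arc, flags = flags, interval = "hour")
  expect_equal(agg2$n_fast_starts, c(2L, 1L))
  expect_error(aggregate_archive(arc, flags = flags[-1]), "aligned")

  # conservation on a simulated archive with planted bursts
  sim <- tiny_sim(days = 2, seed = 8)
  ma <- magnitude(sim$ax, sim$ay, sim$az)
  fs <- detect_fast_starts(ma)
  hh <- aggregate_archive(sim, flags = fs$flags, interval = "hour")
  expect_equal(sum(hh$n_fast_starts), fs$n_flagged)
  mm <- aggregate_archive(sim, flags = fs$flags, interval = "min")
  expect_equal(sum(mm$n_fast_starts), fs$n_flagged)
})

test_that("sparse intervals are emitted as missing, not dropped", {
  # one lone valid sample in the second hour (interval 1200 s, nominal 3):
  # the other two samples of that hour are sensor gaps (NA depth)
  arc2 <- make_archive(depth = c(10, 11, 12, NA, 50, NA),
                       interval_s = 1200)
  agg <- aggregate_archive(arc2, interval = "hour")
  expect_equal(nrow(agg), 2)
  expect_true(is.na(agg$median_depth_m[2]))
  expect_equal(agg$n_samples[2], 1)
})

test_that("an nDVM archive descends at dawn and ascends at dusk", {
  sim <- generate_archive(sim_config(duration_days = 4, seed = 12,
                                     depth_noise_sd = 5))
  agg <- aggregate_archive(sim, interval = "hour")
  vmean <- tapply(agg$mean_vspeed_m_s, agg$diel4, mean, na.rm = TRUE)
  expect_lt(vmean[["dawn"]], 0)
  expect_gt(vmean[["dusk"]], 0)
})
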