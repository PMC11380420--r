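# Synthetic tag archive generator.  Emulates the structure of a recovered
# PSAT archive -- regular multichannel sampling, diel depth cycling with
# crepuscular ramps, a two-layer thermal profile, light decaying with depth
# on a diel surface cycle, and sparse high-magnitude acceleration bursts --
# so that downstream analyses can be validated against known ground truth.

.normalise_schedule <- function(schedule, duration_days) {
  if (is.null(schedule) || length(schedule) == 0) {
    return(data.frame(start = integer(), end = integer(), mode = character()))
  }
  if (is.data.frame(schedule)) {
    df <- data.frame(start = as.integer(schedule[[1]]),
                     end = as.integer(schedule[[2]]),
                     mode = as.character(schedule[[3]]))
  } else {
    df <- do.call(rbind, lapply(schedule, function(iv) {
      iv <- unlist(iv, use.names = FALSE)
      data.frame(start = as.integer(iv[1]), end = as.integer(iv[2]),
                 mode = as.character(iv[3]))
    }))
  }
  if (!all(df$mode %in% c("nDVM", "rDVM", "none"))) {
    stop("dvm_schedule modes must be one of 'nDVM', 'rDVM', 'none'")
  }
  if (any(df$start < 1) || any(df$end > duration_days) ||
      any(df$end < df$start)) {
    stop("dvm_schedule intervals must satisfy 1 <= start <= end <= duration_days")
  }
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) > 1 && any(df$start[-1] <= df$end[-nrow(df)])) {
    stop("dvm_schedule intervals must not overlap")
  }
  df
}

#' Simulation configuration for synthetic tag archives
#'
#' Bundles and validates all parameters of the archive generator.  Defaults
#' describe a late-autumn fjord deployment: strict normal DVM between a
#' daytime baseline of 198.5 m and a nighttime baseline of 60 m, a two-layer
#' thermal profile with a 15 m thermocline, and acceleration bursts that are
#' more frequent by day during DVM than at night or outside DVM.
#'
#' @param duration_days Length of the simulated deployment (days, >= 2).
#' @param sample_interval_s Sampling interval in seconds (5 s = 0.2 Hz).
#' @param day_depth_m,night_depth_m Diel depth baselines (m, positive down).
#' @param dvm_schedule List of `(start_day, end_day, mode)` triplets with
#'   mode one of `"nDVM"`, `"rDVM"`, `"none"`; non-overlapping, within
#'   `[1, duration_days]`.  Days not covered behave as `"none"` (night
#'   baseline held).
#' @param transition_minutes Width of the logistic dawn/dusk depth ramp
#'   (minutes between the ~10% and ~90% points), centred on sunrise/sunset.
#' @param ar1_coef_depth Lag-one autocorrelation of the slow depth noise at
#'   the hourly timescale, in `[0, 1)`.  The slow component is an hourly
#'   AR(1) held within each hour, so the hourly-aggregated depth series
#'   follows the same red-noise model that the wavelet significance test
#'   assumes under the null.
#' @param depth_noise_sd Stationary standard deviation of the slow depth
#'   noise (m).
#' @param depth_jitter_sd Standard deviation of fast white sample-level
#'   depth jitter (m).
#' @param thermocline_depth_m,thermocline_width_m,surface_temp_C,deep_temp_C
#'   Two-layer hydrography: temperature relaxes from the surface value to
#'   the deep value across a logistic transition of the given width centred
#'   at the thermocline depth.
#' @param temp_noise_sd Standard deviation of a slow shared temperature
#'   offset (degrees C); applied uniformly in depth so the instantaneous
#'   profile stays monotone.
#' @param burst_rate_per_hour Named list by DVM mode, each a named numeric
#'   `c(day = , night = )` of Poisson burst rates per hour.
#' @param burst_magnitude Acceleration-vector magnitude added per burst
#'   (arbitrary tag units; the fast-start statistic is percentile based).
#' @param baseline_accel_sd Per-axis standard deviation of baseline
#'   acceleration noise.
#' @param light_surface_peak Tag-unit light level at the surface with the
#'   sun at the zenith.  Tag light units are log-scaled: 20 units per decade
#'   of irradiance.
#' @param light_attenuation_per_m Tag units lost per metre of depth.
#' @param light_noise_sd Sample-level light noise (tag units).
#' @param start_date Calendar date (UTC) of the first sample.
#' @param latitude,longitude Reference coordinate for solar geometry.
#' @param seed Integer seed; mandatory, every archive must be reproducible.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(duration_days = 3, seed = 1)
#' @export
sim_config <- function(duration_days = 90,
                       sample_interval_s = 5,
                       day_depth_m = 198.5,
                       night_depth_m = 60,
                       dvm_schedule = list(c(1, duration_days, "nDVM")),
                       transition_minutes = 60,
                       ar1_coef_depth = 0.5,
                       depth_noise_sd = 25,
                       depth_jitter_sd = 1.5,
                       thermocline_depth_m = 15,
                       thermocline_width_m = 5,
                       surface_temp_C = 14,
                       deep_temp_C = 8,
                       temp_noise_sd = 0.1,
                       burst_rate_per_hour = list(
                         nDVM = c(day = 25, night = 10),
                         rDVM = c(day = 10, night = 25),
                         none = c(day = 3, night = 3)),
                       burst_magnitude = 10,
                       baseline_accel_sd = 1,
                       light_surface_peak = 150,
                       light_attenuation_per_m = 1,
                       light_noise_sd = 1,
                       start_date = "2021-11-01",
                       latitude = 60.3,
                       longitude = 5.2,
                       seed = NULL) {
  if (is.null(seed)) stop("sim_config: `seed` is mandatory (reproducibility)")
  stopifnot(duration_days >= 2,
            sample_interval_s > 0,
            day_depth_m >= 0, night_depth_m >= 0,
            ar1_coef_depth >= 0, ar1_coef_depth < 1,
            depth_noise_sd >= 0, depth_jitter_sd >= 0,
            transition_minutes > 0, abs(latitude) <= 90)
  schedule <- .normalise_schedule(dvm_schedule, duration_days)
  stopifnot(all(c("nDVM", "rDVM", "none") %in% names(burst_rate_per_hour)))
  cfg <- list(
    duration_days = as.integer(duration_days),
    sample_interval_s = sample_interval_s,
    day_depth_m = day_depth_m, night_depth_m = night_depth_m,
    dvm_schedule = schedule,
    transition_minutes = transition_minutes,
    ar1_coef_depth = ar1_coef_depth,
    depth_noise_sd = depth_noise_sd,
    depth_jitter_sd = depth_jitter_sd,
    thermocline_depth_m = thermocline_depth_m,
    thermocline_width_m = thermocline_width_m,
    surface_temp_C = surface_temp_C, deep_temp_C = deep_temp_C,
    temp_noise_sd = temp_noise_sd,
    burst_rate_per_hour = burst_rate_per_hour,
    burst_magnitude = burst_magnitude,
    baseline_accel_sd = baseline_accel_sd,
    light_surface_peak = light_surface_peak,
    light_attenuation_per_m = light_attenuation_per_m,
    light_noise_sd = light_noise_sd,
    start_date = as.Date(start_date),
    latitude = latitude, longitude = longitude,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# Two-layer hydrographic profile: temperature as a function of depth.
.temp_profile <- function(depth, cfg) {
  cfg$deep_temp_C + (cfg$surface_temp_C - cfg$deep_temp_C) *
    plogis(-(depth - cfg$thermocline_depth_m) / cfg$thermocline_width_m)
}

# Hourly AR(1) held constant within the hour, expanded to sample level.
.hourly_ar1 <- function(n_samples, interval_s, phi, sd_stat) {
  n_hours <- ceiling(n_samples * interval_s / 3600) + 1L
  z <- numeric(n_hours)
  z[1] <- rnorm(1, 0, sd_stat)
  if (n_hours > 1) {
    innov <- rnorm(n_hours - 1, 0, sd_stat * sqrt(1 - phi^2))
    z <- filter(c(z[1], innov), phi, method = "recursive")
  }
  idx <- floor((seq_len(n_samples) - 1) * interval_s / 3600) + 1L
  as.numeric(z)[idx]
}

#' Generate a synthetic tag archive
#'
#' Simulates one individual's multichannel archive at the configured
#' sampling rate.  During `nDVM` days the depth baseline oscillates between
#' the night and day values with logistic ramps centred on sunrise (descent)
#' and sunset (ascent); `rDVM` swaps the baselines; `none` holds the night
#' baseline.  Temperature is the two-layer profile evaluated at the
#' instantaneous depth plus a slow shared offset; light is the log-scaled
#' diel surface cycle minus linear attenuation with depth (floored at 0);
#' acceleration is isotropic Gaussian noise plus Poisson-timed bursts of
#' fixed magnitude in a random direction, at a rate set by the day's DVM
#' mode and the diel period.
#'
#' @param config A [sim_config()] object.
#' @param animal_id Identifier stored with the archive.
#' @return A `tag_archive`: data.frame with columns `timestamp` (POSIXct
#'   UTC), `depth` (m), `temp` (C), `light` (tag units), `ax`, `ay`, `az`,
#'   with attributes `animal_id`, `interval_s`, `latitude`, `longitude`,
#'   `burst_index` (ground-truth sample indices of planted bursts) and
#'   `mode_by_day` (ground-truth DVM mode per track day).
#' @examples
#' arc <- generate_archive(sim_config(duration_days = 2, seed = 7))
#' head(arc)
#' @export
generate_archive <- function(config, animal_id = "sim01") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dt <- config$sample_interval_s
  n <- as.integer(round(config$duration_days * 86400 / dt))
  t0 <- as.POSIXct(paste(format(config$start_date), "00:00:00"), tz = "UTC")
  times <- t0 + (seq_len(n) - 1) * dt
  elapsed <- as.numeric(times) - as.numeric(t0)
  day_of_track <- pmin(floor(elapsed / 86400) + 1L, config$duration_days)

  mode_by_day <- rep("none", config$duration_days)
  sch <- config$dvm_schedule
  for (i in seq_len(nrow(sch))) {
    mode_by_day[sch$start[i]:sch$end[i]] <- sch$mode[i]
  }
  mode <- mode_by_day[day_of_track]

  dates <- seq(config$start_date, by = "day",
               length.out = config$duration_days + 1L)
  dtab <- sun_times(dates, config$latitude, config$longitude)
  date_idx <- findInterval(elapsed, (seq_along(dates) - 1) * 86400)
  sr <- as.numeric(dtab$sunrise[date_idx])
  ss <- as.numeric(dtab$sunset[date_idx])

  # logistic ramp: transition_minutes spans ~10%..90% of the swing
  k <- config$transition_minutes * 60 / (2 * log(9))
  tt <- as.numeric(times)
  g <- ifelse(is.na(sr) | is.na(ss), 0,
              plogis((tt - sr) / k) * (1 - plogis((tt - ss) / k)))
  base <- ifelse(mode == "nDVM",
                 config$night_depth_m +
                   (config$day_depth_m - config$night_depth_m) * g,
          ifelse(mode == "rDVM",
                 config$day_depth_m +
                   (config$night_depth_m - config$day_depth_m) * g,
                 config$night_depth_m))

  slow <- .hourly_ar1(n, dt, config$ar1_coef_depth, config$depth_noise_sd)
  jitter <- rnorm(n, 0, config$depth_jitter_sd)
  depth <- pmax(base + slow + jitter, -1)

  temp_off <- .hourly_ar1(n, dt, 0.9, config$temp_noise_sd)
  temp <- .temp_profile(depth, config) + temp_off

  elev <- solar_elevation(times, config$latitude, config$longitude)
  l_surf <- config$light_surface_peak +
    20 * log10(pmax(sin(elev * pi / 180), 1e-4))
  light <- pmax(0, l_surf - config$light_attenuation_per_m * depth +
                  rnorm(n, 0, config$light_noise_sd))

  ax <- rnorm(n, 0, config$baseline_accel_sd)
  ay <- rnorm(n, 0, config$baseline_accel_sd)
  az <- rnorm(n, 0, config$baseline_accel_sd)

  # Poisson burst process per hour, rate by (DVM mode of day, diel period)
  hour_start <- seq(0, max(elapsed), by = 3600)
  hour_mid <- t0 + hour_start + 1800
  hour_diel <- classify_diel(hour_mid, dtab, scheme = 2)
  hour_day <- pmin(floor(hour_start / 86400) + 1L, config$duration_days)
  hour_mode <- mode_by_day[hour_day]
  rate <- mapply(function(m, p) config$burst_rate_per_hour[[m]][[p]],
                 hour_mode, hour_diel)
  counts <- rpois(length(rate), rate)
  samples_per_hour <- 3600 / dt
  burst_index <- integer(0)
  hot <- which(counts > 0)
  if (length(hot)) {
    burst_index <- unlist(lapply(hot, function(h) {
      lo <- (h - 1L) * samples_per_hour + 1L
      hi <- min(h * samples_per_hour, n)
      lo - 1L + sample.int(hi - lo + 1L, min(counts[h], hi - lo + 1L))
    }))
    burst_index <- sort(burst_index)
    u <- matrix(rnorm(3 * length(burst_index)), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    ax[burst_index] <- ax[burst_index] + config$burst_magnitude * u[, 1]
    ay[burst_index] <- ay[burst_index] + config$burst_magnitude * u[, 2]
    az[burst_index] <- az[burst_index] + config$burst_magnitude * u[, 3]
  }

  out <- data.frame(timestamp = times, depth = depth, temp = temp,
                    light = light, ax = ax, ay = ay, az = az)
  attr(out, "animal_id") <- animal_id
  attr(out, "interval_s") <- dt
  attr(out, "latitude") <- config$latitude
  attr(out, "longitude") <- config$longitude
  attr(out, "burst_index") <- burst_index
  attr(out, "mode_by_day") <- mode_by_day
  class(out) <- c("tag_archive", "data.frame")
  out
}

#' @export
print.tag_archive <- function(x, ...) {
  cat(sprintf("<tag_archive> %s: %d samples @ %gs, %s .. %s\n",
              attr(x, "animal_id") %||% "?", nrow(x), attr(x, "interval_s"),
              format(x$timestamp[1]), format(x$timestamp[nrow(x)])))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
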