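# Reading/writing tag archives, track cleaning, derived channels and
# aggregation to 1-min / hourly resolution.

.ARCHIVE_COLS <- c("timestamp", "depth", "temp", "light", "ax", "ay", "az")

#' Write a tag archive to delimited text
#'
#' Comma-separated, header `timestamp,depth,temp,light,ax,ay,az`,
#' ISO-8601 UTC timestamps.
#'
#' @param archive A `tag_archive`.
#' @param path Output file path.
#' @export
write_archive <- function(archive, path) {
  out <- data.table::as.data.table(archive[.ARCHIVE_COLS])
  out[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a tag archive from delimited text
#'
#' Parses the archive format written by [write_archive()].  The seven
#' channels are mandatory; timestamps must be strictly increasing at a
#' uniform interval (sensor gaps are encoded as missing values in channels,
#' never as dropped rows).
#'
#' @param path File path.
#' @param animal_id Identifier to attach; defaults to the file stem.
#' @return A `tag_archive` data.frame.
#' @export
read_archive <- function(path, animal_id = NULL) {
  if (!file.exists(path)) stop("read_archive: file not found: ", path)
  dt <- data.table::fread(path)
  missing_cols <- setdiff(.ARCHIVE_COLS, names(dt))
  if (length(missing_cols)) {
    stop("read_archive: missing channel column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ts <- as.POSIXct(dt$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                  "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(ts)) stop("read_archive: unparseable timestamps")
  dts <- diff(as.numeric(ts))
  if (any(dts <= 0)) stop("read_archive: timestamps not strictly increasing")
  if (length(unique(round(dts, 6))) > 1) {
    stop("read_archive: non-uniform sampling interval")
  }
  out <- data.frame(timestamp = ts, depth = dt$depth, temp = dt$temp,
                    light = dt$light, ax = dt$ax, ay = dt$ay, az = dt$az)
  attr(out, "animal_id") <- animal_id %||%
    sub("\\.[^.]*$", "", basename(path))
  attr(out, "interval_s") <- if (length(dts)) dts[1] else NA_real_
  class(out) <- c("tag_archive", "data.frame")
  out
}

.subset_archive <- function(archive, keep) {
  out <- archive[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("animal_id", "interval_s", "latitude", "longitude",
              "mode_by_day", "cleaned")) {
    attr(out, a) <- attr(archive, a)
  }
  bi <- attr(archive, "burst_index")
  if (!is.null(bi)) {
    kidx <- which(keep)
    attr(out, "burst_index") <- match(intersect(bi, kidx), kidx)
  }
  class(out) <- c("tag_archive", "data.frame")
  out
}

#' Detect mortality-like windows (constant pressure at depth)
#'
#' Flags sliding windows (stepped hourly) in which the depth standard
#' deviation is at or below `var_threshold_m` while the median depth
#' exceeds 1 m -- the "constant pressure at depth" criterion tags use to
#' trigger early release.  The printed threshold carries a length unit, so
#' it is interpreted on the standard-deviation scale (metres).
#'
#' @param depth_series Numeric depth vector (m).
#' @param interval_s Sampling interval of the series (s).
#' @param window_hours Window length (h).
#' @param var_threshold_m Threshold on the windowed depth SD (m).
#' @return data.frame of flagged windows with sample index ranges
#'   (`start`, `end`), empty if nothing is flagged.
#' @export
detect_mortality <- function(depth_series, interval_s = 5,
                             window_hours = 48, var_threshold_m = 2.5) {
  n <- length(depth_series)
  win <- as.integer(round(window_hours * 3600 / interval_s))
  if (n < win) stop("detect_mortality: series shorter than one window")
  step <- max(1L, as.integer(round(3600 / interval_s)))
  starts <- seq(1L, n - win + 1L, by = step)
  x <- ifelse(is.na(depth_series), 0, depth_series)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  flagged <- vapply(starts, function(s) {
    e <- s + win - 1L
    seg_n <- win
    m <- (cs[e + 1] - cs[s]) / seg_n
    v <- (cs2[e + 1] - cs2[s]) / seg_n - m^2
    sqrt(max(v, 0)) <= var_threshold_m &&
      median(depth_series[s:e], na.rm = TRUE) > 1
  }, logical(1))
  data.frame(start = starts[flagged],
             end = pmin(starts[flagged] + win - 1L, n))
}

#' Clean a tag archive
#'
#' Removes the first `head_hours` of the record (tagging/capture effects)
#' and any trailing terminal segment that is either mortality-like
#' (constant depth, see [detect_mortality()]) or persistent surface
#' drifting (depth <= `surface_depth_m` for at least `surface_hours`
#' up to the end of the record).
#'
#' @param archive A `tag_archive` longer than `head_hours` + 1 h.
#' @param head_hours Hours removed from the start (default 24).
#' @param mortality_window_hours,mortality_sd_m Passed to
#'   [detect_mortality()].
#' @param surface_depth_m,surface_hours Surface-drift rule: a terminal run
#'   at or above this depth lasting at least this long is removed.
#' @return list(archive = cleaned `tag_archive`, report = `cleaning_report`)
#' @export
clean_track <- function(archive, head_hours = 24,
                        mortality_window_hours = 48, mortality_sd_m = 2.5,
                        surface_depth_m = 1, surface_hours = 1) {
  stopifnot(inherits(archive, "tag_archive"))
  dt <- attr(archive, "interval_s")
  n <- nrow(archive)
  # a record that has already been cleaned keeps its head (idempotence)
  n_head <- if (isTRUE(attr(archive, "cleaned"))) 0L else {
    as.integer(round(head_hours * 3600 / dt))
  }
  if (n * dt <= n_head * dt + 3600) {
    stop("clean_track: archive shorter than head_hours + 1 h")
  }
  first_keep <- n_head + 1L
  last_keep <- n

  # terminal surface drift: trailing run with depth <= surface_depth_m
  at_surface <- !is.na(archive$depth) & archive$depth <= surface_depth_m
  run_start <- last_keep + 1L
  i <- last_keep
  while (i >= first_keep && at_surface[i]) {
    run_start <- i
    i <- i - 1L
  }
  tail_surface <- 0L
  if (run_start <= last_keep &&
      (last_keep - run_start + 1L) * dt >= surface_hours * 3600) {
    tail_surface <- last_keep - run_start + 1L
    last_keep <- run_start - 1L
  }

  # terminal mortality-like constant depth: extend excision while the
  # trailing window keeps triggering the rule
  mortality_flag <- FALSE
  win <- as.integer(round(mortality_window_hours * 3600 / dt))
  repeat {
    if (last_keep - first_keep + 1L < win) break
    seg <- archive$depth[(last_keep - win + 1L):last_keep]
    if (sd(seg, na.rm = TRUE) <= mortality_sd_m &&
        median(seg, na.rm = TRUE) > 1) {
      mortality_flag <- TRUE
      # walk back to the start of the constant-depth plateau
      ref <- median(seg, na.rm = TRUE)
      j <- last_keep - win
      while (j >= first_keep && !is.na(archive$depth[j]) &&
             abs(archive$depth[j] - ref) <= 3 * mortality_sd_m) {
        j <- j - 1L
      }
      last_keep <- j
    } else break
  }

  keep <- rep(FALSE, n)
  if (last_keep >= first_keep) keep[first_keep:last_keep] <- TRUE
  cleaned <- .subset_archive(archive, keep)
  attr(cleaned, "cleaned") <- TRUE
  report <- list(
    animal_id = attr(archive, "animal_id"),
    samples_removed_head = first_keep - 1L,
    samples_removed_tail = n - last_keep,
    mortality_flag = mortality_flag,
    retained_span = if (last_keep >= first_keep) {
      c(archive$timestamp[first_keep], archive$timestamp[last_keep])
    } else NULL
  )
  class(report) <- "cleaning_report"
  list(archive = cleaned, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "<cleaning_report> %s: removed %d head / %d tail samples; mortality=%s\n",
    x$animal_id %||% "?", x$samples_removed_head, x$samples_removed_tail,
    x$mortality_flag))
  invisible(x)
}

#' Vertical speed from a depth series
#'
#' First differences with the oceanographic sign convention: positive speed
#' is an ascent (depth decreasing).  `speed[i] = -(depth[i+1] - depth[i]) / dt`,
#' assigned to the leading sample's interval; length `n - 1`.
#'
#' @param depth_series Numeric depth vector (m, positive down), length >= 2.
#' @param dt Sampling interval (s); scalar.
#' @return Numeric vector of speeds (m/s), length `n - 1`.
#' @examples
#' vertical_speed(c(100, 90), dt = 60)  # +0.1667 m/s, an ascent
#' @export
vertical_speed <- function(depth_series, dt) {
  stopifnot(length(depth_series) >= 2)
  if (length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    stop("vertical_speed: `dt` must be a single positive interval; ",
         "non-uniform sampling is not supported")
  }
  -diff(depth_series) / dt
}

#' Convert tag light level to irradiance
#'
#' Log-linear sensor calibration: `E = 10^((L - 250) / 20)` W/cm^2, the
#' unique log-linear map through the calibration points 150 -> 1e-5,
#' 110 -> 1e-7 and 70 -> 1e-9 W/cm^2 (20 tag units per decade).
#'
#' @param L Light level in tag units.
#' @return Irradiance in W/cm^2.
#' @export
light_to_irradiance <- function(L) 10^((L - 250) / 20)

#' Diel times table for an archive
#'
#' Convenience wrapper: [sun_times()] for every date spanned by the
#' archive at its reference coordinate.
#'
#' @param archive A `tag_archive`.
#' @param lat,lon Coordinate; defaults to the archive's own attributes,
#'   falling back to 60.3N, 5.2E.
#' @return A `diel_times` table.
#' @export
archive_diel_times <- function(archive, lat = NULL, lon = NULL) {
  lat <- lat %||% attr(archive, "latitude") %||% 60.3
  lon <- lon %||% attr(archive, "longitude") %||% 5.2
  dr <- range(as.Date(archive$timestamp, tz = "UTC"))
  sun_times(seq(dr[1], dr[2], by = "day"), lat, lon)
}

#' Aggregate an archive to 1-min or hourly resolution
#'
#' Medians for depth, temperature and light (their distributions are
#' skewed), means for acceleration magnitude and vertical speed, and sums
#' for fast-start flags.  Intervals are half-open `[t, t + delta)` and
#' labelled by their start time; diel labels are taken at the interval
#' midpoint.  Intervals with under `min_prop` of their nominal samples
#' present are emitted with missing summaries (never silently dropped).
#'
#' @param archive A `tag_archive` (typically cleaned).
#' @param flags Logical fast-start flags aligned to `archive` rows (e.g.
#'   from [detect_fast_starts()]); `NULL` for all-FALSE.
#' @param diel_times Table from [sun_times()]/[archive_diel_times()]
#'   covering the archive's dates; computed automatically when `NULL`.
#' @param interval `"hour"` or `"min"`.
#' @param min_prop Minimum fraction of nominal samples for a summary.
#' @return An `aggregated_series` data.frame with columns `animal_id`,
#'   `interval_start`, `date`, `julian_day`, `median_depth_m`,
#'   `median_temp_C`, `median_light`, `mean_MA`, `mean_vspeed_m_s`,
#'   `n_fast_starts`, `diel2`, `diel4`, `n_samples`.
#' @export
aggregate_archive <- function(archive, flags = NULL, diel_times = NULL,
                              interval = c("hour", "min"), min_prop = 0.5) {
  interval <- match.arg(interval)
  stopifnot(inherits(archive, "tag_archive"))
  if (is.null(flags)) flags <- rep(FALSE, nrow(archive))
  if (length(flags) != nrow(archive)) {
    stop("aggregate_archive: `flags` not aligned to archive samples")
  }
  if (is.null(diel_times)) diel_times <- archive_diel_times(archive)
  dt_s <- attr(archive, "interval_s")
  width <- if (interval == "hour") 3600 else 60

  x <- data.table::as.data.table(archive)
  x[, MA := sqrt(ax^2 + ay^2 + az^2)]
  vs <- vertical_speed(archive$depth, dt_s)
  x[, vspeed := c(vs, NA_real_)]
  x[, flag := flags]
  tnum <- as.numeric(archive$timestamp)
  x[, bucket := floor(tnum / width) * width]

  agg <- x[, .(
    median_depth_m = median(depth, na.rm = TRUE),
    median_temp_C = median(temp, na.rm = TRUE),
    median_light = median(light, na.rm = TRUE),
    mean_MA = mean(MA, na.rm = TRUE),
    mean_vspeed_m_s = mean(vspeed, na.rm = TRUE),
    n_fast_starts = sum(flag, na.rm = TRUE),
    n_samples = sum(!is.na(depth))
  ), by = bucket]

  nominal <- width / dt_s
  low <- agg$n_samples < min_prop * nominal
  if (any(low)) {
    for (cl in c("median_depth_m", "median_temp_C", "median_light",
                 "mean_MA", "mean_vspeed_m_s")) {
      data.table::set(agg, which(low), cl, NA_real_)
    }
  }

  start <- as.POSIXct(agg$bucket, origin = "1970-01-01", tz = "UTC")
  mid <- start + width / 2
  out <- data.frame(
    animal_id = attr(archive, "animal_id") %||% NA_character_,
    interval_start = start,
    date = as.Date(start, tz = "UTC"),
    julian_day = as.integer(format(start, "%j")),
    median_depth_m = agg$median_depth_m,
    median_temp_C = agg$median_temp_C,
    median_light = agg$median_light,
    mean_MA = agg$mean_MA,
    mean_vspeed_m_s = agg$mean_vspeed_m_s,
    n_fast_starts = as.integer(agg$n_fast_starts),
    diel2 = classify_diel(mid, diel_times, scheme = 2),
    diel4 = classify_diel(mid, diel_times, scheme = 4),
    n_samples = agg$n_samples
  )
  out <- out[order(out$interval_start), ]
  rownames(out) <- NULL
  attr(out, "interval") <- interval
  attr(out, "interval_s") <- width
  class(out) <- c("aggregated_series", "data.frame")
  out
}
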