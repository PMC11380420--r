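# Fixture builders shared across test files.  All fixtures are constructed
# in code; nothing is read from disk.

# Minimal hand-built archive: depth (and optionally other channels) on a
# uniform grid.  Default interval 60 s keeps hand-built fixtures small.
make_archive <- function(depth, interval_s = 60,
                         start = as.POSIXct("2021-11-01", tz = "UTC"),
                         temp = NULL, light = NULL,
                         ax = NULL, ay = NULL, az = NULL,
                         animal_id = "fix01") {
  n <- length(depth)
  zero <- rep(0, n)
  out <- data.frame(
    timestamp = start + (seq_len(n) - 1) * interval_s,
    depth = depth,
    temp = temp %||% rep(8, n),
    light = light %||% zero,
    ax = ax %||% zero, ay = ay %||% zero, az = az %||% zero
  )
  attr(out, "animal_id") <- animal_id
  attr(out, "interval_s") <- interval_s
  attr(out, "latitude") <- 60.3
  attr(out, "longitude") <- 5.2
  class(out) <- c("tag_archive", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small simulated archive with sensible test defaults.
tiny_sim <- function(days = 3, seed = 1, ...) {
  generate_archive(sim_config(duration_days = days, seed = seed, ...))
}

# Fabricated wavelet result with a controllable p-value row at 24 h, for
# exercising the DVM classification rules in isolation.
fake_wavelet_24h <- function(p24, start = as.POSIXct("2021-11-02", tz = "UTC")) {
  n <- length(p24)
  periods <- c(12, 24, 48)
  structure(list(
    periods = periods, scales = periods / 1.033,
    times = start + (seq_len(n) - 1) * 3600,
    power = matrix(1, 3, n),
    coi_period = rep(Inf, n),  # keep all cells outside-COI for rule tests
    global_power = rep(1, 3),
    pvalues = rbind(rep(0.5, n), p24, rep(0.5, n)),
    global_pvalues = c(0.5, min(p24), 0.5),
    series = rep(0, n), interp_idx = integer(0),
    n = n, dt = 1, omega0 = 6, dj = 1 / 20,
    config = wavelet_config()
  ), class = "wavelet_result")
}

# Direct (brute force) time-domain Morlet convolution: the independent
# oracle for the FFT-based transform.
direct_morlet_power <- function(x, scales, dt = 1, omega0 = 6) {
  xd <- x - mean(x)
  n <- length(xd)
  t(vapply(scales, function(s) {
    w <- vapply(seq_len(n), function(t0) {
      eta <- (seq_len(n) - t0) * dt / s
      sum(xd * sqrt(dt / s) * pi^(-0.25) *
            exp(-1i * omega0 * eta) * exp(-eta^2 / 2))
    }, complex(1))
    Mod(w)^2 / s
  }, numeric(n)))
}

# Hourly AR(1) series with coefficient phi and unit stationary sd: the
# red-noise null of the surrogate test.
ar1_series <- function(n, phi = 0.5, mean = 100, sd_stat = 10) {
  innov <- rnorm(n, 0, sd_stat * sqrt(1 - phi^2))
  innov[1] <- rnorm(1, 0, sd_stat)
  mean + as.numeric(filter(innov, phi, method = "recursive"))
}
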