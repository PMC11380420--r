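# Weighted two-dimensional depth-temperature kernel density niche with
# mass-fraction isopleths and occupancy summaries.

#' Julian-day weights for pooled hourly records
#'
#' Each record is weighted by the reciprocal of the number of pooled hourly
#' records on its Julian day, then weights are renormalised to sum to one.
#' This removes the seasonal imbalance caused by unequal times at liberty:
#' every covered Julian day contributes equal total mass.
#'
#' @param julian_day Integer vector (1-366), one entry per pooled record.
#' @param id Optional individual identifiers; when given, counts are taken
#'   per individual and day instead of pooled across the cohort.
#' @return Numeric weights summing to 1.
#' @export
julian_day_weights <- function(julian_day, id = NULL) {
  stopifnot(length(julian_day) >= 1)
  key <- if (is.null(id)) as.character(julian_day) else {
    stopifnot(length(id) == length(julian_day))
    paste(id, julian_day)
  }
  counts <- table(key)
  w <- 1 / as.numeric(counts[key])
  w / sum(w)
}

#' Normal-reference bandwidth
#'
#' `h = 4 * 1.06 * min(sd(x), IQR(x)/1.34) * n^(-1/5)`: the normal
#' reference rule in the dialect where the Gaussian kernel standard
#' deviation is `h / 4`.
#'
#' @param x Numeric sample, `n >= 4`, non-degenerate spread.
#' @return Bandwidth `h` on the scale of `x`.
#' @export
reference_bandwidth <- function(x) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 4)
  iqr <- unname(diff(quantile(x, c(0.25, 0.75), type = 7)))
  spread <- min(sd(x), iqr / 1.34)
  if (spread <= 0) stop("reference_bandwidth: zero spread in x")
  4 * 1.06 * spread * length(x)^(-1 / 5)
}

#' Weighted 2-D kernel density estimate of the depth-temperature niche
#'
#' Product-Gaussian KDE on an axis-aligned grid covering the data range
#' with a 10% margin; kernel standard deviations are `h / 4` per axis.
#' Weights need not be normalised.
#'
#' @param depth,temp Equal-length numeric vectors (m, degrees C).
#' @param weights Non-negative weights, not all zero; default uniform.
#' @param bandwidths Numeric `c(h_depth, h_temp)`; default
#'   [reference_bandwidth()] per axis.
#' @param grid Grid size `c(n_depth, n_temp)` (default 200 x 200).
#' @return A `niche_estimate` list: `depth_grid`, `temp_grid`, `density`
#'   (depth x temp, integrates to ~1), `bandwidths`, `weights_used`,
#'   `isopleth_levels` (density thresholds for the 50% and 95% mass
#'   fractions).
#' @export
weighted_kde2d <- function(depth, temp, weights = NULL, bandwidths = NULL,
                           grid = c(200, 200)) {
  ok <- complete.cases(depth, temp)
  depth <- depth[ok]; temp <- temp[ok]
  n <- length(depth)
  stopifnot(n >= 4, length(temp) == n)
  if (is.null(weights)) weights <- rep(1, n) else weights <- weights[ok]
  stopifnot(all(weights >= 0), any(weights > 0))
  w <- weights / sum(weights)
  if (is.null(bandwidths)) {
    bandwidths <- c(reference_bandwidth(depth), reference_bandwidth(temp))
  }
  if (any(!is.finite(bandwidths)) || any(bandwidths <= 0)) {
    stop("weighted_kde2d: degenerate bandwidth")
  }
  sd_d <- bandwidths[1] / 4
  sd_t <- bandwidths[2] / 4
  margin <- function(r) diff(r) * 0.1
  rd <- range(depth); rt <- range(temp)
  dg <- seq(rd[1] - margin(rd), rd[2] + margin(rd), length.out = grid[1])
  tg <- seq(rt[1] - margin(rt), rt[2] + margin(rt), length.out = grid[2])
  Kd <- outer(dg, depth, function(g, xi) dnorm(g, xi, sd_d))
  Kt <- outer(tg, temp, function(g, xi) dnorm(g, xi, sd_t))
  dens <- Kd %*% (w * t(Kt))
  est <- structure(list(depth_grid = dg, temp_grid = tg, density = dens,
                        bandwidths = bandwidths, weights_used = w,
                        isopleth_levels = NULL),
                   class = "niche_estimate")
  est$isopleth_levels <- isopleth_levels(est)
  est
}

#' @export
print.niche_estimate <- function(x, ...) {
  cat(sprintf(
    "<niche_estimate> %dx%d grid, h=(%.3g m, %.3g C), levels 50%%=%.3g 95%%=%.3g\n",
    length(x$depth_grid), length(x$temp_grid),
    x$bandwidths[1], x$bandwidths[2],
    x$isopleth_levels[["0.5"]], x$isopleth_levels[["0.95"]]))
  invisible(x)
}

#' Isopleth density levels for mass fractions
#'
#' For each fraction `f`, the largest density level `L` such that grid
#' cells with density `>= L` contain at least `f` of the total mass
#' (descending cumulative sum over sorted cells).  Higher fractions give
#' lower levels: `L(0.5) >= L(0.95)`.
#'
#' @param est A `niche_estimate` (or a plain density matrix with uniform
#'   cell area).
#' @param mass_fractions Fractions in (0, 1); default 0.5 and 0.95.
#' @return Named numeric vector of levels.
#' @export
isopleth_levels <- function(est, mass_fractions = c(0.5, 0.95)) {
  stopifnot(all(mass_fractions > 0), all(mass_fractions < 1))
  dens <- if (inherits(est, "niche_estimate")) est$density else est
  p <- sort(as.numeric(dens), decreasing = TRUE)
  cum <- cumsum(p) / sum(p)
  out <- vapply(mass_fractions, function(f) p[which(cum >= f)[1]],
                numeric(1))
  names(out) <- as.character(mass_fractions)
  out
}

#' Evaluate a niche density at data points
#'
#' Bilinear interpolation of the density grid; used for isopleth coverage
#' checks.
#'
#' @param est A `niche_estimate`.
#' @param depth,temp Point coordinates.
#' @return Density values (0 outside the grid).
#' @export
niche_density_at <- function(est, depth, temp) {
  dg <- est$depth_grid; tg <- est$temp_grid
  fi <- approx(dg, seq_along(dg), xout = depth, rule = 1)$y
  fj <- approx(tg, seq_along(tg), xout = temp, rule = 1)$y
  out <- numeric(length(depth))
  ok <- !is.na(fi) & !is.na(fj)
  i0 <- pmin(floor(fi[ok]), length(dg) - 1L)
  j0 <- pmin(floor(fj[ok]), length(tg) - 1L)
  u <- fi[ok] - i0
  v <- fj[ok] - j0
  d <- est$density
  out[ok] <- (1 - u) * (1 - v) * d[cbind(i0, j0)] +
    u * (1 - v) * d[cbind(i0 + 1, j0)] +
    (1 - u) * v * d[cbind(i0, j0 + 1)] +
    u * v * d[cbind(i0 + 1, j0 + 1)]
  out
}

#' Occupancy fractions per depth or temperature bin
#'
#' Per individual, the Julian-day-weighted fraction of hourly records per
#' bin; reported as mean and standard error across individuals.  Default
#' depth bins are 25 m wide; named zones (shallow <= 75 m, epipelagic
#' <= 200 m, mesopelagic 200-1000 m) are summarised alongside.
#'
#' @param hourly A pooled `aggregated_series`-like data.frame with columns
#'   `animal_id`, `julian_day` and the binned variable.
#' @param variable `"median_depth_m"` or `"median_temp_C"`.
#' @param breaks Bin edges partitioning the observed range; default 25 m
#'   depth bins (2 C bins for temperature).
#' @param weights Per-record weights; default pooled [julian_day_weights()].
#' @return list(`bins` = data.frame(bin, mean_pct, se_pct),
#'   `zones` = data.frame(zone, mean_pct, se_pct) for depth,
#'   `per_individual` = matrix of per-animal percentages).
#' @export
occupancy_fractions <- function(hourly, variable = "median_depth_m",
                                breaks = NULL, weights = NULL) {
  x <- hourly[[variable]]
  ok <- !is.na(x)
  x <- x[ok]
  id <- as.character(hourly$animal_id)[ok]
  if (is.null(weights)) weights <- julian_day_weights(hourly$julian_day[ok])
  else weights <- weights[ok]
  if (is.null(breaks)) {
    step <- if (grepl("depth", variable)) 25 else 2
    breaks <- seq(floor(min(x) / step) * step,
                  ceiling(max(x) / step) * step, by = step)
  }
  if (length(breaks) < 2) stop("occupancy_fractions: empty bin set")
  bin <- cut(x, breaks, right = FALSE, include.lowest = TRUE)
  ids <- sort(unique(id))
  per_ind <- sapply(ids, function(a) {
    sel <- id == a
    wa <- weights[sel] / sum(weights[sel])
    100 * vapply(levels(bin), function(b) sum(wa[bin[sel] == b]), numeric(1))
  })
  per_ind <- matrix(per_ind, nrow = nlevels(bin),
                    dimnames = list(levels(bin), ids))
  summarise <- function(m) {
    se <- if (ncol(m) == 1) rep(0, nrow(m)) else {
      apply(m, 1, sd) / sqrt(ncol(m))
    }
    data.frame(bin = rownames(m), mean_pct = rowMeans(m), se_pct = se)
  }
  out <- list(bins = summarise(per_ind), per_individual = per_ind)
  if (grepl("depth", variable)) {
    zones <- sapply(ids, function(a) {
      sel <- id == a
      wa <- weights[sel] / sum(weights[sel])
      xa <- x[sel]
      100 * c(shallow = sum(wa[xa <= 75]),
              epipelagic = sum(wa[xa <= 200]),
              mesopelagic = sum(wa[xa > 200 & xa <= 1000]))
    })
    zones <- matrix(zones, nrow = 3,
                    dimnames = list(c("shallow", "epipelagic", "mesopelagic"),
                                    ids))
    zse <- if (ncol(zones) == 1) rep(0, 3) else {
      apply(zones, 1, sd) / sqrt(ncol(zones))
    }
    out$zones <- data.frame(zone = rownames(zones),
                            mean_pct = rowMeans(zones), se_pct = zse)
  }
  out
}
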