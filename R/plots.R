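# Base-graphics exports of the three standard figures: scalogram, niche
# density with isopleths, and monthly hotspot heat map.

#' Plot a wavelet scalogram
#'
#' Bias-corrected power on log2 period against time, with the cone of
#' influence and (when p-values are available) contours of the significant
#' region (p <= alpha).
#'
#' @param result A `wavelet_result`.
#' @param alpha Significance level for the contour overlay.
#' @param ... Passed to [graphics::image()].
#' @export
plot_scalogram <- function(result, alpha = result$config$alpha, ...) {
  stopifnot(inherits(result, "wavelet_result"))
  tx <- as.numeric(result$times)
  y <- log2(result$periods)
  graphics::image(tx, y, t(log10(result$power + 1e-12)),
                  xlab = "time", ylab = "period (h, log2)", axes = FALSE,
                  ...)
  yat <- pretty(y)
  graphics::axis(2, at = yat, labels = round(2^yat, 1))
  graphics::axis(1)
  graphics::box()
  graphics::lines(tx, log2(pmax(result$coi_period, min(result$periods))),
                  lty = 2)
  if (!is.null(result$pvalues)) {
    graphics::contour(tx, y, t(result$pvalues <= alpha) + 0,
                      levels = 0.5, add = TRUE, drawlabels = FALSE)
  }
  invisible(result)
}

#' Plot a depth-temperature niche estimate
#'
#' Density image (depth increasing downward) with the 50% and 95%
#' isopleth contours.
#'
#' @param est A `niche_estimate`.
#' @param max_depth Optional display cap for the depth axis (presentation
#'   only; the estimate itself is unchanged).
#' @param ... Passed to [graphics::image()].
#' @export
plot_niche <- function(est, max_depth = NULL, ...) {
  stopifnot(inherits(est, "niche_estimate"))
  graphics::image(est$temp_grid, est$depth_grid, t(est$density),
                  xlab = "temperature (C)", ylab = "depth (m)",
                  ylim = c(min(max_depth %||% max(est$depth_grid),
                               max(est$depth_grid)),
                           min(est$depth_grid)), ...)
  graphics::contour(est$temp_grid, est$depth_grid, t(est$density),
                    levels = est$isopleth_levels, add = TRUE,
                    labels = c("50%", "95%"))
  invisible(est)
}

#' Plot a monthly hotspot map
#'
#' Scaled fast starts per 10 m x 1 h cell, depth increasing downward.
#'
#' @param map A `hotspot_map`.
#' @param ... Passed to [graphics::image()].
#' @export
plot_hotspot <- function(map, ...) {
  stopifnot(inherits(map, "hotspot_map"))
  if (!nrow(map$scaled_fast_starts)) {
    stop("plot_hotspot: empty map (no samples in month)")
  }
  mids <- utils::head(map$depth_edges, -1) + diff(map$depth_edges) / 2
  graphics::image(map$hours, mids, t(map$scaled_fast_starts),
                  xlab = "hour of day (UTC)", ylab = "depth (m)",
                  ylim = rev(range(mids)),
                  main = sprintf("month %d (n = %d)", map$month,
                                 map$n_points), ...)
  invisible(map)
}
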