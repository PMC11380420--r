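# Monthly depth x hour-of-day occupancy and scaled fast-start activity maps.

#' Monthly depth-by-hour activity hotspot map
#'
#' Bins raw-rate (0.2 Hz) samples into cells of 10 m depth by 1 h of day
#' (UTC) for one calendar month across all supplied archives, and scales
#' the fast-start count per cell by the month's total sample count so maps
#' are comparable between months.  Depth bins are half-open
#' `[lower, upper)` from 0; samples deeper than the deepest edge extend the
#' bin set.
#'
#' @param archives List of (cleaned) `tag_archive` objects.
#' @param flags List of logical fast-start flag vectors aligned to each
#'   archive.
#' @param month Calendar month 1-12.
#' @param depth_bin_m Bin width (default 10 m).
#' @return A `hotspot_map` list: `month`, `depth_edges`, `hours` (0-23),
#'   `scaled_fast_starts` and `occupancy` matrices (depth bin x hour),
#'   `n_points`, `n_fast_starts`, `n_individuals`.
#' @export
bin_activity <- function(archives, flags, month, depth_bin_m = 10) {
  stopifnot(month %in% 1:12, length(archives) == length(flags))
  pieces <- list()
  contributing <- 0L
  for (i in seq_along(archives)) {
    a <- archives[[i]]
    f <- flags[[i]]
    if (length(f) != nrow(a)) stop("bin_activity: flags not aligned")
    lt <- as.POSIXlt(a$timestamp, tz = "UTC")
    sel <- (lt$mon + 1L) == month & !is.na(a$depth)
    if (!any(sel)) next
    contributing <- contributing + 1L
    pieces[[length(pieces) + 1L]] <- data.table::data.table(
      dbin = floor(pmax(a$depth[sel], 0) / depth_bin_m),
      hour_of_day = lt$hour[sel],
      flag = f[sel])
  }
  if (!length(pieces)) {
    return(structure(list(month = month, depth_edges = numeric(0),
                          hours = 0:23,
                          scaled_fast_starts = matrix(0, 0, 24),
                          occupancy = matrix(0L, 0, 24),
                          n_points = 0L, n_fast_starts = 0L,
                          n_individuals = 0L),
                     class = "hotspot_map"))
  }
  x <- data.table::rbindlist(pieces)
  n_points <- nrow(x)
  cells <- x[, .(n = .N, n_flag = sum(flag)), by = .(dbin, hour_of_day)]
  max_bin <- max(cells$dbin)
  occ <- matrix(0L, max_bin + 1L, 24,
                dimnames = list(paste0(depth_bin_m * (0:max_bin), "-",
                                       depth_bin_m * (1:(max_bin + 1)), "m"),
                                0:23))
  sfs <- matrix(0, max_bin + 1L, 24, dimnames = dimnames(occ))
  idx <- cbind(cells$dbin + 1L, cells$hour_of_day + 1L)
  occ[idx] <- cells$n
  sfs[idx] <- cells$n_flag / n_points
  structure(list(month = month,
                 depth_edges = depth_bin_m * (0:(max_bin + 1)),
                 hours = 0:23,
                 scaled_fast_starts = sfs, occupancy = occ,
                 n_points = n_points,
                 n_fast_starts = sum(cells$n_flag),
                 n_individuals = contributing),
            class = "hotspot_map")
}

#' @export
print.hotspot_map <- function(x, ...) {
  cat(sprintf(
    "<hotspot_map> month %d: %d samples, %d fast starts, %d individuals\n",
    x$month, x$n_points, x$n_fast_starts, x$n_individuals))
  invisible(x)
}

#' Remove the first hours of each archive (tagging-effect sensitivity)
#'
#' Truncates each archive's first `hours` so hotspot maps can be recomputed
#' without early post-tagging data.  Archives not longer than the cut are
#' dropped (with a message).
#'
#' @param archives List of `tag_archive` objects.
#' @param hours Hours to excise from the head (default 120 = 5 days).
#' @return List of truncated archives (possibly shorter than the input).
#' @export
sensitivity_excise_head <- function(archives, hours = 120) {
  out <- list()
  for (a in archives) {
    dt <- attr(a, "interval_s")
    n_cut <- as.integer(round(hours * 3600 / dt))
    if (nrow(a) <= n_cut) {
      message("sensitivity_excise_head: dropping archive ",
              attr(a, "animal_id") %||% "?", " (not longer than ", hours,
              " h)")
      next
    }
    out[[length(out) + 1L]] <-
      .subset_archive(a, seq_len(nrow(a)) > n_cut)
  }
  out
}
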