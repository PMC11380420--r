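# Daily DVM classification from wavelet significance at the diel period,
# p-value smoothing, and between-individual clustering.

#' Classify diel vertical migration per day
#'
#' Extracts the hourly p-value at the grid period nearest 24 h from a
#' significance-filled wavelet result and flags each day as DVM when a
#' strict majority (`> majority`) of its valid hours are significant at
#' `alpha`.  Days with fewer than 12 valid hours get a missing flag.
#' Hours inside the cone of influence are retained but marked.
#'
#' @param result A `wavelet_result` (hourly depth) with `pvalues` filled and
#'   POSIXct `times`.
#' @param majority Fraction of significant hours required (strict), 0.5 =
#'   "more than half the time".
#' @param alpha Hourly significance level.
#' @param animal_id Identifier carried into the result.
#' @return A `dvm_classification` list: `animal_id`, `period_used_h`,
#'   `hourly` (data.frame: time, p24, in_coi, valid), `daily` (data.frame:
#'   date, julian_day, n_valid_hours, prop_hours_significant, daily_mean_p,
#'   dvm_flag, smoothed_p).
#' @export
classify_dvm <- function(result, majority = 0.5, alpha = 0.05,
                         animal_id = NA_character_) {
  stopifnot(inherits(result, "wavelet_result"))
  if (is.null(result$pvalues)) {
    stop("classify_dvm: wavelet result has no surrogate p-values")
  }
  if (!inherits(result$times, "POSIXct")) {
    stop("classify_dvm: wavelet result needs POSIXct times")
  }
  j24 <- which.min(abs(log2(result$periods / 24)))
  if (abs(log2(result$periods[j24] / 24)) > result$dj) {
    stop("classify_dvm: no grid period within one dj step of 24 h")
  }
  p24 <- result$pvalues[j24, ]
  in_coi <- result$periods[j24] > result$coi_period
  valid <- !(seq_along(p24) %in% result$interp_idx)
  date <- as.Date(result$times, tz = "UTC")
  hourly <- data.frame(time = result$times, p24 = p24,
                       in_coi = in_coi, valid = valid)
  sig <- p24 <= alpha
  dtab <- data.table::data.table(date = date, p = p24, sig = sig,
                                 valid = valid)
  daily <- dtab[, .(
    n_valid_hours = sum(valid),
    prop_hours_significant = mean(sig[valid]),
    daily_mean_p = mean(p[valid])
  ), by = date]
  data.table::setorder(daily, date)
  daily <- as.data.frame(daily)
  daily$dvm_flag <- ifelse(daily$n_valid_hours >= 12,
                           daily$prop_hours_significant > majority, NA)
  daily$julian_day <- as.integer(format(daily$date, "%j"))
  daily$smoothed_p <- smooth_daily_pvalues(daily$daily_mean_p)
  structure(list(animal_id = animal_id,
                 period_used_h = result$periods[j24],
                 hourly = hourly, daily = daily,
                 majority = majority, alpha = alpha),
            class = "dvm_classification")
}

#' @export
print.dvm_classification <- function(x, ...) {
  cat(sprintf(
    "<dvm_classification> %s: %d days, %.0f%% flagged DVM (period %.2f h)\n",
    x$animal_id, nrow(x$daily),
    100 * mean(x$daily$dvm_flag, na.rm = TRUE), x$period_used_h))
  invisible(x)
}

#' Proportion of individuals showing DVM per Julian day
#'
#' @param classifications List of `dvm_classification` objects.
#' @return data.frame with `julian_day`, `n_individuals` (with data and a
#'   defined flag on that day) and `proportion_dvm` (NA when no coverage).
#' @export
dvm_proportion_by_day <- function(classifications) {
  stopifnot(length(classifications) >= 1)
  all_days <- data.table::rbindlist(lapply(classifications, function(cl) {
    data.table::data.table(julian_day = cl$daily$julian_day,
                           flag = cl$daily$dvm_flag)
  }))
  out <- all_days[!is.na(flag),
                  .(n_individuals = .N, proportion_dvm = mean(flag)),
                  by = julian_day]
  data.table::setorder(out, julian_day)
  full <- data.frame(julian_day = 1:366)
  out <- merge(full, as.data.frame(out), by = "julian_day", all.x = TRUE)
  out$n_individuals[is.na(out$n_individuals)] <- 0L
  out
}

#' Centred rolling mean of a daily p-value series
#'
#' Window of `window` days (odd); ends are computed over the available days
#' (shrinking window).  Missing days stay missing; missing neighbours are
#' excluded from the mean.
#'
#' @param daily_mean_p Numeric vector, one value per day.
#' @param window Odd window length (default 11).
#' @return Smoothed vector of equal length.
#' @export
smooth_daily_pvalues <- function(daily_mean_p, window = 11) {
  stopifnot(window %% 2 == 1)
  out <- zoo::rollapply(daily_mean_p, width = window,
                        FUN = function(v) {
                          if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
                        },
                        align = "center", partial = TRUE)
  out[is.na(daily_mean_p)] <- NA_real_
  out
}

#' Missing-value-scaled Euclidean distance between DVM p-value series
#'
#' For each pair, days missing in either series are excluded and the sum of
#' squared differences is scaled up proportionally to the number of columns
#' used: `d = sqrt((N / n_used) * sum((p_a - p_b)^2))` with `N` the total
#' number of days in the common index.  Pairs with no co-observed days get
#' a missing distance.
#'
#' @param series Named list of numeric vectors, all aligned to a common
#'   day index (e.g. Julian days 1..365; shorter deployments padded with
#'   NA).
#' @return A `dvm_distance` list: `ids`, `distance` (symmetric matrix, zero
#'   diagonal), `n_used` (co-observed day counts per pair).
#' @export
dvm_distance_matrix <- function(series) {
  stopifnot(length(series) >= 2)
  N <- unique(vapply(series, length, integer(1)))
  if (length(N) != 1) {
    stop("dvm_distance_matrix: series must share a common day index")
  }
  ids <- names(series) %||% paste0("id", seq_along(series))
  k <- length(series)
  D <- matrix(0, k, k, dimnames = list(ids, ids))
  U <- matrix(N, k, k, dimnames = list(ids, ids))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      ok <- !is.na(series[[a]]) & !is.na(series[[b]])
      n_used <- sum(ok)
      U[a, b] <- U[b, a] <- n_used
      D[a, b] <- D[b, a] <- if (n_used == 0) NA_real_ else {
        sqrt(N / n_used * sum((series[[a]][ok] - series[[b]][ok])^2))
      }
    }
  }
  structure(list(ids = ids, distance = D, n_used = U, n_days = N),
            class = "dvm_distance")
}

#' Hierarchical clustering of individuals by DVM similarity
#'
#' Agglomerative clustering (complete linkage) on a DVM distance matrix;
#' leaf order is made deterministic by sorting ids before clustering.
#'
#' @param dist_obj A `dvm_distance` from [dvm_distance_matrix()], or a
#'   symmetric distance matrix.
#' @param method Linkage method passed to [stats::hclust()].
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(dist_obj, method = "complete") {
  D <- if (inherits(dist_obj, "dvm_distance")) dist_obj$distance else dist_obj
  if (anyNA(D)) {
    stop("hierarchical_cluster: missing pairwise distances; impute or ",
         "exclude individuals with no co-observed days")
  }
  ord <- order(rownames(D))
  D <- D[ord, ord]
  hclust(as.dist(D), method = method)
}

#' Export a dendrogram as Newick text
#'
#' @param hc An `hclust` object.
#' @param path Output file; when `NULL` the Newick string is returned.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(path)
}
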