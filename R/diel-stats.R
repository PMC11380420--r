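# Diel and DVM-conditional comparisons on aggregated series: paired rank
# tests for day/night depth, one-sample t tests on crepuscular vertical
# speed, Mann-Whitney comparisons of fast starts, and environmental
# correlations of fast-start counts.

.diel_row <- function(test_name, grouping, statistic, p_value, n,
                      direction = NA_character_, note = NA_character_) {
  data.frame(test_name = test_name, grouping = grouping,
             statistic = statistic, p_value = p_value, n = n,
             direction = direction, note = note)
}

# day/night value per animal-date: median of the interval medians
.day_night_pairs <- function(aggregated, value_col, fun = median) {
  x <- data.table::as.data.table(aggregated)
  x <- x[!is.na(x[[value_col]]) & diel2 %in% c("day", "night")]
  p <- x[, .(v = fun(.SD[[1]])), by = .(animal_id, date, diel2),
         .SDcols = value_col]
  wide <- data.table::dcast(p, animal_id + date ~ diel2, value.var = "v")
  wide[!is.na(wide$day) & !is.na(wide$night), ]
}

#' Paired day-night depth comparison on DVM days
#'
#' Wilcoxon signed-rank test on per-animal-day pairs of (day median depth,
#' night median depth), restricted to days flagged as DVM.  Direction
#' "day deeper" corresponds to normal DVM.
#'
#' @param aggregated Pooled `aggregated_series` (1-min or hourly) rows from
#'   one or more animals.
#' @param dvm_flags Optional data.frame with `animal_id`, `date`,
#'   `dvm_flag`; when supplied only flagged days enter the pairing.
#' @return A `diel_comparison` data.frame (one row).
#' @export
compare_day_night_depth <- function(aggregated, dvm_flags = NULL) {
  pairs <- .day_night_pairs(aggregated, "median_depth_m")
  if (!is.null(dvm_flags)) {
    f <- data.table::as.data.table(dvm_flags)
    keep <- f[f$dvm_flag %in% TRUE, c("animal_id", "date")]
    pairs <- merge(pairs, keep, by = c("animal_id", "date"))
  }
  n <- nrow(pairs)
  if (n < 5) {
    return(structure(.diel_row("wilcoxon_signed_rank", "day_vs_night_depth",
                               NA_real_, NA_real_, n,
                               note = "insufficient data (< 5 pairs)"),
                     class = c("diel_comparison", "data.frame")))
  }
  diffs <- pairs$day - pairs$night
  if (all(diffs == 0)) {
    out <- .diel_row("wilcoxon_signed_rank", "day_vs_night_depth",
                     n * (n + 1) / 4, 1, n, "none",
                     note = "identical day/night medians")
  } else {
    wt <- suppressWarnings(wilcox.test(pairs$day, pairs$night,
                                       paired = TRUE))
    dir <- if (median(diffs) > 0) "day deeper" else if (median(diffs) < 0) {
      "night deeper"
    } else "none"
    out <- .diel_row("wilcoxon_signed_rank", "day_vs_night_depth",
                     unname(wt$statistic), wt$p.value, n, dir)
  }
  structure(out, class = c("diel_comparison", "data.frame"))
}

#' One-sample t tests of hourly vertical speed against zero
#'
#' Per 4-level diel period: positive mean speed marks ascent (expected at
#' dusk under normal DVM), negative marks descent (dawn).
#'
#' @param aggregated Pooled hourly `aggregated_series`.
#' @param periods Diel periods to test.
#' @return A `diel_comparison` data.frame, one row per period.
#' @export
test_vspeed_nonzero <- function(aggregated,
                                periods = c("dawn", "day", "dusk", "night")) {
  rows <- lapply(periods, function(p) {
    v <- aggregated$mean_vspeed_m_s[aggregated$diel4 == p]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n < 2) {
      return(.diel_row("one_sample_t", paste0("vspeed_", p), NA_real_,
                       NA_real_, n, note = "insufficient data"))
    }
    if (sd(v) == 0) {
      p_val <- if (mean(v) == 0) 1 else 0
      return(.diel_row("one_sample_t", paste0("vspeed_", p), NA_real_,
                       p_val, n, if (mean(v) > 0) "ascent" else if
                       (mean(v) < 0) "descent" else "none",
                       note = "zero variance"))
    }
    tt <- t.test(v, mu = 0)
    .diel_row("one_sample_t", paste0("vspeed_", p), unname(tt$statistic),
              tt$p.value, n,
              if (mean(v) > 0) "ascent" else "descent")
  })
  structure(do.call(rbind, rows),
            class = c("diel_comparison", "data.frame"))
}

#' Fast starts during DVM versus non-DVM behaviour
#'
#' Pooled one-sided Mann-Whitney test (DVM hours stochastically greater),
#' plus a per-individual breakdown of one-sided paired day-versus-night
#' Wilcoxon tests on daily fast-start totals.
#'
#' @param aggregated Pooled hourly `aggregated_series`.
#' @param dvm_flags data.frame with `animal_id`, `date`, `dvm_flag`.
#' @param alternative Direction of the pooled test (default `"greater"`:
#'   DVM hours stochastically larger); the chosen direction is recorded in
#'   the output row.
#' @return list(`pooled` = one-row `diel_comparison`,
#'   `per_individual` = `diel_comparison` with one row per animal).
#' @export
compare_fast_starts_by_dvm <- function(aggregated, dvm_flags,
                                       alternative = "greater") {
  x <- data.table::as.data.table(aggregated)
  f <- data.table::as.data.table(dvm_flags)
  x <- merge(x, f[, c("animal_id", "date", "dvm_flag")],
             by = c("animal_id", "date"))
  x <- x[!is.na(x$dvm_flag) & !is.na(x$n_fast_starts), ]
  g1 <- x$n_fast_starts[x$dvm_flag == TRUE]
  g0 <- x$n_fast_starts[x$dvm_flag == FALSE]
  pooled <- if (!length(g1) || !length(g0)) {
    .diel_row("mann_whitney_one_sided", "fast_starts_dvm_vs_nondvm",
              NA_real_, NA_real_, length(g1) + length(g0),
              note = "one group empty")
  } else {
    mw <- suppressWarnings(wilcox.test(g1, g0, alternative = alternative))
    .diel_row("mann_whitney_one_sided", "fast_starts_dvm_vs_nondvm",
              unname(mw$statistic), mw$p.value, length(g1) + length(g0),
              if (median(g1) >= median(g0)) "dvm higher" else "nondvm higher",
              note = paste0("alternative=", alternative))
  }
  per_id <- lapply(split(as.data.frame(x), x$animal_id), function(xa) {
    pairs <- .day_night_pairs(xa, "n_fast_starts", fun = sum)
    n <- nrow(pairs)
    if (n < 5 || all(pairs$day == pairs$night)) {
      return(.diel_row("wilcoxon_signed_rank_one_sided",
                       paste0("fast_starts_day_vs_night:",
                              xa$animal_id[1]),
                       NA_real_, NA_real_, n, note = "degenerate"))
    }
    wt <- suppressWarnings(wilcox.test(pairs$day, pairs$night,
                                       paired = TRUE,
                                       alternative = "greater"))
    .diel_row("wilcoxon_signed_rank_one_sided",
              paste0("fast_starts_day_vs_night:", xa$animal_id[1]),
              unname(wt$statistic), wt$p.value, n,
              if (median(pairs$day - pairs$night) > 0) "day higher"
              else "night higher")
  })
  list(pooled = structure(pooled,
                          class = c("diel_comparison", "data.frame")),
       per_individual = structure(do.call(rbind, per_id),
                                  class = c("diel_comparison",
                                            "data.frame")))
}

#' Correlation of hourly fast starts with environment
#'
#' Pearson correlations of hourly fast-start counts with hourly median
#' depth, temperature and light.  Constant covariates give a missing r.
#'
#' @param aggregated Pooled hourly `aggregated_series`.
#' @return A `diel_comparison` data.frame with rows for depth, temperature
#'   and light.
#' @export
faststart_environment_correlations <- function(aggregated) {
  covars <- c(depth = "median_depth_m", temperature = "median_temp_C",
              light = "median_light")
  rows <- lapply(names(covars), function(nm) {
    v <- aggregated[[covars[[nm]]]]
    y <- aggregated$n_fast_starts
    ok <- !is.na(v) & !is.na(y)
    n <- sum(ok)
    if (n < 3 || sd(v[ok]) == 0 || sd(y[ok]) == 0) {
      return(.diel_row("pearson_correlation",
                       paste0("fast_starts_vs_", nm), NA_real_, NA_real_,
                       n, note = "constant covariate or too few records"))
    }
    r <- cor(y[ok], v[ok])
    .diel_row("pearson_correlation", paste0("fast_starts_vs_", nm),
              r, NA_real_, n, if (r > 0) "positive" else "negative")
  })
  structure(do.call(rbind, rows),
            class = c("diel_comparison", "data.frame"))
}
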