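# End-to-end pipeline: simulate/read -> clean -> fast starts -> aggregate ->
# wavelet + surrogates -> DVM classification & clustering -> niche ->
# hotspots -> diel statistics, with delimited-text outputs and a manifest.

#' Pipeline configuration
#'
#' Exactly one of `input_paths` (archive files to read) or `simulation`
#' (a list of generator settings) must be supplied.  `seed` is mandatory
#' whenever simulation or surrogate testing runs.
#'
#' @param input_paths Character vector of archive files, or `NULL`.
#' @param simulation List with `n_animals`, `duration_days` and optional
#'   overrides for [sim_config()] fields, or `NULL`.
#' @param latitude,longitude Reference coordinate for solar times.
#' @param quantile_q Fast-start MA quantile.
#' @param wavelet List of overrides for [wavelet_config()] fields.
#' @param majority,alpha DVM daily-classification parameters.
#' @param head_hours Hours removed from each track head during cleaning.
#' @param write_scalograms Write full power/p-value matrices per animal
#'   (large); the global spectra are always written.
#' @param hotspot_sensitivity Also recompute hotspot maps with the first
#'   120 h excised.
#' @param seed Integer base seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_paths = NULL, simulation = NULL,
                            latitude = 60.3, longitude = 5.2,
                            quantile_q = 0.95, wavelet = list(),
                            majority = 0.5, alpha = 0.05, head_hours = 24,
                            write_scalograms = FALSE,
                            hotspot_sensitivity = FALSE, seed = NULL) {
  if (is.null(input_paths) == is.null(simulation)) {
    stop("pipeline_config: supply exactly one of `input_paths` or ",
         "`simulation`")
  }
  if ((!is.null(simulation) || is.null(input_paths)) && is.null(seed)) {
    stop("pipeline_config: `seed` is required when simulating")
  }
  if (is.null(seed)) {
    stop("pipeline_config: `seed` is required (surrogate significance)")
  }
  structure(list(input_paths = input_paths, simulation = simulation,
                 latitude = latitude, longitude = longitude,
                 quantile_q = quantile_q, wavelet = wavelet,
                 majority = majority, alpha = alpha,
                 head_hours = head_hours,
                 write_scalograms = isTRUE(write_scalograms),
                 hotspot_sensitivity = isTRUE(hotspot_sensitivity),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.log_stage <- function(...) message("[divetag] ", sprintf(...))

.acquire_archives <- function(config) {
  if (!is.null(config$input_paths)) {
    archives <- lapply(config$input_paths, read_archive)
  } else {
    sim <- config$simulation
    n_animals <- sim$n_animals %||% 1L
    overrides <- sim[setdiff(names(sim), "n_animals")]
    archives <- lapply(seq_len(n_animals), function(i) {
      cfg <- do.call(sim_config, c(overrides,
                                   list(seed = config$seed + i,
                                        latitude = config$latitude,
                                        longitude = config$longitude)))
      generate_archive(cfg, animal_id = sprintf("sim%02d", i))
    })
  }
  archives
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a cohort of archives, cleans them, detects fast
#' starts, aggregates to hourly resolution, runs the wavelet analysis with
#' AR(1) surrogate significance on each hourly depth series, classifies
#' daily DVM, clusters individuals by smoothed 24-h p-value series,
#' estimates the pooled weighted depth-temperature niche, builds monthly
#' activity hotspot maps, and computes the diel statistics.  All outputs
#' are written as delimited text under `out_dir` together with a JSON run
#' manifest; results are also returned invisibly.  Deterministic for a
#' fixed config seed.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @return (invisibly) list with `cleaned`, `reports`,
#'   `fast_starts`, `hourly`, `wavelets`, `classifications`, `dvm_flags`,
#'   `proportion_by_day`, `distance`, `dendrogram`, `niche`, `occupancy`,
#'   `hotspots`, `stats`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  .log_stage("stage simulate/read")
  archives <- .acquire_archives(config)
  ids <- vapply(archives, function(a) attr(a, "animal_id"), character(1))

  .log_stage("stage preprocess (%d archives)", length(archives))
  cleaned <- list(); reports <- list(); fast_starts <- list()
  hourly <- list()
  for (i in seq_along(archives)) {
    cl <- clean_track(archives[[i]], head_hours = config$head_hours)
    # raw archives are only needed again for the head-excision sensitivity
    if (!config$hotspot_sensitivity) archives[[i]] <- NA
    cleaned[[i]] <- cl$archive
    reports[[i]] <- cl$report
    ma <- magnitude(cl$archive$ax, cl$archive$ay, cl$archive$az)
    fast_starts[[i]] <- detect_fast_starts(ma, q = config$quantile_q)
    hourly[[i]] <- aggregate_archive(cl$archive,
                                     flags = fast_starts[[i]]$flags,
                                     interval = "hour")
  }

  .log_stage("stage wavelet + surrogates")
  wavelets <- list(); classifications <- list()
  for (i in seq_along(cleaned)) {
    h <- hourly[[i]]
    wcfg_args <- config$wavelet
    wcfg_args$seed <- (wcfg_args$seed %||% (config$seed + 100000L)) + i
    wcfg <- do.call(wavelet_config, wcfg_args)
    wres <- morlet_cwt(h$median_depth_m, wcfg, times = h$interval_start)
    wres <- ar1_surrogate_pvalues(wres)
    wavelets[[i]] <- wres
    classifications[[i]] <- classify_dvm(wres, majority = config$majority,
                                         alpha = config$alpha,
                                         animal_id = ids[i])
  }
  dvm_flags <- do.call(rbind, lapply(classifications, function(cl) {
    data.frame(animal_id = cl$animal_id, date = cl$daily$date,
               dvm_flag = cl$daily$dvm_flag)
  }))

  .log_stage("stage dvm summaries")
  prop_day <- dvm_proportion_by_day(classifications)
  series <- lapply(classifications, function(cl) {
    v <- rep(NA_real_, 365)
    jd <- pmin(cl$daily$julian_day, 365L)
    agg <- tapply(cl$daily$smoothed_p, jd, mean)
    v[as.integer(names(agg))] <- as.numeric(agg)
    v
  })
  names(series) <- ids
  distance <- NULL; dendro <- NULL
  if (length(series) >= 2) {
    distance <- dvm_distance_matrix(series)
    if (!anyNA(distance$distance)) {
      dendro <- hierarchical_cluster(distance)
    } else {
      .log_stage("dendrogram skipped: pairs with no co-observed days")
    }
  }

  .log_stage("stage niche")
  pooled <- do.call(rbind, hourly)
  ok <- !is.na(pooled$median_depth_m) & !is.na(pooled$median_temp_C)
  pooled_ok <- pooled[ok, ]
  w <- julian_day_weights(pooled_ok$julian_day)
  niche <- weighted_kde2d(pooled_ok$median_depth_m,
                          pooled_ok$median_temp_C, weights = w)
  occupancy <- occupancy_fractions(pooled_ok, weights = w)

  .log_stage("stage hotspots")
  flag_list <- lapply(fast_starts, function(f) f$flags)
  months <- sort(unique(unlist(lapply(cleaned, function(a) {
    as.POSIXlt(a$timestamp, tz = "UTC")$mon + 1L
  }))))
  hotspots <- lapply(months, function(m) {
    bin_activity(cleaned, flag_list, month = m)
  })
  names(hotspots) <- sprintf("month%02d", months)
  hotspots_excised <- NULL
  if (config$hotspot_sensitivity) {
    exc <- sensitivity_excise_head(archives, hours = 120)
    exc_flags <- lapply(exc, function(a) {
      ma <- magnitude(a$ax, a$ay, a$az)
      detect_fast_starts(ma, q = config$quantile_q)$flags
    })
    hotspots_excised <- lapply(months, function(m) {
      bin_activity(exc, exc_flags, month = m)
    })
    names(hotspots_excised) <- names(hotspots)
  }

  .log_stage("stage stats")
  stats_tab <- rbind(
    compare_day_night_depth(pooled, dvm_flags),
    test_vspeed_nonzero(pooled),
    compare_fast_starts_by_dvm(pooled, dvm_flags)$pooled,
    faststart_environment_correlations(pooled)
  )

  manifest <- list(
    package = "divetag",
    version = as.character(packageVersion("divetag")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "input_paths")],
    animals = ids,
    n_samples = vapply(cleaned, nrow, integer(1))
  )

  res <- list(cleaned = cleaned, reports = reports,
              fast_starts = fast_starts, hourly = hourly,
              wavelets = wavelets, classifications = classifications,
              dvm_flags = dvm_flags, proportion_by_day = prop_day,
              distance = distance, dendrogram = dendro, niche = niche,
              occupancy = occupancy, hotspots = hotspots,
              hotspots_excised = hotspots_excised, stats = stats_tab,
              manifest = manifest)
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir, config)
  invisible(res)
}

.write_pipeline_outputs <- function(res, out_dir, config) {
  fw <- function(x, name) {
    data.table::fwrite(x, file.path(out_dir, name))
  }
  for (i in seq_along(res$hourly)) {
    id <- res$manifest$animals[i]
    fw(res$hourly[[i]], sprintf("hourly_%s.csv", id))
    wres <- res$wavelets[[i]]
    fw(data.frame(period_h = wres$periods,
                  global_power = wres$global_power,
                  global_p = wres$global_pvalues),
       sprintf("global_spectrum_%s.csv", id))
    if (config$write_scalograms) {
      pow <- as.data.frame(wres$power)
      names(pow) <- format(wres$times, "%Y-%m-%dT%H:%M:%SZ")
      fw(cbind(period_h = wres$periods, pow),
         sprintf("scalogram_power_%s.csv", id))
      pv <- as.data.frame(wres$pvalues)
      names(pv) <- names(pow)
      fw(cbind(period_h = wres$periods, pv),
         sprintf("scalogram_p_%s.csv", id))
    }
    fw(res$classifications[[i]]$daily, sprintf("dvm_daily_%s.csv", id))
  }
  fw(res$dvm_flags, "dvm_flags.csv")
  fw(res$proportion_by_day, "dvm_proportion_by_day.csv")
  if (!is.null(res$distance)) {
    fw(cbind(id = rownames(res$distance$distance),
             as.data.frame(res$distance$distance)), "dvm_distance.csv")
  }
  if (!is.null(res$dendrogram)) {
    dendrogram_newick(res$dendrogram,
                      file.path(out_dir, "dvm_dendrogram.nwk"))
  }
  fw(cbind(depth_m = res$niche$depth_grid,
           as.data.frame(res$niche$density)), "niche_density.csv")
  fw(data.frame(mass_fraction = names(res$niche$isopleth_levels),
                level = unname(res$niche$isopleth_levels)),
     "niche_isopleths.csv")
  fw(res$occupancy$bins, "occupancy_depth_bins.csv")
  if (!is.null(res$occupancy$zones)) fw(res$occupancy$zones,
                                        "occupancy_zones.csv")
  for (nm in names(res$hotspots)) {
    hm <- res$hotspots[[nm]]
    if (!nrow(hm$scaled_fast_starts)) next
    fw(cbind(depth_bin = rownames(hm$scaled_fast_starts),
             as.data.frame(hm$scaled_fast_starts)),
       sprintf("hotspot_%s.csv", nm))
  }
  fw(res$stats, "diel_stats.csv")
  jsonlite::write_json(res$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
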