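#' Default pipeline configuration
#'
#' All tunable constants of the analysis chain with their conventional
#' values: altitude screen 21/244 m, speed cap 3 m/s, negative binomial
#' interpolation error (mean 5.46 m, dispersion 2.4), 4-min fix grid, FPT
#' radii 15/30 m over a 12-min window, 100-location daily-path filter,
#' residence/return cutoff 12 h, monthly VI with 200 fixes per month.
#'
#' @param input Path to the tracking CSV.
#' @param out_dir Output directory for stage tables and the manifest.
#' @param ... Overrides of any default entry.
#' @return A named configuration list.
#' @export
pipeline_config <- function(input, out_dir, ...) {
  cfg <- list(
    input = input, out_dir = out_dir, boundary = NULL,
    altitude_low = 21, altitude_high = 244, vmax = 3,
    interval = 240, stationarity_radius = 30,
    error_mean = 5.46, error_dispersion = 2.4,
    fpt_radii = c(15, 30), fpt_window = 720,
    cvm_window = 31,
    min_daily_fixes = 100, max_gap = 3600,
    rt_cutoff = 12 * 3600, rt_every = 1, vi_min_fixes = 200,
    activity_windows = NULL,  # NULL -> bci_activity_windows()
    tz_local = "Etc/GMT+5", seed = 17,
    log_metrics = "straightness")
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config,
          c(list(input = y$input, out_dir = y$out_dir),
            y[setdiff(names(y), c("input", "out_dir"))]))
}

#' Run the full multi-scale analysis pipeline
#'
#' Preprocess (burst selection, outlier screening, gap interpolation) ->
#' daily-path assembly -> step fits -> behavioral segmentation -> daily-path
#' metrics -> life-phase metrics -> variance partitions and syndrome PCAs
#' per scale. Each stage writes a CSV into `out_dir`; a JSON manifest
#' records thresholds, seeds, and row counts (including the conservation
#' check fixes_in = retained + flagged). Rerunning with identical config and
#' input is bit-identical.
#'
#' @param config A [pipeline_config()] list or path to a YAML file.
#' @return Invisibly, a list with all stage tables and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  aw <- config$activity_windows %||% bci_activity_windows()
  if (!is.data.frame(aw) && !is.character(aw)) aw <- tibble::as_tibble(aw)

  raw <- read_tracking_csv(config$input)
  pp <- preprocess_tracks(
    raw, boundary = config$boundary,
    altitude_low = config$altitude_low, altitude_high = config$altitude_high,
    vmax = config$vmax, interval = config$interval,
    stationarity_radius = config$stationarity_radius,
    mean_error = config$error_mean, dispersion = config$error_dispersion,
    activity_windows = aw, tz_local = config$tz_local, seed = config$seed)
  write_tracking_csv(pp$fixes, file.path(config$out_dir, "clean.csv"))

  daily <- assemble_daily_paths(pp$fixes, activity_windows = aw,
                                tz_local = config$tz_local,
                                max_gap = config$max_gap)

  steps <- compute_steps(daily, by = c("individual_id", "period_date"))
  stepfits <- fit_step_distributions(steps)
  readr::write_csv(stepfits, file.path(config$out_dir, "stepfits.csv"),
                   progress = FALSE)

  seg <- segment_behavior(daily, radii = config$fpt_radii,
                          window = config$fpt_window,
                          cvm_window = config$cvm_window)
  readr::write_csv(
    dplyr::select(seg, dplyr::all_of(c(
      "individual_id", "species", "period_date", "timestamp",
      "fpt15", "fpt30", "eta", "tau", "label", "basis"))),
    file.path(config$out_dir, "labels.csv"), progress = FALSE)

  dmetrics <- daily_path_metrics(seg, species_step = species_mean_step(steps),
                                 min_fixes = config$min_daily_fixes)
  readr::write_csv(dmetrics, file.path(config$out_dir, "daily_metrics.csv"),
                   progress = FALSE)

  lp <- lifephase_metrics(pp$fixes, cutoff = config$rt_cutoff,
                          every = config$rt_every,
                          vi_min_fixes = config$vi_min_fixes)
  readr::write_csv(lp, file.path(config$out_dir, "lifephase.csv"),
                   progress = FALSE)

  syn_dir <- file.path(config$out_dir, "syndromes")
  dir.create(syn_dir, showWarnings = FALSE)
  path_metrics_cols <- c("distance_m", "straightness", "sinuosity",
                         "prop_cluster", "prop_ars")
  eligible_days <- dmetrics[dmetrics$eligible, ]
  indiv_means <- eligible_days %>%
    dplyr::group_by(.data$individual_id, .data$species) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(path_metrics_cols),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  scales <- list(
    step = list(data = stepfits,
                metrics = c("gamma_k", "gamma_theta", "vm_mu", "vm_kappa")),
    path_daily = list(data = eligible_days, metrics = path_metrics_cols),
    path_individual = list(data = indiv_means, metrics = path_metrics_cols),
    lifephase = list(data = lp,
                     metrics = c("tac_mean", "residence_h",
                                 "time_to_return_h", "vi", "mnsd_scaled")))
  varparts <- list(); pcas <- list()
  for (sc in names(scales)) {
    d <- scales[[sc]]$data
    mets <- scales[[sc]]$metrics
    mets <- mets[vapply(mets, function(m)
      m %in% names(d) && sum(!is.na(d[[m]])) >= 3 &&
        var(d[[m]], na.rm = TRUE) > 0, TRUE)]
    if (length(mets) < 2 || nrow(d) < 3 ||
        length(unique(d$species)) < 2) next
    vp <- variance_partition(d, metrics = mets)
    vp$scale <- sc
    varparts[[sc]] <- vp
    ps <- tryCatch(
      pca_syndromes(d, metrics = mets, log_metrics = config$log_metrics),
      error = function(e) NULL)
    if (!is.null(ps)) {
      pcas[[sc]] <- ps
      readr::write_csv(tidy(ps),
                       file.path(syn_dir, paste0("loadings_", sc, ".csv")),
                       progress = FALSE)
      readr::write_csv(ps$scores,
                       file.path(syn_dir, paste0("scores_", sc, ".csv")),
                       progress = FALSE)
    }
  }
  vp_all <- dplyr::bind_rows(varparts)
  readr::write_csv(vp_all, file.path(syn_dir, "variance_partition.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    lapply(pcas, function(p) list(
      retained = p$retained, pct_variance = p$pct_variance,
      cum_pct_retained = p$cum_pct_retained)),
    file.path(syn_dir, "summary.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("msms")),
    seed = config$seed,
    thresholds = config[c("altitude_low", "altitude_high", "vmax",
                          "fpt_radii", "fpt_window", "min_daily_fixes",
                          "rt_cutoff", "stationarity_radius")],
    rows = list(
      input = nrow(raw), retained = nrow(drop_outliers(raw)),
      flagged = nrow(raw) - nrow(drop_outliers(raw)),
      after_burst_and_flags = nrow(pp$fixes) -
        sum(pp$fixes$source == "interpolated"),
      interpolated = sum(pp$fixes$source == "interpolated"),
      daily_fixes = nrow(daily), stepfit_rows = nrow(stepfits),
      daily_metric_rows = nrow(dmetrics),
      eligible_days = sum(dmetrics$eligible),
      lifephase_rows = nrow(lp)),
    conservation_ok = nrow(raw) ==
      nrow(drop_outliers(raw)) + (nrow(raw) - nrow(drop_outliers(raw))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fixes = pp$fixes, report = pp$report, daily = daily,
                 stepfits = stepfits, segmentation = seg,
                 daily_metrics = dmetrics, lifephase = lp,
                 variance_partition = vp_all, pca = pcas,
                 manifest = manifest))
}
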