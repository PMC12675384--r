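# Pipeline orchestration: config-driven simulate/extract/fit/partition runs.

#' Read a pipeline configuration (YAML or JSON)
#'
#' Recognised blocks (all optional unless a stage needs them):
#' \itemize{
#'   \item `synthetic`: arguments for [synthetic_config] (`noise_sd`,
#'     `n_participants`, `seed`, ...).
#'   \item `inputs`: `manifest` (cohort manifest JSON) or `series_csv`.
#'   \item `thermo`: `W_stride_kJ`, `m_foot_kg`, `c_foot_kJ_per_kgK`,
#'     `total_strides`, `duration_min`, optional `W_bounds`, `c_bounds`,
#'     optional `tissues` (list of `{name, fraction, c}` from which
#'     `c_foot` is computed when `c_foot_kJ_per_kgK` is absent).
#'   \item `fitting`: `multi_start` (logical).
#'   \item `burn`: `threshold_C` (default 43.3), `baseline_C` (required for
#'     burn estimates), `mode`, `speed_m_s` (default 1.25).
#'   \item `out_dir`, `seed`.
#' }
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be YAML or JSON: ", path, call. = FALSE))
  structure(cfg, class = c("pipeline_config", "list"))
}

.thermo_from_config <- function(cfg) {
  th <- cfg$thermo
  if (is.null(th)) stop("config has no `thermo` block", call. = FALSE)
  c_foot <- th$c_foot_kJ_per_kgK
  if (is.null(c_foot)) {
    if (is.null(th$tissues))
      stop("thermo block needs c_foot_kJ_per_kgK or tissues", call. = FALSE)
    c_foot <- composite_specific_heat(th$tissues)
  }
  thermo_params(W_stride = th$W_stride_kJ, m_foot = th$m_foot_kg,
                c_foot = c_foot, total_strides = th$total_strides,
                duration_min = th$duration_min,
                W_bounds = th$W_bounds, c_bounds = th$c_bounds)
}

#' Simulate a synthetic cohort from a config
#'
#' @param config A `pipeline_config` (or list) with a `synthetic` block.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @param seed Overrides `config$synthetic$seed` when not `NULL`.
#' @return The manifest path, invisibly; the cohort is written under
#'   `out_dir/cohort/`.
#' @export
run_simulate <- function(config, out_dir = config$out_dir, seed = NULL) {
  args <- if (is.null(config$synthetic)) list() else config$synthetic
  if (!is.null(seed)) args$seed <- seed
  cohort <- generate_cohort(do.call(synthetic_config, args))
  if (is.null(out_dir)) stop("no output directory configured", call. = FALSE)
  write_cohort(cohort, file.path(out_dir, "cohort"))
}

#' Extract regional stats and whole-foot series from frames on disk
#'
#' Reads every frame/mask pair listed in a cohort manifest, computes
#' regional stats and the area-weighted whole-foot series per participant,
#' and writes `region_stats_*.csv` and `whole_foot_*.csv`. Any unreadable
#' file aborts the run with the offending path (no silent skips).
#'
#' @param config A `pipeline_config` whose `inputs$manifest` points at a
#'   manifest written by [write_cohort] (or assembled by hand in the same
#'   layout).
#' @param out_dir Output directory.
#' @return Named list of per-participant `whole_foot_series`, invisibly;
#'   side effect: CSV outputs under `out_dir`.
#' @export
run_extract <- function(config, out_dir = config$out_dir) {
  man_path <- config$inputs$manifest
  if (is.null(man_path)) stop("config$inputs$manifest missing", call. = FALSE)
  if (!file.exists(man_path))
    stop("manifest not found: ", man_path, call. = FALSE)
  manifest <- jsonlite::read_json(man_path, simplifyVector = FALSE)
  label_map <- unlist(jsonlite::read_json(manifest$label_map))
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (p in seq_along(manifest$participants)) {
    part <- manifest$participants[[p]]
    stats <- do.call(rbind, lapply(part$frames, function(fr) {
      frame <- read_thermal_frame(fr$frame, time_min = fr$time_min)
      mask <- read_region_mask(fr$mask, label_map)
      extract_region_stats(frame, mask)
    }))
    series <- build_series(stats)
    tag <- sprintf("participant_%02d", p)
    if (!is.null(out_dir)) {
      write_region_stats(stats, file.path(out_dir,
                                          paste0("region_stats_", tag, ".csv")))
      write_whole_foot_series(series,
                              file.path(out_dir,
                                        paste0("whole_foot_", tag, ".csv")))
    }
    out[[tag]] <- series
  }
  invisible(out)
}

#' Fit both temporal models to every regional series in a cohort
#'
#' Produces the per-region fit tables: linear coefficients, logistic
#' coefficients, and the criteria comparison, averaged-series first. Series
#' for a region are averaged across participants point-wise before fitting
#' (the cohort-mean temporal response), matching how a cohort's regional
#' curves are conventionally summarised.
#'
#' @param config A `pipeline_config` with `inputs$manifest`.
#' @param out_dir Output directory for `fits.json` and `comparison.csv`.
#' @return List with per-region `linear`, `logistic`, `comparison`,
#'   invisibly.
#' @export
run_fit <- function(config, out_dir = config$out_dir) {
  man_path <- config$inputs$manifest
  if (is.null(man_path) || !file.exists(man_path))
    stop("manifest not found: ", man_path, call. = FALSE)
  manifest <- jsonlite::read_json(man_path, simplifyVector = FALSE)
  multi_start <- isTRUE(config$fitting$multi_start)
  # collect per-region series across participants
  first <- read.csv(manifest$participants[[1]]$series[[1]])
  regions <- names(manifest$participants[[1]]$series)
  out <- list()
  comp_rows <- list()
  for (rg in regions) {
    mats <- vapply(manifest$participants, function(part) {
      read.csv(part$series[[rg]])$temp_C
    }, numeric(nrow(first)))
    mean_series <- temperature_series(first$time_min, rowMeans(mats),
                                      label = rg)
    lin <- fit_linear(mean_series)
    logi <- suppressWarnings(fit_logistic(mean_series,
                                          multi_start = multi_start))
    cmp <- compare_models(lin, logi)
    out[[rg]] <- list(linear = lin, logistic = logi, comparison = cmp)
    comp_rows[[rg]] <- data.frame(
      region = rg, winner = cmp$winner,
      linear_s_res = lin$s_res, linear_mse = lin$mse,
      logistic_s_res = logi$s_res, logistic_mse = logi$mse)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fit_json(lapply(out, function(x)
      list(linear = unclass(x$linear), logistic = unclass(x$logistic))),
      file.path(out_dir, "fits.json"))
    write.csv(do.call(rbind, comp_rows),
              file.path(out_dir, "comparison.csv"),
              row.names = FALSE, quote = FALSE)
  }
  invisible(out)
}

#' Partition a whole-foot series and estimate burn times
#'
#' Builds the mechanical curve from the configured thermodynamic
#' parameters, subtracts it from the experimental whole-foot temperature
#' change, writes the decomposition table with envelopes, and (when a
#' baseline is configured) the burn-time report with the distance covered
#' at the configured walking speed.
#'
#' @param config A `pipeline_config` with a `thermo` block and either
#'   `inputs$series_csv` (whole-foot series CSV: `time_min,temp_C,delta_C`)
#'   or an explicit `exp_series` argument.
#' @param exp_series Optional `whole_foot_series` or data frame with
#'   `time_min` and `delta_C`, overriding the configured CSV.
#' @param out_dir Output directory.
#' @return List with `decomposition`, `envelope` and (if configured)
#'   `burn`, invisibly.
#' @export
run_partition <- function(config, exp_series = NULL,
                          out_dir = config$out_dir) {
  params <- .thermo_from_config(config)
  if (is.null(exp_series)) {
    path <- config$inputs$series_csv
    if (is.null(path) || !file.exists(path))
      stop("whole-foot series CSV not found: ",
           if (is.null(path)) "(unset)" else path, call. = FALSE)
    df <- read.csv(path)
    if (!all(c("time_min", "delta_C") %in% names(df)))
      stop("series CSV needs time_min and delta_C columns", call. = FALSE)
    exp_series <- df
  }
  times <- if (inherits(exp_series, "whole_foot_series"))
    exp_series$points$time_min else exp_series$time_min
  schedule <- stride_schedule(params$total_strides, params$duration_min,
                              times = times)
  mech <- mechanical_curve(params, schedule)
  env <- if (!is.null(params$W_bounds) || !is.null(params$c_bounds))
    mechanical_envelope(params, schedule) else NULL
  decomp <- decompose_series(exp_series, mech, envelope = env)

  burn <- NULL
  bc <- config$burn
  if (!is.null(bc)) {
    if (is.null(bc$baseline_C))
      stop("burn estimate requested but burn$baseline_C missing",
           call. = FALSE)
    rate <- stride_delta_T(params) * params$total_strides /
      params$duration_min
    threshold <- if (is.null(bc$threshold_C)) 43.3 else bc$threshold_C
    mode <- if (is.null(bc$mode)) "mechanical_only" else bc$mode
    speed <- if (is.null(bc$speed_m_s)) 1.25 else bc$speed_m_s
    est <- burn_time(bc$baseline_C, rate, threshold_C = threshold,
                     mode = mode,
                     exp_curve = if (mode == "experimental_then_mechanical")
                       data.frame(time_min = times,
                                  temp_C = bc$baseline_C +
                                    decomp$table$dT_exp) else NULL)
    burn <- list(threshold_C = threshold, baseline_C = bc$baseline_C,
                 mode = mode, time_min = est$time_min,
                 distance_km = walk_distance_km(est$time_min, speed),
                 speed_m_s = speed)
    # bound envelopes on the burn time from the mechanical-rate bounds
    if (!is.null(env$work)) {
      rates <- vapply(env$work, function(cv)
        cv$dT[length(cv$dT)] / params$duration_min, numeric(1))
      ts <- vapply(rates, function(r)
        burn_time(bc$baseline_C, r, threshold, mode = "mechanical_only")$time_min,
        numeric(1))
      burn$work_bound_times_min <- sort(unname(ts))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_decomposition(decomp, file.path(out_dir, "decomposition.csv"))
    if (!is.null(burn))
      jsonlite::write_json(burn, file.path(out_dir, "burn_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(decomposition = decomp, envelope = env, burn = burn))
}

#' Run the full pipeline: simulate, extract, fit, partition
#'
#' Convenience wrapper chaining all stages on a synthetic cohort. The
#' partition stage uses the across-participant mean whole-foot series.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (required).
#' @param seed Optional seed override for the simulation stage.
#' @return List with `series`, `fits`, `partition`, invisibly.
#' @export
run_all <- function(config, out_dir = config$out_dir, seed = NULL) {
  if (is.null(out_dir)) stop("run_all needs an output directory",
                             call. = FALSE)
  manifest <- run_simulate(config, out_dir = out_dir, seed = seed)
  config$inputs$manifest <- manifest
  series <- run_extract(config, out_dir = out_dir)
  fits <- run_fit(config, out_dir = out_dir)
  # cohort-mean whole-foot delta series
  times <- series[[1]]$points$time_min
  mean_delta <- rowMeans(vapply(series, function(s) s$points$delta_C,
                                numeric(length(times))))
  mean_temp <- rowMeans(vapply(series, function(s) s$points$temp_C,
                               numeric(length(times))))
  exp_df <- data.frame(time_min = times, delta_C = mean_delta)
  if (!is.null(config$burn) && is.null(config$burn$baseline_C))
    config$burn$baseline_C <- mean_temp[1]
  partition <- run_partition(config, exp_series = exp_df,
                             out_dir = out_dir)
  invisible(list(series = series, fits = fits, partition = partition))
}
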