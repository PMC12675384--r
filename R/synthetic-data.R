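# Seeded synthetic cohorts: regional series with generalized-logistic ground
# truth plus Gaussian noise, and matching thermal frames with region masks.

#' Default per-region generalized-logistic ground truth
#'
#' Coefficient sets typical of the five plantar regions of healthy adults
#' during a 30-min walk: the hallux warms most (several degC, strongly
#' S-shaped), the arch least. These serve as the generator's ground truth so
#' synthetic cohorts reproduce realistic temporal shapes.
#'
#' @return Named list of coefficient vectors (`A,K,C,Q,B,nu`) per region.
#' @export
default_region_truth <- function() {
  list(
    hallux  = c(A = 27.28, K = 32.80, C = 0.994, Q = 0.92,   B = 0.19, nu = 0.078),
    MTP     = c(A = 29.88, K = 33.69, C = 0.976, Q = 4.79,   B = 0.18, nu = 0.43),
    arch    = c(A = 31.20, K = 31.61, C = 0.998, Q = 0.017,  B = 0.17, nu = 0.0012),
    midfoot = c(A = 30.25, K = 31.50, C = 0.999, Q = 0.0081, B = 0.14, nu = 0.0014),
    heel    = c(A = 29.19, K = 30.11, C = 0.999, Q = 0.0057, B = 0.15, nu = 0.00078)
  )
}

#' Synthetic cohort configuration
#'
#' @param region_truth Named list of logistic coefficient vectors per region;
#'   default [default_region_truth].
#' @param region_areas Named integer vector of pixel areas per region.
#'   Defaults are proportional to plausible plantar surface shares (the MTP
#'   ball largest, the hallux smallest).
#' @param noise_sd Additive Gaussian noise SD on each temporal sample
#'   (degC). Default 0.2, well below the regional temperature changes.
#' @param spatial_noise_sd Per-pixel Gaussian SD within a frame (degC);
#'   default 0 so frame-derived regional means equal the series exactly.
#' @param sample_interval_min Minutes between thermal photos (default 5).
#' @param duration_min Walk duration (default 30).
#' @param n_participants Cohort size (default 8).
#' @param participant_spread SD of per-participant random offsets applied to
#'   both `A` and `K` (degC, default 0.5), emulating between-participant
#'   baseline differences.
#' @param seed Integer seed; identical configs and seeds give identical
#'   cohorts.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(region_truth = default_region_truth(),
                             region_areas = c(hallux = 60, MTP = 180,
                                              midfoot = 120, arch = 100,
                                              heel = 140),
                             noise_sd = 0.2, spatial_noise_sd = 0,
                             sample_interval_min = 5, duration_min = 30,
                             n_participants = 8, participant_spread = 0.5,
                             seed = 42L) {
  if (noise_sd < 0 || spatial_noise_sd < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  if (duration_min %% sample_interval_min != 0)
    stop("sample interval must divide the duration", call. = FALSE)
  if (n_participants < 1) stop("need at least one participant", call. = FALSE)
  if (!setequal(names(region_truth), names(region_areas)))
    stop("region_truth and region_areas must name the same regions",
         call. = FALSE)
  for (rg in names(region_truth)) {
    p <- region_truth[[rg]]
    if (!all(c("A", "K", "C", "Q", "B", "nu") %in% names(p)))
      stop("truth for ", rg, " must name A, K, C, Q, B, nu", call. = FALSE)
    if (p[["B"]] <= 0 || p[["nu"]] <= 0 || p[["C"]] <= 0 || p[["Q"]] < 0)
      stop("invalid truth coefficients for ", rg,
           ": need B, nu, C > 0 and Q >= 0", call. = FALSE)
  }
  structure(list(region_truth = region_truth,
                 region_areas = region_areas[names(region_truth)],
                 noise_sd = noise_sd, spatial_noise_sd = spatial_noise_sd,
                 sample_interval_min = sample_interval_min,
                 duration_min = duration_min,
                 n_participants = as.integer(n_participants),
                 participant_spread = participant_spread,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Derive a child stream seed from (seed, indices): deterministic integer
# mixing kept inside 32-bit range, so each participant/region/frame draws
# from its own stream and adding a participant never perturbs earlier ones.
.stream_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) h <- (h * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
  as.integer(h)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate one regional temperature series
#'
#' Samples the generalized-logistic ground truth on the photo grid and adds
#' i.i.d. Gaussian noise.
#'
#' @param truth Named coefficients `A,K,C,Q,B,nu` with `B, nu, C > 0`,
#'   `Q >= 0`.
#' @param times Sampling times in minutes.
#' @param noise_sd Gaussian SD in degC (0 gives the exact curve).
#' @param seed Stream seed for reproducibility.
#' @param label Series label.
#' @return A [temperature_series].
#' @export
generate_region_series <- function(truth, times = seq(0, 30, by = 5),
                                   noise_sd = 0.2, seed = 1L,
                                   label = "region") {
  truth <- unlist(truth)
  if (truth[["B"]] <= 0 || truth[["nu"]] <= 0 || truth[["C"]] <= 0 ||
      truth[["Q"]] < 0)
    stop("invalid coefficients: need B, nu, C > 0 and Q >= 0", call. = FALSE)
  mu <- evaluate_logistic(truth, times)
  temps <- if (noise_sd > 0)
    .with_seed(seed, mu + rnorm(length(times), 0, noise_sd)) else mu
  temperature_series(times, temps, label = label)
}

#' Generate a synthetic thermal frame and matching mask
#'
#' Lays the regions out as non-overlapping rectangular blocks stacked on a
#' uniform ambient background (geometry is abstract: the area-weighted
#' whole-foot average depends only on areas and means, not on outlines).
#' Each region's pixels are drawn around its nominal temperature.
#'
#' @param region_temps Named vector: one temperature per region (degC).
#' @param region_areas Named vector of pixel areas, same regions.
#' @param time_min Frame time stamp.
#' @param spatial_noise_sd Per-pixel Gaussian SD (0 = uniform blocks).
#' @param seed Stream seed.
#' @param background_C Ambient background temperature (default 22 degC).
#' @param width Frame width in pixels.
#' @return List with elements `frame` ([thermal_frame]) and `mask`
#'   ([region_mask]); with `spatial_noise_sd = 0`,
#'   [extract_region_stats] recovers each regional temperature and area
#'   exactly.
#' @export
generate_frame <- function(region_temps, region_areas, time_min = 0,
                           spatial_noise_sd = 0, seed = 1L,
                           background_C = 22, width = 20L) {
  regions <- names(region_temps)
  if (is.null(regions) || !setequal(regions, names(region_areas)))
    stop("region_temps and region_areas must name the same regions",
         call. = FALSE)
  areas <- region_areas[regions]
  if (any(areas < 1)) stop("region areas must be >= 1", call. = FALSE)
  block_rows <- ceiling(areas / width)
  total_rows <- sum(block_rows) + 2L  # background margin rows
  pixels <- matrix(background_C, nrow = total_rows, ncol = width)
  labels <- matrix(0L, nrow = total_rows, ncol = width)
  values <- .with_seed(seed, lapply(seq_along(regions), function(i) {
    if (spatial_noise_sd > 0)
      rnorm(areas[[i]], region_temps[[i]], spatial_noise_sd)
    else rep(region_temps[[i]], areas[[i]])
  }))
  offset <- 1L
  for (i in seq_along(regions)) {
    # fill `area` cells row-major inside this region's block of rows
    cells <- seq_len(areas[[i]]) - 1L
    rr <- offset + cells %/% width
    cc <- 1L + cells %% width
    idx <- cbind(rr, cc)
    pixels[idx] <- values[[i]]
    labels[idx] <- i
    offset <- offset + block_rows[[i]]
  }
  list(frame = thermal_frame(pixels, time_min),
       mask = region_mask(labels, setNames(seq_along(regions), regions)))
}

#' Generate a full synthetic cohort
#'
#' For each participant: draw one random offset (applied to both plateau
#' parameters `A` and `K`, preserving the shape), generate the five regional
#' series with temporal noise, and build one frame + mask pair per time
#' point whose regional blocks carry the (noisy) regional temperatures.
#' Ground truth is retained for recovery experiments.
#'
#' @param config A [synthetic_config].
#' @param include_frames Build the per-time-point frame/mask pairs (default
#'   `TRUE`); set `FALSE` when only the series are needed, e.g. in large
#'   simulation studies.
#' @return Object of class `synthetic_cohort`: per-participant lists with
#'   `series` (per region), `frames` (per time point, each `frame` +
#'   `mask`), `offset`, and `truth` (the participant's shifted coefficient
#'   sets); plus `config` and the noise-free `ground_truth` curves on the
#'   sampling grid.
#' @export
generate_cohort <- function(config = synthetic_config(),
                            include_frames = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  times <- seq(0, config$duration_min, by = config$sample_interval_min)
  regions <- names(config$region_truth)

  ground_truth <- lapply(config$region_truth, evaluate_logistic, t = times)

  participants <- lapply(seq_len(config$n_participants), function(p) {
    offset <- if (config$participant_spread > 0)
      .with_seed(.stream_seed(config$seed, p, 0L),
                 rnorm(1, 0, config$participant_spread)) else 0
    truth_p <- lapply(config$region_truth, function(co) {
      co[["A"]] <- co[["A"]] + offset
      co[["K"]] <- co[["K"]] + offset
      co
    })
    series <- lapply(seq_along(regions), function(r) {
      generate_region_series(truth_p[[regions[r]]], times = times,
                             noise_sd = config$noise_sd,
                             seed = .stream_seed(config$seed, p, r),
                             label = regions[r])
    })
    names(series) <- regions
    frames <- if (!include_frames) NULL else lapply(seq_along(times), function(k) {
      temps_k <- vapply(series, function(s) s$temps[k], numeric(1))
      generate_frame(temps_k, config$region_areas, time_min = times[k],
                     spatial_noise_sd = config$spatial_noise_sd,
                     seed = .stream_seed(config$seed, p, 1000L + k))
    })
    list(series = series, frames = frames, offset = offset,
         truth = truth_p)
  })
  structure(list(participants = participants, times = times,
                 ground_truth = ground_truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants x %d regions x %d time points (seed %d, noise %.2g degC)\n",
              length(x$participants), length(x$ground_truth),
              length(x$times), x$config$seed, x$config$noise_sd))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the same formats the ingestion side reads: per-participant regional
#' series CSVs, per-time-point frame and mask CSV matrices, a JSON label
#' map, and a manifest JSON listing every file plus the ground-truth
#' coefficients.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Path of the manifest JSON, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  regions <- names(cohort$ground_truth)
  label_map <- setNames(as.list(seq_along(regions)), regions)
  label_map_path <- file.path(dir, "label_map.json")
  jsonlite::write_json(label_map, label_map_path, auto_unbox = TRUE)
  manifest <- list(label_map = label_map_path, participants = list())
  for (p in seq_along(cohort$participants)) {
    part <- cohort$participants[[p]]
    pdir <- file.path(dir, sprintf("participant_%02d", p))
    dir.create(pdir, showWarnings = FALSE)
    series_files <- list()
    for (rg in regions) {
      s <- part$series[[rg]]
      f <- file.path(pdir, paste0("series_", rg, ".csv"))
      write.csv(data.frame(time_min = s$times, temp_C = s$temps,
                           label = rg),
                f, row.names = FALSE, quote = FALSE)
      series_files[[rg]] <- f
    }
    frame_files <- lapply(seq_along(part$frames), function(k) {
      fr <- part$frames[[k]]
      fpath <- file.path(pdir, sprintf("frame_t%02d.csv",
                                       as.integer(cohort$times[k])))
      mpath <- file.path(pdir, sprintf("mask_t%02d.csv",
                                       as.integer(cohort$times[k])))
      write.table(fr$frame$pixels, fpath, sep = ",", row.names = FALSE,
                  col.names = FALSE)
      write.table(fr$mask$labels, mpath, sep = ",", row.names = FALSE,
                  col.names = FALSE)
      list(time_min = cohort$times[k], frame = fpath, mask = mpath)
    })
    manifest$participants[[p]] <- list(series = series_files,
                                       frames = frame_files)
  }
  manifest$ground_truth <- lapply(cohort$config$region_truth, as.list)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest_path)
}
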