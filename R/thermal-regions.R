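# Regional temperature extraction from thermal frames and label masks.

PLANTAR_REGIONS <- c("hallux", "MTP", "midfoot", "arch", "heel")

#' Construct a thermal frame
#'
#' A thermal frame is a rectangular matrix of plantar surface temperatures
#' (degrees Celsius) captured at one time point of the walk.
#'
#' @param pixels Numeric matrix of temperatures in degrees C.
#' @param time_min Minutes since the start of the walk (baseline frame = 0).
#' @param frame_id Optional text label.
#' @return An object of class `thermal_frame`.
#' @details Pixel values outside the physiological band \[10, 50\] degrees C
#'   trigger a warning but are kept: cold floors and hot spots are plausible,
#'   sensor garbage is not silently accepted either way.
#' @examples
#' fr <- thermal_frame(matrix(31, 10, 10), time_min = 0)
#' @export
thermal_frame <- function(pixels, time_min, frame_id = NULL) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty numeric matrix", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("`pixels` contains non-finite values", call. = FALSE)
  if (!is.numeric(time_min) || length(time_min) != 1L || !is.finite(time_min))
    stop("`time_min` must be a single finite number", call. = FALSE)
  if (any(pixels < 10 | pixels > 50))
    warning("pixel temperatures outside [10, 50] degrees C present",
            call. = FALSE)
  structure(
    list(pixels = pixels, time_min = as.numeric(time_min),
         frame_id = if (is.null(frame_id)) sprintf("t%g", time_min)
                    else as.character(frame_id)),
    class = "thermal_frame")
}

#' Construct a region label mask
#'
#' Pairs an integer label matrix with a map from plantar region names to
#' positive label values; 0 marks background. Region names are conventionally
#' drawn from hallux, MTP, midfoot, arch, heel, but any unique names are
#' accepted (masks are produced by manual segmentation upstream, never
#' computed here).
#'
#' @param labels Integer matrix, same shape as the frames it will be applied
#'   to; 0 = background.
#' @param label_map Named list or vector mapping region name to its positive
#'   integer label, e.g. `c(hallux = 1, MTP = 2)`.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(labels, label_map) {
  labels <- as.matrix(labels)
  if (!is.numeric(labels) || length(labels) == 0L)
    stop("`labels` must be a non-empty integer matrix", call. = FALSE)
  if (any(labels != round(labels)) || any(labels < 0))
    stop("`labels` must contain non-negative integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  label_map <- unlist(label_map)
  if (is.null(names(label_map)) || any(!nzchar(names(label_map))))
    stop("`label_map` must be named (region name -> label value)",
         call. = FALSE)
  if (anyDuplicated(names(label_map)))
    stop("region names in `label_map` must be unique", call. = FALSE)
  if (anyDuplicated(label_map))
    stop("label values in `label_map` must be unique", call. = FALSE)
  if (any(label_map <= 0))
    stop("label values must be positive (0 is reserved for background)",
         call. = FALSE)
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(present, as.integer(label_map))
  if (length(unknown))
    stop("mask contains labels absent from `label_map`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(labels = labels,
                 label_map = setNames(as.integer(label_map),
                                      names(label_map))),
            class = "region_mask")
}

#' Per-region mean temperature and pixel area
#'
#' Computes, for every labelled region present in the mask, the arithmetic
#' mean of that region's pixel temperatures and its area in pixels. Physical
#' pixel size is irrelevant downstream: it cancels in the area-weighted
#' whole-foot average, so areas are plain pixel counts.
#'
#' @param frame A [thermal_frame].
#' @param mask A [region_mask] with the same matrix shape.
#' @return A data frame with columns `region`, `time_min`, `mean_C`, `area`,
#'   one row per region that has at least one pixel. Regions named in the
#'   label map but absent from the mask are dropped with a warning.
#' @examples
#' fr <- thermal_frame(matrix(c(30, 32, 22, 22), 2, 2), time_min = 0)
#' mk <- region_mask(matrix(c(1L, 1L, 0L, 0L), 2, 2), c(hallux = 1))
#' extract_region_stats(fr, mk)  # mean 31, area 2
#' @export
extract_region_stats <- function(frame, mask) {
  stopifnot(inherits(frame, "thermal_frame"), inherits(mask, "region_mask"))
  if (!identical(dim(frame$pixels), dim(mask$labels)))
    stop(sprintf("frame is %dx%d but mask is %dx%d",
                 nrow(frame$pixels), ncol(frame$pixels),
                 nrow(mask$labels), ncol(mask$labels)), call. = FALSE)
  lv <- as.vector(mask$labels)
  px <- as.vector(frame$pixels)
  if (!any(lv > 0L))
    stop("mask contains no labelled pixels", call. = FALSE)
  rows <- lapply(names(mask$label_map), function(rg) {
    sel <- lv == mask$label_map[[rg]]
    n <- sum(sel)
    if (n == 0L) return(NULL)
    data.frame(region = rg, time_min = frame$time_min,
               mean_C = sum(px[sel]) / n, area = n,
               stringsAsFactors = FALSE)
  })
  empty <- names(mask$label_map)[vapply(rows, is.null, logical(1))]
  if (length(empty))
    warning("regions with zero pixels dropped: ",
            paste(empty, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Area-weighted whole-foot temperature
#'
#' Combines regional means at a single time point into the whole-foot
#' temperature, weighting each region by its surface area:
#' \deqn{T_{foot} = \frac{\sum_r A_r T_r}{\sum_r A_r}}
#' The result always lies between the minimum and maximum regional mean.
#'
#' @param stats Data frame with columns `mean_C` and `area` (as produced by
#'   [extract_region_stats]) for one time point.
#' @return The weighted mean temperature in degrees C.
#' @examples
#' whole_foot_temperature(data.frame(mean_C = c(30, 33), area = c(2, 1)))
#' # (2*30 + 1*33)/3 = 31
#' @export
whole_foot_temperature <- function(stats) {
  if (!is.data.frame(stats) || !all(c("mean_C", "area") %in% names(stats)))
    stop("`stats` must have columns mean_C and area", call. = FALSE)
  if (nrow(stats) == 0L || sum(stats$area) <= 0)
    stop("total region area must be positive", call. = FALSE)
  if (any(stats$area < 1))
    stop("every region must cover at least one pixel", call. = FALSE)
  sum(stats$area * stats$mean_C) / sum(stats$area)
}

#' Assemble a whole-foot temperature series
#'
#' Collapses regional stats across time points into one whole-foot
#' temperature per time point via [whole_foot_temperature], recomputing the
#' area weights at every frame (regional areas may change between photos).
#'
#' @param stats Data frame of regional stats across time points, columns
#'   `region`, `time_min`, `mean_C`, `area`.
#' @param missing_policy What to do when a region present at baseline is
#'   missing at a later time: `"renormalize"` (default) drops it there and
#'   reweights the remaining regions, with a warning; `"strict"` errors.
#' @return An object of class `whole_foot_series`: a list with `points`
#'   (data frame `time_min`, `temp_C`, `delta_C`), `baseline_C` and `label`.
#'   `delta_C` is `temp_C` minus the baseline temperature; its first element
#'   is exactly 0.
#' @export
build_series <- function(stats, missing_policy = c("renormalize", "strict")) {
  missing_policy <- match.arg(missing_policy)
  need <- c("region", "time_min", "mean_C", "area")
  if (!is.data.frame(stats) || !all(need %in% names(stats)))
    stop("`stats` must have columns region, time_min, mean_C, area",
         call. = FALSE)
  times <- unique(stats$time_min)
  if (is.unsorted(times)) {
    warning("time points were unordered; sorting", call. = FALSE)
    times <- sort(times)
  }
  per_time <- split(stats, stats$time_min)
  for (chunk in per_time)
    if (anyDuplicated(chunk$region))
      stop("duplicate region entries at time ", chunk$time_min[1],
           call. = FALSE)
  all_regions <- unique(stats$region)
  temp <- vapply(as.character(times), function(tm) {
    chunk <- per_time[[tm]]
    missing <- setdiff(all_regions, chunk$region)
    if (length(missing)) {
      if (missing_policy == "strict")
        stop("region(s) missing at time ", tm, ": ",
             paste(missing, collapse = ", "), call. = FALSE)
      warning("renormalizing over available regions at time ", tm,
              " (missing: ", paste(missing, collapse = ", "), ")",
              call. = FALSE)
    }
    whole_foot_temperature(chunk)
  }, numeric(1))
  if (times[1] != 0)
    stop("series must start at time 0 (baseline frame)", call. = FALSE)
  structure(list(points = data.frame(time_min = times, temp_C = unname(temp),
                                     delta_C = unname(temp) - temp[[1]]),
                 baseline_C = unname(temp[[1]]), label = "whole_foot"),
            class = "whole_foot_series")
}

#' @export
print.whole_foot_series <- function(x, ...) {
  cat(sprintf("Whole-foot temperature series: %d time points, baseline %.2f degC, rise %.2f degC\n",
              nrow(x$points), x$baseline_C,
              x$points$delta_C[nrow(x$points)]))
  print(x$points, ...)
  invisible(x)
}

# --- file IO -----------------------------------------------------------------

#' Read a thermal frame from CSV or single-band float TIFF
#'
#' CSV frames are plain numeric matrices (one row per pixel row, comma
#' separated, no header). TIFF frames must be single-band; values are taken
#' as degrees C as stored (32-bit float TIFFs written with
#' `tiff::writeTIFF(..., reduce = FALSE)` round-trip exactly).
#'
#' @param path File path ending in `.csv` or `.tif`/`.tiff`.
#' @param time_min Minutes since walk start for this frame.
#' @param frame_id Optional label; defaults to the file name.
#' @return A [thermal_frame].
#' @export
read_thermal_frame <- function(path, time_min, frame_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pixels <- switch(ext,
    csv = as.matrix(read.csv(path, header = FALSE)),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package 'tiff' is required to read TIFF frames", call. = FALSE)
      img <- tiff::readTIFF(path, as.is = FALSE)
      if (length(dim(img)) == 3L)
        stop("multi-band TIFF not supported: ", path, call. = FALSE)
      img
    },
    stop("unsupported frame format '", ext, "': ", path, call. = FALSE))
  dimnames(pixels) <- NULL
  thermal_frame(pixels, time_min,
                frame_id = if (is.null(frame_id)) basename(path) else frame_id)
}

#' Read a region mask from CSV or 8-bit PNG plus a JSON label map
#'
#' @param path Integer-matrix CSV (no header) or greyscale 8-bit PNG whose
#'   pixel values are the labels.
#' @param label_map Named vector/list, or path to a JSON file such as
#'   `{"hallux": 1, "MTP": 2}`.
#' @return A [region_mask].
#' @export
read_region_mask <- function(path, label_map) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(label_map) && length(label_map) == 1L &&
      file.exists(label_map))
    label_map <- unlist(jsonlite::read_json(label_map))
  ext <- tolower(tools::file_ext(path))
  labels <- switch(ext,
    csv = as.matrix(read.csv(path, header = FALSE)),
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("package 'png' is required to read PNG masks", call. = FALSE)
      img <- png::readPNG(path)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      round(img * 255)  # readPNG rescales 8-bit values to [0, 1]
    },
    stop("unsupported mask format '", ext, "': ", path, call. = FALSE))
  dimnames(labels) <- NULL
  region_mask(labels, label_map)
}

#' Write regional stats / whole-foot series CSV outputs
#'
#' `write_region_stats` writes columns `time_min,region,mean_C,area_px`;
#' `write_whole_foot_series` writes `time_min,temp_C,delta_C`.
#'
#' @param stats Regional stats data frame.
#' @param series A `whole_foot_series`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_region_stats <- function(stats, path) {
  out <- data.frame(time_min = stats$time_min, region = stats$region,
                    mean_C = stats$mean_C, area_px = stats$area)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_region_stats
#' @export
write_whole_foot_series <- function(series, path) {
  stopifnot(inherits(series, "whole_foot_series"))
  write.csv(series$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
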