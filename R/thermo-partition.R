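# First-law thermodynamic partition of the walking temperature rise.

#' Thermodynamic input parameters
#'
#' Bundles the quantities entering the mechanical-heating estimate: the net
#' work done by the foot per stride, the foot mass, the composite specific
#' heat of foot tissue, and the stride count over the walk. Negative net
#' work means the foot dissipates energy, which under the first-law
#' assumption (no net energy storage over a stride) appears as heat.
#'
#' @param W_stride Net foot work per stride in kJ (signed; negative = net
#'   dissipation, hence heating).
#' @param m_foot Foot mass in kg.
#' @param c_foot Specific heat in kJ kg^-1 K^-1.
#' @param total_strides Stride count over the walk.
#' @param duration_min Walk duration in minutes.
#' @param W_bounds Optional `c(low, high)` bounds on `W_stride` (kJ).
#' @param c_bounds Optional `c(low, high)` bounds on `c_foot`.
#' @return Object of class `thermo_params`.
#' @examples
#' # literature-derived cohort means for a 30-min walk at 1.25 m/s
#' thermo_params(W_stride = -0.0034, m_foot = 1.17, c_foot = 1.96,
#'               total_strides = 1674, duration_min = 30,
#'               W_bounds = c(-0.0071, 0.00023), c_bounds = c(1.31, 3.62))
#' @export
thermo_params <- function(W_stride, m_foot, c_foot, total_strides,
                          duration_min, W_bounds = NULL, c_bounds = NULL) {
  if (!is.finite(W_stride)) stop("W_stride must be finite", call. = FALSE)
  if (!isTRUE(m_foot > 0)) stop("m_foot must be > 0", call. = FALSE)
  if (!isTRUE(c_foot > 0)) stop("c_foot must be > 0", call. = FALSE)
  if (!isTRUE(total_strides >= 0))
    stop("total_strides must be >= 0", call. = FALSE)
  if (!isTRUE(duration_min > 0))
    stop("duration_min must be > 0", call. = FALSE)
  chk_bounds <- function(b, nm) {
    if (is.null(b)) return(NULL)
    if (length(b) != 2L || !all(is.finite(b)) || b[1] > b[2])
      stop(nm, " must be c(low, high) with low <= high", call. = FALSE)
    as.numeric(b)
  }
  structure(list(W_stride = as.numeric(W_stride),
                 m_foot = as.numeric(m_foot), c_foot = as.numeric(c_foot),
                 total_strides = as.numeric(total_strides),
                 duration_min = as.numeric(duration_min),
                 W_bounds = chk_bounds(W_bounds, "W_bounds"),
                 c_bounds = chk_bounds(c_bounds, "c_bounds")),
            class = "thermo_params")
}

#' Foot mass from body mass by standard segment anthropometry
#'
#' The foot segment carries a fixed fraction of body mass (0.0145 by the
#' standard anthropometric tables).
#'
#' @param body_mass_kg Body mass in kg (> 0).
#' @param fraction Foot mass fraction of body mass.
#' @return Foot mass in kg.
#' @examples
#' foot_mass_from_body(80.42)  # ~1.17 kg
#' @export
foot_mass_from_body <- function(body_mass_kg, fraction = 0.0145) {
  if (!isTRUE(body_mass_kg > 0))
    stop("body_mass_kg must be > 0", call. = FALSE)
  if (!isTRUE(fraction >= 0)) stop("fraction must be >= 0", call. = FALSE)
  fraction * body_mass_kg
}

#' Composite specific heat of foot tissue
#'
#' Mass-weighted mixture rule over tissue components: the foot's effective
#' specific heat is \eqn{\sum_i f_i c_i} with mass fractions \eqn{f_i}
#' summing to 1. The result is a convex combination, so it always lies
#' between the smallest and largest component value (bone ~1.31 and blood
#' ~3.62 kJ kg^-1 K^-1 bracket plausible compositions).
#'
#' @param components Data frame with columns `name`, `fraction` (mass
#'   fraction in \[0, 1\]), `c` (kJ kg^-1 K^-1), or a list of such records.
#' @return Composite specific heat in kJ kg^-1 K^-1.
#' @examples
#' composite_specific_heat(data.frame(name = c("bone", "blood"),
#'                                    fraction = c(0.5, 0.5),
#'                                    c = c(1.31, 3.62)))  # 2.465
#' @export
composite_specific_heat <- function(components) {
  if (!is.data.frame(components))
    components <- do.call(rbind, lapply(components, as.data.frame))
  if (!all(c("fraction", "c") %in% names(components)))
    stop("components need `fraction` and `c` columns", call. = FALSE)
  f <- components$fraction
  if (any(f < 0 | f > 1))
    stop("mass fractions must lie in [0, 1]", call. = FALSE)
  if (any(components$c <= 0))
    stop("specific heats must be positive", call. = FALSE)
  s <- sum(f)
  if (abs(s - 1) > 1e-9)
    stop(sprintf("mass fractions sum to %.12g (off by %.3g from 1)",
                 s, s - 1), call. = FALSE)
  sum(f * components$c)
}

#' Temperature change per stride from net foot work
#'
#' Under the first-law assumption the heat generated in one stride equals
#' minus the net work, so
#' \deqn{\Delta T_{stride} = \frac{-W_{stride}}{m_{foot}\, c_{foot}}}
#' Negative net work (dissipation) yields a positive temperature change.
#'
#' @param params A [thermo_params] (or any list with `W_stride`, `m_foot`,
#'   `c_foot`).
#' @return Temperature change per stride in degrees C.
#' @export
stride_delta_T <- function(params) {
  -params$W_stride / (params$m_foot * params$c_foot)
}

#' Stride schedule: cumulative strides over walk time
#'
#' By default cadence is constant, so the cumulative count at time t is
#' `total_strides * t / duration`. A custom non-decreasing count vector may
#' be supplied for non-constant cadence.
#'
#' @param total_strides Total strides over the walk.
#' @param duration_min Walk duration in minutes.
#' @param times Time grid in minutes (must start at 0).
#' @param cumulative_strides Optional explicit counts aligned to `times`;
#'   must start at 0, be non-decreasing, and end at `total_strides`.
#' @return Object of class `stride_schedule` with `times` and
#'   `cumulative_strides`.
#' @export
stride_schedule <- function(total_strides, duration_min,
                            times = seq(0, duration_min, by = 5),
                            cumulative_strides = NULL) {
  if (times[1] != 0) stop("schedule must start at time 0", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (is.null(cumulative_strides)) {
    cumulative_strides <- total_strides * times / duration_min
  } else {
    if (length(cumulative_strides) != length(times))
      stop("cumulative_strides must align with times", call. = FALSE)
    if (cumulative_strides[1] != 0)
      stop("cumulative strides must start at 0", call. = FALSE)
    if (any(diff(cumulative_strides) < 0))
      stop("cumulative strides must be non-decreasing", call. = FALSE)
    last <- cumulative_strides[length(cumulative_strides)]
    if (abs(last - total_strides) > 1e-9)
      stop(sprintf("final count %g != total_strides %g", last,
                   total_strides), call. = FALSE)
  }
  structure(list(times = as.numeric(times),
                 cumulative_strides = as.numeric(cumulative_strides)),
            class = "stride_schedule")
}

#' Cumulative mechanical temperature change
#'
#' Accumulates the per-stride temperature change over the stride schedule:
#' \deqn{\Delta T_{mech}(t) = \Delta T_{stride} \cdot strides(t)}
#' With constant cadence this is a straight line through the origin.
#'
#' @param params A [thermo_params].
#' @param schedule A [stride_schedule]; defaults to constant cadence on the
#'   walk's 5-min grid.
#' @return Object of class `mechanical_curve` with `times` and `dT`
#'   (degrees C, 0 at time 0) and the per-stride change `dT_stride`.
#' @export
mechanical_curve <- function(params,
                             schedule = stride_schedule(params$total_strides,
                                                        params$duration_min)) {
  stopifnot(inherits(params, "thermo_params"),
            inherits(schedule, "stride_schedule"))
  final <- schedule$cumulative_strides[length(schedule$cumulative_strides)]
  if (abs(final - params$total_strides) > 1e-9)
    stop(sprintf("schedule ends at %g strides but params say %g",
                 final, params$total_strides), call. = FALSE)
  dTs <- stride_delta_T(params)
  structure(list(times = schedule$times,
                 dT = dTs * schedule$cumulative_strides,
                 dT_stride = dTs),
            class = "mechanical_curve")
}

#' Bound envelopes on the mechanical curve
#'
#' Recomputes the mechanical curve at the work bounds (holding specific heat
#' at its mean) and at the specific-heat bounds (holding work at its mean).
#' Since heating scales with -W, the *upper* work bound (least negative W)
#' gives the *smallest* heating; the curves are returned so that `lower`
#' is pointwise below `upper` for t > 0.
#'
#' @param params A [thermo_params] carrying `W_bounds` and/or `c_bounds`.
#' @param schedule A [stride_schedule].
#' @return List with elements `work` and `specific_heat` (those whose bounds
#'   are present), each a list of `lower` and `upper` [mechanical_curve]s
#'   bracketing the mean curve.
#' @export
mechanical_envelope <- function(params,
                                schedule = stride_schedule(params$total_strides,
                                                           params$duration_min)) {
  stopifnot(inherits(params, "thermo_params"))
  if (is.null(params$W_bounds) && is.null(params$c_bounds))
    stop("no bounds present: supply W_bounds and/or c_bounds", call. = FALSE)
  with_par <- function(W, cc) {
    p <- params; p$W_stride <- W; p$c_foot <- cc
    mechanical_curve(p, schedule)
  }
  sort_pair <- function(a, b) {
    if (a$dT[length(a$dT)] <= b$dT[length(b$dT)])
      list(lower = a, upper = b) else list(lower = b, upper = a)
  }
  out <- list()
  if (!is.null(params$W_bounds))
    out$work <- sort_pair(with_par(params$W_bounds[1], params$c_foot),
                          with_par(params$W_bounds[2], params$c_foot))
  if (!is.null(params$c_bounds))
    out$specific_heat <- sort_pair(with_par(params$W_stride,
                                            params$c_bounds[1]),
                                   with_par(params$W_stride,
                                            params$c_bounds[2]))
  out
}

#' Partition the observed temperature change
#'
#' The observed whole-foot temperature change is modeled as the sum of a
#' mechanical and a physiological contribution; the physiological part is
#' defined as the pointwise residual
#' \deqn{\Delta T_{phys}(t) = \Delta T_{exp}(t) - \Delta T_{mech}(t)}
#' so the three curves satisfy the conservation identity exactly at every
#' time point. Envelopes on the mechanical curve propagate to the
#' physiological residual by subtraction.
#'
#' @param exp_series A `whole_foot_series` (its `delta_C` column), or a data
#'   frame with `time_min` and `delta_C`.
#' @param mech A [mechanical_curve] on the same time grid, or one to be
#'   linearly interpolated onto it when `interpolate = TRUE`.
#' @param envelope Optional output of [mechanical_envelope] to propagate.
#' @param interpolate Allow linear interpolation of the mechanical curve
#'   onto the experimental time grid (default `FALSE`: grids must match).
#' @return Object of class `decomposition`: data frame `table` with columns
#'   `time_min`, `dT_exp`, `dT_mech`, `dT_phys` and, when an envelope is
#'   given, `phys_low_work`, `phys_high_work`, `phys_low_c`, `phys_high_c`
#'   (physiological residuals at the respective mechanical bound curves).
#' @export
decompose_series <- function(exp_series, mech, envelope = NULL,
                             interpolate = FALSE) {
  if (inherits(exp_series, "whole_foot_series"))
    exp_df <- data.frame(time_min = exp_series$points$time_min,
                         delta_C = exp_series$points$delta_C)
  else exp_df <- exp_series
  if (!all(c("time_min", "delta_C") %in% names(exp_df)))
    stop("experimental series needs time_min and delta_C", call. = FALSE)
  if (exp_df$delta_C[1] != 0 || exp_df$time_min[1] != 0)
    stop("experimental delta series must start at (0, 0)", call. = FALSE)
  stopifnot(inherits(mech, "mechanical_curve"))

  mech_at <- function(curve) {
    if (identical(as.numeric(curve$times), as.numeric(exp_df$time_min)))
      return(curve$dT)
    if (!interpolate)
      stop("time grids differ; set interpolate = TRUE to interpolate",
           call. = FALSE)
    approx(curve$times, curve$dT, xout = exp_df$time_min, rule = 2)$y
  }
  dT_mech <- mech_at(mech)
  tab <- data.frame(time_min = exp_df$time_min, dT_exp = exp_df$delta_C,
                    dT_mech = dT_mech,
                    dT_phys = exp_df$delta_C - dT_mech)
  if (!is.null(envelope)) {
    if (!is.null(envelope$work)) {
      # the *upper* mechanical curve leaves the *smaller* physiological residual
      tab$phys_low_work <- exp_df$delta_C - mech_at(envelope$work$upper)
      tab$phys_high_work <- exp_df$delta_C - mech_at(envelope$work$lower)
    }
    if (!is.null(envelope$specific_heat)) {
      tab$phys_low_c <- exp_df$delta_C - mech_at(envelope$specific_heat$upper)
      tab$phys_high_c <- exp_df$delta_C - mech_at(envelope$specific_heat$lower)
    }
  }
  structure(list(table = tab), class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  n <- nrow(x$table)
  cat(sprintf("Temperature partition over %d time points (final: exp %.2f = mech %.2f + phys %.2f degC)\n",
              n, x$table$dT_exp[n], x$table$dT_mech[n], x$table$dT_phys[n]))
  print(x$table, ...)
  invisible(x)
}

#' Write a decomposition table to CSV
#'
#' @param decomp A `decomposition`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_decomposition <- function(decomp, path) {
  stopifnot(inherits(decomp, "decomposition"))
  write.csv(decomp$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extrapolated time to the first-degree-burn threshold
#'
#' Skin held above 43.3 degrees C for long enough may develop first-degree
#' burns. This extrapolates when a foot heated only by the mechanical term
#' would cross that threshold.
#'
#' Two modes reflect two readings of "mechanical heating added to the
#' experimental temperature":
#' \describe{
#'   \item{`mechanical_only`}{temperature rises from `baseline_C` at the
#'     constant mechanical rate: crossing at
#'     `(threshold - baseline) / rate`.}
#'   \item{`experimental_then_mechanical`}{temperature follows the supplied
#'     experimental curve to its last time point, then continues at the
#'     mechanical rate.}
#' }
#'
#' @param baseline_C Starting whole-foot temperature in degrees C (the
#'   cohort baseline is a required input; it is not a universal constant).
#' @param mech_rate_per_min Mechanical heating rate in degC/min (e.g.
#'   `mechanical_curve(...)$dT` at the walk end divided by its duration).
#' @param threshold_C Burn threshold, default 43.3 degC.
#' @param mode See Details.
#' @param exp_curve Data frame `time_min`, `temp_C` (absolute temperature),
#'   required for `experimental_then_mechanical`.
#' @return Object of class `burn_estimate`: `threshold_C`, `baseline_C`,
#'   `mode`, and `time_min` (minutes, 0 if already at threshold, `Inf` =
#'   never when the rate is non-positive).
#' @examples
#' burn_time(30, 2.4819 / 30)  # ~160.8 min
#' @export
burn_time <- function(baseline_C, mech_rate_per_min, threshold_C = 43.3,
                      mode = c("mechanical_only",
                               "experimental_then_mechanical"),
                      exp_curve = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(threshold_C)) stop("threshold must be finite", call. = FALSE)
  t_cross <- function(start_T, start_t, rate) {
    if (start_T >= threshold_C) return(start_t)
    if (rate <= 0) return(Inf)
    start_t + (threshold_C - start_T) / rate
  }
  if (mode == "mechanical_only") {
    tm <- t_cross(baseline_C, 0, mech_rate_per_min)
  } else {
    if (is.null(exp_curve) ||
        !all(c("time_min", "temp_C") %in% names(exp_curve)))
      stop("experimental_then_mechanical mode needs exp_curve with time_min and temp_C",
           call. = FALSE)
    above <- which(exp_curve$temp_C >= threshold_C)
    if (length(above)) {
      tm <- exp_curve$time_min[above[1]]
    } else {
      last <- nrow(exp_curve)
      tm <- t_cross(exp_curve$temp_C[last], exp_curve$time_min[last],
                    mech_rate_per_min)
    }
  }
  structure(list(threshold_C = threshold_C, baseline_C = baseline_C,
                 mode = mode, time_min = tm),
            class = "burn_estimate")
}

#' @export
print.burn_estimate <- function(x, ...) {
  when <- if (is.infinite(x$time_min)) "never"
          else sprintf("%.1f min", x$time_min)
  cat(sprintf("Time to exceed %.1f degC from %.1f degC (%s): %s\n",
              x$threshold_C, x$baseline_C, x$mode, when))
  invisible(x)
}

#' Walking distance covered in a given time
#'
#' @param time_min Walking time in minutes (may be `Inf`).
#' @param speed_m_s Walking speed in m/s (default 1.25, a typical
#'   self-selected pace).
#' @return Distance in km.
#' @examples
#' walk_distance_km(160)   # 12 km
#' walk_distance_km(77.5)  # ~5.8 km
#' @export
walk_distance_km <- function(time_min, speed_m_s = 1.25) {
  if (!isTRUE(all(speed_m_s > 0))) stop("speed must be > 0", call. = FALSE)
  speed_m_s * time_min * 60 / 1000
}
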