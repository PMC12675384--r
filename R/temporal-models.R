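# Linear and generalized-logistic temporal models for temperature series.

#' Construct a temperature series
#'
#' @param times Minutes since walk start, strictly increasing.
#' @param temps Temperatures in degrees C, same length.
#' @param label Region name or `"whole_foot"`.
#' @return An object of class `temperature_series`.
#' @export
temperature_series <- function(times, temps, label = "whole_foot") {
  times <- as.numeric(times); temps <- as.numeric(temps)
  if (length(times) != length(temps))
    stop("`times` and `temps` must have equal length", call. = FALSE)
  if (length(times) < 1L || !all(is.finite(times)) || !all(is.finite(temps)))
    stop("times and temps must be finite and non-empty", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  structure(list(times = times, temps = temps, label = as.character(label)),
            class = "temperature_series")
}

#' Residual fit criteria
#'
#' The two criteria used to compare the temporal models: the mean squared
#' error and the residual standard deviation, both computed on residual
#' degrees of freedom:
#' \deqn{SS_{res} = \sum_i (obs_i - pred_i)^2, \quad
#'   MSE = SS_{res} / (n - p), \quad S_{res} = \sqrt{MSE}}
#' so that \eqn{MSE = S_{res}^2} holds exactly by construction.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param p Number of fitted parameters (2 for the line, 6 for the
#'   generalized logistic).
#' @return List with `ss_res`, `mse`, `s_res`, `n`. When `n <= p` the
#'   denominator is undefined: `mse` and `s_res` are `NA` with a warning.
#' @examples
#' fit_criteria(rep(0.5, 7), rep(0, 7), p = 2)  # mse 0.35, s_res 0.5916
#' @export
fit_criteria <- function(observed, predicted, p) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  n <- length(observed)
  ss_res <- sum((observed - predicted)^2)
  if (n <= p) {
    warning(sprintf("n = %d <= p = %d: MSE and S_res undefined", n, p),
            call. = FALSE)
    return(list(ss_res = ss_res, mse = NA_real_, s_res = NA_real_, n = n))
  }
  mse <- ss_res / (n - p)
  list(ss_res = ss_res, mse = mse, s_res = sqrt(mse), n = n)
}

#' Fit the linear temporal model T = m t + b
#'
#' Ordinary least squares of temperature on time. Under the mechanical-only
#' hypothesis (constant heat per stride, constant cadence) the temperature
#' rise is linear, so this model is the null shape against which the
#' generalized logistic is compared.
#'
#' @param series A [temperature_series] with at least 2 points.
#' @return Object of class `linear_fit`: `m` (slope, degC/min), `b`
#'   (intercept, degC), plus `ss_res`, `mse`, `s_res`, `n`.
#' @export
fit_linear <- function(series) {
  stopifnot(inherits(series, "temperature_series"))
  if (length(series$times) < 2L)
    stop("linear fit needs at least 2 points", call. = FALSE)
  if (length(unique(series$times)) < 2L)
    stop("degenerate design: all time values identical", call. = FALSE)
  fit <- lm(temps ~ times, data = list(times = series$times,
                                       temps = series$temps))
  pred <- as.numeric(fitted(fit))
  crit <- suppressWarnings(fit_criteria(series$temps, pred, p = 2))
  structure(list(m = unname(coef(fit)[["times"]]),
                 b = unname(coef(fit)[["(Intercept)"]]),
                 ss_res = crit$ss_res, mse = crit$mse, s_res = crit$s_res,
                 n = crit$n, label = series$label),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit [%s]: T = %.4g*t + %.4g (n=%d, MSE=%.4g, S_res=%.4g)\n",
              x$label, x$m, x$b, x$n, x$mse, x$s_res))
  invisible(x)
}

#' Evaluate the generalized logistic (Richards) curve
#'
#' \deqn{T(t) = A + \frac{K - A}{(C + Q e^{-B t})^{1/\nu}}}
#' `A` and `K` shape the lower and upper plateaus (degC), `B` is the rate
#' (1/min), and `C`, `Q`, `nu` are dimensionless shape parameters. With
#' `C = 1, Q = 0` the curve collapses to the constant `K`.
#'
#' @param params Named list/vector with `A`, `K`, `C`, `Q`, `B`, `nu`.
#' @param t Time(s) in minutes.
#' @return Temperature(s) in degrees C.
#' @examples
#' hallux <- c(A = 27.28, K = 32.80, C = 0.994, Q = 0.92, B = 0.19,
#'             nu = 0.078)
#' evaluate_logistic(hallux, 0)    # ~27.28
#' evaluate_logistic(hallux, 1e6)  # plateau A + (K-A)/C^(1/nu) ~ 33.24
#' @export
evaluate_logistic <- function(params, t) {
  p <- as.list(params)
  base <- p$C + p$Q * exp(-p$B * t)
  if (any(is.nan(base) | base <= 0))
    stop("C + Q*exp(-B*t) must be positive over the requested times",
         call. = FALSE)
  p$A + (p$K - p$A) * base^(-1 / p$nu)
}

# unchecked evaluator for optimizer internals: wandering parameters may
# produce NaN/Inf, which the residual guard absorbs
.eval_logistic_raw <- function(p, t)
  p$A + (p$K - p$A) * (p$C + p$Q * exp(-p$B * t))^(-1 / p$nu)

# Unconstrained <-> box-constrained parameter transforms: C, Q, B, nu are
# optimized on the log scale so positivity never has to be policed by the
# optimizer itself.
.logistic_pack <- function(p)
  c(p$A, p$K, log(p$C), log(max(p$Q, 1e-12)), log(p$B), log(p$nu))
.logistic_unpack <- function(theta)
  list(A = theta[1], K = theta[2], C = exp(theta[3]), Q = exp(theta[4]),
       B = exp(theta[5]), nu = exp(theta[6]))

#' Fit the generalized logistic temporal model
#'
#' Minimizes the residual sum of squares with the Levenberg-Marquardt damped
#' least-squares algorithm. The positivity constraints (`B, nu, C > 0`,
#' `Q > 0`) are enforced by optimizing those parameters on the log scale.
#'
#' The six-parameter form is structurally non-identifiable (a joint rescaling
#' of `C` and `Q` can be absorbed into `K - A`), so different coefficient
#' sets can describe the same curve; judge fits by their predictions, not by
#' coefficient equality.
#'
#' @param series A [temperature_series].
#' @param init Optional named initial coefficients (`A,K,C,Q,B,nu`). Default:
#'   `A = min(T)`, `K = max(T)`, `C = 1`, `Q = 1`, `B = 0.1`, `nu = 1`.
#' @param multi_start If `TRUE`, additionally start from a small grid over
#'   `B` in \{0.05, 0.1, 0.2, 0.5\} and `nu` in \{0.1, 1, 5\} and keep the
#'   best (never worse than the single default start).
#' @param max_iter Maximum LM iterations per start.
#' @return Object of class `logistic_fit`: coefficients `A,K,C,Q,B,nu`,
#'   criteria `ss_res`, `mse`, `s_res`, `n` (with `p = 6`), plus `converged`
#'   and `n_iter`.
#' @export
fit_logistic <- function(series, init = NULL, multi_start = FALSE,
                         max_iter = 500L) {
  stopifnot(inherits(series, "temperature_series"))
  tt <- series$times; yy <- series$temps
  if (length(tt) < 2L)
    stop("logistic fit needs at least 2 points", call. = FALSE)
  if (length(tt) <= 6L)
    warning(sprintf("fitting 6 parameters to %d points: fit is under- or just-determined",
                    length(tt)), call. = FALSE)
  default_init <- list(A = min(yy), K = max(yy), C = 1, Q = 1, B = 0.1,
                       nu = 1)
  if (!is.null(init)) {
    init <- as.list(init)
    if (!all(c("A", "K", "C", "Q", "B", "nu") %in% names(init)))
      stop("`init` must name A, K, C, Q, B, nu", call. = FALSE)
    if (init$C <= 0 || init$Q < 0 || init$B <= 0 || init$nu <= 0)
      stop("invalid init: need C > 0, Q >= 0, B > 0, nu > 0", call. = FALSE)
    default_init <- init
  }
  # flat data makes min(T) == max(T); nudge K so K - A is not pinned at 0
  if (default_init$K == default_init$A)
    default_init$K <- default_init$A + 1e-3

  starts <- list(default_init)
  if (multi_start) {
    for (B0 in c(0.05, 0.1, 0.2, 0.5))
      for (nu0 in c(0.1, 1, 5)) {
        s <- default_init; s$B <- B0; s$nu <- nu0
        starts <- c(starts, list(s))
      }
  }

  run_start <- function(s) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = .logistic_pack(s),
        fn = function(theta) {
          r <- yy - .eval_logistic_raw(.logistic_unpack(theta), tt)
          # keep LM stable if the power term overflows mid-iteration
          r[!is.finite(r)] <- 1e6
          r
        },
        control = minpack.lm::nls.lm.control(
          maxiter = max_iter, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    list(par = .logistic_unpack(res$par), ss = res$deviance,
         converged = res$info %in% 1:4, n_iter = res$niter)
  }
  fits <- Filter(Negate(is.null), lapply(starts, run_start))
  if (!length(fits))
    stop("logistic fit failed from every start", call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ss"))]]

  pred <- evaluate_logistic(best$par, tt)
  crit <- suppressWarnings(fit_criteria(yy, pred, p = 6))
  structure(c(best$par,
              list(ss_res = crit$ss_res, mse = crit$mse, s_res = crit$s_res,
                   n = crit$n, converged = best$converged,
                   n_iter = best$n_iter, label = series$label)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Generalized logistic fit [%s]: A=%.4g K=%.4g C=%.4g Q=%.4g B=%.4g nu=%.4g\n",
              x$label, x$A, x$K, x$C, x$Q, x$B, x$nu))
  cat(sprintf("  n=%d, SS_res=%.4g, MSE=%.4g, S_res=%.4g, converged=%s (%d iter)\n",
              x$n, x$ss_res, x$mse, x$s_res, x$converged, x$n_iter))
  invisible(x)
}

#' Predict from fitted temporal models
#'
#' @param object A `linear_fit` or `logistic_fit`.
#' @param times Times (minutes) at which to predict.
#' @param ... Unused.
#' @return Predicted temperatures in degrees C.
#' @export
predict.linear_fit <- function(object, times, ...) object$m * times + object$b

#' @rdname predict.linear_fit
#' @export
predict.logistic_fit <- function(object, times, ...)
  evaluate_logistic(object[c("A", "K", "C", "Q", "B", "nu")], times)

#' Compare linear and generalized-logistic fits by MSE
#'
#' The model with the strictly lower MSE wins; exactly equal MSE is a tie.
#' If either model's criteria are undefined (too few residual degrees of
#' freedom) the comparison is inconclusive.
#'
#' @param linear A `linear_fit`.
#' @param logistic A `logistic_fit` on the same series.
#' @return Object of class `fit_comparison`: `winner` in
#'   \{"linear", "logistic", "tie", "inconclusive"\} and both models'
#'   `mse` and `s_res`.
#' @export
compare_models <- function(linear, logistic) {
  stopifnot(inherits(linear, "linear_fit"), inherits(logistic, "logistic_fit"))
  winner <-
    if (is.na(linear$mse) || is.na(logistic$mse)) "inconclusive"
    else if (logistic$mse < linear$mse) "logistic"
    else if (linear$mse < logistic$mse) "linear"
    else "tie"
  structure(list(winner = winner,
                 linear = list(mse = linear$mse, s_res = linear$s_res),
                 logistic = list(mse = logistic$mse, s_res = logistic$s_res),
                 label = linear$label),
            class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat(sprintf("Model comparison [%s]: winner = %s\n", x$label, x$winner))
  cat(sprintf("  linear:   MSE=%.4g S_res=%.4g\n", x$linear$mse, x$linear$s_res))
  cat(sprintf("  logistic: MSE=%.4g S_res=%.4g\n", x$logistic$mse, x$logistic$s_res))
  invisible(x)
}

#' Read a temperature series from CSV
#'
#' Expects columns `time_min`, `temp_C` and optionally `label`.
#'
#' @param path CSV path.
#' @return A [temperature_series].
#' @export
read_temperature_series <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_min", "temp_C") %in% names(df)))
    stop("series CSV must have columns time_min and temp_C: ", path,
         call. = FALSE)
  temperature_series(df$time_min, df$temp_C,
                     label = if ("label" %in% names(df))
                       as.character(df$label[1]) else "whole_foot")
}

#' Serialize fits to JSON
#'
#' Writes coefficients under their conventional names (`m`, `b` for the
#' line; `A`, `K`, `C`, `Q`, `B`, `nu` for the logistic) together with
#' `ss_res`, `mse`, `s_res`, `n` (and `converged` where applicable).
#'
#' @param fit A `linear_fit` or `logistic_fit` (or a named list of them).
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  strip <- function(f) unclass(f)[setdiff(names(unclass(f)), "label")]
  payload <- if (inherits(fit, c("linear_fit", "logistic_fit"))) strip(fit)
             else lapply(fit, strip)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
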