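hallux_coefs <- c(A = 27.28, K = 32.80, C = 0.994, Q = 0.92, B = 0.19,
                  nu = 0.078)

test_that("fit criteria follow the residual-degrees-of-freedom definition", {
  perfect <- fit_criteria(rep(30, 7), rep(30, 7), p = 2)
  expect_equal(perfect[c("ss_res", "mse", "s_res")],
               list(ss_res = 0, mse = 0, s_res = 0))
  # 7 residuals of magnitude 0.5, p = 2
  cr <- fit_criteria(rep(0.5, 7), rep(0, 7), p = 2)
  expect_equal(cr$ss_res, 1.75)
  expect_equal(cr$mse, 0.35)
  expect_equal(cr$s_res, sqrt(0.35))
  # mse = s_res^2 exactly, by construction, on random residuals
  set.seed(3)
  for (p in c(2, 6)) {
    cr <- fit_criteria(rnorm(10), rnorm(10), p = p)
    expect_equal(cr$mse, cr$s_res^2, tolerance = 1e-15)
  }
  expect_warning(und <- fit_criteria(1:3, 1:3, p = 6), "undefined")
  expect_true(is.na(und$mse) && is.na(und$s_res))
})

test_that("linear fit matches hand-solved and closed-form normal equations", {
  # exact line
  t7 <- seq(0, 30, by = 5)
  lin <- fit_linear(temperature_series(t7, 0.1 * t7 + 30))
  expect_equal(lin$m, 0.1)
  expect_equal(lin$b, 30)
  expect_equal(lin$ss_res, 0, tolerance = 1e-12)
  # hand-solved 3-point case
  lin3 <- fit_linear(temperature_series(c(0, 10, 20), c(30, 31, 33)))
  expect_equal(lin3$m, 0.15)
  expect_equal(lin3$b, 29 + 5 / 6, tolerance = 1e-12)
  # closed-form oracle on random series
  set.seed(11)
  for (i in 1:20) {
    tt <- sort(sample(0:60, 8))
    yy <- rnorm(8, 30 + 0.05 * tt, 0.3)
    f <- fit_linear(temperature_series(tt, yy))
    m_hat <- sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
    b_hat <- mean(yy) - m_hat * mean(tt)
    expect_equal(f$m, m_hat, tolerance = 1e-10)
    expect_equal(f$b, b_hat, tolerance = 1e-10)
  }
  expect_error(fit_linear(temperature_series(5, 30)), "at least 2")
})

test_that("a line cannot interpolate an inflected curve", {
  t7 <- seq(0, 30, by = 5)
  s <- temperature_series(t7, evaluate_logistic(hallux_coefs, t7))
  expect_gt(fit_linear(s)$ss_res, 0)
})

test_that("generalized logistic evaluation matches its closed form", {
  # Q = 0, C = 1 collapses to the constant K
  expect_equal(evaluate_logistic(c(A = 20, K = 33, C = 1, Q = 0, B = 0.1,
                                   nu = 2), c(0, 10, 1e4)),
               rep(33, 3))
  # region coefficients: value at t = 0 and the t -> Inf plateau
  expect_equal(evaluate_logistic(hallux_coefs, 0),
               27.28 + (32.80 - 27.28) * (0.994 + 0.92)^(-1 / 0.078))
  expect_equal(evaluate_logistic(hallux_coefs, 0), 27.281, tolerance = 1e-3)
  plateau <- 27.28 + (32.80 - 27.28) / 0.994^(1 / 0.078)
  expect_equal(evaluate_logistic(hallux_coefs, 1e6), plateau)
  expect_equal(plateau, 33.24, tolerance = 1e-3)
  # non-positive base is a domain error
  expect_error(evaluate_logistic(c(A = 20, K = 33, C = -1, Q = 0, B = 0.1,
                                   nu = 0.5), 0), "positive")
})

test_that("logistic fitting recovers curves (not coefficients) from noiseless data", {
  t7 <- seq(0, 30, by = 5)
  truths <- default_region_truth()
  grid <- seq(0, 30, by = 0.25)
  for (rg in names(truths)) {
    s <- temperature_series(t7, evaluate_logistic(truths[[rg]], t7),
                            label = rg)
    f <- suppressWarnings(fit_logistic(s, multi_start = TRUE))
    expect_lte(f$ss_res, 1e-6)
    expect_lte(max(abs(predict(f, grid) -
                         evaluate_logistic(truths[[rg]], grid))), 1e-3)
  }
})

test_that("logistic fit handles flat data and respects its constraints", {
  t7 <- seq(0, 30, by = 5)
  f <- suppressWarnings(fit_logistic(temperature_series(t7, rep(30, 7))))
  expect_lte(max(abs(predict(f, t7) - 30)), 1e-6)
  expect_true(f$B > 0 && f$nu > 0 && f$C > 0 && f$Q >= 0)
  expect_error(suppressWarnings(
    fit_logistic(temperature_series(t7, rep(30, 7)),
                 init = list(A = 1, K = 2, C = -1, Q = 1, B = 1, nu = 1))),
    "invalid init")
  w <- capture_warnings(fit_logistic(temperature_series(c(0, 5, 10), 28:30)))
  expect_true(any(grepl("under", w)))
})

test_that("multi-start never ends with a higher ss_res than the default start", {
  set.seed(21)
  t7 <- seq(0, 30, by = 5)
  for (i in 1:5) {
    yy <- evaluate_logistic(default_region_truth()$MTP, t7) + rnorm(7, 0, 0.2)
    s <- temperature_series(t7, yy)
    single <- suppressWarnings(fit_logistic(s))
    multi <- suppressWarnings(fit_logistic(s, multi_start = TRUE))
    expect_lte(multi$ss_res, single$ss_res + 1e-12)
  }
})

test_that("adding a constant shifts both fits and leaves ss_res invariant", {
  t7 <- seq(0, 30, by = 5)
  set.seed(5)
  yy <- evaluate_logistic(hallux_coefs, t7) + rnorm(7, 0, 0.2)
  for (shift in c(-4, 3)) {
    a <- fit_linear(temperature_series(t7, yy))
    b <- fit_linear(temperature_series(t7, yy + shift))
    expect_equal(b$b - a$b, shift, tolerance = 1e-10)
    expect_equal(b$m, a$m, tolerance = 1e-10)
    expect_equal(b$ss_res, a$ss_res, tolerance = 1e-10)
    la <- suppressWarnings(fit_logistic(temperature_series(t7, yy),
                                        multi_start = TRUE))
    lb <- suppressWarnings(fit_logistic(temperature_series(t7, yy + shift),
                                        multi_start = TRUE))
    expect_equal(lb$ss_res, la$ss_res, tolerance = 1e-6)
    expect_equal(predict(lb, t7) - predict(la, t7), rep(shift, 7),
                 tolerance = 1e-3)
  }
})

test_that("model comparison picks the lower MSE, ties, or is inconclusive", {
  mk_lin <- function(mse) structure(list(mse = mse, s_res = sqrt(mse),
                                         label = "x"), class = "linear_fit")
  mk_log <- function(mse) structure(list(mse = mse, s_res = sqrt(mse),
                                         label = "x"), class = "logistic_fit")
  expect_equal(compare_models(mk_lin(0.335), mk_log(0.018))$winner,
               "logistic")
  expect_equal(compare_models(mk_lin(0.01), mk_log(0.02))$winner, "linear")
  expect_equal(compare_models(mk_lin(0.05), mk_log(0.05))$winner, "tie")
  expect_equal(compare_models(mk_lin(NA_real_), mk_log(0.05))$winner,
               "inconclusive")
})

test_that("series CSV reading and fit JSON writing round-trip", {
  d <- withr::local_tempdir()
  sp <- file.path(d, "s.csv")
  write.csv(data.frame(time_min = c(0, 5, 10), temp_C = c(30, 31, 31.5),
                       label = "hallux"), sp, row.names = FALSE)
  s <- read_temperature_series(sp)
  expect_s3_class(s, "temperature_series")
  expect_equal(s$label, "hallux")
  f <- fit_linear(s)
  jp <- file.path(d, "fit.json")
  write_fit_json(f, jp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$m, f$m)
  expect_equal(back$b, f$b)
  expect_true(all(c("ss_res", "mse", "s_res", "n") %in% names(back)))
})
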