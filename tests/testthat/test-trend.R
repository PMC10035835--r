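test_that("max-normalization is exact and scale-invariant", {
  expect_equal(normalize_by_max(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(normalize_by_max(c(5, 5, 5)), c(1, 1, 1))
  x <- c(3, NA, 9, 6)
  expect_equal(normalize_by_max(7 * x), normalize_by_max(x))
  expect_error(normalize_by_max(c(NA_real_, NA_real_)), "all-missing")
  expect_error(normalize_by_max(c(0, 0, 0)), "positive")
})

test_that("a noiseless line is fitted exactly with no error model", {
  t <- 1:38
  tr <- kelp_trend(0.5 + 0.01 * t, t)
  expect_equal(tr$slope_pct, 1.0)
  expect_equal(tr$ar_order, 0L)
  expect_lt(max(abs(residuals(tr))), 1e-12)
})

test_that("the order-0 fit reproduces ordinary least squares exactly", {
  set.seed(14)
  for (i in 1:5) {
    yrs <- 1984:2021
    y <- rnorm(38, 0.5, 0.1)
    tr <- kelp_trend(y, yrs, orders = 0)
    f <- lm(y ~ I(yrs - mean(yrs)))
    expect_lt(max(abs(coef(tr) - coef(f))), 1e-8)
    expect_lt(abs(tr$stderr_pct / 100 - summary(f)$coefficients[2, 2]), 1e-8)
    expect_lt(abs(tr$p_value - summary(f)$coefficients[2, 4]), 1e-8)
  }
})

test_that("AR(1) and AR(2) ML fits agree with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  set.seed(9)
  yrs <- 1984:2021
  y <- as.numeric(0.5 + 0.005 * (yrs - 2000) +
                    arima.sim(list(ar = 0.5), n = 38, sd = 0.04))
  tr <- kelp_trend(y, yrs)
  d <- data.frame(y = y, tc = yrs - mean(yrs), ti = yrs)
  g_re <- nlme::gls(y ~ tc, data = d, correlation = nlme::corAR1(form = ~ti),
                    method = "REML")
  expect_equal(tr$ar_order, 1L)
  expect_lt(abs(unname(tr$aic["AR1"]) - stats::AIC(g_re)), 1e-4)
  expect_lt(abs(tr$ar_coefficients -
                  coef(g_re$modelStruct$corStruct, unconstrained = FALSE)), 1e-4)
  expect_lt(abs(coef(tr)[2] - coef(g_re)[2]), 1e-6)
  expect_lt(abs(tr$stderr_pct / 100 - summary(g_re)$tTable[2, 2]), 1e-5)

  set.seed(11)
  y2 <- as.numeric(0.4 + arima.sim(list(ar = c(0.5, 0.3)), n = 120, sd = 0.05))
  tr2 <- kelp_trend(y2, 1:120, orders = 2)
  d2 <- data.frame(y = y2, tc = 1:120 - mean(1:120), ti = 1:120)
  g2 <- nlme::gls(y ~ tc, data = d2,
                  correlation = nlme::corARMA(p = 2, form = ~ti),
                  method = "REML")
  expect_lt(max(abs(tr2$ar_coefficients -
                      coef(g2$modelStruct$corStruct, unconstrained = FALSE))),
            1e-3)
  expect_lt(abs(tr2$loglik - as.numeric(stats::logLik(g2))), 1e-4)
})

test_that("the gap-aware likelihood handles missing years exactly", {
  skip_if_not_installed("nlme")
  set.seed(9)
  yrs <- 1984:2021
  y <- as.numeric(0.5 + 0.005 * (yrs - 2000) +
                    arima.sim(list(ar = 0.5), n = 38, sd = 0.04))
  keep <- setdiff(seq_along(yrs), c(5, 12, 13, 25))
  tr <- kelp_trend(y[keep], yrs[keep])
  d <- data.frame(y = y[keep], tc = yrs[keep] - mean(yrs[keep]),
                  ti = yrs[keep])
  g_re <- nlme::gls(y ~ tc, data = d, correlation = nlme::corAR1(form = ~ti),
                    method = "REML")
  expect_lt(abs(coef(tr)[2] - coef(g_re)[2]), 1e-6)
  expect_lt(abs(tr$ar_coefficients -
                  coef(g_re$modelStruct$corStruct, unconstrained = FALSE)), 1e-4)
  expect_lt(abs(min(tr$aic) - stats::AIC(g_re)), 1e-4)
  expect_error(kelp_trend(y[1:5], yrs[1:5]), "at least 6")
})

test_that("AIC selects the generating order on long AR(1) series", {
  set.seed(15)
  sel <- vapply(1:60, function(i) {
    y <- as.numeric(arima.sim(list(ar = 0.6), n = 200, sd = 0.1))
    kelp_trend(y, 1:200)$ar_order
  }, integer(1))
  expect_gt(mean(sel == 1L), 0.6)
  sel0 <- vapply(1:60, function(i) {
    kelp_trend(rnorm(38), 1984:2021)$ar_order
  }, integer(1))
  expect_equal(as.integer(names(which.max(table(sel0)))), 0L)
})

test_that("trend methods behave like a standard model object", {
  set.seed(16)
  yrs <- 1990:2021
  y <- 0.8 - 0.004 * (yrs - 1990) + rnorm(32, 0, 0.05)
  tr <- kelp_trend(y, yrs)
  expect_s3_class(tr, "kelp_trend")
  expect_named(coef(tr), c("(Intercept)", "year"))
  expect_equal(length(fitted(tr)), 32)
  expect_equal(fitted(tr) + residuals(tr), y)
  expect_equal(predict(tr, yrs), fitted(tr))
  expect_output(print(tr), "%/yr")
  expect_output(summary(tr), "AIC by candidate order")
})

test_that("heatwave response and recovery follow their definitions", {
  yrs <- 1984:2021
  const <- setNames(rep(200, 38), yrs)
  expect_equal(heatwave_response(const), 100)
  expect_equal(heatwave_recovery(const), 100)
  expect_equal(recent_state(const), 100)
  s <- const
  s[as.character(2014:2016)] <- c(80, 50, 60)
  expect_equal(heatwave_response(s), 25)       # min 50 over baseline 200
  s[as.character(2017:2021)] <- 960
  expect_equal(heatwave_recovery(s), 480)      # recovery above 100% allowed
  # scale invariance
  expect_equal(heatwave_response(3 * s), heatwave_response(s))
  expect_equal(heatwave_recovery(0.1 * s), heatwave_recovery(s))
  # missing years dropped from both means
  s2 <- const
  s2[as.character(c(1990, 2015, 2018))] <- NA
  s2[as.character(2014:2021)] <- c(40, NA, 60, 20, NA, 20, 20, 20)
  base <- mean(s2[as.character(1984:2013)], na.rm = TRUE)
  expect_equal(recent_state(s2), 100 * mean(c(40, 60, 20, 20, 20, 20)) / base)
  # degenerate baselines are flagged
  z <- setNames(c(rep(0, 30), rep(5, 8)), yrs)
  expect_warning(r <- heatwave_response(z), "zero")
  expect_true(is.na(r))
})

test_that("configured disturbance magnitudes round-trip through the metrics", {
  dom <- tiny_domain()
  cfg <- dynamics_config(n_years = 38, start_year = 1984, trend = 0,
                         noise_sd = 0, oscillation_amplitude = 0,
                         heatwave_depth = 0.2, recovery_level = 0.8,
                         cloud_cover = 0, clouded_quarter_prob = 0,
                         acquisitions_per_quarter = 1, seed = 3)
  cfg$baseline_area <- 5e4
  ann <- setNames(generate_scene_series(cfg, dom)$truth_annual$area_m2,
                  1984:2021)
  expect_equal(heatwave_response(ann), 20)
  expect_equal(heatwave_recovery(ann), 80)
})

test_that("latitude correlations use log(metric + 1) and flag degeneracy", {
  lat <- seq(30, 42, length.out = 10)
  metric <- exp(0.3 * lat) - 1          # exactly log-linear in latitude
  r <- latitude_correlation(metric, lat)
  expect_equal(r$r, 1)
  expect_lt(r$p_value, 1e-10)
  expect_warning(rc <- latitude_correlation(rep(50, 10), lat), "zero variance")
  expect_true(is.na(rc$r))
  expect_error(latitude_correlation(c(1, 2), c(30, 31)), "at least 3")
  expect_error(latitude_correlation(c(-1, 2, 3), c(30, 31, 32)),
               "non-negative")
})

test_that("latitude correlation p-values agree with a permutation oracle", {
  set.seed(19)
  lat <- runif(15, 28, 44)
  metric <- pmax(0, 50 + 8 * (lat - 36) + rnorm(15, 0, 30))
  r <- latitude_correlation(metric, lat)
  perm <- vapply(1:1000, function(i) {
    abs(cor(log(metric + 1), sample(lat)))
  }, numeric(1))
  p_perm <- mean(perm >= abs(r$r))
  expect_lt(abs(r$p_value - p_perm), 0.02)
})
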