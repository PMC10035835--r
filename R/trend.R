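# Long-term trend estimation and marine-heatwave response/recovery metrics.
#
# Trends are fitted to max-normalized annual series by generalized least
# squares with stationary AR(p) errors (p in {0, 1, 2}), each order fitted
# by exact Gaussian maximum likelihood and the winner chosen by AIC. The
# correlation between observations h years apart is the stationary AR
# autocorrelation at lag h, so series with missing years are handled
# exactly (gap-aware likelihood) rather than by imputation.

#' Normalize an annual series by its maximum
#'
#' Divides every value by the series maximum so the peak year maps to 1 and
#' a fitted slope reads as fraction-of-maximum per year. Scale-invariant.
#'
#' @param x numeric series (may contain `NA`).
#' @return Normalized series.
#' @export
normalize_by_max <- function(x) {
  if (all(is.na(x))) stop("all-missing series cannot be normalized")
  m <- max(x, na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("series maximum must be positive to normalize")
  x / m
}

# Durbin-Levinson map from partial autocorrelations to AR coefficients.
pacf_to_ar <- function(pac) {
  p <- length(pac)
  if (p == 0L) return(numeric(0))
  phi <- pac[1]
  if (p >= 2L) for (k in 2:p) {
    phi <- c(phi - pac[k] * rev(phi), pac[k])
  }
  phi
}

# Profile log-likelihood machinery: given AR coefficients and observation
# times, build the stationary correlation matrix, whiten, and profile out
# the regression coefficients and the innovation scale.
ar_profile_fit <- function(phi, y, x, reml = FALSE) {
  n <- length(y)
  lags <- abs(outer(x, x, "-"))
  maxlag <- max(lags)
  rho <- ar_autocorr(phi, maxlag)
  R <- matrix(rho[lags + 1L], n, n)
  U <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(U)) return(NULL)
  X <- cbind(1, x - mean(x))
  yw <- backsolve(U, y, transpose = TRUE)
  Xw <- backsolve(U, X, transpose = TRUE)
  qr_ <- qr(Xw)
  beta <- qr.coef(qr_, yw)
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  logdet <- 2 * sum(log(diag(U)))
  XtX_inv <- chol2inv(qr.R(qr_))
  if (reml) {
    # restricted likelihood: profile over beta and the residual variance
    sigma2 <- rss / (n - 2L)
    loglik <- -0.5 * ((n - 2L) * log(2 * pi * sigma2) + (n - 2L) + logdet -
                        determinant(XtX_inv, logarithm = TRUE)$modulus)
  } else {
    sigma2 <- rss / n
    loglik <- -0.5 * (n * log(2 * pi * sigma2) + n + logdet)
  }
  s2 <- rss / (n - 2L)
  list(beta = beta, se = sqrt(s2 * diag(XtX_inv)), rss = rss,
       sigma2 = sigma2, loglik = as.numeric(loglik),
       resid_white = as.numeric(res),
       fitted = as.numeric(X %*% beta), center = mean(x))
}

fit_one_order <- function(p, y, x, reml = FALSE) {
  negll <- function(theta) {
    fit <- ar_profile_fit(pacf_to_ar(tanh(theta)), y, x, reml = reml)
    if (is.null(fit)) return(1e10)
    -fit$loglik
  }
  if (p == 0L) {
    phi <- numeric(0)
  } else {
    # start from Yule-Walker pacf of OLS residuals, fall back to 0
    ols <- ar_profile_fit(numeric(0), y, x)
    pac <- tryCatch(stats::pacf(y - ols$fitted, lag.max = p,
                                plot = FALSE)$acf[seq_len(p)],
                    error = function(e) rep(0, p))
    pac[!is.finite(pac)] <- 0
    start <- atanh(pmin(pmax(pac, -0.95), 0.95))
    opt <- if (p == 1L) {
      o <- stats::optimize(function(t) negll(t), interval = atanh(c(-0.995, 0.995)))
      list(par = o$minimum, value = o$objective)
    } else {
      stats::optim(start, negll, method = "Nelder-Mead",
                   control = list(maxit = 500L, reltol = 1e-10))
    }
    phi <- pacf_to_ar(tanh(opt$par))
  }
  fit <- ar_profile_fit(phi, y, x, reml = reml)
  if (is.null(fit)) return(NULL)
  k <- p + 3L  # intercept, slope, p AR coefficients, innovation variance
  fit$phi <- phi
  fit$order <- p
  fit$aic <- 2 * k - 2 * fit$loglik
  fit$df <- length(y) - 2L
  fit
}

#' Fit an annual canopy trend by GLS with autoregressive errors
#'
#' Fits `y = b0 + b1 * year + e` where `e` follows a stationary AR(p)
#' process, for each candidate order, by maximizing the exact restricted
#' Gaussian likelihood (REML, the convention of standard GLS software),
#' and keeps the order with the minimum AIC. Restricted likelihoods are
#' directly comparable here because every candidate shares the same trend
#' (mean) model and differs only in its error-correlation structure; REML
#' also removes the downward small-sample bias of ML variance estimates,
#' keeping interval coverage close to nominal at the series lengths
#' typical of satellite records. Missing years are simply absent
#' observations: the error correlation between two observations is the
#' stationary AR autocorrelation at their year lag (gap-aware likelihood,
#' no imputation). The two-sided p-value uses the t distribution with
#' `n - 2` degrees of freedom. The slope is reported as percent of the
#' series maximum per year when `y` is a max-normalized series
#' (i.e. `100 * b1`).
#'
#' @param y annual values (typically [normalize_by_max()] output); `NA`s
#'   are dropped together with their years.
#' @param years integer calendar years aligned with `y`.
#' @param orders candidate AR orders (default `0:2`).
#' @return An object of class `kelp_trend` with components `slope_pct`,
#'   `stderr_pct`, `p_value`, `ar_order`, `ar_coefficients`, `aic` (named
#'   vector over candidate orders), `n`, plus the selected fit. Standard
#'   methods: `print`, `summary`, `coef`, `predict`, `residuals`, `fitted`,
#'   `plot`.
#' @export
kelp_trend <- function(y, years, orders = 0:2) {
  stopifnot(length(y) == length(years))
  ok <- is.finite(y) & is.finite(years)
  y <- y[ok]; x <- as.numeric(years[ok])
  if (length(y) < 6L) stop("need at least 6 non-missing years, got ", length(y))
  if (any(duplicated(x))) stop("duplicated years")
  fits <- vector("list", length(orders))
  aic <- stats::setNames(rep(NA_real_, length(orders)),
                         paste0("AR", orders))
  for (i in seq_along(orders)) {
    f <- fit_one_order(as.integer(orders[i]), y, x, reml = TRUE)
    if (is.null(f)) {
      kc_log("kelp_trend: AR(%d) fit invalid, excluded from selection",
             orders[i])
      next
    }
    fits[[i]] <- f
    aic[i] <- f$aic
  }
  if (all(is.na(aic))) stop("no valid autoregressive fit")
  # a numerically exact fit needs no error model: prefer the lowest order
  # among degenerate fits rather than comparing AICs at the residual floor
  degen <- vapply(seq_along(orders), function(i) !is.null(fits[[i]]) &&
                    fits[[i]]$sigma2 < 1e-18 * max(1, stats::var(y)),
                  logical(1))
  best <- if (any(degen)) fits[[which(degen)[1]]] else fits[[which.min(aic)]]
  tstat <- best$beta[2] / best$se[2]
  structure(list(
    coefficients = stats::setNames(as.numeric(best$beta),
                                   c("(Intercept)", "year")),
    slope_pct = 100 * best$beta[2],
    stderr_pct = 100 * best$se[2],
    p_value = 2 * stats::pt(-abs(tstat), df = best$df),
    ar_order = best$order,
    ar_coefficients = best$phi,
    aic = aic,
    loglik = best$loglik,
    sigma2 = best$sigma2,
    n = length(y),
    years = x, y = y,
    center = best$center,
    fitted.values = best$fitted,
    residuals = y - best$fitted,
    resid_white = best$resid_white,
    se = best$se, df = best$df),
    class = "kelp_trend")
}

#' @export
print.kelp_trend <- function(x, ...) {
  cat(sprintf("Kelp canopy trend: %+.3f %%/yr (SE %.3f, p = %.4g), AR(%d), n = %d\n",
              x$slope_pct, x$stderr_pct, x$p_value, x$ar_order, x$n))
  invisible(x)
}

#' @export
summary.kelp_trend <- function(object, ...) {
  cat("Generalized least squares trend with AR errors (REML, AIC-selected)\n\n")
  cat("AIC by candidate order:\n")
  print(round(object$aic, 2))
  cat(sprintf("\nSelected: AR(%d)", object$ar_order))
  if (object$ar_order > 0)
    cat(sprintf("  phi = %s", paste(round(object$ar_coefficients, 3),
                                    collapse = ", ")))
  cat("\n\nCoefficients (year centered):\n")
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `t value` = object$coefficients / object$se)
  tab <- cbind(tab, `Pr(>|t|)` = 2 * stats::pt(-abs(tab[, "t value"]),
                                               df = object$df))
  print(tab)
  cat(sprintf("\nSlope: %+.3f %% of maximum per year (n = %d years)\n",
              object$slope_pct, object$n))
  invisible(object)
}

#' @export
coef.kelp_trend <- function(object, ...) object$coefficients

#' @export
fitted.kelp_trend <- function(object, ...) object$fitted.values

#' @export
residuals.kelp_trend <- function(object, type = c("response", "whitened"),
                                 ...) {
  type <- match.arg(type)
  if (type == "response") object$residuals else object$resid_white
}

#' @export
predict.kelp_trend <- function(object, years = object$years, ...) {
  b <- object$coefficients
  as.numeric(b[1] + b[2] * (as.numeric(years) - object$center))
}

#' @export
plot.kelp_trend <- function(x, ...) {
  graphics::plot(x$years, x$y, xlab = "year",
                 ylab = "canopy area (fraction of maximum)", pch = 16, ...)
  graphics::lines(x$years, x$fitted.values, col = "red3", lwd = 2)
  invisible(x)
}

# Coerce annual input (named vector or data.frame year/area_m2) to a named
# numeric series.
as_annual_series <- function(series, years = NULL) {
  if (is.data.frame(series)) {
    stopifnot(all(c("year", "area_m2") %in% names(series)))
    return(stats::setNames(series$area_m2, series$year))
  }
  if (!is.null(years)) return(stats::setNames(as.numeric(series), years))
  if (is.null(names(series))) stop("annual series needs year names")
  series
}

window_mean <- function(s, yrs, fun = mean) {
  v <- s[names(s) %in% as.character(yrs)]
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  fun(v)
}

#' Heatwave response
#'
#' The minimum annual canopy area during the event window as a percentage of
#' the mean annual area over the historical baseline (missing years are
#' dropped from both windows). A constant series gives 100%.
#'
#' @param series annual canopy areas: a named numeric vector (names = years)
#'   or a data frame with `year` and `area_m2`.
#' @param baseline_years,event_years calendar-year windows (defaults
#'   1984-2013 and 2014-2016).
#' @param years optional years if `series` is an unnamed vector.
#' @return Response percentage (`NA` with a warning if the baseline mean is
#'   zero or a window is empty).
#' @export
heatwave_response <- function(series, baseline_years = 1984:2013,
                              event_years = 2014:2016, years = NULL) {
  s <- as_annual_series(series, years)
  base <- window_mean(s, baseline_years)
  ev <- window_mean(s, event_years, fun = min)
  if (is.na(base) || is.na(ev)) { warning("empty baseline or event window"); return(NA_real_) }
  if (base == 0) { warning("baseline mean is zero; response undefined"); return(NA_real_) }
  100 * ev / base
}

#' Heatwave recovery
#'
#' The mean annual canopy area over the post-event window as a percentage of
#' the historical baseline mean. Values above 100% indicate canopy exceeding
#' its historical mean after the event.
#'
#' @inheritParams heatwave_response
#' @param recovery_years post-event window (default 2017-2021).
#' @return Recovery percentage.
#' @export
heatwave_recovery <- function(series, baseline_years = 1984:2013,
                              recovery_years = 2017:2021, years = NULL) {
  s <- as_annual_series(series, years)
  base <- window_mean(s, baseline_years)
  rec <- window_mean(s, recovery_years)
  if (is.na(base) || is.na(rec)) { warning("empty baseline or recovery window"); return(NA_real_) }
  if (base == 0) { warning("baseline mean is zero; recovery undefined"); return(NA_real_) }
  100 * rec / base
}

#' Recent state of the canopy
#'
#' Mean annual canopy area across the combined event-and-after window
#' (default 2014-2021) as a percentage of the historical baseline mean; the
#' local-scale variant of the heatwave metrics.
#'
#' @inheritParams heatwave_response
#' @param window recent window (default 2014:2021).
#' @return Recent-state percentage.
#' @export
recent_state <- function(series, baseline_years = 1984:2013,
                         window = 2014:2021, years = NULL) {
  s <- as_annual_series(series, years)
  base <- window_mean(s, baseline_years)
  rec <- window_mean(s, window)
  if (is.na(base) || is.na(rec)) { warning("empty baseline or recent window"); return(NA_real_) }
  if (base == 0) { warning("baseline mean is zero; recent state undefined"); return(NA_real_) }
  100 * rec / base
}

#' Latitudinal correlation of a heatwave metric
#'
#' Pearson correlation between `log(metric + 1)` (a constant of 1 percentage
#' point added before the log, since response/recovery can be exactly zero)
#' and cell latitude, with a two-sided p-value from the t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param metric_pct non-negative metric per cell, in percent.
#' @param latitude cell centroid latitudes (degrees).
#' @return List with `r`, `p_value`, `n`. Zero variance in either variable
#'   gives `r = NA` with a warning.
#' @export
latitude_correlation <- function(metric_pct, latitude) {
  stopifnot(length(metric_pct) == length(latitude))
  ok <- is.finite(metric_pct) & is.finite(latitude)
  m <- metric_pct[ok]; lat <- latitude[ok]
  if (length(m) < 3L) stop("need at least 3 cells")
  if (any(m < 0)) stop("metric_pct must be non-negative")
  lm_ <- log(m + 1)
  if (stats::sd(lm_) == 0 || stats::sd(lat) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = length(m)))
  }
  ct <- stats::cor.test(lm_, lat)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(m))
}
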