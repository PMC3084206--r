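as_series <- function(x, value = NULL) {
  if (is.list(x) && !is.data.frame(x) && all(c("time", "value") %in% names(x)))
    return(data.frame(time = x$time, value = x$value))
  if (is.data.frame(x)) {
    if (all(c("time", "value") %in% names(x)))
      return(data.frame(time = x$time, value = x$value))
    stop_config("series data frame needs columns time, value")
  }
  if (is.null(value)) stop_config("supply a series as data.frame(time, value)")
  data.frame(time = x, value = value)
}

check_uniform_grid <- function(time, tol = 0.01) {
  dt <- diff(time)
  if (!length(dt) || any(dt <= 0))
    stop_config("time grid must be strictly increasing")
  if ((max(dt) - min(dt)) / median(dt) > tol)
    stop_config("time grid not uniform (tolerance %g)", tol)
  median(dt)
}

#' Local-polynomial (Savitzky-Golay) smoothing with analytic derivative
#'
#' At every sample a least-squares polynomial of the given degree is fitted
#' over a centred window of `window` points; the smoothed value and the
#' analytic first derivative of the local fit are returned.  Near the
#' edges the window keeps its full width but shifts inward and the local
#' polynomial is evaluated off-centre (Savitzky-Golay filtering with
#' polynomial edge interpolation), so the output covers the full grid
#' without the variance blow-up of short one-sided fits.
#'
#' @param series data frame with `time` (h) and `value`, on a uniform grid
#'   (1% tolerance).
#' @param window window width in points; odd and >= `degree + 2`.
#' @param degree polynomial degree.
#' @return an object of class `smoothed_series`: list with `time`, `value`
#'   (smoothed), `deriv` (d value / d t), `window`, `degree`.
#' @export
smooth_and_differentiate <- function(series, window = 11, degree = 2) {
  s <- as_series(series)
  n <- nrow(s)
  if (window %% 2 == 0 || window < degree + 2)
    stop_config("window must be odd and >= degree + 2 (got window=%d, degree=%d)",
                window, degree)
  if (n < window) stop_config("need at least %d points, got %d", window, n)
  check_uniform_grid(s$time)
  half <- (window - 1) / 2
  val <- der <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, lo + window - 1)
    lo <- max(1, hi - window + 1)
    tt <- s$time[lo:hi] - s$time[i]
    X <- outer(tt, 0:degree, `^`)
    cf <- qr.coef(qr(X), s$value[lo:hi])
    val[i] <- cf[1]
    der[i] <- cf[2]
  }
  structure(list(time = s$time, value = val, deriv = der,
                 window = window, degree = degree),
            class = "smoothed_series")
}

#' Numerical growth rate from an OD time course
#'
#' The specific growth rate is the log-derivative of biomass,
#' \eqn{\hat\mu(t) = d\,\ln \mathrm{OD}/dt}, computed by local-polynomial
#' smoothing of ln OD.  Negative values are preserved (mild lysis shows up
#' as slightly negative rates and is informative).  The estimate is
#' invariant to rescaling the OD by any positive constant.
#'
#' @param od_series data frame `time`, `value` of blank-corrected OD600;
#'   all values must be positive.
#' @param window,degree smoothing parameters, see
#'   [smooth_and_differentiate()].
#' @return a `smoothed_series` whose `value` is \eqn{\hat\mu} (1/h); the
#'   smoothed ln OD is kept in `$log_od`.
#' @export
growth_rate <- function(od_series, window = 11, degree = 2) {
  s <- as_series(od_series)
  if (any(s$value <= 0))
    stop_config("nonpositive OD; blank-correct (with a positive floor) first")
  sm <- smooth_and_differentiate(data.frame(time = s$time, value = log(s$value)),
                                 window, degree)
  structure(list(time = sm$time, value = sm$deriv, deriv = sm$deriv,
                 log_od = sm$value, window = window, degree = degree),
            class = "smoothed_series")
}

new_activity_estimate <- function(time, value, estimator, delta = NULL,
                                  window = NULL, degree = NULL) {
  structure(list(time = time, value = value, estimator = estimator,
                 delta = delta, window = window, degree = degree),
            class = "activity_estimate")
}

#' OD-corrected luminescence (naive promoter-activity readout)
#'
#' The classic readout: luminescence divided by biomass,
#' \eqn{A_{naive}(t) = \mathrm{RLU}(t)/\mathrm{OD}(t)}.  With an unstable
#' reporter this already tracks the transcription rate up to the reporter
#' relaxation time \eqn{1/\delta}; [activity_deconvolved()] removes that
#' remaining filter.
#'
#' @param rlu_series,od_series data frames `time`, `value` on a common grid.
#' @return an `activity_estimate` with estimator tag `"naive"`.
#' @export
activity_naive <- function(rlu_series, od_series) {
  r <- as_series(rlu_series); o <- as_series(od_series)
  if (nrow(r) != nrow(o) || max(abs(r$time - o$time)) > 1e-9)
    stop_config("RLU and OD series must share one time grid")
  if (any(o$value <= 0)) stop_config("nonpositive OD; blank-correct first")
  new_activity_estimate(r$time, r$value / o$value, "naive")
}

#' Deconvolved promoter activity from an unstable reporter
#'
#' Inverts the reporter kinetics: with total reporter obeying
#' \eqn{dL/dt = a(t)\,\mathrm{OD}(t) - \delta L} (light units), the
#' transcription-rate estimate is
#' \deqn{\hat a(t) = \frac{d\mathrm{RLU}/dt + \delta\,\mathrm{RLU}(t)}{\mathrm{OD}(t)},}
#' with the derivative from [smooth_and_differentiate()].  Negative
#' excursions are reported, not clipped: persistent negativity diagnoses a
#' misspecified \eqn{\delta}.  As \eqn{\delta \to 0} the estimator tends to
#' the stable-reporter limit \eqn{(d\mathrm{RLU}/dt)/\mathrm{OD}}.
#'
#' @param rlu_series,od_series data frames `time`, `value` on a common grid.
#' @param delta reporter degradation rate \eqn{\ln 2 / t_{1/2}}, 1/h; > 0.
#' @param window,degree smoothing parameters for the RLU derivative.
#' @return an `activity_estimate` with estimator tag `"deconvolved"` and
#'   the `delta` used.
#' @export
activity_deconvolved <- function(rlu_series, od_series, delta,
                                 window = 11, degree = 2) {
  if (!is.finite(delta) || delta <= 0) stop_config("delta must be > 0")
  r <- as_series(rlu_series); o <- as_series(od_series)
  if (nrow(r) != nrow(o) || max(abs(r$time - o$time)) > 1e-9)
    stop_config("RLU and OD series must share one time grid")
  if (any(o$value <= 0)) stop_config("nonpositive OD; blank-correct first")
  sm <- smooth_and_differentiate(r, window, degree)
  new_activity_estimate(r$time, (sm$deriv + delta * sm$value) / o$value,
                        "deconvolved", delta = delta,
                        window = window, degree = degree)
}

#' Calibrate the reporter half-life from a translation-arrest run
#'
#' After translation is blocked, luciferase synthesis stops and the
#' luminescence decays as \eqn{L(t) = L(t_a) e^{-\delta (t - t_a)}}.  An
#' ordinary least-squares fit of \eqn{\ln \mathrm{RLU}} against time over
#' the fit window gives \eqn{\delta = -\mathrm{slope}} and
#' \eqn{t_{1/2} = \ln 2/\delta}.
#'
#' @param run a `plate_table` from [simulate_arrest()] (or real data), or a
#'   data frame `time`, `value` of one RLU series.
#' @param t_arrest arrest time, h (defaults to the run metadata).
#' @param fit_window `c(from, to)` in h; default from one sample after
#'   arrest to 0.5 h after arrest.
#' @param well well to fit when `run` is a plate table (default: first
#'   non-blank well with an RLU channel).
#' @param noise_floor RLU values at or below this are dropped (with a
#'   warning) before taking logs.
#' @return an object of class `half_life_fit`: list with `half_life` (h),
#'   `half_life_min` (minutes), `delta` (1/h), `se_delta`, `r_squared`,
#'   `fit_window`, `n`.
#' @export
fit_half_life <- function(run, t_arrest = NULL, fit_window = NULL,
                          well = NULL, noise_floor = 0) {
  if (inherits(run, "plate_table")) {
    meta <- plate_meta(run)
    t_arrest <- t_arrest %||% meta$t_arrest
    if (is.null(t_arrest)) stop_config("t_arrest not given and not in metadata")
    if (is.null(well)) {
      wells <- setdiff(unique(run$well), meta$blank_wells %||% character())
      well <- wells[1]
    }
    s <- plate_series(run, well, "RLU")
  } else {
    s <- as_series(run)
    if (is.null(t_arrest)) stop_config("t_arrest required for a bare series")
  }
  dt <- median(diff(s$time))
  fit_window <- fit_window %||% c(t_arrest + dt, t_arrest + 0.5)
  sel <- s$time >= fit_window[1] & s$time <= fit_window[2]
  tt <- s$time[sel]; vv <- s$value[sel]
  pos <- vv > noise_floor
  if (any(!pos)) {
    warning(sprintf("%d nonpositive RLU reading(s) dropped from the fit window",
                    sum(!pos)))
    tt <- tt[pos]; vv <- vv[pos]
  }
  if (length(tt) < 6)
    stop_config("need at least 6 usable post-arrest samples, got %d", length(tt))
  fit <- lm(log(vv) ~ tt)
  slope <- coef(fit)[["tt"]]
  if (slope >= 0) stop_config("no decay: post-arrest slope is %.3g >= 0", slope)
  delta <- -slope
  sfit <- suppressWarnings(summary(fit))  # exact decay: zero residual is fine
  structure(list(half_life = log(2) / delta,
                 half_life_min = 60 * log(2) / delta,
                 delta = delta,
                 se_delta = sfit$coefficients["tt", "Std. Error"],
                 r_squared = sfit$r.squared,
                 fit_window = fit_window, n = length(tt)),
            class = "half_life_fit")
}

#' @export
print.half_life_fit <- function(x, ...) {
  cat(sprintf("Reporter half-life: %.3f h (%.1f min), delta = %.3f 1/h (SE %.3g), R^2 = %.4f, n = %d\n",
              x$half_life, x$half_life_min, x$delta, x$se_delta, x$r_squared, x$n))
  invisible(x)
}
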