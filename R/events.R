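# Interior local maxima (plateau-tolerant: the centre index of a plateau).
find_local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer())
  out <- integer()
  i <- 2
  while (i <= n - 1) {
    if (v[i] > v[i - 1]) {
      j <- i
      while (j < n && v[j + 1] == v[i]) j <- j + 1
      if (j < n && v[j + 1] < v[i]) out <- c(out, (i + j) %/% 2)
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# Topographic prominence of peak at index p: height above the key saddle
# on the way to higher terrain; global max is measured from the series min.
peak_prominence <- function(v, p) {
  higher_l <- which(v[seq_len(p - 1)] > v[p])
  higher_r <- which(v[seq(p + 1, length(v))] > v[p]) + p
  col_l <- if (length(higher_l)) min(v[(max(higher_l)):p]) else -Inf
  col_r <- if (length(higher_r)) min(v[p:(min(higher_r))]) else -Inf
  if (is.infinite(col_l) && is.infinite(col_r)) return(v[p] - min(v))
  v[p] - max(col_l, col_r)
}

#' Detect transcriptional bursts in an activity series
#'
#' Bursts are local maxima whose topographic prominence exceeds
#' `min_prominence` as a fraction of the series range (max minus min); the
#' range normalisation makes detection invariant to affine rescaling of
#' the activity.  Peaks closer together than `merge_within` are merged
#' (the higher one kept), which prevents double-counting of shouldered
#' waves.
#'
#' @param activity_series data frame `time`, `value` (an
#'   `activity_estimate` works directly) on a uniform grid.
#' @param min_prominence prominence threshold as fraction of range
#'   (default 0.15).
#' @param merge_within merge radius, h (default 0.15).
#' @return data frame of class `burst_events`: `time` (peak), `peak`
#'   (activity at the peak), `prominence` (fraction of range),
#'   `rise_start` (time of the preceding key saddle), sorted by time.
#' @export
detect_bursts <- function(activity_series, min_prominence = 0.15,
                          merge_within = 0.15) {
  s <- as_series(activity_series)
  v <- s$value
  rng <- max(v) - min(v)
  empty <- data.frame(time = numeric(), peak = numeric(),
                      prominence = numeric(), rise_start = numeric())
  class(empty) <- c("burst_events", "data.frame")
  if (rng == 0) return(empty)
  cand <- find_local_maxima(v)
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(p) peak_prominence(v, p), 0) / rng
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)
  # merge close peaks, higher first
  o <- order(v[cand], decreasing = TRUE)
  sel <- logical(length(cand))
  for (i in o) {
    if (!any(sel & abs(s$time[cand] - s$time[cand[i]]) < merge_within))
      sel[i] <- TRUE
  }
  cand <- cand[sel]; prom <- prom[sel]
  o <- order(s$time[cand])
  cand <- cand[o]; prom <- prom[o]
  # rise starts at the activity minimum since the previous burst (or the
  # record start for the first one)
  rise <- vapply(seq_along(cand), function(k) {
    lo <- if (k == 1) 1 else cand[k - 1]
    s$time[lo + which.min(v[lo:cand[k]]) - 1]
  }, 0)
  out <- data.frame(time = s$time[cand], peak = v[cand],
                    prominence = prom, rise_start = rise)
  class(out) <- c("burst_events", "data.frame")
  out
}

#' Detect growth-rate pauses
#'
#' A pause is a local minimum of the smoothed growth rate whose depth
#' (1 minus the ratio of the minimum to the lower of the two flanking
#' maxima) is at least `min_depth` and which stays below half-depth for at
#' least `min_width` hours.  With `include_terminal = TRUE` the terminal
#' descent into stationary phase is additionally recorded as one pause
#' (the growth arrest at T0 behaves like a pause that never recovers).
#'
#' @param mu_series a `smoothed_series` from [growth_rate()] or a data
#'   frame `time`, `value`.
#' @param min_depth minimal relative depth (default 0.2).
#' @param min_width minimal width at half depth, h (default 0.1).
#' @param before keep only pauses at or before this time (e.g. T0), if given.
#' @param include_terminal also record the terminal entry to stationary
#'   phase as a pause (off by default: a plain logistic arrest is then not
#'   called a pause; the pipeline turns it on so the growth arrest at T0 is
#'   counted alongside the diauxic pauses, as in sporulation-medium runs).
#' @param min_flank both flanking maxima must reach this fraction of the
#'   upper (90th percentile) growth rate, so that noise wiggles in the
#'   stationary tail are not mistaken for pauses.
#' @param min_drop the absolute dip (flank minus minimum) must reach this
#'   fraction of the upper growth rate; a relative-depth criterion alone
#'   would accept shallow noise dips during slow-growth phases.
#' @return data frame of class `pause_events`: `time`, `mu_min`, `depth`,
#'   `width`, `terminal`, sorted by time.
#' @export
detect_pauses <- function(mu_series, min_depth = 0.2, min_width = 0.1,
                          before = NULL, include_terminal = FALSE,
                          min_flank = 0.25, min_drop = 0.2) {
  s <- as_series(mu_series)
  v <- s$value
  n <- length(v)
  dt <- median(diff(s$time))
  scale <- quantile(pmax(v, 0), 0.9)
  cand <- find_local_maxima(-v)
  cand <- cand[order(v[cand])]          # deepest first
  acc <- integer(); rec <- list()
  for (p in cand) {
    lo <- max(c(1, acc[acc < p] + 1)); hi <- min(c(n, acc[acc > p] - 1))
    flank <- min(max(v[lo:p]), max(v[p:hi]))
    if (flank <= 0 || flank < min_flank * scale) next
    depth <- min(1 - v[p] / flank, 1)
    if (depth < min_depth || (flank - v[p]) < min_drop * scale) next
    half <- v[p] + 0.5 * (flank - v[p])
    below <- v < half
    l <- p; while (l > 1 && below[l - 1]) l <- l - 1
    r <- p; while (r < n && below[r + 1]) r <- r + 1
    width <- s$time[r] - s$time[l] + dt
    if (width < min_width) next
    if (any(vapply(rec, function(e) abs(e$time - s$time[p]) < min_width, TRUE)))
      next
    acc <- sort(c(acc, p))
    rec[[length(rec) + 1]] <- list(time = s$time[p], mu_min = v[p],
                                   depth = depth, width = width,
                                   terminal = FALSE)
  }
  if (include_terminal) {
    lo <- max(c(1, acc + 1))
    tail_v <- v[lo:n]
    flank_i <- lo + which.max(tail_v) - 1
    flank <- v[flank_i]
    thr <- 0.1 * quantile(pmax(v, 0), 0.9)
    low <- which(v < thr & seq_len(n) > flank_i)
    if (flank > 0 && length(low)) {
      i0 <- low[1]
      if (all(v[i0:n] < flank * (1 - min_depth) + 1e-12)) {
        depth <- min(1 - min(v[i0:n]) / flank, 1)
        if (depth >= min_depth) {
          rec[[length(rec) + 1]] <- list(time = s$time[i0],
                                         mu_min = min(v[i0:n]), depth = depth,
                                         width = s$time[n] - s$time[i0],
                                         terminal = TRUE)
        }
      }
    }
  }
  out <- if (length(rec)) do.call(rbind, lapply(rec, as.data.frame))
         else data.frame(time = numeric(), mu_min = numeric(),
                         depth = numeric(), width = numeric(),
                         terminal = logical())
  out <- out[order(out$time), , drop = FALSE]
  if (!is.null(before)) out <- out[out$time <= before, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pause_events", "data.frame")
  out
}

#' Time of entry into stationary phase (T0)
#'
#' T0 is taken as the first time the smoothed growth rate drops below
#' `frac` times its 90th percentile and stays below for at least `hold`
#' consecutive samples.  The transient diauxic pauses do not trigger the
#' rule because they recover within a few samples.
#'
#' @param mu_series a `smoothed_series` from [growth_rate()] or data frame
#'   `time`, `value`.
#' @param frac threshold as a fraction of the upper growth rate (default 0.1).
#' @param hold number of consecutive below-threshold samples required.
#' @return T0 in hours.
#' @export
define_T0 <- function(mu_series, frac = 0.1, hold = 20) {
  s <- as_series(mu_series)
  v <- s$value
  thr <- frac * quantile(pmax(v, 0), 0.9)
  below <- v < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= hold)
  if (!length(ok))
    stop_config("T0 undefined: culture still growing at the end of the run")
  s$time[starts[ok[1]]]
}

#' Pair growth-rate pauses with transcription bursts
#'
#' Greedy nearest-time matching: candidate (pause, burst) pairs within
#' `max_lag` are accepted in order of increasing |lag|, each event used at
#' most once.
#'
#' @param pauses `pause_events` from [detect_pauses()].
#' @param bursts `burst_events` from [detect_bursts()].
#' @param max_lag maximal |burst time - pause time|, h (default 0.3).
#' @return list with `pairs` (data frame `pause_time`, `burst_time`,
#'   `lag`), `unmatched_pauses`, `unmatched_bursts` (times).
#' @export
match_events <- function(pauses, bursts, max_lag = 0.3) {
  pt <- pauses$time; bt <- bursts$time
  pairs <- data.frame(pause_time = numeric(), burst_time = numeric(),
                      lag = numeric())
  if (length(pt) && length(bt)) {
    grid <- expand.grid(p = seq_along(pt), b = seq_along(bt))
    grid$lag <- bt[grid$b] - pt[grid$p]
    grid <- grid[abs(grid$lag) <= max_lag, ]
    grid <- grid[order(abs(grid$lag)), ]
    used_p <- logical(length(pt)); used_b <- logical(length(bt))
    for (i in seq_len(nrow(grid))) {
      p <- grid$p[i]; b <- grid$b[i]
      if (!used_p[p] && !used_b[b]) {
        used_p[p] <- used_b[b] <- TRUE
        pairs <- rbind(pairs, data.frame(pause_time = pt[p],
                                         burst_time = bt[b],
                                         lag = grid$lag[i]))
      }
    }
    unmatched_p <- pt[!used_p[seq_along(pt)]]
    unmatched_b <- bt[!used_b[seq_along(bt)]]
  } else {
    unmatched_p <- pt
    unmatched_b <- bt
  }
  list(pairs = pairs[order(pairs$pause_time), , drop = FALSE],
       unmatched_pauses = unmatched_p, unmatched_bursts = unmatched_b)
}

# Sub-sample refinement of a discrete extremum by fitting a parabola to
# the extremum and its two neighbours; returns the fractional index shift.
parabolic_shift <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(0)
  d2 <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (d2 == 0) return(0)
  s <- 0.5 * (v[i - 1] - v[i + 1]) / d2
  max(-0.5, min(0.5, s))
}

window_series <- function(s, window) {
  if (is.null(window)) return(s)
  s[s$time >= window[1] & s$time <= window[2], , drop = FALSE]
}

detrend <- function(s, detrend_window = NULL, degree = 2) {
  n <- nrow(s)
  w <- detrend_window %||% max(degree + 3, 2 * (n %/% 4) + 1)
  if (w %% 2 == 0) w <- w + 1
  w <- min(w, if (n %% 2 == 1) n else n - 1)
  tr <- smooth_and_differentiate(s, window = w, degree = degree)
  data.frame(time = s$time, value = s$value - tr$value)
}

#' Phase displacement between growth rate and promoter activity
#'
#' Quantifies the antiphase relationship of two quasi-periodic rate
#' curves.  Both series are detrended by subtracting a long-window local
#' polynomial; the dominant oscillation period is the lag of the first
#' peak of the growth-rate autocorrelation; the lag between the curves is
#' the maximiser of their normalised cross-correlation within plus or
#' minus 0.6 period; the phase is `|360 * lag / period|` mapped to
#' \[0, 360).  Pearson r over the window is reported alongside.
#'
#' @param mu_series growth-rate series (data frame `time`, `value` or
#'   `smoothed_series`).
#' @param activity_series activity series on the same grid.
#' @param window `c(from, to)` in hours restricting the analysis (e.g. the
#'   growth phase); `NULL` uses the full overlap.
#' @param min_acf minimal autocorrelation at the period peak for an
#'   oscillation to count (default 0.2).
#' @param T0 optional stationary-entry time to record in the report.
#' @param detrend_window window (points) of the detrending polynomial;
#'   default about half the analysis window.
#' @return an object of class `phase_report`: list with `period` (h),
#'   `lag` (h), `phase` (degrees), `r` (Pearson, on the windowed series),
#'   `T0`, `T1`, `T2`, `n`.
#' @export
phase_offset <- function(mu_series, activity_series, window = NULL,
                         min_acf = 0.2, T0 = NULL, detrend_window = NULL) {
  mu <- window_series(as_series(mu_series), window)
  ac <- window_series(as_series(activity_series), window)
  if (nrow(mu) != nrow(ac) || max(abs(mu$time - ac$time)) > 1e-9)
    stop_config("series must share one time grid over the window")
  n <- nrow(mu)
  if (n < 20) stop_config("analysis window too short (%d samples)", n)
  dt <- check_uniform_grid(mu$time)
  dmu <- detrend(mu, detrend_window)$value
  dac <- detrend(ac, detrend_window)$value
  if (sd(dmu) < 1e-10 * max(1, abs(mean(mu$value))))
    stop_config("no detectable oscillation (growth rate is constant over the window)")
  # dominant period: first prominent autocorrelation peak of the growth rate
  max_lag <- floor((n - 5) / 2) * 2  # allow up to ~2/3 of the window
  max_lag <- min(max_lag, n - 5)
  acfv <- vapply(0:max_lag, function(L)
    if (L == 0) 1 else cor(dmu[1:(n - L)], dmu[(1 + L):n]), 0)
  peaks <- find_local_maxima(acfv)
  peaks <- peaks[acfv[peaks] >= min_acf]
  if (!length(peaks))
    stop_config("no detectable oscillation (autocorrelation peak < %.2f)", min_acf)
  period <- (peaks[1] - 1 + parabolic_shift(acfv, peaks[1])) * dt
  # lag of the cross-correlation extremum within +/- 0.6 period
  Lmax <- max(1, min(round(0.6 * period / dt), n - 5))
  lags <- -Lmax:Lmax
  ccf <- vapply(lags, function(L) {
    if (L >= 0) cor(dmu[1:(n - L)], dac[(1 + L):n])
    else cor(dmu[(1 - L):n], dac[1:(n + L)])
  }, 0)
  imax <- which.max(ccf)
  lag <- (lags[imax] + parabolic_shift(ccf, imax)) * dt
  phase <- abs(360 * lag / period) %% 360
  structure(list(period = period, lag = lag, phase = phase,
                 r = cor(mu$value, ac$value),
                 T0 = T0, T1 = if (!is.null(T0)) T0 + 1,
                 T2 = if (!is.null(T0)) T0 + 2, n = n),
            class = "phase_report")
}

#' @export
print.phase_report <- function(x, ...) {
  cat(sprintf("Phase report: period %.2f h, lag %.3f h, phase %.0f deg, r = %.3f (n = %d)\n",
              x$period, x$lag, x$phase, x$r, x$n))
  invisible(x)
}

#' Correlation of promoter activities with the growth rate
#'
#' Pearson correlation of each activity channel with the growth rate over
#' a window (typically the growth phase).  An rrn-like promoter correlates
#' positively (it tracks the growth rate), a polymerase-limited vegetative
#' promoter negatively (it bursts when growth pauses).
#'
#' @param mu_series growth-rate series.
#' @param activities named list of activity series on the same grid.
#' @param window `c(from, to)` in hours, or `NULL`.
#' @return named numeric vector of Pearson r (NA for constant channels).
#' @export
correlation_signs <- function(mu_series, activities, window = NULL) {
  mu <- window_series(as_series(mu_series), window)
  vapply(activities, function(a) {
    ac <- window_series(as_series(a), window)
    if (nrow(ac) != nrow(mu)) stop_config("channel grid mismatch")
    if (sd(ac$value) == 0 || sd(mu$value) == 0) return(NA_real_)
    cor(mu$value, ac$value)
  }, 0)
}
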