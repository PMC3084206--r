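test_that("local-polynomial smoothing reproduces polynomials exactly", {
  tgrid <- seq(0, 2, by = 0.02)
  cubic <- 1 + 2 * tgrid - 3 * tgrid^2 + 0.5 * tgrid^3
  dcubic <- 2 - 6 * tgrid + 1.5 * tgrid^2
  sm <- smooth_and_differentiate(data.frame(time = tgrid, value = cubic),
                                 window = 11, degree = 3)
  expect_lt(max(abs(sm$value - cubic)), 1e-9)
  expect_lt(max(abs(sm$deriv - dcubic)), 1e-9)
  # constant series: zero derivative
  smc <- smooth_and_differentiate(data.frame(time = tgrid, value = rep(4, length(tgrid))),
                                  window = 11, degree = 2)
  expect_lt(max(abs(smc$deriv)), 1e-10)
  expect_error(smooth_and_differentiate(data.frame(time = tgrid, value = cubic),
                                        window = 10, degree = 2), "odd")
  expect_error(smooth_and_differentiate(data.frame(time = tgrid, value = cubic),
                                        window = 3, degree = 2), "window")
})

test_that("smoothing agrees with reference Savitzky-Golay filters away from edges", {
  skip_if_not_installed("signal")
  tgrid <- seq(0, 2, by = 0.02)
  set.seed(1)
  y <- sin(2 * pi * tgrid) + rnorm(length(tgrid), 0, 0.05)
  sm <- smooth_and_differentiate(data.frame(time = tgrid, value = y),
                                 window = 11, degree = 2)
  ref <- signal::sgolayfilt(y, p = 2, n = 11)
  interior <- 6:(length(y) - 5)
  expect_equal(sm$value[interior], ref[interior], tolerance = 1e-8)
})

test_that("smoothed derivative beats central differences on noisy data", {
  tgrid <- seq(0, 2, by = 0.02)
  truth_d <- 2 * pi * cos(2 * pi * tgrid)
  set.seed(42)
  noisy <- sin(2 * pi * tgrid) + rnorm(length(tgrid), 0, 0.02)
  sm <- smooth_and_differentiate(data.frame(time = tgrid, value = noisy),
                                 window = 11, degree = 2)
  central <- c(NA, diff(noisy, lag = 2) / (2 * 0.02), NA)
  interior <- 6:(length(tgrid) - 5)
  rmse <- function(e) sqrt(mean(e^2))
  expect_lt(rmse(sm$deriv[interior] - truth_d[interior]),
            rmse(central[interior] - truth_d[interior]))
})

test_that("growth rate recovers exponential growth and is scale invariant", {
  tgrid <- seq(0, 3, by = 0.025)
  od <- 0.05 * exp(0.9 * tgrid)
  mu <- growth_rate(data.frame(time = tgrid, value = od))
  interior <- 10:(length(tgrid) - 10)
  expect_lt(max(abs(mu$value[interior] - 0.9)), 1e-3)
  # rescaling OD leaves mu-hat untouched
  mu2 <- growth_rate(data.frame(time = tgrid, value = 37.5 * od))
  expect_lt(max(abs(mu$value - mu2$value)), 1e-10)
  expect_error(growth_rate(data.frame(time = tgrid, value = od - 1)),
               "blank")
})

test_that("negative growth rates (lysis) are preserved, not clipped", {
  tgrid <- seq(0, 3, by = 0.025)
  od <- ifelse(tgrid < 1.5, 0.5, 0.5 * exp(-0.05 * (tgrid - 1.5)))
  mu <- growth_rate(data.frame(time = tgrid, value = od))
  expect_lt(min(mu$value), 0)
  expect_equal(median(mu$value[tgrid > 2]), -0.05, tolerance = 0.005)
})

test_that("growth rate matches simulator ground truth on a noiseless diauxie", {
  traj <- simulate_diauxic_growth(diauxie_scenario())
  # noiseless data tolerates a narrow window, minimising bias at the
  # sharp diauxic dip; the wider default trades that bias for noise rejection
  mu <- growth_rate(data.frame(time = traj$time, value = traj$biomass),
                    window = 7)
  interior <- 10:(length(traj$time) - 10)
  mu_max <- max(traj$mu)
  expect_lt(max(abs(mu$value[interior] - traj$mu[interior])), 0.05 * mu_max)
})

test_that("naive activity is RLU/OD and reaches the steady-state ratio", {
  tgrid <- seq(0, 2, by = 0.02)
  expect_equal(
    activity_naive(data.frame(time = tgrid, value = rep(0, length(tgrid))),
                   data.frame(time = tgrid, value = rep(1, length(tgrid))))$value,
    rep(0, length(tgrid)))
  one <- activity_naive(data.frame(time = 0, value = 1000),
                        data.frame(time = 0, value = 0.5))
  expect_equal(one$value, 2000)
  expect_equal(one$estimator, "naive")
  # constant per-cell activity, constant biomass: settles to lc * a / delta
  rep_ <- reporter_spec(half_life = 0.1, light_coeff = 100)
  a <- 3
  sim <- simulate_reporter(rep(a, length(tgrid)), rep(0.4, length(tgrid)),
                           tgrid, rep_)
  nv <- activity_naive(data.frame(time = tgrid, value = sim$light),
                       data.frame(time = tgrid, value = rep(0.4, length(tgrid))))
  expect_equal(tail(nv$value, 1), 100 * a / rep_$delta, tolerance = 0.01)
})

test_that("deconvolution inverts the reporter model", {
  tgrid <- seq(0, 2, by = 0.02)
  n <- length(tgrid)
  # zero-derivative case: A = delta * L0 / N
  const <- activity_deconvolved(data.frame(time = tgrid, value = rep(500, n)),
                                data.frame(time = tgrid, value = rep(0.25, n)),
                                delta = 6.93)
  expect_equal(const$value, rep(6.93 * 500 / 0.25, n), tolerance = 1e-9)
  expect_equal(const$estimator, "deconvolved")
  zero <- activity_deconvolved(data.frame(time = tgrid, value = rep(0, n)),
                               data.frame(time = tgrid, value = rep(1, n)),
                               delta = 6.93)
  expect_equal(zero$value, rep(0, n))
  expect_error(activity_deconvolved(data.frame(time = tgrid, value = rep(1, n)),
                                    data.frame(time = tgrid, value = rep(1, n)),
                                    delta = 0), "delta")
})

test_that("deconvolved activity recovers a square-wave input on growing cells", {
  scn <- mini_scenario()
  tgrid <- seq(0, 2, by = 0.025)
  X <- 0.05 * exp(0.7 * tgrid)
  A <- ifelse(tgrid >= 0.5 & tgrid < 1.2, 8, 2)   # square wave, per cell
  rep_ <- reporter_spec(half_life = 0.1, light_coeff = 1000)
  sim <- simulate_reporter(A, X, tgrid, rep_, l0 = 2 / rep_$delta * X[1])
  dec <- activity_deconvolved(data.frame(time = tgrid, value = sim$light),
                              data.frame(time = tgrid, value = X),
                              delta = rep_$delta)
  # exclude the smoothing half-window around each step and the edges
  excl <- abs(tgrid - 0.5) <= 6 * 0.025 | abs(tgrid - 1.2) <= 6 * 0.025
  keep <- !excl & seq_along(tgrid) > 6 & seq_along(tgrid) < length(tgrid) - 5
  rel_rmse <- sqrt(mean((dec$value[keep] - 1000 * A[keep])^2)) /
    mean(1000 * A[keep])
  expect_lt(rel_rmse, 0.05)
})

test_that("deconvolution tends to the stable-reporter limit as delta -> 0", {
  tgrid <- seq(0, 2, by = 0.02)
  set.seed(2)
  L <- 100 + cumsum(runif(length(tgrid), 0, 5))
  OD <- 0.2 + 0.1 * tgrid
  sm <- smooth_and_differentiate(data.frame(time = tgrid, value = L), 11, 2)
  limit <- sm$deriv / OD
  small <- activity_deconvolved(data.frame(time = tgrid, value = L),
                                data.frame(time = tgrid, value = OD),
                                delta = 1e-8)
  expect_equal(small$value, limit, tolerance = 1e-5)
})

test_that("half-life fitting is exact on clean decay and robust to noise", {
  # pure exponential halving every 0.1 h
  tgrid <- seq(0, 1, by = 0.025)
  rlu <- 1000 * 0.5^(tgrid / 0.1)
  fit <- fit_half_life(data.frame(time = tgrid, value = rlu), t_arrest = 0,
                       fit_window = c(0.025, 0.5))
  expect_equal(fit$half_life, 0.1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # simulated arrest with 2% noise recovers the generating value within 10%
  run <- simulate_arrest(dsm_scenario(), t_arrest = 1.0, seed = 1)
  fit2 <- fit_half_life(run)
  expect_lt(abs(fit2$half_life - 0.1) / 0.1, 0.10)
  # the bundled reporter rounds to 6 minutes
  expect_equal(round(fit2$half_life_min), 6)
  # growing signal: no decay to fit
  expect_error(fit_half_life(data.frame(time = tgrid, value = rev(rlu)),
                             t_arrest = 0, fit_window = c(0.025, 0.5)),
               "no decay")
})
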