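new_plate_table <- function(df, meta = list()) {
  df <- df[order(df$well, df$channel, df$time_h), c("time_h", "well", "channel", "value")]
  rownames(df) <- NULL
  structure(df, class = c("plate_table", "data.frame"), meta = meta)
}

#' Metadata of a plate table
#' @param x a `plate_table`.
#' @return named list of metadata (scenario, seed, blank wells, provenance).
#' @export
plate_meta <- function(x) attr(x, "meta") %||% list()

mean_one_lognormal <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Render a synthetic plate-reader run from a trajectory
#'
#' Lays the ground-truth trajectory onto a virtual 96-well plate: each
#' promoter strain occupies `n_replicate_wells` wells read in both channels
#' (OD600 = optical background + biomass; RLU = emitted light of that
#' promoter's reporter), plus blank wells reading only the background.
#' Every reading gets independent multiplicative log-normal noise with
#' coefficient of variation `noise_cv` (mean-one, so noiseless values are
#' recovered in expectation).  The run is deterministic for a fixed seed.
#'
#' @param traj a `trajectory` from [simulate_diauxic_growth()].
#' @param scn the generating [scenario()] (defaults to the one in `traj`).
#' @param n_replicate_wells wells per promoter strain (>= 1).
#' @param seed integer RNG seed recorded in the metadata.
#' @param n_blank_wells blank (medium-only) wells.
#' @return a `plate_table` with metadata: scenario name, seed, blank wells,
#'   and the well-to-promoter map.
#' @export
render_plate_run <- function(traj, scn = traj$scenario, n_replicate_wells = 2,
                             seed = 1, n_blank_wells = 2) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_replicate_wells < 1) stop_config("n_replicate_wells must be >= 1")
  time <- traj$time
  proms <- colnames(traj$activity)
  light <- traj$light
  if (scn$reporter$maturation_delay > 0) {
    shift <- function(v) approxfun(time + scn$reporter$maturation_delay, v,
                                   yleft = 0, rule = 2)(time)
    light <- apply(light, 2, shift)
  }
  set.seed(seed)
  rows <- list()
  well_map <- character()
  for (p in proms) {
    for (j in seq_len(n_replicate_wells)) {
      w <- sprintf("%s_%d", p, j)
      well_map[w] <- p
      od <- (scn$od_background + traj$biomass) *
        mean_one_lognormal(length(time), scn$noise_cv)
      rlu <- light[, p] * mean_one_lognormal(length(time), scn$noise_cv)
      rows[[length(rows) + 1]] <- data.frame(
        time_h = rep(time, 2), well = w,
        channel = rep(c("OD600", "RLU"), each = length(time)),
        value = c(od, rlu))
    }
  }
  blanks <- sprintf("blank_%d", seq_len(n_blank_wells))
  for (w in blanks) {
    od <- scn$od_background * mean_one_lognormal(length(time), scn$noise_cv)
    rows[[length(rows) + 1]] <- data.frame(
      time_h = rep(time, 2), well = w,
      channel = rep(c("OD600", "RLU"), each = length(time)),
      value = c(od, rep(0, length(time))))
  }
  new_plate_table(do.call(rbind, rows),
                  meta = list(scenario = scn$name, seed = seed,
                              blank_wells = blanks, well_map = as.list(well_map),
                              od_background = scn$od_background))
}

#' Simulate a translation-arrest (puromycin) run
#'
#' Runs the scenario normally up to `t_arrest`; from then on translation is
#' blocked, so all promoter-driven reporter synthesis stops, biomass is
#' frozen, and the remaining luciferase decays purely exponentially at the
#' reporter degradation rate.  The post-arrest log-luminescence is
#' therefore linear with slope \eqn{-\delta}, which is what
#' [fit_half_life()] exploits to calibrate the reporter half-life.
#'
#' @param scn a [scenario()].
#' @param t_arrest arrest time, h; must lie inside the run.
#' @param seed RNG seed for the measurement noise.
#' @param n_replicate_wells wells per promoter strain.
#' @return a `plate_table` with `t_arrest` recorded in the metadata.
#' @export
simulate_arrest <- function(scn, t_arrest, seed = 1, n_replicate_wells = 2) {
  stopifnot(inherits(scn, "scenario"))
  if (t_arrest < 0 || t_arrest > scn$duration)
    stop_config("t_arrest = %.3f h outside the run [0, %.3f]", t_arrest, scn$duration)
  traj <- simulate_diauxic_growth(scn)
  post <- traj$time >= t_arrest
  ia <- which(post)[1]
  delta <- scn$reporter$delta
  traj$biomass[post] <- traj$biomass[ia]
  traj$mu[post] <- 0
  traj$activity[post, ] <- 0
  dtime <- traj$time[post] - traj$time[ia]
  traj$reporter[post, ] <- rep(traj$reporter[ia, ], each = sum(post)) *
    exp(-delta * dtime)
  traj$light <- scn$reporter$light_coeff * traj$reporter
  run <- render_plate_run(traj, scn, n_replicate_wells, seed)
  meta <- attr(run, "meta")
  meta$t_arrest <- t_arrest
  attr(run, "meta") <- meta
  run
}
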