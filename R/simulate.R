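#' RNA-polymerase allocation as a function of growth rate
#'
#' Implements the passive-regulation allocation: the rRNA-committed
#' fraction is \eqn{f_{rrn} = f_{max}\,\mu/(\mu + K_\mu)} and the free pool
#' is \eqn{R_{free} = R_{total}(1 - f_{rrn})}.  At \eqn{\mu = 0} no
#' polymerase is committed to rRNA and the whole pool is free, which is the
#' mechanistic core of the growth-pause transcription bursts.
#'
#' @param mu growth rate(s), 1/h; must be >= 0.
#' @param params an [rnap_params()].
#' @return list with numeric vectors `f_rrn` and `R_free`.
#' @export
allocate_rnap <- function(mu, params) {
  stopifnot(inherits(params, "rnap_params"))
  if (any(!is.finite(mu)) || any(mu < 0))
    stop_config("growth rate mu must be finite and >= 0")
  f_rrn <- params$f_max * mu / (mu + params$K_mu)
  list(f_rrn = f_rrn, R_free = params$R_total * (1 - f_rrn))
}

intp_factor <- function(spec, gtp_factor) {
  if (spec$initiating_nucleotide != "G") return(rep(1, length(gtp_factor)))
  # saturating GTP dependence, normalised to 1 at a full pool
  (gtp_factor / (gtp_factor + spec$intp_K)) * (1 + spec$intp_K)
}

#' Instantaneous promoter activity
#'
#' Evaluates the activity of one promoter given the polymerase state, the
#' GTP-pool factor, and the Spo0A~P level.  All arguments after `spec` may
#' be vectors over time.
#'
#' @param spec a [promoter_spec()].
#' @param f_rrn rRNA-committed polymerase fraction.
#' @param R_free free polymerase pool.
#' @param gtp_factor GTP-pool factor in \[0, 1\] (1 = replete).
#' @param spo0A_P Spo0A~P level (arbitrary units); only used by the
#'   `repressed` and `activated` classes.
#' @param R_total total polymerase pool (used by `rrn_like`).
#' @return numeric vector of activities (units/h).
#' @export
promoter_activity <- function(spec, f_rrn, R_free, gtp_factor = 1,
                              spo0A_P = 0, R_total = 1) {
  stopifnot(inherits(spec, "promoter_spec"))
  if (any(gtp_factor < 0 | gtp_factor > 1))
    stop_config("gtp_factor must lie in [0, 1]")
  base <- switch(spec$class,
    constitutive = spec$strength * R_free / (R_free + spec$K_R),
    rrn_like = spec$strength * f_rrn,
    repressed = spec$strength * R_free / (R_free + spec$K_R) /
      (1 + (spo0A_P / spec$regulator_K)^spec$hill_n),
    activated = spec$strength * spo0A_P^spec$hill_n /
      (spec$regulator_K^spec$hill_n + spo0A_P^spec$hill_n),
    stop_config("unknown promoter class '%s'", spec$class))
  base * intp_factor(spec, gtp_factor)
}

# Step function of the scripted stationary program for one promoter.
program_offset <- function(scn, promoter, time) {
  prog <- scn$stationary_program
  if (is.null(prog)) return(rep(0, length(time)))
  prog <- prog[prog$promoter == promoter, , drop = FALSE]
  if (!nrow(prog)) return(rep(0, length(time)))
  vapply(time, function(t) sum(prog$step[prog$time <= t]), 0)
}

gtp_profile <- function(scn, time) {
  g <- rep(1, length(time))
  sched <- scn$gtp_dip_schedule
  if (!is.null(sched)) {
    for (i in seq_len(nrow(sched))) {
      on <- time >= sched$start[i] & time < sched$end[i]
      g[on] <- g[on] - sched$depth[i]
    }
  }
  pmin(pmax(g, 0), 1)
}

kappa_fun <- function(spo0a) {
  k <- spo0a$kappa
  if (is.numeric(k) && length(k) == 1) function(t) rep(k, length(t))
  else {
    k <- as.data.frame(k)
    approxfun(k$time, k$value, rule = 2)
  }
}

# Activities of every promoter at given polymerase/GTP/Spo0A~P state,
# including the scripted stationary offsets (clamped at zero from below).
all_activities <- function(scn, time, f_rrn, R_free, gtp, Sp) {
  sapply(scn$promoters, function(p) {
    a <- promoter_activity(p, f_rrn, R_free, gtp, Sp, scn$rnap$R_total) +
      program_offset(scn, p$name, time)
    pmax(a, 0)
  })
}

#' Simulate a diauxic batch-culture trajectory
#'
#' Integrates the coupled growth / substrate / polymerase-allocation /
#' reporter / Spo0A~P system and returns the ground truth on the sampling
#' grid.  Growth follows multi-substrate Monod kinetics,
#' \eqn{dX/dt = \mu X} with \eqn{\mu = \sum_i g_i\,\mu_{max,i}\,S_i/(K_i + S_i)}
#' and \eqn{dS_i/dt = -\mu_i X / Y_i}, where the gating \eqn{g_i} is 1 for
#' the preferred substrate and equals an induction variable \eqn{E_i}
#' (\eqn{dE_i/dt = k_{ind}\,I_i\,(1-E_i) - k_{dec}E_i}, with \eqn{I_i} a
#' smooth indicator that all preferred substrates are exhausted) otherwise,
#' so a growth pause of finite width emerges at each substrate exhaustion.
#' The total reporter pool per promoter obeys
#' \eqn{dT_p/dt = A_p(t)X - \delta T_p}, equivalently a per-cell reporter
#' subject to degradation plus dilution; emitted light is
#' `light_coeff * T_p`.
#'
#' @param scn a [scenario()].
#' @return an object of class `trajectory`: list with `time`, `biomass`,
#'   `substrates` (matrix), `induction` (matrix), `mu`, `f_rrn`, `R_free`,
#'   `gtp_factor`, `activity` (matrix, one column per promoter), `reporter`
#'   (matrix of total reporter pools), `light` (matrix of RLU),
#'   `spo0A_protein`, `spo0A_P`, and the scenario.
#' @export
simulate_diauxic_growth <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  med <- scn$medium
  subs <- med$substrates
  if (!any(subs$conc > 0) && scn$x0 <= 0)
    stop_config("at least one substrate must have positive concentration")
  ord <- match(med$repression_order, subs$name)  # preference rank -> row
  m <- nrow(subs)
  prom <- scn$promoters
  k <- length(prom)
  delta <- scn$reporter$delta
  has_sp <- !is.null(scn$spo0a)
  kap <- if (has_sp) kappa_fun(scn$spo0a)
  src <- if (has_sp) scn$spo0a$source

  idx <- list(X = 1, S = 1 + seq_len(m), E = 1 + m + seq_len(m),
              T = 1 + 2 * m + seq_len(k),
              P = 2 + 2 * m + k, Sp = 3 + 2 * m + k)

  rates <- function(t, y, parms) {
    X <- y[idx$X]
    S <- pmax(y[idx$S], 0)
    E <- pmin(pmax(y[idx$E], 0), 1)
    # gating by catabolite repression: rank-1 substrate always on
    g <- numeric(m)
    g[ord[1]] <- 1
    for (r in seq_len(m)[-1]) {
      i <- ord[r]
      g[i] <- E[i]
    }
    mu_i <- g * subs$mu_max * S / (subs$K_s + S)
    mu <- sum(mu_i)
    al <- allocate_rnap(mu, scn$rnap)
    gtp <- gtp_profile(scn, t)
    Sp <- if (has_sp) max(y[idx$Sp], 0) else 0
    A <- vapply(prom, function(p)
      max(promoter_activity(p, al$f_rrn, al$R_free, gtp, Sp, scn$rnap$R_total) +
            program_offset(scn, p$name, t), 0), 0)
    dX <- mu * X
    dS <- -mu_i * X / subs$yield
    dE <- numeric(m)
    for (r in seq_len(m)[-1]) {
      i <- ord[r]
      pref <- ord[seq_len(r - 1)]
      I <- prod(med$switch_conc / (S[pref] + med$switch_conc))
      dE[i] <- med$induction_rate * I * (1 - E[i]) - med$decay_rate * E[i]
    }
    dT <- A * X - delta * y[idx$T]
    dP <- dSp <- 0
    if (has_sp) {
      P <- y[idx$P]
      dP <- A[[src]] - scn$spo0a$gamma_P * P
      dSp <- scn$spo0a$k_phos * P * kap(t) - scn$spo0a$k_deph * y[idx$Sp]
    }
    if (any(!is.finite(c(dX, dS, dE, dT, dP, dSp))))
      stop_config("integration failure: non-finite state at t = %.3f h", t)
    list(c(dX, dS, dE, dT, dP, dSp))
  }

  y0 <- numeric(3 + 2 * m + k)
  y0[idx$X] <- scn$x0
  y0[idx$S] <- subs$conc
  times <- seq(0, scn$duration, by = scn$sampling_interval)
  sol <- deSolve::lsoda(y0, times, rates, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  if (nrow(sol) < length(times))
    stop_config("integration failure at t = %.3f h", max(sol[, 1]))

  X <- sol[, 1 + idx$X]
  S <- pmax(sol[, 1 + idx$S, drop = FALSE], 0)
  E <- pmin(pmax(sol[, 1 + idx$E, drop = FALSE], 0), 1)
  colnames(S) <- colnames(E) <- subs$name
  g <- matrix(0, length(times), m)
  g[, ord[1]] <- 1
  for (r in seq_len(m)[-1]) g[, ord[r]] <- E[, ord[r]]
  mu <- rowSums(g * rep(subs$mu_max, each = length(times)) *
                  S / (matrix(subs$K_s, length(times), m, byrow = TRUE) + S))
  al <- allocate_rnap(mu, scn$rnap)
  gtp <- gtp_profile(scn, times)
  Sp <- if (has_sp) pmax(sol[, 1 + idx$Sp], 0) else rep(0, length(times))
  A <- all_activities(scn, times, al$f_rrn, al$R_free, gtp, Sp)
  Tm <- sol[, 1 + idx$T, drop = FALSE]
  colnames(A) <- colnames(Tm) <- names(prom)

  structure(list(time = times, biomass = X, substrates = S, induction = E,
                 mu = mu, f_rrn = al$f_rrn, R_free = al$R_free,
                 gtp_factor = gtp, activity = A, reporter = Tm,
                 light = scn$reporter$light_coeff * Tm,
                 spo0A_protein = if (has_sp) sol[, 1 + idx$P] else rep(0, length(times)),
                 spo0A_P = Sp, scenario = scn),
            class = "trajectory")
}

#' Reporter kinetics for a prescribed activity course
#'
#' Solves the unstable-reporter equation \eqn{dT/dt = A(t)X(t) - \delta T}
#' for the total reporter pool on the trajectory grid (exact
#' exponential-integrator stepping with trapezoidal source), and returns
#' emitted light `light_coeff * T`.  This is the forward model that the
#' deconvolution estimator inverts.
#'
#' @param activity per-cell activity series (units/h) on the time grid.
#' @param biomass biomass series on the same grid.
#' @param time time grid, h.
#' @param reporter a [reporter_spec()].
#' @param l0 initial total reporter pool.
#' @return list with `time`, `reporter` (total pool) and `light` (RLU).
#' @export
simulate_reporter <- function(activity, biomass, time, reporter, l0 = 0) {
  stopifnot(inherits(reporter, "reporter_spec"))
  n <- length(time)
  if (length(activity) != n || length(biomass) != n)
    stop_config("activity, biomass and time must share one grid")
  delta <- reporter$delta
  src <- activity * biomass
  Tp <- numeric(n)
  Tp[1] <- l0
  for (i in seq_len(n - 1)) {
    h <- time[i + 1] - time[i]
    e <- exp(-delta * h)
    # exact for source linear on [t_i, t_{i+1}]
    s0 <- src[i]; s1 <- src[i + 1]
    slope <- (s1 - s0) / h
    Tp[i + 1] <- Tp[i] * e + s0 * (1 - e) / delta +
      slope * (h - (1 - e) / delta) / delta
  }
  list(time = time, reporter = Tp, light = reporter$light_coeff * Tp)
}

#' Spo0A synthesis and phosphorylation from a trajectory
#'
#' Integrates \eqn{dP/dt = A_{spo0A}(t) - \gamma_P P} and
#' \eqn{dSp/dt = k_{phos} P\,\kappa(t) - k_{deph} Sp} on the trajectory
#' grid, driven by the designated source promoter's activity.  In a full
#' simulation the same equations are integrated jointly with the growth
#' model; this standalone form lets the response be recomputed for
#' alternative phosphorelay parameters without re-simulating growth.
#'
#' @param traj a `trajectory`.
#' @param params a [spo0a_params()].
#' @return list with `time`, `protein` and `spo0A_P` series.
#' @export
simulate_spo0A_response <- function(traj, params) {
  stopifnot(inherits(traj, "trajectory"), inherits(params, "spo0a_params"))
  if (!params$source %in% colnames(traj$activity))
    stop_config("source promoter '%s' absent from trajectory", params$source)
  A <- traj$activity[, params$source]
  time <- traj$time
  kap <- kappa_fun(params)(time)
  n <- length(time)
  P <- Sp <- numeric(n)
  for (i in seq_len(n - 1)) {
    h <- time[i + 1] - time[i]
    # trapezoidal semi-implicit update (unconditionally stable, O(h^2))
    P[i + 1] <- (P[i] + h / 2 * (A[i] + A[i + 1] - params$gamma_P * P[i])) /
      (1 + h / 2 * params$gamma_P)
    ph0 <- params$k_phos * P[i] * kap[i]
    ph1 <- params$k_phos * P[i + 1] * kap[i + 1]
    Sp[i + 1] <- (Sp[i] + h / 2 * (ph0 + ph1 - params$k_deph * Sp[i])) /
      (1 + h / 2 * params$k_deph)
  }
  list(time = time, protein = P, spo0A_P = Sp)
}
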