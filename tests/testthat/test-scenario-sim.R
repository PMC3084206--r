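test_that("polymerase allocation follows the growth rate", {
  p <- rnap_params(f_max = 0.8, K_mu = 0.2, R_total = 1)
  # no growth: nothing committed to rRNA, whole pool free
  a0 <- allocate_rnap(0, p)
  expect_equal(a0$f_rrn, 0)
  expect_equal(a0$R_free, 1)
  # direct formula evaluation
  a2 <- allocate_rnap(2, p)
  expect_equal(a2$f_rrn, 0.8 * 2 / 2.2, tolerance = 1e-12)
  # brute-force monotonicity over a dense grid
  grid <- seq(0, 3, by = 0.01)
  al <- allocate_rnap(grid, p)
  expect_true(all(diff(al$f_rrn) > 0))
  expect_true(all(diff(al$R_free) < 0))
  expect_true(all(al$f_rrn >= 0 & al$f_rrn <= p$f_max))
  expect_error(allocate_rnap(-0.1, p), "mu")
})

test_that("promoter classes respond to polymerase, GTP pool and Spo0A~P", {
  act <- promoter_spec("spoIIG", "activated", strength = 10,
                       regulator_K = 5, hill_n = 2)
  expect_equal(promoter_activity(act, 0.5, 0.5, 1, spo0A_P = 0), 0)
  con <- promoter_spec("P", "constitutive", strength = 10, K_R = 0.5)
  expect_equal(promoter_activity(con, 0, 0, 1), 0)     # no free polymerase
  # G-initiating promoter is depressed by a GTP dip, A-initiating is not
  conG <- promoter_spec("PG", "constitutive", strength = 10, K_R = 0.5,
                        initiating_nucleotide = "G", intp_K = 0.3)
  a_full <- promoter_activity(con, 0.5, 0.5, 1)
  expect_equal(promoter_activity(con, 0.5, 0.5, 0.5), a_full)
  expect_equal(promoter_activity(conG, 0.5, 0.5, 1), a_full)  # normalised
  expect_lt(promoter_activity(conG, 0.5, 0.5, 0.5), a_full)
  # Hill midpoint: repression halves activity at spo0A_P = regulator_K
  rep1 <- promoter_spec("abrB", "repressed", strength = 10, K_R = 0.5,
                        regulator_K = 3, hill_n = 1)
  expect_equal(promoter_activity(rep1, 0.5, 0.5, 1, spo0A_P = 3),
               promoter_activity(con, 0.5, 0.5, 1) / 2, tolerance = 1e-12)
  expect_error(promoter_spec("x", "enhancer", 1), "class")
  expect_error(promoter_activity(con, 0.5, 0.5, gtp_factor = 1.5), "gtp")
})

test_that("constitutive activity decreases with growth rate", {
  p <- rnap_params(f_max = 0.9, K_mu = 0.2)
  con <- promoter_spec("P", "constitutive", strength = 10, K_R = 0.3)
  grid <- seq(0, 3, by = 0.05)
  al <- allocate_rnap(grid, p)
  a <- promoter_activity(con, al$f_rrn, al$R_free, 1)
  expect_true(all(diff(a) < 0))
})

test_that("diauxic growth produces a pause only with a secondary substrate", {
  # single substrate: no internal pause in the true growth rate
  single <- simulate_diauxic_growth(diauxie_scenario(glucose = 2.5,
                                                     arabinose = 0))
  mu1 <- data.frame(time = single$time, value = single$mu)
  expect_equal(nrow(detect_pauses(mu1)), 0)
  # two substrates: exactly one pause, at glucose exhaustion
  both <- simulate_diauxic_growth(diauxie_scenario(glucose = 0.5,
                                                   arabinose = 2.0))
  mu2 <- data.frame(time = both$time, value = both$mu)
  p <- detect_pauses(mu2)
  expect_equal(nrow(p), 1)
  glc_gone <- both$time[which(both$substrates[, "glucose"] <
                                0.01 * 0.5)[1]]
  expect_lt(abs(p$time - glc_gone), 0.15)
})

test_that("the diauxic pause moves later when glucose is increased", {
  lo <- simulate_diauxic_growth(diauxie_scenario(glucose = 0.5, arabinose = 2.0))
  hi <- simulate_diauxic_growth(diauxie_scenario(glucose = 1.0, arabinose = 1.5))
  t_lo <- detect_pauses(data.frame(time = lo$time, value = lo$mu))$time
  t_hi <- detect_pauses(data.frame(time = hi$time, value = hi$mu))$time
  expect_length(t_lo, 1)
  expect_length(t_hi, 1)
  expect_gt(t_hi, t_lo)
})

test_that("no substrate means no growth", {
  scn <- mini_scenario()
  scn$medium$substrates$conc <- 0
  traj <- simulate_diauxic_growth(scn)
  expect_equal(traj$biomass, rep(scn$x0, length(traj$time)), tolerance = 1e-10)
  expect_equal(max(abs(traj$mu)), 0, tolerance = 1e-10)
})

test_that("biomass gained balances substrate consumed", {
  for (traj in list(dsm_trajectory(),
                    simulate_diauxic_growth(diauxie_scenario()))) {
    scn <- traj$scenario
    consumed <- sweep(-sweep(traj$substrates, 2,
                             scn$medium$substrates$conc, `-`),
                      2, scn$medium$substrates$yield, `*`)
    expect_lt(max(abs(traj$biomass - traj$biomass[1] - rowSums(consumed))),
              1e-6)
    expect_true(all(diff(traj$biomass) > -1e-9))
    expect_true(all(apply(traj$substrates, 2, function(s) all(diff(s) <= 1e-9))))
  }
})

test_that("reporter kinetics match the constant-activity closed form", {
  tgrid <- seq(0, 1, by = 0.01)
  rep_ <- reporter_spec(half_life = 0.1)
  delta <- rep_$delta
  # nothing expressed, nothing emitted
  z <- simulate_reporter(rep(0, length(tgrid)), rep(1, length(tgrid)),
                         tgrid, rep_)
  expect_equal(z$light, rep(0, length(tgrid)))
  # constant activity a with constant biomass: l(t) = a/delta (1 - e^-dt)
  a <- 5
  sim <- simulate_reporter(rep(a, length(tgrid)), rep(1, length(tgrid)),
                           tgrid, rep_)
  check <- seq(5, length(tgrid), length.out = 10)
  closed <- a / delta * (1 - exp(-delta * tgrid[check]))
  expect_equal(sim$reporter[check], closed, tolerance = 1e-8)
})

test_that("after an activity step to zero, light halves every half-life", {
  tgrid <- seq(0, 2, by = 0.005)
  rep_ <- reporter_spec(half_life = 0.1)
  A <- ifelse(tgrid < 1, 4, 0)
  sim <- simulate_reporter(A, rep(1, length(tgrid)), tgrid, rep_)
  i_star <- which(tgrid >= 1)[1]
  for (k in 1:5) {
    i_k <- which(tgrid >= 1 + k * 0.1)[1]
    ratio <- sim$light[i_k] / sim$light[i_star]
    expect_equal(ratio, 0.5^k, tolerance = 0.01 * k)
  }
})

test_that("Spo0A~P follows bursts of its source promoter with a lag", {
  traj <- dsm_trajectory()
  sp <- simulate_spo0A_response(traj, traj$scenario$spo0a)
  # zero input gives zero response
  t0 <- traj
  t0$activity[, "spo0A"] <- 0
  expect_equal(max(simulate_spo0A_response(t0, traj$scenario$spo0a)$spo0A_P), 0)
  # joint ODE integration and the standalone reconstruction agree
  expect_rel_error(sp$spo0A_P[-(1:5)], traj$spo0A_P[-(1:5)], 0.02)
  # each growth-phase burst is followed (lag > 0) by rising Spo0A~P
  bursts <- detect_bursts(data.frame(time = traj$time,
                                     value = traj$activity[, "spo0A"]))
  growth_bursts <- bursts$time[bursts$time < 3]
  expect_gte(length(growth_bursts), 2)
  for (tb in growth_bursts) {
    i_b <- which(traj$time >= tb)[1]
    i_a <- which(traj$time >= tb + 0.3)[1]
    expect_gt(traj$spo0A_P[i_a], traj$spo0A_P[i_b])
  }
})

test_that("abrB-class output dips as Spo0A~P rises past its operator affinity", {
  traj <- dsm_trajectory()
  abrB <- traj$activity[, "abrB"]
  K <- traj$scenario$promoters$abrB$regulator_K
  # in stationary phase the polymerase state is constant, so the decline
  # of abrB activity is attributable to accumulating Spo0A~P
  stat <- traj$mu < 0.01 & traj$time > 4.2
  expect_gt(max(traj$spo0A_P[stat]), K)
  expect_lt(cor(traj$spo0A_P[stat], abrB[stat]), -0.9)
  expect_lt(abrB[stat][sum(stat)], 0.75 * abrB[stat][1])
})

test_that("plate rendering is deterministic, faithful at zero noise, and has the configured noise law", {
  traj <- dsm_trajectory()
  scn0 <- dsm_scenario(noise_cv = 0)
  r0 <- render_plate_run(traj, scn0, n_replicate_wells = 1, seed = 7)
  od <- plate_series(r0, "spo0A_1", "OD600")
  expect_equal(od$value, scn0$od_background + traj$biomass)
  rlu <- plate_series(r0, "spo0A_1", "RLU")
  expect_equal(rlu$value, traj$light[, "spo0A"])
  # determinism
  scn <- dsm_scenario()
  a <- render_plate_run(traj, scn, 2, seed = 3)
  b <- render_plate_run(traj, scn, 2, seed = 3)
  expect_identical(a$value, b$value)
  expect_false(identical(a$value,
                         render_plate_run(traj, scn, 2, seed = 4)$value))
  # per-timepoint CV across 10 wells matches the generating CV
  r10 <- render_plate_run(traj, scn, n_replicate_wells = 10, seed = 1)
  df <- as.data.frame(r10)
  df <- df[df$channel == "OD600" & grepl("^spo0A", df$well), ]
  cv <- tapply(df$value, df$time_h, function(v) sd(v) / mean(v))
  expect_true(abs(median(cv) - 0.02) < 0.01)
})

test_that("translation arrest freezes growth and leaves pure reporter decay", {
  scn <- mini_scenario(noise_cv = 0)
  run <- simulate_arrest(scn, t_arrest = 1.0, seed = 1, n_replicate_wells = 1)
  rlu <- plate_series(run, "P1_1", "RLU")
  post <- rlu$time >= 1.0 & rlu$value > 0
  fit <- lm(log(rlu$value[post]) ~ rlu$time[post])
  expect_equal(unname(coef(fit)[2]), -scn$reporter$delta, tolerance = 1e-6)
  od <- plate_series(run, "P1_1", "OD600")
  expect_equal(length(unique(round(od$value[od$time >= 1], 12))), 1)
  # arrest at t = 0 with nothing expressed yet: flat zero light
  r0 <- simulate_arrest(scn, t_arrest = 0, seed = 1, n_replicate_wells = 1)
  expect_equal(max(abs(plate_series(r0, "P1_1", "RLU")$value)), 0)
  expect_error(simulate_arrest(scn, t_arrest = 99), "outside")
})

test_that("scenario files round-trip and reject unknown keys", {
  path <- system.file("extdata", "dsm.yaml", package = "luxrate")
  scn <- read_scenario(path)
  expect_s3_class(scn, "scenario")
  expect_named(scn$promoters, c("spo0A", "rrnB", "abrB", "spoIIG", "comK"))
  expect_equal(scn$reporter$half_life, 0.1)
  expect_equal(scn$sampling_interval, 0.025)
  raw <- yaml::read_yaml(path)
  raw$typo_field <- 1
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, tmp)
  expect_error(read_scenario(tmp), "typo_field")
  raw$typo_field <- NULL
  raw$reporter$halflife <- 0.2   # misspelled key must not be ignored
  yaml::write_yaml(raw, tmp)
  expect_error(read_scenario(tmp), "halflife")
})

test_that("scenario invariants are enforced", {
  expect_error(rnap_params(f_max = 1.2), "f_max")
  expect_error(reporter_spec(half_life = 0), "half_life")
  expect_error(medium_spec(data.frame(name = "a", conc = -1, mu_max = 1,
                                      K_s = 0.1, yield = 0.5)), ">= 0")
  expect_error(medium_spec(data.frame(name = "a", conc = 1, mu_max = 1,
                                      K_s = 0.1, yield = 0.5),
                           repression_order = c("a", "b")), "permutation")
})
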