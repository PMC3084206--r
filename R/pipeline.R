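#' Analyze a plate run into growth-rate and activity series
#'
#' Blank-corrects the run, averages replicate wells per strain (group),
#' then derives the growth rate from ln OD and the promoter activity from
#' the luminescence channel for every group.
#'
#' @param run a `plate_table` (e.g. from [render_plate_run()] or
#'   [read_plate_csv()]).
#' @param delta reporter degradation rate (1/h); required for the
#'   deconvolved estimator.
#' @param estimator `"deconvolved"` (default) or `"naive"`.
#' @param window,degree Savitzky-Golay parameters (defaults 11 points,
#'   degree 2).
#' @param group_map optional well grouping, see [align_replicates()].
#' @param od_floor floor for blank-corrected OD.
#' @return an object of class `run_analysis`: list with `groups` (per
#'   group: `time`, `od`, `rlu`, `mu` [`smoothed_series`], `activity`
#'   [`activity_estimate`]) and the parameters used.
#' @export
analyze_plate_run <- function(run, delta = NULL,
                              estimator = c("deconvolved", "naive"),
                              window = 11, degree = 2, group_map = NULL,
                              od_floor = 1e-4) {
  estimator <- match.arg(estimator)
  if (estimator == "deconvolved" && (is.null(delta) || !is.finite(delta) || delta <= 0))
    stop_config("estimator 'deconvolved' needs the reporter decay rate delta > 0 (half_life)")
  meta <- plate_meta(run)
  corrected <- if (isTRUE(meta$blank_corrected)) run else blank_correct(run, od_floor = od_floor)
  reps <- align_replicates(corrected, group_map)
  groups <- list()
  for (g in unique(reps$group)) {
    od <- reps[reps$group == g & reps$channel == "OD600", ]
    rlu <- reps[reps$group == g & reps$channel == "RLU", ]
    od_s <- data.frame(time = od$time, value = od$mean)
    rlu_s <- data.frame(time = rlu$time, value = rlu$mean)
    mu <- growth_rate(od_s, window, degree)
    act <- if (estimator == "deconvolved")
      activity_deconvolved(rlu_s, od_s, delta, window, degree)
    else activity_naive(rlu_s, od_s)
    groups[[g]] <- list(time = od_s$time, od = od_s, rlu = rlu_s,
                        mu = mu, activity = act)
  }
  # pooled growth rate: the growth curve is a property of the culture and
  # is shared by all strains, so every OD well informs one mu-hat estimate
  od_df <- as.data.frame(corrected)
  od_df <- od_df[od_df$channel == "OD600", ]
  od_pool <- tapply(od_df$value, od_df$time_h, mean)
  od_pool_s <- data.frame(time = as.numeric(names(od_pool)),
                          value = as.numeric(od_pool))
  od_pool_s <- od_pool_s[order(od_pool_s$time), ]
  mu_pool <- growth_rate(od_pool_s, window, degree)
  structure(list(groups = groups,
                 pooled = list(od = od_pool_s, mu = mu_pool),
                 params = list(estimator = estimator, delta = delta,
                               window = window, degree = degree)),
            class = "run_analysis")
}

#' Event report: pauses, bursts, pairing, phase, correlations
#'
#' Runs the event-detection battery on an analyzed run: T0 from the growth
#' rate, growth-rate pauses (including the terminal arrest at T0), bursts
#' per activity channel, greedy pause/burst pairing, the phase offset over
#' the growth window, and the correlation signs of every channel with the
#' growth rate.
#'
#' @param analysis a `run_analysis` from [analyze_plate_run()].
#' @param channel channel for burst pairing and phase (default
#'   `"spo0A"` if present, else the first group).
#' @param min_depth,min_width pause-detection parameters.
#' @param min_prominence burst-detection prominence threshold.
#' @param max_lag pairing window, h.
#' @param phase_window `c(from, to)` for the phase statistic; default
#'   `c(0.5, T0)`.
#' @return an object of class `event_report`: list with `T0`, `pauses`,
#'   `bursts` (per channel), `pairs`, `phase`, `correlations`.
#' @export
events_report <- function(analysis, channel = NULL, min_depth = 0.2,
                          min_width = 0.1, min_prominence = 0.15,
                          max_lag = 0.3, phase_window = NULL) {
  stopifnot(inherits(analysis, "run_analysis"))
  groups <- analysis$groups
  channel <- channel %||% if ("spo0A" %in% names(groups)) "spo0A" else names(groups)[1]
  if (!channel %in% names(groups))
    stop_config("channel '%s' not among analyzed groups", channel)
  mu <- analysis$pooled$mu %||% groups[[channel]]$mu
  T0 <- tryCatch(define_T0(mu), error = function(e) NA_real_)
  pauses <- detect_pauses(mu, min_depth, min_width,
                          before = if (is.finite(T0)) T0 + 0.2,
                          include_terminal = TRUE)
  bursts <- lapply(groups, function(g)
    detect_bursts(g$activity, min_prominence = min_prominence))
  pairs <- match_events(pauses, bursts[[channel]], max_lag = max_lag)
  # growth window for phase/correlation: ends at the terminal growth arrest
  # (more stable under noise than the 20-sample T0 rule), else at T0
  t_end <- if (any(pauses$terminal)) min(pauses$time[pauses$terminal])
           else if (is.finite(T0)) T0
  window <- phase_window %||% if (!is.null(t_end)) c(0.5, t_end)
  phase <- tryCatch(
    phase_offset(mu, groups[[channel]]$activity, window = window, T0 = T0),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "phase_report"))
  acts <- lapply(groups, `[[`, "activity")
  corr <- correlation_signs(mu, acts, window = window)
  structure(list(T0 = T0, channel = channel, pauses = pauses,
                 bursts = bursts, pairs = pairs, phase = phase,
                 correlations = corr),
            class = "event_report")
}

#' Developmental-response report for an analyzed run
#'
#' Drives the stochastic competence-transition model with the comK-channel
#' activity and reports cumulative transitioned fractions (with exact
#' binomial intervals) at the query times.
#'
#' @param analysis a `run_analysis`.
#' @param model a [transition_model()]; `K_c` is on the analysis activity
#'   scale (RLU/OD units per hour).
#' @param channel activity channel driving the hazard (default `"comK"`).
#' @param n_cells cells simulated.
#' @param seed RNG seed.
#' @param query_times report times, h.
#' @return list with `counts` (data frame `time`, `transitioned`,
#'   `fraction`, `freq_percent`, `lower`, `upper`) and the model used.
#' @export
response_report <- function(analysis, model, channel = "comK",
                            n_cells = 20000, seed = 1,
                            query_times = c(0.65, 3.4)) {
  stopifnot(inherits(analysis, "run_analysis"))
  if (!channel %in% names(analysis$groups))
    stop_config("channel '%s' not among analyzed groups", channel)
  act <- analysis$groups[[channel]]$activity
  sim <- simulate_transitions(data.frame(time = act$time, value = act$value),
                              model, n_cells, seed, query_times)
  cc <- sim$counts
  ci <- lapply(cc$transitioned, event_frequency, total = n_cells)
  cc$freq_percent <- vapply(ci, `[[`, 0, "frequency")
  cc$lower <- vapply(ci, `[[`, 0, "lower")
  cc$upper <- vapply(ci, `[[`, 0, "upper")
  list(counts = cc, model = model, channel = channel, n_cells = n_cells,
       seed = seed)
}

pipeline_schema <- c("scenario", "seed", "wells", "estimator", "window",
                     "degree", "half_life", "channel", "min_depth",
                     "min_width", "min_prominence", "max_lag", "transitions",
                     "arrest_at", "stages")
transitions_schema <- c("channel", "lambda0", "m", "K_c", "n_cells",
                        "query_times")

#' Run the full simulate-analyze-events-response pipeline
#'
#' Executes the requested stages in order and writes plain-text artefacts
#' to `out_dir`: the plate run (`plate_run.csv` + metadata sidecar), the
#' analysis (`analysis.json`), the event report (`events.json`), the
#' developmental response (`response.json`), and a run manifest
#' (`manifest.json`) recording the command, configuration hash, seed and
#' package version.  Identical configuration and seed give identical
#' outputs.
#'
#' @param config path to a YAML/JSON configuration file, or an equivalent
#'   named list.  Fields: `scenario` (path to a scenario file, or `"dsm"`
#'   for the bundled scenario, or an inline scenario object), `seed`,
#'   `wells` (replicate wells per strain), `estimator`, `window`,
#'   `degree`, `half_life` (h; defaults to the scenario reporter's),
#'   `channel`, detection parameters, and `transitions` (hazard-model
#'   settings).  Unknown fields are rejected.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config) && length(config) == 1) {
    ext <- tolower(tools::file_ext(config))
    if (ext %in% c("yaml", "yml")) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  } else config
  bad <- setdiff(names(cfg), pipeline_schema)
  if (length(bad))
    stop_config("unknown configuration field(s): %s", paste(bad, collapse = ", "))
  if (!is.null(cfg$transitions)) {
    badt <- setdiff(names(cfg$transitions), transitions_schema)
    if (length(badt))
      stop_config("unknown configuration field(s): transitions.%s",
                  paste(badt, collapse = ", "))
  }
  scn <- cfg$scenario %||% "dsm"
  scn <- if (inherits(scn, "scenario")) scn
         else if (identical(scn, "dsm")) dsm_scenario()
         else if (is.character(scn)) read_scenario(scn)
         else scenario_from_list(scn)
  seed <- cfg$seed %||% 1
  estimator <- cfg$estimator %||% "deconvolved"
  half_life <- cfg$half_life %||% scn$reporter$half_life
  if (estimator == "deconvolved" && (is.null(half_life) || half_life <= 0))
    stop_config("configuration field 'half_life' required (> 0) for estimator=deconvolved")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  t_start <- Sys.time()
  traj <- simulate_diauxic_growth(scn)
  run <- if (!is.null(cfg$arrest_at))
    simulate_arrest(scn, cfg$arrest_at, seed = seed,
                    n_replicate_wells = cfg$wells %||% 2)
  else render_plate_run(traj, scn, n_replicate_wells = cfg$wells %||% 2,
                        seed = seed)
  write_plate_csv(run, file.path(out_dir, "plate_run.csv"))

  analysis <- analyze_plate_run(run, delta = log(2) / half_life,
                                estimator = estimator,
                                window = cfg$window %||% 11,
                                degree = cfg$degree %||% 2)
  jsonlite::write_json(
    lapply(analysis$groups, function(g)
      list(time = g$time, mu = g$mu$value, activity = g$activity$value)),
    file.path(out_dir, "analysis.json"), auto_unbox = TRUE, digits = NA)

  events <- events_report(analysis, channel = cfg$channel,
                          min_depth = cfg$min_depth %||% 0.2,
                          min_width = cfg$min_width %||% 0.1,
                          min_prominence = cfg$min_prominence %||% 0.15,
                          max_lag = cfg$max_lag %||% 0.3)
  jsonlite::write_json(
    list(T0 = events$T0, channel = events$channel,
         pauses = events$pauses,
         bursts = lapply(events$bursts, function(b) as.data.frame(b)),
         pairs = events$pairs$pairs,
         unmatched_bursts = events$pairs$unmatched_bursts,
         phase = unclass(events$phase)[c("period", "lag", "phase", "r")],
         correlations = as.list(events$correlations)),
    file.path(out_dir, "events.json"), auto_unbox = TRUE, digits = NA,
    null = "null")

  response <- NULL
  tr <- cfg$transitions
  if (!is.null(tr) || "comK" %in% names(analysis$groups)) {
    tr <- tr %||% list()
    model <- transition_model(lambda0 = tr$lambda0 %||% 0.001,
                              m = tr$m %||% 6,
                              K_c = tr$K_c %||% 12000)
    response <- response_report(analysis, model,
                                channel = tr$channel %||% "comK",
                                n_cells = tr$n_cells %||% 20000, seed = seed,
                                query_times = unlist(tr$query_times) %||% c(0.65, 3.4))
    jsonlite::write_json(
      list(model = unclass(model), channel = response$channel,
           n_cells = response$n_cells, counts = response$counts),
      file.path(out_dir, "response.json"), auto_unbox = TRUE, digits = NA)
  }

  cfg_path <- file.path(out_dir, "config_echo.json")
  cfg_clean <- cfg
  if (inherits(cfg_clean$scenario, "scenario"))
    cfg_clean$scenario <- cfg_clean$scenario$name
  jsonlite::write_json(cfg_clean, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(command = "run_pipeline",
                   config_hash = unname(tools::md5sum(cfg_path)),
                   scenario = scn$name, seed = seed,
                   package_version = as.character(utils::packageVersion("luxrate")),
                   outputs = c("plate_run.csv", "analysis.json", "events.json",
                               if (!is.null(response)) "response.json"),
                   elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                                   units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(scenario = scn, trajectory = traj, run = run,
                 analysis = analysis, events = events, response = response,
                 manifest = manifest))
}
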