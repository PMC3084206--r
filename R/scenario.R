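#' @importFrom stats approxfun coef cor lm median qbeta quantile rexp rlnorm
#'   sd
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Growth-medium specification for batch-culture simulation
#'
#' Describes the carbon sources available to a batch culture, their Monod
#' growth parameters, and the catabolite-repression hierarchy that makes
#' growth on mixed substrates diauxic.  Secondary substrates are only used
#' after every preferred substrate is exhausted; the switch is not
#' instantaneous but governed by an induction variable with rate
#' `induction_rate`, so the diauxic pause has finite width.
#'
#' @param substrates data frame with columns `name`, `conc` (initial
#'   concentration, mg/ml), `mu_max` (maximal growth rate on that substrate,
#'   1/h), `K_s` (Monod half-saturation, mg/ml) and `yield` (OD units of
#'   biomass per mg/ml consumed).
#' @param repression_order character vector: a permutation of the substrate
#'   names, most-preferred first.  Defaults to the row order of `substrates`.
#' @param induction_rate rate (1/h) at which utilisation of a secondary
#'   substrate is induced once all preferred substrates are exhausted.
#' @param decay_rate decay rate (1/h) of the induction variable.
#' @param switch_conc concentration scale (mg/ml) below which a substrate
#'   counts as exhausted for the purpose of inducing the next one.
#' @return an object of class `medium_spec`.
#' @export
medium_spec <- function(substrates, repression_order = NULL,
                        induction_rate = 20, decay_rate = 0,
                        switch_conc = 0.01) {
  substrates <- as.data.frame(substrates)
  need <- c("name", "conc", "mu_max", "K_s", "yield")
  if (!all(need %in% names(substrates)))
    stop_config("substrates must have columns: %s", paste(need, collapse = ", "))
  num <- substrates[c("conc", "mu_max", "K_s", "yield")]
  if (any(!is.finite(as.matrix(num))) || any(as.matrix(num) < 0))
    stop_config("substrate concentrations and rates must be finite and >= 0")
  if (is.null(repression_order)) repression_order <- as.character(substrates$name)
  if (!setequal(repression_order, substrates$name) ||
      length(repression_order) != nrow(substrates))
    stop_config("repression_order must be a permutation of the substrate names")
  if (induction_rate < 0 || decay_rate < 0 || switch_conc <= 0)
    stop_config("induction_rate, decay_rate must be >= 0 and switch_conc > 0")
  structure(list(substrates = substrates,
                 repression_order = as.character(repression_order),
                 induction_rate = induction_rate, decay_rate = decay_rate,
                 switch_conc = switch_conc),
            class = "medium_spec")
}

#' RNA-polymerase allocation parameters
#'
#' Under passive regulation, the fraction of RNA polymerase committed to
#' rRNA synthesis rises with growth rate as
#' \eqn{f_{rrn}(\mu) = f_{max}\,\mu/(\mu + K_\mu)}; the remainder
#' \eqn{R_{free} = R_{total}(1 - f_{rrn})} is available to housekeeping
#' promoters.  A growth pause therefore releases polymerase and transiently
#' boosts the activity of polymerase-limited promoters.
#'
#' @param f_max maximal rRNA-committed fraction, in (0, 1).
#' @param K_mu growth rate (1/h) at which half of `f_max` is committed.
#' @param R_total total polymerase pool (arbitrary units).
#' @return an object of class `rnap_params`.
#' @export
rnap_params <- function(f_max = 0.8, K_mu = 0.2, R_total = 1) {
  if (!(f_max > 0 && f_max < 1)) stop_config("f_max must lie in (0, 1)")
  if (K_mu <= 0) stop_config("K_mu must be > 0")
  if (R_total <= 0) stop_config("R_total must be > 0")
  structure(list(f_max = f_max, K_mu = K_mu, R_total = R_total),
            class = "rnap_params")
}

promoter_classes <- c("constitutive", "rrn_like", "repressed", "activated")

#' Promoter specification
#'
#' Four promoter classes are supported.  `constitutive` promoters are
#' limited by free polymerase (Monod form in `R_free` with half-saturation
#' `K_R`); `rrn_like` promoters follow the rRNA-committed fraction and hence
#' track the growth rate; `repressed` promoters are constitutive promoters
#' multiplied by a repressive Hill function of Spo0A~P; `activated`
#' promoters follow an activating Hill function of Spo0A~P.  Promoters whose
#' transcript initiates with G are additionally sensitive to the GTP pool:
#' their activity is scaled by a saturating function of the pool factor,
#' normalised to 1 when the pool is full.
#'
#' @param name promoter label (used as the channel name throughout).
#' @param class one of `"constitutive"`, `"rrn_like"`, `"repressed"`,
#'   `"activated"`.
#' @param strength maximal activity (arbitrary units/h), >= 0.
#' @param K_R free-polymerase half-saturation (same units as `R_total`).
#' @param initiating_nucleotide `"A"` (GTP-insensitive) or `"G"`.
#' @param intp_K half-saturation of the GTP-pool factor (only used when
#'   `initiating_nucleotide == "G"`); must be > 0.
#' @param regulator_K Spo0A~P level at half response (repressed/activated).
#' @param hill_n Hill coefficient, >= 1 (repressed/activated).
#' @return an object of class `promoter_spec`.
#' @export
promoter_spec <- function(name, class, strength, K_R = 0.5,
                          initiating_nucleotide = "A", intp_K = 0.3,
                          regulator_K = NULL, hill_n = 1) {
  if (!class %in% promoter_classes)
    stop_config("unknown promoter class '%s' (promoter '%s')", class, name)
  if (strength < 0) stop_config("promoter strength must be >= 0")
  if (!initiating_nucleotide %in% c("A", "G"))
    stop_config("initiating_nucleotide must be 'A' or 'G'")
  if (intp_K <= 0) stop_config("intp_K must be > 0")
  if (class %in% c("repressed", "activated")) {
    if (is.null(regulator_K) || regulator_K <= 0)
      stop_config("promoter '%s' (%s) needs regulator_K > 0", name, class)
    if (hill_n < 1) stop_config("hill_n must be >= 1")
  }
  structure(list(name = as.character(name), class = class, strength = strength,
                 K_R = K_R, initiating_nucleotide = initiating_nucleotide,
                 intp_K = intp_K, regulator_K = regulator_K, hill_n = hill_n),
            class = "promoter_spec")
}

#' Destabilized-reporter specification
#'
#' The firefly luciferase reporter used here is unstable (half-life about
#' 6 minutes), which is what makes the luminescence signal track the *rate*
#' of transcription rather than its integral.
#'
#' @param half_life reporter half-life in hours (default 0.1 h = 6 min).
#'   The degradation rate is \eqn{\delta = \ln 2 / t_{1/2}}.
#' @param light_coeff RLU emitted per reporter unit.
#' @param maturation_delay delay (h) between synthesis and light emission.
#' @return an object of class `reporter_spec`.
#' @export
reporter_spec <- function(half_life = 0.1, light_coeff = 1000,
                          maturation_delay = 0) {
  if (!is.finite(half_life) || half_life <= 0)
    stop_config("reporter half_life must be > 0")
  if (maturation_delay < 0) stop_config("maturation_delay must be >= 0")
  structure(list(half_life = half_life, light_coeff = light_coeff,
                 maturation_delay = maturation_delay,
                 delta = log(2) / half_life),
            class = "reporter_spec")
}

#' Spo0A synthesis and phosphorylation parameters
#'
#' Spo0A protein is produced in proportion to the activity of a designated
#' source promoter and decays at rate `gamma_P`; phosphorylation by the
#' phosphorelay proceeds at `k_phos` times a kinase-availability profile
#' `kappa(t)` and is reversed at `k_deph`.
#'
#' @param source name of the promoter whose activity drives Spo0A synthesis.
#' @param gamma_P protein decay/dilution rate, 1/h.
#' @param k_phos phosphorylation rate constant, 1/h.
#' @param k_deph dephosphorylation rate, 1/h.
#' @param kappa either a single number (constant kinase availability) or a
#'   data frame `time`, `value` interpolated linearly.
#' @return an object of class `spo0a_params`.
#' @export
spo0a_params <- function(source = "spo0A", gamma_P = 0.7, k_phos = 0.4,
                         k_deph = 1.0, kappa = 1) {
  if (any(c(gamma_P, k_phos, k_deph) < 0))
    stop_config("spo0A rate constants must be >= 0")
  structure(list(source = source, gamma_P = gamma_P, k_phos = k_phos,
                 k_deph = k_deph, kappa = kappa),
            class = "spo0a_params")
}

#' Assemble a simulation scenario
#'
#' A scenario bundles everything needed to generate a ground-truth
#' trajectory and a synthetic plate-reader run: the medium, the polymerase
#' allocation model, the promoters carried by the (virtual) reporter
#' strains, the reporter kinetics, a GTP-pool dip schedule, a scripted
#' stationary-phase activation program, and the measurement layer
#' (sampling grid, noise, optical-density background).
#'
#' @param medium a [medium_spec()].
#' @param rnap an [rnap_params()].
#' @param promoters list of [promoter_spec()] objects (unique names).
#' @param reporter a [reporter_spec()].
#' @param spo0a a [spo0a_params()]; `NULL` disables the Spo0A~P layer.
#' @param gtp_dip_schedule data frame `start`, `end`, `depth` (fraction in
#'   \[0,1\]); the GTP-pool factor is 1 minus the sum of active depths.
#' @param stationary_program data frame `time`, `step`, `promoter`:
#'   additive activity steps (units/h, may be negative) applied to a
#'   promoter from `time` onwards; used to script the stationary-phase
#'   transcription waves that are not mechanistically modelled.
#' @param x0 initial biomass (OD units).
#' @param duration run length, h.
#' @param sampling_interval sampling grid spacing, h (default 0.025 h =
#'   1.5 min, the plate-reader cadence).
#' @param noise_cv fractional multiplicative measurement noise per reading.
#' @param od_background additive OD background (read in blank wells).
#' @param name scenario label recorded in run metadata.
#' @return an object of class `scenario`.
#' @export
scenario <- function(medium, rnap, promoters, reporter,
                     spo0a = NULL, gtp_dip_schedule = NULL,
                     stationary_program = NULL, x0 = 0.05, duration = 7,
                     sampling_interval = 0.025, noise_cv = 0.02,
                     od_background = 0.04, name = "scenario") {
  stopifnot(inherits(medium, "medium_spec"), inherits(rnap, "rnap_params"),
            inherits(reporter, "reporter_spec"))
  if (!length(promoters) || !all(vapply(promoters, inherits, TRUE, "promoter_spec")))
    stop_config("promoters must be a non-empty list of promoter_spec objects")
  nm <- vapply(promoters, `[[`, "", "name")
  if (anyDuplicated(nm)) stop_config("duplicate promoter names: %s",
                                     paste(nm[duplicated(nm)], collapse = ", "))
  names(promoters) <- nm
  if (sampling_interval <= 0) stop_config("sampling_interval must be > 0")
  if (noise_cv < 0) stop_config("noise_cv must be >= 0")
  if (x0 <= 0 || duration <= 0) stop_config("x0 and duration must be > 0")
  if (!is.null(gtp_dip_schedule)) {
    gtp_dip_schedule <- as.data.frame(gtp_dip_schedule)
    if (!all(c("start", "end", "depth") %in% names(gtp_dip_schedule)))
      stop_config("gtp_dip_schedule needs columns start, end, depth")
    if (any(gtp_dip_schedule$depth < 0 | gtp_dip_schedule$depth > 1))
      stop_config("gtp dip depth must lie in [0, 1]")
  }
  if (!is.null(stationary_program)) {
    stationary_program <- as.data.frame(stationary_program)
    if (!all(c("time", "step", "promoter") %in% names(stationary_program)))
      stop_config("stationary_program needs columns time, step, promoter")
    bad <- setdiff(stationary_program$promoter, nm)
    if (length(bad)) stop_config("stationary_program targets unknown promoter: %s",
                                 paste(bad, collapse = ", "))
  }
  if (!is.null(spo0a)) {
    stopifnot(inherits(spo0a, "spo0a_params"))
    if (!spo0a$source %in% nm)
      stop_config("spo0a source promoter '%s' not in scenario", spo0a$source)
  }
  structure(list(medium = medium, rnap = rnap, promoters = promoters,
                 reporter = reporter, spo0a = spo0a,
                 gtp_dip_schedule = gtp_dip_schedule,
                 stationary_program = stationary_program,
                 x0 = x0, duration = duration,
                 sampling_interval = sampling_interval,
                 noise_cv = noise_cv, od_background = od_background,
                 name = name),
            class = "scenario")
}

# ---- scenario files ---------------------------------------------------------

scenario_schema <- list(
  top = c("name", "medium", "rnap", "promoters", "reporter", "spo0a",
          "gtp_dip_schedule", "stationary_program", "x0", "duration",
          "sampling_interval", "noise_cv", "od_background"),
  medium = c("substrates", "repression_order", "induction_rate", "decay_rate",
             "switch_conc"),
  substrate = c("name", "conc", "mu_max", "K_s", "yield"),
  rnap = c("f_max", "K_mu", "R_total"),
  promoter = c("name", "class", "strength", "K_R", "initiating_nucleotide",
               "intp_K", "regulator_K", "hill_n"),
  reporter = c("half_life", "light_coeff", "maturation_delay"),
  spo0a = c("source", "gamma_P", "k_phos", "k_deph", "kappa"),
  dip = c("start", "end", "depth"),
  step = c("time", "step", "promoter")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop_config("unknown key(s) in %s: %s", where, paste(extra, collapse = ", "))
  x
}

#' Read a scenario from a YAML or JSON file
#'
#' Files must follow the scenario schema; unknown keys are rejected so that
#' typos do not silently fall back to defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return a validated [scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop_config("scenario file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop_config("unsupported scenario format: .%s", ext)
  scenario_from_list(raw)
}

rows_to_df <- function(x) {
  if (is.data.frame(x)) x else do.call(rbind, lapply(x, as.data.frame))
}

scenario_from_list <- function(raw) {
  check_keys(raw, scenario_schema$top, "scenario")
  med <- check_keys(raw$medium, scenario_schema$medium, "medium")
  subs <- lapply(if (is.data.frame(med$substrates))
                   split(med$substrates, seq_len(nrow(med$substrates)))
                 else med$substrates,
                 check_keys, scenario_schema$substrate, "substrate")
  medium <- medium_spec(rows_to_df(subs),
                        repression_order = unlist(med$repression_order),
                        induction_rate = med$induction_rate %||% 20,
                        decay_rate = med$decay_rate %||% 0,
                        switch_conc = med$switch_conc %||% 0.01)
  rn <- check_keys(raw$rnap %||% list(), scenario_schema$rnap, "rnap")
  rnap <- do.call(rnap_params, rn)
  promoters <- lapply(if (is.data.frame(raw$promoters))
                        split(raw$promoters, seq_len(nrow(raw$promoters)))
                      else raw$promoters, function(p) {
    p <- check_keys(as.list(p), scenario_schema$promoter, "promoter")
    p <- p[!vapply(p, function(v) is.atomic(v) && length(v) == 1 && is.na(v), TRUE)]
    do.call(promoter_spec, p)
  })
  rep_ <- check_keys(raw$reporter %||% list(), scenario_schema$reporter, "reporter")
  reporter <- do.call(reporter_spec, rep_)
  spo0a <- if (!is.null(raw$spo0a)) {
    sp <- check_keys(raw$spo0a, scenario_schema$spo0a, "spo0a")
    do.call(spo0a_params, sp)
  }
  dips <- if (!is.null(raw$gtp_dip_schedule)) {
    d <- lapply(if (is.data.frame(raw$gtp_dip_schedule))
                  split(raw$gtp_dip_schedule, seq_len(nrow(raw$gtp_dip_schedule)))
                else raw$gtp_dip_schedule,
                check_keys, scenario_schema$dip, "gtp_dip_schedule")
    rows_to_df(d)
  }
  prog <- if (!is.null(raw$stationary_program)) {
    s <- lapply(if (is.data.frame(raw$stationary_program))
                  split(raw$stationary_program, seq_len(nrow(raw$stationary_program)))
                else raw$stationary_program,
                check_keys, scenario_schema$step, "stationary_program")
    rows_to_df(s)
  }
  scenario(medium = medium, rnap = rnap, promoters = promoters,
           reporter = reporter, spo0a = spo0a, gtp_dip_schedule = dips,
           stationary_program = prog,
           x0 = raw$x0 %||% 0.05, duration = raw$duration %||% 7,
           sampling_interval = raw$sampling_interval %||% 0.025,
           noise_cv = raw$noise_cv %||% 0.02,
           od_background = raw$od_background %||% 0.04,
           name = raw$name %||% "scenario")
}

#' Two-sugar diauxie scenario (minimal medium, glucose + arabinose)
#'
#' Builds the classic diauxie setup: cells grow fast on glucose, pause
#' when it is exhausted while arabinose utilisation is induced, then
#' resume at a lower rate.  The single reporter strain carries the
#' polymerase-limited spo0A-like vegetative promoter, which bursts during
#' the pause.  Raising the glucose share moves the pause later; with
#' glucose only there is no pause at all.
#'
#' @param glucose glucose concentration, mg/ml (default 0.5).
#' @param arabinose arabinose concentration, mg/ml (default 2.0).
#' @param duration run length, h.
#' @param noise_cv measurement noise CV (default 0: ground-truth runs).
#' @param ... further fields passed to [scenario()].
#' @return a [scenario()].
#' @export
diauxie_scenario <- function(glucose = 0.5, arabinose = 2.0, duration = 8,
                             noise_cv = 0, ...) {
  subs <- data.frame(name = c("glucose", "arabinose"),
                     conc = c(glucose, arabinose),
                     mu_max = c(1.2, 0.7), K_s = c(0.02, 0.05),
                     yield = c(0.45, 0.35))
  subs <- subs[subs$conc > 0, ]
  scenario(
    medium = medium_spec(subs, induction_rate = 6, switch_conc = 0.002),
    rnap = rnap_params(f_max = 0.9, K_mu = 0.2, R_total = 1),
    promoters = list(promoter_spec("spo0A", "constitutive", strength = 100,
                                   K_R = 0.3)),
    reporter = reporter_spec(),
    x0 = 0.02, duration = duration, noise_cv = noise_cv,
    name = sprintf("diauxie_glc%.2g_ara%.2g", glucose, arabinose), ...)
}

#' The bundled sporulation-medium (DSM) scenario
#'
#' Loads the packaged scenario that reproduces the canonical behaviour of a
#' *Bacillus subtilis* culture entering sporulation in DSM: three
#' sequentially exhausted nutrients give two diauxic growth-rate pauses and
#' a final arrest at the entry to stationary phase (T0); the spo0A-like
#' vegetative promoter, being polymerase-limited, bursts at each pause,
#' and a scripted stationary-phase program adds the three post-T0
#' transcription waves, the last one the strongest.
#'
#' @param ... fields overriding the packaged values (e.g. `noise_cv = 0`).
#' @return a [scenario()].
#' @export
dsm_scenario <- function(...) {
  path <- system.file("extdata", "dsm.yaml", package = "luxrate", mustWork = TRUE)
  sc <- read_scenario(path)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), scenario_schema$top)
    if (length(bad)) stop_config("unknown scenario field(s): %s",
                                 paste(bad, collapse = ", "))
    for (f in names(over)) sc[[f]] <- over[[f]]
  }
  sc
}
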