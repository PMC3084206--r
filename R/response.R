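#' Hill-type response of a Spo0A~P target promoter
#'
#' Spo0A~P acts on its targets with a hierarchy set by DNA-binding
#' affinity: high-affinity operators (low `K`, e.g. the abrB operator)
#' respond at low Spo0A~P, low-affinity ones (e.g. the spoIIG promoter)
#' only at high Spo0A~P.  The response is returned as a multiplicative
#' factor on the promoter's basal activity: repression
#' \eqn{1/(1 + (Sp/K)^n)}, activation \eqn{Sp^n/(K^n + Sp^n)}.
#'
#' @param spo0A_P Spo0A~P series (numeric vector, arbitrary units).
#' @param mode `"repressed"` or `"activated"`.
#' @param K half-maximal Spo0A~P level, > 0.
#' @param hill_n Hill coefficient, >= 1.
#' @return numeric vector of response factors in \[0, 1\].
#' @export
target_response <- function(spo0A_P, mode = c("repressed", "activated"),
                            K, hill_n = 1) {
  mode <- match.arg(mode)
  if (K <= 0) stop_config("K must be > 0")
  if (hill_n < 1) stop_config("hill_n must be >= 1")
  x <- (pmax(spo0A_P, 0) / K)^hill_n
  if (mode == "repressed") 1 / (1 + x) else x / (1 + x)
}

#' Transition-hazard model for rare developmental switches
#'
#' Cells switch to competence stochastically; the per-cell hazard grows
#' with the comK expression level relative to the switching threshold:
#' \eqn{\lambda(t) = \lambda_0\,(A(t)/K_c)^m}.  Bursts of comK expression
#' bring the average cell closer to the threshold and transiently raise
#' the hazard.
#'
#' @param lambda0 hazard scale, 1/h (>= 0).
#' @param m threshold-proximity exponent, >= 1.
#' @param K_c threshold activity, > 0.
#' @return an object of class `transition_model`.
#' @export
transition_model <- function(lambda0, m = 1, K_c = 1) {
  if (lambda0 < 0) stop_config("lambda0 must be >= 0")
  if (m < 1) stop_config("m must be >= 1")
  if (K_c <= 0) stop_config("K_c must be > 0")
  structure(list(lambda0 = lambda0, m = m, K_c = K_c),
            class = "transition_model")
}

#' Simulate stochastic transitions to competence
#'
#' Samples, for each of `n_cells` cells, the first event of an
#' inhomogeneous Poisson process with hazard
#' \eqn{\lambda(t) = \lambda_0 (A(t)/K_c)^m} driven by the comK-channel
#' activity, via the inverse cumulative-hazard method (one exponential
#' deviate per cell, transition when the integrated hazard first exceeds
#' it).  Deterministic for a fixed seed.
#'
#' @param comk_rate data frame `time`, `value`: comK-channel activity.
#' @param model a [transition_model()].
#' @param n_cells number of cells (>= 1).
#' @param seed RNG seed.
#' @param query_times times at which to report cumulative transitioned
#'   counts (default: the series grid ends).
#' @return list with `transition_times` (finite times only, sorted) and
#'   `counts`: data frame `time`, `transitioned`, `fraction`.
#' @export
simulate_transitions <- function(comk_rate, model, n_cells, seed = 1,
                                 query_times = NULL) {
  stopifnot(inherits(model, "transition_model"))
  if (n_cells < 1) stop_config("n_cells must be >= 1")
  s <- as_series(comk_rate)
  lam <- model$lambda0 * (pmax(s$value, 0) / model$K_c)^model$m
  n <- nrow(s)
  # cumulative hazard, trapezoidal
  Lam <- c(0, cumsum((lam[-1] + lam[-n]) / 2 * diff(s$time)))
  set.seed(seed)
  u <- stats::rexp(n_cells)
  # first grid time at which the integrated hazard reaches the deviate
  idx <- findInterval(u, Lam, left.open = TRUE) + 1
  tt <- ifelse(idx > n | u > Lam[n], NA_real_, s$time[pmin(idx, n)])
  query_times <- query_times %||% s$time[n]
  counts <- data.frame(time = query_times,
                       transitioned = vapply(query_times, function(q)
                         sum(!is.na(tt) & tt <= q), 0L))
  counts$fraction <- counts$transitioned / n_cells
  list(transition_times = sort(tt[!is.na(tt)]), counts = counts)
}

#' Frequency of a rare event with an exact binomial confidence interval
#'
#' Point estimate `100 * positives / total` (percent) with a
#' Clopper-Pearson interval.  With zero positives the lower bound is 0 and
#' a one-sided upper bound is returned (which reproduces the rule of
#' three, 3/n, for small alpha).
#'
#' @param positives number of positive cells/colonies.
#' @param total number examined (> 0).
#' @param conf_level confidence level (default 0.95).
#' @return list with `frequency` (percent), `lower`, `upper` (percent),
#'   `positives`, `total`, `conf_level`.
#' @export
event_frequency <- function(positives, total, conf_level = 0.95) {
  if (total <= 0) stop_config("total must be > 0")
  if (positives < 0 || positives > total)
    stop_config("positives must lie in [0, total]")
  alpha <- 1 - conf_level
  if (positives == 0) {
    lower <- 0
    upper <- 1 - alpha^(1 / total)          # one-sided exact upper bound
  } else if (positives == total) {
    lower <- alpha^(1 / total)
    upper <- 1
  } else {
    lower <- qbeta(alpha / 2, positives, total - positives + 1)
    upper <- qbeta(1 - alpha / 2, positives + 1, total - positives)
  }
  list(frequency = 100 * positives / total,
       lower = 100 * lower, upper = 100 * upper,
       positives = positives, total = total, conf_level = conf_level)
}

#' Sporulation frequency from plate counts
#'
#' Heat-resistant (spore) counts divided by total viable counts, as a
#' percentage.  If spores exceed viable cells a warning flags a likely
#' count inversion but the value is still returned.
#'
#' @param spores_per_ml heat-resistant count per ml.
#' @param viable_per_ml total viable count per ml (> 0).
#' @return frequency in percent.
#' @export
sporulation_frequency <- function(spores_per_ml, viable_per_ml) {
  if (viable_per_ml <= 0) stop_config("viable count must be > 0")
  if (spores_per_ml < 0) stop_config("spore count must be >= 0")
  if (spores_per_ml > viable_per_ml)
    warning("spores exceed viable count; possible count inversion")
  100 * spores_per_ml / viable_per_ml
}

#' Fold change between two frequencies
#'
#' @param freq_a,freq_b frequencies (same units, e.g. percent).
#' @return `freq_a / freq_b`; if `freq_b` is 0, `Inf` with a warning
#'   flagging the infinite fold.
#' @export
fold_change <- function(freq_a, freq_b) {
  if (freq_a < 0 || freq_b < 0) stop_config("frequencies must be >= 0")
  if (freq_b == 0) {
    warning("reference frequency is 0: fold change is infinite")
    return(Inf)
  }
  freq_a / freq_b
}

#' Molar concentration from a mass concentration
#'
#' @param mass_mg_ml mass concentration, mg/ml (> 0).
#' @param molar_mass_g_mol molar mass, g/mol (> 0).
#' @return concentration in mM (`1000 * mass / molar_mass`).
#' @export
molarity_from_mass_conc <- function(mass_mg_ml, molar_mass_g_mol) {
  if (mass_mg_ml <= 0 || molar_mass_g_mol <= 0)
    stop_config("mass and molar mass must be > 0")
  1000 * mass_mg_ml / molar_mass_g_mol
}

#' Read a count table (microscopy or spore counts)
#'
#' Accepts either the positives layout (`label,positives,total`) or the
#' spore-count layout
#' (`label,viable,spores_12h,spores_24h,spores_48h`).
#'
#' @param path CSV path.
#' @return data frame as read, with the layout recorded in
#'   `attr(, "layout")`.
#' @export
read_count_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, strip.white = TRUE)
  if (all(c("label", "positives", "total") %in% names(df))) {
    attr(df, "layout") <- "positives"
  } else if (all(c("label", "viable") %in% names(df)) &&
             any(grepl("^spores", names(df)))) {
    attr(df, "layout") <- "spores"
  } else stop_config("unrecognised count table layout in %s", path)
  df
}
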