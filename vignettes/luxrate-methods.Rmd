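---
title: "Measuring transcription rates with a destabilized luciferase reporter: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transcription rates with a destabilized luciferase reporter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luxrate)
```

## The measurement problem

A promoter fused to firefly luciferase in *Bacillus subtilis* emits light in
proportion to the amount of active enzyme in the culture.  Because the
enzyme is degraded quickly (half-life $t_{1/2} \approx 6$ min, i.e.
$\delta = \ln 2 / t_{1/2} \approx 6.9\,\mathrm{h^{-1}}$), the enzyme pool
relaxes to the current synthesis rate within minutes, and the luminescence
reading effectively reports the *rate* of transcription.  A stable reporter
such as $\beta$-galactosidase integrates over the past and blurs exactly the
transient features this package is about: short bursts of transcription that
coincide with pauses in growth.

`luxrate` implements the full chain from a generative model of the biology
to the statistics computed from plate-reader data, so that every analysis
stage can be validated against simulated ground truth.

## Reporter model and deconvolution

Let $X(t)$ be biomass (OD units), $a(t)$ the per-cell transcription rate of
the fusion (arbitrary units/h), and $T(t)$ the total reporter pool in the
well.  The package models

$$\frac{dT}{dt} = a(t)\,X(t) - \delta\,T, \qquad
  \mathrm{RLU}(t) = c\,T(t),$$

with $c$ the instrument's light coefficient.  Equivalently, the per-cell
reporter $\ell = T/X$ obeys $d\ell/dt = a - (\delta + \mu)\ell$: degradation
plus dilution by growth.  Including the dilution term is essential for
consistency; with it, the deconvolution estimator

$$\hat a(t) \;=\; \frac{d\mathrm{RLU}/dt + \delta\,\mathrm{RLU}(t)}
  {\mathrm{OD}(t)}$$

inverts the reporter equation *exactly* (up to smoothing error), which is
what the package's oracle-equivalence tests verify: on noiseless simulated
runs `activity_deconvolved()` recovers the simulator's input activity
(times $c$) to a relative RMSE below 5% away from scripted discontinuities.
Without dilution the estimator would carry a bias of order $\mu/\delta$
(about 15% at $\mu = 1\,\mathrm{h^{-1}}$).

The classic readout $\mathrm{RLU}/\mathrm{OD}$ is also provided
(`activity_naive()`); it equals $c\,a/( \delta + \mu)$ in quasi-steady
state and is adequate whenever features are slower than $1/\delta \approx
9$ min.  Every `ActivityEstimate` records which estimator produced it.

Negative deconvolved activities are reported, never clipped: persistent
negative excursions after a signal drop are the signature of an
overestimated $\delta$ and are diagnostically useful.

## Growth model: multi-substrate Monod kinetics with diauxie

Batch growth on a mixture of carbon sources uses

$$\frac{dX}{dt} = \mu X, \quad
  \mu = \sum_i g_i\, \mu_{\max,i}\, \frac{S_i}{K_i + S_i}, \quad
  \frac{dS_i}{dt} = -\frac{\mu_i X}{Y_i},$$

with catabolite repression encoded by gating variables $g_i$: the preferred
substrate has $g = 1$; each secondary substrate is gated by an induction
variable $E_i$ with

$$\frac{dE_i}{dt} = k_{\mathrm{ind}}\, I_i\,(1 - E_i) - k_{\mathrm{dec}} E_i,$$

where $I_i$ is a smooth indicator that all more-preferred substrates are
exhausted ($I_i = \prod_j K_{sw}/(S_j + K_{sw})$ over preferred $j$, with a
small switching scale $K_{sw}$).  The $(1-E_i)$ factor saturates induction
at 1 so that the gated growth rate never exceeds $\mu_{\max,i}$; the finite
induction rate gives the diauxic pause its finite width.  The identity
$d(X + \sum_i Y_i S_i)/dt = 0$ holds exactly in the model, and the
integrator (`deSolve::lsoda`, relative tolerance $10^{-8}$) preserves this
mass balance to $10^{-6}$, which the test suite asserts on every simulated
trajectory.

## Passive regulation: polymerase allocation

During fast growth a major fraction of RNA polymerase is committed to rRNA
synthesis.  The package models the committed fraction as a saturating
function of growth rate,

$$f_{rrn}(\mu) = f_{\max}\,\frac{\mu}{\mu + K_\mu}, \qquad
  R_{\mathrm{free}} = R_{\mathrm{tot}}\,(1 - f_{rrn}),$$

so that a growth pause releases polymerase.  Promoter classes then respond
as:

* **constitutive** (polymerase-limited, e.g. the vegetative spo0A promoter
  or mecA): $a = s\,R_{\mathrm{free}}/(R_{\mathrm{free}} + K_R)$ — these
  inevitably *burst* when growth pauses;
* **rrn-like**: $a = s\,f_{rrn}$ — these *track* the growth rate;
* **repressed** (abrB-like): the constitutive form times a repressive Hill
  function of Spo0A~P;
* **activated** (spoIIG-like): an activating Hill function of Spo0A~P —
  silent until Spo0A~P is high, i.e. until the entry to stationary phase.

Promoters whose transcript initiates with GTP are additionally multiplied
by a saturating function of a GTP-pool factor, normalised to 1 at a replete
pool.  The pool itself is not modelled mechanistically — no nucleotide
kinetics are available to constrain one — instead a scenario can script
dips (`gtp_dip_schedule`); the bundled scenario depresses the pool only
during the first growth pause, which selectively blunts G-initiating
promoters there.

Spo0A synthesis and phosphorylation are a two-stage linear chain driven by
the spo0A-channel activity ($dP/dt = a_{spo0A} - \gamma_P P$;
$dS_p/dt = k_{\mathrm{phos}} P \kappa(t) - k_{\mathrm{deph}} S_p$, with a
configurable kinase-availability profile $\kappa$, constant by default).
The downstream hierarchy is purely a matter of operator affinity: the
abrB-like promoter (low $K$) responds to Spo0A~P before the spoIIG-like
promoter (high $K$) for *any* monotone ramp, which is tested as a property.

## The bundled "dsm" scenario

The packaged scenario (`dsm_scenario()`, stored as
`inst/extdata/dsm.yaml`) represents a sporulation-medium culture:

* three sequentially exhausted nutrients (glucose-like preferred substrate,
  then two lower-$\mu$ "overflow" nutrients) produce two diauxic growth
  pauses at about 1.8 h and 2.8 h and a final growth arrest — T0 — near
  3.6 h;
* the constitutive spo0A-like promoter bursts at both pauses and rises at
  T0; a scripted `stationary_program` of additive activity steps produces
  the third, fourth and fifth transcription waves (at T0, ~20–30 min later,
  and from ~T1 with a sustained rise past T2), the fifth being the global
  maximum;
* the growth-phase burst peaks sit at 50–75% of that final maximum
  (about 62% as configured);
* sampling every 0.025 h (1.5 min), multiplicative log-normal measurement
  noise with CV 2% per reading, additive OD background 0.04, duplicate
  wells per strain — the reproducibility regime of a modern plate reader.

Monod constants, yields and the RNAP parameters ($f_{\max} = 0.9$,
$K_\mu = 0.2\,\mathrm{h^{-1}}$) were chosen once to place the pauses and T0
at realistic times for a culture inoculated at OD 0.05 and to give the
burst/baseline contrast described above; they are stated in the YAML file
and are not fitted to data.  The stationary program is scripted rather than
mechanistic because the underlying sigma-factor circuitry is only partially
characterised; the package makes no claim about its dynamics beyond the
shape of the resulting activity waves.

What the generator deliberately does *not* emulate: instrument drift and
well-position effects, luciferin depletion or permeability kinetics,
oxygen- or pH-mediated feedback on growth, cell-to-cell variability in
reporter expression (only the competence hazard is stochastic), and
correlated noise between channels.  Passing tests therefore demonstrate
correctness of the estimators under the stated noise law, not robustness
to every artefact of real plates.

## Rate estimation and numerical choices

Growth rate is the log-derivative $\hat\mu = d\ln \mathrm{OD}/dt$,
estimated by local polynomial least squares (Savitzky–Golay): a polynomial
of degree 2 over a centred window of 11 samples (~16.5 min at the 1.5-min
cadence), with the analytic derivative of the local fit.  The default
window suppresses 2% multiplicative noise while preserving bursts on the
20–30 min scale; it is exposed everywhere and narrower windows are
preferable for noiseless ground-truth comparisons.  At the record edges
the window keeps its full width and shifts inward (the polynomial is
evaluated off-centre) — the standard Savitzky–Golay edge treatment —
because genuinely one-sided short fits have roughly an order of magnitude
larger derivative variance and produce spurious rate spikes at the ends of
a noisy record.

The estimator is invariant to rescaling OD by any positive constant, and
negative $\hat\mu$ (mild lysis) is preserved.  Blank correction subtracts
the per-time median of designated blank wells; corrected OD is floored at
$10^{-4}$ (with a warning count) because logs are taken downstream.

Because every strain in a run shares the culture's growth behaviour, the
pipeline estimates a single $\hat\mu$ from the mean of *all* sample wells'
OD rather than per strain.  With duplicate wells and 2% noise this reduces
the early-record noise (where OD is close to the blank background) enough
that pause detection needs no per-scenario tuning; per-strain growth rates
remain available in the analysis object.

## Event detection and phase

**T0** is defined as the first time $\hat\mu$ falls below 10% of its 90th
percentile and stays below for at least 20 consecutive samples (30 min).
The transient diauxic pauses recover too quickly to trigger the rule.
These constants are exposed; the 90th percentile makes the threshold
scale-free.

**Pauses** are local minima of $\hat\mu$ with relative depth
$1 - \mu_{\min}/\mu_{\mathrm{flank}} \ge 0.2$ (flank = the lower of the two
flanking maxima) and width at half depth $\ge 0.1$ h.  Two scale-free
gates make detection robust at realistic noise: the flanking maxima must
reach 25%, and the absolute dip 20%, of the 90th-percentile growth rate —
otherwise a relative criterion alone calls shallow noise dips during
slow-growth phases.  The terminal descent into stationary phase can be
counted as one additional pause (`include_terminal`), because the growth
arrest at T0 behaves like a pause that never recovers; the pipeline
enables this so that the arrest pairs with the transcription wave at T0,
while the plain function defaults to interior minima only (a logistic
slowdown is then, correctly, not a pause).

**Bursts** are local maxima of an activity series whose topographic
prominence exceeds 15% of the series range (max minus min); the range
normalisation makes detection invariant to affine rescaling — relevant
because activity units are arbitrary.  Peaks closer than 0.15 h are
merged, which prevents double-counting shouldered waves.

**Pairing** of pauses and bursts is greedy nearest-time matching within a
0.3 h lag window.

**Phase** between the growth-rate and activity curves is computed without
spectral decomposition, which would be unreliable for two to three
quasi-periodic oscillations: both series are detrended by subtracting a
long-window local polynomial (about half the analysis window); the
dominant period is the lag of the first autocorrelation peak of
$\hat\mu$ (required to exceed 0.2, else a no-oscillation error); the lag
between the curves is the maximiser of their normalised cross-correlation
within $\pm 0.6$ period, refined to sub-sample resolution by parabolic
interpolation; and the phase is $|360^\circ \cdot \mathrm{lag}/\mathrm{period}|$
mapped to $[0^\circ, 360^\circ)$.  Identities `phase(x, x) = 0` and
`phase(x, -x) = 180` hold by construction and are property-tested on random
smooth signals.  On the bundled scenario the growth rate and the
spo0A-like activity come out about $180^\circ$ apart, while an rrn-like
channel correlates positively and the spo0A-like channel negatively with
$\hat\mu$.

## Half-life calibration

A translation-arrest experiment (`simulate_arrest()`) freezes biomass and
sets all promoter activities to zero from the arrest time; the remaining
light decays as $e^{-\delta t}$.  `fit_half_life()` fits ordinary least
squares to $\ln \mathrm{RLU}$ over a window from one sample to 0.5 h after
arrest (20 points at the default cadence), reporting
$t_{1/2} = \ln 2/\hat\delta$ with its standard error and $R^2$.  Whether
biomass truly freezes after a translation inhibitor is uncertain; the
simulator freezes it, and since $\hat\mu = 0$ either way in the fit window
the estimate is insensitive to that choice.  At 2% noise the bundled
reporter's fitted half-life rounds to 6 minutes.

## Rare developmental transitions

Competence is modelled as a first-passage hazard, not a mechanistic
bistable circuit: each cell transitions as the first event of an
inhomogeneous Poisson process with
$\lambda(t) = \lambda_0 (A_{comK}(t)/K_c)^m$, sampled by inverting the
integrated hazard against one exponential deviate per cell.  The
threshold-proximity exponent $m$ makes bursts of comK expression
transiently multiply the hazard, which is the substance of the claim being
modelled — bursts bring the average cell closer to the switching
threshold.  The defaults ($\lambda_0 = 10^{-3}\,\mathrm{h^{-1}}$, $m = 6$,
$K_c$ at roughly 1.5 times the growth-phase comK baseline on the estimated
activity scale) place the transitioned fraction near $10^{-2}$% before the
first burst and near $10^{-1}$% after the second — the observed order of
magnitude for competence in growing cultures — but only the ordering
(more transitions after the bursts than before) and the sub-1% bound are
asserted anywhere.

Frequencies of rare positives use exact Clopper–Pearson intervals
(via the beta quantile), chosen because observed counts include 0 and 1;
with zero positives a one-sided upper bound is returned, which reproduces
the rule of three, $3/n$.  Sporulation frequency is the heat-resistant
count over the viable count; fold changes are reported unrounded (e.g.
the wild-type versus codY-mutant contrast of about 20.5% / 2.2% ≈ 9.5,
conventionally described as ten-fold).

## Degenerate inputs and error behaviour

Nonpositive OD after blank correction is an error naming the correction
step; duplicate (time, well, channel) records and non-monotone time are
parse errors; unknown keys in scenario or pipeline configuration files are
rejected rather than ignored; an arrest time outside the run, a
non-decaying arrest signal, negative rate constants, and a still-growing
culture at the end of a record (undefined T0) all raise descriptive
errors.  Constant series yield `NA` correlations and a no-oscillation
error from the phase estimator.  Missing single readings can be bridged by
linear interpolation up to two samples; longer gaps are left missing.

## Problem sizes

The bundled scenario integrates a ~14-state ODE over 7 h and renders 12
wells at 281 time points; a full pipeline run (simulate, render, analyze,
events, 20,000-cell transition sampling) takes a few seconds on one CPU.
The test suite's property checks use grids of a few hundred points and
10 measurement-noise seeds; the transition sampler's law is checked at
10,000 cells against the closed-form survival function and at 2,000 cells
times 50 seeds against the inhomogeneous-Poisson integral.

## Known limitations

* Activity units are arbitrary: only shapes, ratios, orderings and phases
  are meaningful, so curve magnitudes are never compared to instrument
  RLU values.
* The deconvolution assumes a single known $\delta$ and no maturation
  delay (an optional fixed delay shift exists in the renderer); no
  regularised or Bayesian deconvolution is provided.
* The stationary-phase program and the GTP dips are scripted, not
  mechanistic; mutant phenotypes can only be represented as parameter
  variants of the scenario.
* Pause/burst detection is tuned for records with a handful of events and
  makes no attempt at changepoint or HMM segmentation, nor at multi-well
  event consensus beyond replicate averaging.
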