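---
title: "Methods: brain-penetration PK/PD from NCA to survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-penetration PK/PD from NCA to survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropk)
```

This vignette is the package's account of its methods: the models and
estimators, the assumptions behind them, the tunable parameters and their
defaults, what the simulators emulate (and what they do not), and the
numerical choices that make every fit reproducible.

## The scientific setting

A drug dosed systemically must cross the blood–brain barrier (BBB) to act
on an intracranial tumor. Two ABC efflux transporters, P-gp (ABCB1) and
Bcrp (ABCG2), pump many small molecules back into blood, so total brain
concentration alone is misleading twice over: the brain may hold far less
drug than plasma, and nearly all of what it holds may be protein- or
lipid-bound and pharmacologically inert. The chain of quantities this
package computes — AUC-based partitioning, unbound fractions, unbound
partitioning, free exposure versus in-vitro potency, and downstream tumor
growth and survival — is the standard way to connect a measured
concentration–time course to an expected pharmacodynamic effect in brain.

## Non-compartmental analysis

`run_nca()` is model-free. AUC(0–t) uses the linear trapezoid by default;
`linlog` switches declining positive segments to the logarithmic trapezoid
(exact under first-order decline). The terminal slope λ~z~ is a log-linear
regression over terminal points chosen by a deterministic rule: start from
the last three positive concentrations and extend the window backwards one
point at a time while the regression r² stays ≥ 0.90. The observed peak is
excluded from the window whenever an absorption phase precedes it; on
iv-bolus profiles that decline from the first sample, every point is
eligible (otherwise a three-point bolus profile could never be fitted).
Both the minimum count and the r² bar are arguments of `fit_lambda_z()`
and fields of `study_config()`.

Derived quantities are definitional: t½ = ln 2/λ~z~,
AUC(0–∞) = AUC(0–t) + C~last~/λ~z~ (with the extrapolated percentage
reported, and a flag rather than an extrapolation when no terminal decline
exists), CL = Dose/AUC(0–∞) and V~d~ = CL/λ~z~. Units are fixed: hours,
ng/mL for plasma, ng/g for tissue with density taken as 1 g/mL (so
tissue-to-plasma ratios are dimensionless), mg/kg doses converted to ng/kg
so CL lands in mL/h/kg.

Destructive sampling — one animal per time point — yields no per-subject
AUC. `composite_profile()` builds the group-mean profile and `run_nca()`
attaches the sparse-sampling standard error of the linear-trapezoid AUC,
Var(AUC) = Σ w~i~² s~i~²/n~i~ with the trapezoid weights w~i~; this is the
conventional estimator for composite designs. Concentrations below a
stated quantification limit are dropped with a logged count rather than
imputed — the tables are small and transparency beats imputation.

## Unbound fractions and dilution correction

Rapid equilibrium dialysis gives f~u,app~ = C~receiver~/C~donor~. Brain
cannot be dialysed neat; homogenising tissue in three volumes of buffer
(dilution factor D = 4) dilutes the binding constituents and inflates the
apparent unbound fraction. Assuming linear, non-saturable binding, the
apparent and undiluted fractions relate by
f~u,app~ = D·f~u~/(1 + (D − 1)·f~u~), and `correct_fu_dilution()` applies
the exact algebraic inverse,
f~u~ = (1/D)·f~u,app~/(1 − f~u,app~ + (1/D)·f~u,app~). The inverse is the
identity at D = 1, fixes f~u~ = 1, and is monotone in f~u,app~ — these are
tested as properties, and the simulator round-trip
(`simulate_red()` → `fu_from_red()` → `correct_fu_dilution()`) is exact at
zero noise. The linear-binding assumption is the one under which the
correction is standard; saturable or device binding is out of scope.

## Partition coefficients

K~p~ is the ratio of brain to plasma exposure; the package supports both
an AUC basis (study-level, the default for `partition_summary()`) and a
single-time-point basis (`regional_partition_table()`, used for tumor
core/rim/normal-brain comparisons where only one sampling time exists).
Every result is labelled with the basis used, because the two do not agree
away from distributional steady state. K~p,uu~ = K~p~·f~u,brain~/f~u,plasma~
converts to free drug: K~p,uu~ ≈ 1 means passive equilibrium, ≪ 1 active
efflux. The distribution advantage DA = K~p,knockout~/K~p,wild-type~
summarises the transporters' total effect. Reports round K~p~/K~p,uu~ to
two decimals for display; machine output keeps full precision.

## Hill dose–response and exposure scenarios

`fit_hill()` fits E(C) = bottom + (top − bottom)/(1 + (C/EC50)^h) by
Levenberg–Marquardt least squares on log10 concentration. The asymptote
policy defaults to top fixed at 100% of control with bottom free in
[0, 100] — viability assays are normalised to control, and freeing the top
mostly trades bias for variance on 8-point grids; `top_policy = "free"`
is available. The start rule is deterministic (EC50 at the tested
concentration whose mean response is nearest the asymptote midpoint,
h = 1), so fits are bit-reproducible. Standard errors come from the
Jacobian at the optimum; the EC50 SE is delta-method transformed from the
log10 scale. Rising response with concentration is flagged
`"no inhibition"`, an EC50 outside the tested range `"extrapolated"`.

`unbound_profile()` converts total tissue concentrations to free molar
units (C~u~ [nM] = C·f~u~·1000/M). `apply_fold()` scales a profile to ask
what an efflux-inhibitor (≈10-fold) or transporter-knockout (≈50-fold)
brain-exposure shift would do, and `time_above_threshold()` measures the
time the free concentration exceeds a potency threshold such as an
in-vitro EC50. Crossings are located log-linearly on declining positive
segments (consistent with first-order elimination) and linearly otherwise;
the identity T(fold·C, θ) = T(C, θ/fold) holds exactly under either rule
and is tested as a property. Fold scaling of raw mean profiles rather than
smoothed fits is the default mode; scenarios can equally be built on a
noiseless model curve from `pk_curve()`.

## Tumor growth and survival

`fit_growth()` is log-linear least squares of ln(flux) on time within a
window (the treatment period, e.g. days 7–37); doubling time is
ln 2/slope, undefined and flagged when the slope is non-positive. Growth
is fitted per animal and summarised per group by the geometric mean of
doubling times — doubling times are exponentials of a log-scale slope, so
the geometric mean is the natural centre; fitting group-mean flux instead
changes only the uncertainty, not noiseless point estimates.

`km_estimate()` and `logrank()` wrap the product-limit estimator and the
log-rank test from the survival package; the package's tests check both
against independent hand computations (a step-down empirical survivor
oracle and an observed-minus-expected/hypergeometric-variance oracle). The
median convention is the earliest event time with S(t) ≤ 0.5, undefined
when the curve never reaches 0.5. Animals alive at study end are
right-censored at last observation. Ties follow the simultaneous-event
convention.

## What the simulators emulate

The generator defaults are the study conditions the analysis chain is
meant for, chosen once:

- `simulate_pk()`: iv bolus 5 mg/kg; bi-exponential plasma
  (V~c~ = 2000 mL/kg so C~0~ = 2500 ng/mL; CL = 600 mL/h/kg giving a
  terminal t½ ≈ 6.9 h; distribution phase 2/h carrying 70% of C~0~); a
  brain compartment dC~b~/dt = k~in~C~p~ − (k~out,passive~ +
  efflux_factor·k~efflux~)C~b~ solved in closed form; sampling at 0.17,
  0.5, 1, 2, 4, 8, 15 h with 4 animals per arm and 20% lognormal noise.
  The brain rates (k~in~ = 1.818/h, k~out,passive~ = 0.15/h,
  k~efflux~ = 7.754/h) put the model's equilibrium K~p~ at exactly 0.23
  (wild-type, efflux_factor 1) and 12.12 (knockout, efflux_factor 0); the
  elacridar preset uses efflux_factor 0.1, an ~8.5-fold K~p~ gain, in the
  ~10-fold class seen with pharmacologic inhibition versus the ~50-fold of
  genetic deletion. The passive rate 0.15/h is a deliberate compromise: a
  slower brain (0.05/h) best matches observed 2 h/6 h concentration-ratio
  behavior but makes knockout equilibration so slow that a 15 h window
  truncates most of the brain AUC; 0.15/h keeps AUC(0–15 h) K~p~ within
  ~30% of the equilibrium value while preserving the rising time-point
  ratios. Brain mass transfer is assumed not to perturb plasma (free brain
  content is a negligible fraction of the dose), which keeps plasma
  closed-form.
- `simulate_red()`: the forward dilution model above, donor spiked to
  1 µM, lognormal assay noise; exact at zero noise. True fractions default
  to the study-scale values f~u,plasma~ = 0.006, f~u,brain~ = 0.0005 via
  `pk_sim_params()`.
- `simulate_viability()`: Hill mean plus additive Gaussian noise clipped
  at 0, on an 8-point log grid spanning 0.025–1000 nM with 10 wells per
  concentration — the assay design. The default truth for the sensitive
  human line is EC50 = 1.4 nM; the Hill coefficient is taken as 1, the
  package's own choice of the canonical one-site form.
- `simulate_bli()`: flux = flux~0~·2^(t/T~d~) with lognormal noise (CV
  20%), 10 animals, 8 observations over days 7–37, starting flux 2×10⁹
  photons/s. Doubling times in the 6–36 day range reproduce the contrast
  between untreated and effectively treated arms.
- `simulate_survival()`: Weibull times with the scale set so the
  distribution median is exact (scale = median/ln 2^(1/shape)); shape 4
  gives the fairly tight event clustering typical of an aggressive
  orthotopic model, and group medians of 61–92 days span the studied arms;
  administrative right-censoring at a stated day.

Noise is multiplicative lognormal for concentrations and flux (bioassay
error is close to log-normal) and additive Gaussian for viability
percentages — conventional choices. Every simulator is a deterministic
function of its parameters and a seed (`withr::with_seed`, leaving the
session RNG untouched), and `derive_seed()` expands one global seed into
per-stage streams below 2³¹.

What the simulators do **not** emulate: ip absorption kinetics (every
simulated profile is iv), inter-animal variability in PK parameters (noise
is observational only), nonlinear or saturable binding and transport,
spatial core/rim gradients (regional data enter as labelled
concentrations, not from a spatial model), BLI saturation or quenching,
and treatment-effect time dynamics in survival (times are drawn from the
target distribution directly). Passing parameter-recovery tests therefore
demonstrates that the estimators recover the truth of *this* generating
model at study-like size and noise — not that real tissue data satisfy the
model's assumptions.

## Numerical choices and degenerate inputs

- All-zero profiles give AUC 0 with a warning; profiles violating type
  invariants (non-increasing times, negative concentrations, receiver >
  donor, non-positive flux) are rejected at construction, never silently
  filtered.
- λ~z~ is refused (flagged, not invented) on rising terminal data; AUC
  extrapolation and CL/V~d~ then stay undefined.
- A zero receiver concentration in dialysis is an error by default, or a
  machine-epsilon floor by explicit option.
- The Hill optimiser runs on log10(C) with box constraints
  (h ∈ [10⁻³, 20], bottom ∈ [0, 100]); non-convergence is flagged with the
  optimiser's message rather than returning a bad fit.
- Threshold-crossing interpolation and the AUC method are enumerated
  choices in `study_config()`, recorded so a report states its own rules.
- Kaplan–Meier medians use first-crossing (S ≤ 0.5); with n = 10 this sits
  at the 5th order statistic and is therefore slightly below the
  distribution median on average — visible in the recovery studies, and a
  property of the convention rather than a defect.

## Problem sizes

The shipped tests and the reproduction script run at the sizes the
analyses are designed for: 4 animals × 7 time points per PK arm, 50
simulated viability assays of 8 × 10 wells, 10 animals × 8 BLI
observations, 500 simulated survival cohorts of n = 10, and 1,000-replicate
null studies for the log-rank calibration; closed-form oracles use dense
grids (Δt = 0.01 h). The full suite runs in well under a minute.

## Known limitations

No compartmental modelling of the in-vivo data, no PK/PD link models
(cell-kill ODEs, Emax over time), no synergy analysis for the
drug–inhibitor combination, no Cox regression, and no handling of
below-quantification data beyond dropping. The dilution correction assumes
linear binding; the unit conventions assume tissue density 1 g/mL. These
are scope boundaries, not planned work.
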