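---
title: "Model and methods behind luadsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind luadsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(luadsim)
```

luadsim simulates tumor size and time to progression (TTP) in
*EGFR*-mutant lung adenocarcinoma under daily gefitinib, at the level
of a virtual population. This vignette explains the model structure,
the choices behind its parameters and numerics, what the synthetic-data
machinery does and does not emulate, and the known limitations. It
states no empirical result beyond what the package's tests and the
acceptance script themselves compute.

## 1. Model structure

### Clones and states

A patient's tumor is a set of 2 to 16 clones, each with its own
mutation profile. The default is two clones sharing the patient's
activating EGFR variant: a drug-sensitive major clone and a resistant
subclone carrying the T790M gatekeeper mutation with initial cell
fraction `f_res`. Each clone contributes five ODE states — P
(proliferating cells), Q (quiescent cells), D (dead, not yet cleared
cells), K (carrying capacity in cells), I (immune pressure) — so a
patient integrates `5 * n_clones` equations. With 15 shared growth
parameters this realizes, per clone, proliferation, death, cell
layering, neo-angiogenic carrying capacity and immune limitation.

### Geometry and layering

The tumor is a sphere of volume `v_cell * sum(P + Q + D)`.
Proliferation-competent cells live in the outer shell of depth `d_rim`
(the viable depth observed in spheroids); the viable volume fraction is
`phi = 1 - ((r - d_rim)/r)^3`. Layering is geometric rather than a
spatial PDE: outside the rim, cells enter quiescence at
`k_pq * (1 - phi)` and re-enter cycle at `k_qp * phi`. This reproduces
the two spheroid observables this class of model is calibrated on
(radius growth and viable depth) with a single parameter.

### Competition and neo-angiogenesis

Proliferation is logistic against the clone's own capacity:
`lambda * s * phi * (1 - (P+Q)/K) * P`, with `K` seeded at
`k_cap0 = 2` times the clone's initial cells and grown by
neo-angiogenesis, `dK/dt = alpha_ang * (P+Q) * (1 - K/K_max)`. Two
design points deserve emphasis:

* *Clone-local competition.* An alternative is to compete every clone
  against the total burden (`1 - N_tot/K_c`). Combined with
  size-proportional capacity seeding, that form gives a small resistant
  subclone a competition factor of about `-1/f_res` and extinguishes
  it; seeding every clone at the total-burden capacity instead makes
  the capacity non-binding and removes neo-angiogenesis from the list
  of TTP drivers. Clone-local competition with proportional seeding
  keeps both stories intact: the resistant clone's relapse speed is
  gated by how fast its own vasculature expands, so `alpha_ang` is a
  first-order determinant of TTP, as expected for this disease model.
  Clones still interact, through the shared spheroid geometry (`phi`
  depends on the total radius) and through immune recruitment driven by
  the total burden.
* *Near-capacity baseline.* `k_cap0 = 2` places a treatment-naive clone
  within a factor two of its angiogenic ceiling, so untreated growth is
  rate-limited jointly by proliferation and vascular expansion.

### Immune pressure

Immune pressure is recruited by total burden with half-saturation
`h_imm` (`1e10` cells, the order of a 1.5 cm tumor), decays at `d_imm`,
and kills both proliferating and quiescent cells at `kappa_I * I`. It
is initialized at its equilibrium for the baseline burden. This part of
the model is deliberately phenomenological; its parameters consequently
get wide population spreads (section 4).

### Signaling

The signaling submodel is algebraic (zero ODEs). In vivo, a clone's
proliferation signal is `s = s0 * (1 + g_EGFR + m_prolif) * (1 - eff * inh)`:
a constitutive gain for the activating EGFR variant, an additive offset
`m_prolif` summarizing implicit mutations acting on the proliferation
hallmark, and a drug term. `eff = prod(1 - rho_res)` over the
resistance mutations present (T790M `rho_res = 0.9`, KRAS
`rho_res = 0.85`) attenuates the drug's effect on the signal: a KRAS
clone under full target inhibition retains most of its downstream
signal, which is what makes KRAS carriers grow through therapy and
progress earlier. The same `eff` attenuates drug-induced death
(`gamma_drug * eff * inh`), since TKI-induced apoptosis is downstream
of the signaling block.

In vitro, the four signaling read-outs are pERK/pAKT responses to
EGF/HGF stimulus, modeled as surge curves
`A_max * (t/tau) * exp(1 - t/tau)` — the simplest two-parameter
unimodal form whose parameters are exactly the two quantities such
experiments calibrate (peak level, peak time).

### Treatment

Gefitinib follows closed-form one-compartment oral kinetics with dose
superposition (Bateman curves summed in a numerically stable geometric
form). Defaults — 250 mg every 24 h from day 0, F 0.6, absorption
half-life ~1.4 h, elimination half-life 48 h, Vd 1400 L — are
package-chosen values representative of published gefitinib population
kinetics; no trial-specific PK constants are claimed. Inhibition is
Emax/Hill on concentration with
`IC50_eff = IC50_base * prod(multipliers)`; exon 19 deletion is the
reference (multiplier 1) and is more sensitive than L858R (1.6), T790M
shifts potency 25-fold, KRAS 4-fold.

Because tumor dynamics are slow relative to the dosing interval, the
default drug driver in the ODEs is the infusion-equivalent exposure
(same average concentration, smooth accumulation to steady state,
`pk_mode = "average"`); this removes a daily forcing term that would
otherwise dominate solver effort without affecting weekly-scale
dynamics. The exact oscillating profile is available with
`pk_mode = "superposition"` (also implemented inside the compiled
right-hand side) and `concentration()` exposes it directly.

### Clinical read-out

Progression is an increase of the largest tumor dimension by at least
20% and at least 0.5 cm; since the model tracks the radius, the
absolute criterion is 0.25 cm on the radius. The reference is the
running nadir by default (RECIST 1.1 convention); the baseline
reference is selectable because published one-line statements of the
rule are ambiguous between the two. TTP granularity is the output grid
(daily by default) with no sub-day interpolation. Patients without
progression at the follow-up cut-off are right censored there — the
model does not represent death, toxicity or discontinuation.

## 2. Parameters

Rates are per day, lengths cm, cells absolute counts. The growth
defaults were calibrated jointly, once, against the behavioral targets
a gefitinib arm of this population should show: median TTP around eight
months with a decline-then-relapse radius trajectory; moderate radius
shrinkage at six months for EGFR-only patients; KRAS co-mutated
patients growing through therapy with shorter TTP; untreated tumors
progressing within a few months; and the descriptor-sensitivity
structure in which immune, neo-angiogenesis, baseline size, resistant
fraction and proliferation-offset parameters are all first-order TTP
drivers. The frozen values are `lambda_prolif = 0.14`,
`delta0 = 0.004`, `delta_q = 0.003`, `k_pq = 0.1`, `k_qp = 0.05`,
`k_cl = 0.05`, `v_cell = 1e-9` cm^3, `d_rim = 0.2` cm, `K_max = 1e12`,
`alpha_ang = 0.065`, `rho_imm = 0.2`, `h_imm = 1e10`, `d_imm = 0.1`,
`kappa_I = 0.008`, `gamma_drug = 0.01`. They are a package calibration,
not published constants.

Allometric rescaling between settings uses `Z = a * M^b` with reference
masses 2.63 g (in vitro), 23 g (mouse) and 70 kg (human; chosen here,
configurable). Exponents default to -1/4 for first-order rates and +1
for capacities — standard metabolic scaling — and are configurable per
parameter because no printed exponent set exists for this model class.

## 3. Virtual populations

Descriptors are sampled from marginal distributions through a Gaussian
copula (identity correlation by default; a rank-correlation matrix can
be supplied, as correlations are typically inherited from calibration
rather than printed). Trial-reported marginals follow the reference
159-patient gefitinib arm: sex 53/159 male; age truncated normal with
median 63 on [36, 89] and sd estimated by treating the range as a
central 99% interval (`estimate_sd_from_quantiles`, giving 10.29
years); EGFR exon 19 deletion 93/159 (a 50/50 split is used for the
sensitivity population); smoking 106/19/34; ethnicity 88/71 Asian;
stage 3/156 IIIb. Only the two common EGFR variants are emitted.
Unreported descriptors come from general-population defaults: KRAS
co-mutation 2.5%, PIK3CA 4%, baseline radius lognormal with median
1.5 cm, proliferative fraction 0.6, resistant-subclone fraction
lognormal with median 0.6% spanning orders of magnitude, and
mechanistic spreads that are wide for the phenomenological immune and
angiogenesis parameters (sdlog 0.5-0.8) and narrow for comparatively
well-characterized proliferation biology (sdlog 0.15). The population
size rule is 10 times the real arm.

Baseline concordance (protocol step 2) uses the two-sided Fisher exact
test for categorical characteristics — r x c tables through the exact
network algorithm with a chi-square fallback above a configurable size
— and the two-sided t-test for age, against a deterministic quantile
reconstruction of the arm's ages from its median and range (no
individual-level data exist to compare against).

## 4. Validation protocol

`validate_vpop()` implements the five-step protocol: Kaplan-Meier
estimation of the virtual TTP curve (through `survival::survfit`); a
bootstrapped 95% pointwise prediction interval from 1000 subsamples of
the real arm's size drawn from the virtual population; raw coverage,
the percentage of the observed curve's own step points lying inside the
band; 7000 bootstrapped log-rank tests (5000 plus 2000 for
convergence, through `survival::survdiff`) of real versus subsample;
and the 80%/80% pass thresholds. Subsampling is without replacement
(the subsample reading of the protocol), with a with-replacement flag.
Coverage is point-based and unweighted at the observed step times by
default — the discretization is not prescribed anywhere — with a
time-weighted variant as an option. All stochastic steps take explicit
seeds that are recorded in the report.

One property of this protocol is worth knowing when interpreting
self-validation experiments (an independently drawn same-process arm
validated against the band): the prediction interval is built by
subsampling the *realized* virtual population, so it carries neither
the virtual population's own finite-sampling deviation from the
generative law nor (without replacement) the full subsample variance.
Against an independent arm its pointwise coverage is therefore a few
points below nominal, and because deviations are correlated along the
curve, whole-curve coverage occasionally dips below 80% even when the
generative processes are identical. The package's acceptance suite
measures exactly this run-level pass rate; a shortfall there reflects
this band-narrowness property of the protocol itself, not a mismatch
of the simulator.

## 5. Synthetic reference data

`generate_reference_dataset()` emulates the *shape* of a digitized
trial data set: latent progression and death times per subject
(defaults: Weibull progression, shape 1.4, median 9 months; exponential
death, median 24 months; 159 subjects; 30-month follow-up), from which
PFS = min(progression, death), OS = death, and TTP tables are derived,
plus Kaplan-Meier curves sampled on a regular grid with at-risk counts
— the form a digitization workflow produces. `infer_ttp()` then
reverses the PFS/OS construction by removing, per death time, at most
one matching PFS event within a tolerance (half the curve resolution
for digitized inputs; exact for event lists). What the generator does
*not* emulate: staggered accrual (all subjects share one
administrative-censoring time), digitization error in the curve
coordinates, toxicity-driven discontinuation, and any correlation
between progression and death hazards. Tests passing on these fixtures
therefore exercise the statistical machinery, not the fidelity of any
real trial.

## 6. Numerics

The ODE system is integrated with `deSolve::lsoda` (stiff-capable)
with relative tolerance 1e-6 and absolute tolerance 1e-3 cells, on a
uniform output grid. The right-hand side is compiled C; an R reference
implementation is kept and tested to agree to solver precision, and
handles arbitrary multi-block regimens. Small negative undershoots
(above `-10 * atol`) are clamped to zero; anything larger aborts with
the last valid time. Empty clones use a `0/0` guard in the competition
term. Dose superposition uses the closed geometric form of the Bateman
sum, stable to arbitrary dose counts.

Population work uses coarser grids chosen as problem sizes: weekly
output for outcome simulation (TTP granularity 7 days ~ 0.23 months)
and half-week output for sensitivity runs; tornado analyses in the
tests use 4000 patients rather than the 5000 default. Ties at a
descriptor median go to the low category; when the median equals the
maximum (majority at the top level of a binary descriptor) the tie
rule is flipped so both categories are populated, and constant
descriptors report zero impact with a message. Median-split impacts of
rare binary descriptors (a few percent prevalence) carry Monte-Carlo
noise of several percent at these population sizes; the tornado is
read with that in mind.

## 7. Known limitations

* The growth defaults are a behavioral calibration against published
  qualitative and summary-level patterns, not a fit to individual-level
  data; absolute TTP predictions inherit that.
* Untreated progression (about three months) sits at the fast end of
  the plausible range; it is a structural consequence of a two-clone
  model in which the resistant clone must regrow from under 1% of
  baseline to progression within about eight treated months.
* No death process, toxicity, dose interruptions, or later-generation
  TKIs; no spatially resolved oxygen/drug gradients; no acquired (as
  opposed to pre-existing) resistance mutations.
* The virtual TTP dispersion is narrower than real trial arms, which
  mix staggered follow-up and larger biological heterogeneity; the
  validation protocol's discriminating power against such arms is
  correspondingly conservative.
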