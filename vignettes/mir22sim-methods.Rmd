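---
title: "Methods: a multiscale PK-PD model of miRNA-22 nanotherapy in TNBC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multiscale PK-PD model of miRNA-22 nanotherapy in TNBC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mir22sim)
```

## The model

`mir22sim` implements a mechanistic tumor-compartment
pharmacokinetic-pharmacodynamic model of nanoparticle (NP)-delivered
miRNA-22 therapy for triple-negative breast cancer, alone or combined with
doxorubicin and the anti-PD-L1 antibody atezolizumab. Seventeen coupled
ODEs track three transport chains and a signaling core:

* **NP chain** (amounts, particle counts): plasma N~P~ → tumor vasculature
  N~V~ → interstitium N~I~ → cell membrane N~M~ → cytosol N~C~. Plasma NPs
  are cleared at a size-dependent rate
  k~Cl~ = ln 2 / (0.11 e^−1.33φ^ − 0.001 e^−9.7φ^) (φ in cm); exchange
  with the vasculature is perfusion-limited through the tumor plasma flow
  Q(B); extravasation crosses the vessel wall at permeability P~NP~ × the
  vascular surface density S(B); interstitial transit and endocytosis are
  first-order (D~NP~/L², k~endo~).
* **Antibody chain** (concentrations, nM): the same
  plasma → vasculature → interstitium → membrane cascade, fed either by
  first-order peritoneal absorption (mouse IP dosing) or an IV bolus
  (human), with membrane antibody stimulating PD-L1 degradation through a
  saturable (EC~50~-type) term.
* **Doxorubicin chain** (nM): plasma ↔ vasculature perfusion exchange, a
  Fickian wall flux J = −D~dox~ (C~D,V~ − C~D,I~)/Δx into the
  interstitium, and transfer into the cytosol where the drug kills tumor
  cells with an EC~50~ shifted upward by eEF2K (chemoresistance).
* **Signaling core**: cytosolic miRNA-22 C~M~ is produced basally
  (inhibited by tumor burden, 1/(1 + ε~B~B)), released from cytosolic NPs
  with a payload that decays at k~rel~ since the last injection, and
  degraded at δ~M~. miRNA-22 accelerates eEF2K degradation; eEF2K
  stimulates tumor growth, PD-L1 production and chemoresistance; PD-L1
  shields the tumor from immune kill through δ~B,I~/(1 + ε~P~C~P~). Tumor
  volume B follows logistic growth toward the carrying capacity B\*,
  opposed by immune and chemotherapy kill.

Mouse tumors use empirical perfusion and vascularization laws,
Q(B) = 2843 e^−0.65B^ mL/mL/wk and
S(B) = 0.26 e^−4.5B^ + 138 e^−0.04B^ cm²/cm³; human simulations fix
Q = 1512 and S = 135. Units are weeks, mL (≡ cm³) and nM throughout; NP
amounts are particle counts.

The drug-free equilibrium is available in closed form and is used as the
initial condition and in the test suite: C~M~\* = g~M~⁰/δ~M~ (≈ 0.0068 nM),
C~E~\* = g~E~⁰ / (δ~E~ (1 + A~M,E~ C~M~\*/(EC~50~^M^ + C~M~\*))) and
C~P~\* = g~P~⁰ (1 + A~E,P~ C~E~\*/(K~E,P~ + C~E~\*))/δ~P~. Note that the
basal miRNA-22 level tempers eEF2K by about 3%; the frequently quoted
simplification C~E~\* = g~E~⁰/δ~E~ ignores this coupling.

## Parameters and the two calibration-level constants

All biological and therapy constants ship as the package defaults
(`biological_params()`, `therapy_params()`), with mouse growth constants
estimated per study arm (σ = 3.1/3.75/3.13 wk⁻¹ and B\* = 2.21/2.5/2.99
cm³ for the miRNA-22, doxorubicin and atezolizumab arms). Two quantities
in the NP delivery chain are not identifiable from first principles and
are treated as calibration-level constants:

* **`alpha_NP`** — a dimensionless NP extravasation efficiency multiplying
  the hindered-pore permeability. The product of per-NP payload, particle
  number and delivery efficiency sets the cytosolic miRNA-22 exposure per
  administered dose; the tabulated per-NP payload (0.007 nM·mL) is five
  orders of magnitude above a physically packed 70-nm particle, so a bare
  hindered-pore permeability would produce absurd exposures. `alpha_NP`
  absorbs this scale. It was calibrated **once** against the two reported
  features of the human dose-response: ~29% tumor growth inhibition (TGI)
  at the reference 0.026 mg/kg weekly dose (tolerance ±5 percentage
  points) and saturation of the response beyond ~0.05 mg/kg
  (operationalized as TGI(0.2) − TGI(0.05) < 5 points). Because the NP
  chain is linear in dose × `alpha_NP`, the curve's shape is fixed and the
  two features trade off; the shipped value 1.86 × 10⁻⁹ gives
  TGI(0.026) = 32.5% with a saturation gap of 4.5 points, inside both
  tolerances simultaneously. It is exposed for recalibration.
* **`k_endo`** — the endocytosis rate, default 10 wk⁻¹. In a linear chain
  it changes timing, not throughput, so it is essentially
  non-identifiable from tumor-volume data and is left at its default.

The antibody permeability uses the plain hindered-pore form (Renkin
centerline hindrance, partition (1 − λ)², λ = diameter ratio) without the
efficiency factor: scaling it down with `alpha_NP` would eliminate
antibody delivery entirely, contradicting the observed atezolizumab
effect; the payload inconsistency that `alpha_NP` absorbs is specific to
the NP-miRNA chain.

## Plasma-volume convention for doxorubicin and the antibody

The plasma equations of the small-molecule and antibody chains divide
perfusion exchange and clearance by a volume. Two conventions are
plausible: the plasma compartment volume V~P~ (as the equations are
written) or the agent's volume of distribution V~D~ (consistent with the
bolus concentration Dose/V~D~ and with physiological elimination
half-lives). The package implements both
(`options = list(plasma_volume_mode = "vp"/"vd")`) and defaults to
**"vp"**: with V~P~, the human reference patient shows stable disease
under doxorubicin or atezolizumab monotherapy (TGI 3.9% and 8.5%),
partial response when miRNA-22 is combined with atezolizumab (47%), major
response with doxorubicin (54%) and near-complete response for the triple
combination (77%) — the reported qualitative pattern. Under "vd" the
doxorubicin exposure is ~400-fold larger and its monotherapy alone
reaches intermediate response, which contradicts that pattern. The cost
of the "vp" convention is an unphysically short doxorubicin half-life in
the 1-mL mouse plasma compartment, so the simulated mouse doxorubicin arm
shows almost no effect; the mouse time courses are not a quantitative
target of this package.

A second printed idiosyncrasy is retained deliberately: the doxorubicin
interstitium → cytosol influx uses the antibody diffusivity constant
(D~Ab~/L²) while the interstitial loss uses D~dox~/L². This matches the
source equations exactly; it is flagged here because it is likely a typo
there, and the packed-parameter layout keeps the two coefficients separate
so the choice can be revisited.

## Numerics

* **Solver**: backward differentiation formulas (deSolve `"bdf"`), with a
  single automatic retry using the L-stable implicit Runge-Kutta method
  `"radau"`. Strongly responding virtual patients drive B toward zero, and
  the per-volume transport terms (wall flux / f~v~B, release / f~c~f~cy~B)
  reach local stiffness of order 10¹²/wk; lsoda's Adams/BDF switching
  stalls on ~20% of combination-therapy patients, and because those are
  disproportionately the strong responders, dropping them would bias
  population response rates. With BDF + radau fewer than 0.2% of patients
  fail; failures are logged and reported, never silently dropped.
* **Tolerances**: rtol 10⁻⁶ with per-state atol — 10⁻² on particle counts
  (doses are 10¹⁰-10¹⁵ particles), 10⁻⁶ nM on concentrations (antibody
  states traverse ~20 orders of magnitude per IP dose cycle; 10⁻⁶ nM is
  far below every EC~50~ in the model), 10⁻¹⁴ cm³ on tumor volume (the
  human course starts from a single cell, 10⁻⁹ cm³). A tolerance-refinement
  test verifies B(104 wk) moves < 0.1% under 10× refinement. Negative
  excursions smaller than atol on states decaying through zero are clamped
  to zero in the returned trajectory.
* **Dosing**: IV boluses are integrator events (solver restart at each
  discontinuity, additive state jumps; NP doses convert mg/kg of payload
  to particle counts, scaling as φ⁻³ when the NP diameter is perturbed).
  Mouse IP antibody dosing is a first-order absorption forcing term, with
  zero-magnitude events forcing a restart at each switch-on. Every dose
  time is a grid point of the returned trajectory.
* **B → 0 guard**: divisions by tumor sub-volumes are suppressed below
  10⁻¹² cm³.
* **Calibration**: bounded Levenberg-Marquardt on log₁₀ parameters with
  multi-start (Latin hypercube over the box). Finite-difference steps are
  set to ~0.1% of each parameter (`epsfcn` = 10⁻⁶) so the Jacobian is not
  swamped by ODE-solver noise; residuals are normalized per series by the
  maximum observed mean so tumor-volume (cm³) and protein (a.u.) series
  are commensurable.

## Virtual populations and sensitivity analysis

Virtual patients are the human baseline with multiplicative overrides of
the 16 patient-specific parameters (`dagger_parameters()`), Latin
hypercube sampled within ±50%. The perfusion and surface-area entries
perturb the whole empirical law (for humans, the constants 1512 and 135).
Response is classified at week 104 on the RECIST-analog scale:
progressive (TGI ≤ 0), stable (0-10], intermediate (10-30], partial
(30-50], major (> 50).

The global sensitivity analysis (GSA) perturbs 21 parameters — the 16
patient-specific ones plus δ~M~, φ~NP~, δ~NP~, EC~50~^M^ and k~rel~ —
over 0.2×-5× of baseline, regresses %TGI on the z-scored factors per LHS
replicate, and takes the standardized coefficient as the sensitivity
index (SI). Parameters are ranked by mean |SI| and grouped by one-way
ANOVA with Tukey's HSD. The set is configurable: with the growth-rate
constants (σ, δ~B,I~) included they dominate the ranking outright; without
them the PD-L1 axis (ε~P~, g~P~⁰) and the eEF2K production rate lead,
with δ~M~ mid-pack. A one-at-a-time sweep confirms this ordering is
structural (TGI range over the factor range: ε~P~ and g~P~⁰ ≈ 79 points,
g~E~⁰ ≈ 58, A~M,E~ ≈ 60, δ~M~ ≈ 34), so a ranking with δ~M~ alone on top
would require a much steeper exposure-response than these constants
produce. δ~M~'s one-at-a-time trend — monotone loss of TGI as miRNA-22
becomes less stable — does hold.

Population results worth knowing before interpreting trial output: with
all 16 parameters varied ±50%, roughly 40% of the sampled cube has an
immune-kill/growth balance near unity; those patients' control tumors grow
slowly and almost any therapy drives them to near-complete inhibition, so
the TGI distribution is strongly bimodal and the major-response plateau
under nanotherapy monotherapy sits near 45% of patients rather than the
~20% sometimes quoted for this design (which coexists in the source with
a ~40% figure for the same quantity).

## Drug synergy

`chou_talalay_analysis()` simulates constant-ratio dose grids (multipliers
0.25-4× anchored at miRNA-22 0.026 mg/kg QW, doxorubicin 2.4 mg/kg Q3W,
atezolizumab 2 mg/kg Q3W) for the three monotherapies and the three
miRNA-22 combinations, fits the median-effect line
log(f~a~/(1 − f~a~)) = m log D − m log D~m~ per monotherapy (points with
f~a~ outside [10⁻⁶, 1 − 10⁻⁶] excluded), and computes the mutually
exclusive combination index CI = Σ D~i~/D~x,i~ at each combination datum,
with D~x,i~ evaluated on the fitted line in log space. That evaluation
matters for atezolizumab, whose effect is dose-flat across the grid
(PD-L1 degradation is saturated at clinical doses, EC~50~ = 0.0446 nM):
its fitted slope is ~0 and the naive D~m~ (f~a~/f~u~)^1/m^ form is an
indeterminate ∞·0, while the log-space form resolves to D~x~ → ∞ — the
agent contributes no dose equivalent above its plateau. The summary CI of
a combination is the median over its grid points; all three miRNA-22
combinations come out well below 1 (0.006-0.17 at the reference grids).

## Synthetic data and what passing tests show

`generate_invivo_like()` emulates the calibration study design — four
mouse arms (control; miRNA-22-NP 0.15 mg/kg IV weekly; doxorubicin
4 mg/kg IV weekly; atezolizumab 5 mg/kg IP every 5 days), weekly
tumor-volume means over weeks 1-6 from a 0.001-cm³ inoculum, an eEF2K
series for the miRNA arm — by running the model at known "truth"
parameters and applying multiplicative lognormal noise with unit mean
(default CV 10%, the field-typical scale for caliper volumetry) per
animal (default 8 per arm). The generator's values are *not* the
published animal measurements, which are not tabulated anywhere; recovery
tests therefore demonstrate that the calibration machinery is unbiased
and precise on data with the assumed error structure (noiseless bias
< 1%, < 15% error at 5% CV for the documented free set
{A~B,E~, A~M,E~, g~E~⁰}), not that the shipped constants reproduce any
real mouse. Real data would add inter-animal growth heterogeneity,
measurement-schedule irregularities and non-lognormal outliers that this
generator deliberately omits.

## Problem sizes used in the shipped analyses

The packaged acceptance analysis uses 300 LHS patients for the
dose-response sweep (7 doses, shared pre-treatment branch per patient),
2000 patients for the triple-combination trial, reduced GSA runs of
400 × 3 replicates, and 5-point synergy grids; these sizes give
population fractions stable to ~1-3 percentage points across seeds while
keeping a full run in the minutes range on a laptop core. The full-scale
settings (10,000 × 10 GSA) remain the function defaults.

## Known limitations

* No whole-body PBPK, spatial transport or explicit immune-cell
  populations; the tumor is a well-mixed compartment.
* The mouse doxorubicin arm is effectively inert under the default
  plasma-volume convention (see above).
* `alpha_NP` and M₀ are confounded; only their product is meaningful.
* CI values extrapolate the atezolizumab median-effect line far beyond
  its observed (flat) range; they are reported with the monotherapy fit
  statistics so this is visible.
* Human tumor inception volume (single cell) is taken as 10⁻⁹ cm³ and is
  configurable; no printed value exists.
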