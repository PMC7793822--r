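---
title: "The vicagrel/clopidogrel PBPK/PD model: structure, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vicagrel/clopidogrel PBPK/PD model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The pharmacological problem

Clopidogrel and vicagrel are thienopyridine prodrugs whose antiplatelet
effect is carried entirely by a common active thiol metabolite (AM-H4) that
binds the platelet P2Y12 receptor irreversibly.  The two prodrugs reach
AM-H4 by different first steps:

* **Clopidogrel** is mostly (85%) hydrolysed by hepatic CES1 to an inactive
  acid; only the remaining 15% enters the two-step oxidative route
  (CYP1A2/2B6/2C19 to 2-oxo-clopidogrel, then CYP3A4/2C19/2B6/2C9 to
  AM-H4).  CYP2C19 loss-of-function therefore cuts active-metabolite
  exposure sharply.
* **Vicagrel** is hydrolysed in the gut wall by CES2 and AADAC (AADAC
  carrying about 53% of the hydrolysis) directly to 2-oxo-clopidogrel, with
  near-total conversion efficiency, bypassing the CYP-dependent first step.

The package simulates both cascades with a shared reduced PBPK topology,
links AM-H4 to platelet inhibition with a turnover model, and reproduces
the genotype/phenotype/inhibitor comparison campaigns on virtual cohorts.

## PBPK model structure

Each parent drug has four states (gut lumen, portal vein, liver, lumped
systemic compartment); each metabolite has three (no lumen).  All internal
amounts are in nmol so metabolite hand-off conserves moles by construction;
molecular weight is used only when converting doses (mg) in and plasma
concentrations (ng/mL) out.  One cumulative-elimination accumulator per
compound closes the mole balance, which is asserted to 1e-6 relative in the
tests.

Absorption is first order (`ka`) from the lumen after applying the absorbed
fraction `fa` to the dose.  Gut-wall metabolism is algebraic: the fraction
escaping is

    Fg = Qgut / (Qgut + fu_gut * CLint_gut)

and the complement `1 - Fg` is routed mole-for-mole to the gut metabolite
product (2-oxo-clopidogrel), split across gut pathways in proportion to
their intrinsic clearances.  Gut-formed metabolite transfers entirely to
the portal vein: the near-total conversion efficiency reported for
vicagrel justifies neglecting enterocyte loss.

The liver is well stirred: each hepatic pathway eliminates at
`fu_liver * CLint_scaled / V_liver` per unit liver amount, where
`CLint_scaled = clint * MPPGL * liver_weight * 60 / 1e6` converts
uL/min/mg protein to L/h and `fu_liver = fu_plasma / blood_plasma_ratio`
approximates the unbound blood fraction.  Within the liver the split of
cleared material across pathways is exactly proportional to their intrinsic
clearances, which is what makes the static formation-fraction arithmetic
below work.  Flow terms (portal, hepatic arterial, total hepatic) carry
plasma-equivalent concentrations; the systemic volume is an apparent plasma
volume.  Saturation (Michaelis-Menten) is deliberately not modelled: the
regimens studied are low-dose and the underlying kinetics are reported as
linear.

The full system is linear (bilinear only while a mechanism-based inhibitor
is active), integrated with `deSolve::lsoda` at relative tolerance 1e-8 and
absolute tolerance 1e-10 nmol.  Doses are bolus events into the lumen; a
dose scheduled at the very first grid point is folded into the initial
state because solver event machinery fires only strictly inside the
integration window.  Output at a later dose instant is the pre-dose state.
The constant-coefficient case is cross-checked against a
matrix-exponential solution to 1e-8 in the tests.

## Platelet PD model

Platelet reactivity follows a turnover model with irreversible
drug-mediated inactivation:

    dP/dt = kin - P*kout - P*C(t)*kirre,   P(0) = kin/kout = 1

with `C(t)` the AM-H4 plasma concentration in uM, interpolated
piecewise-linearly between PK output samples.  `P` is normalised to a
baseline of 1 (so `kin = kout` numerically); maximal platelet aggregation
is proportional, `MPA(t) = MPA0 * P(t)`, which makes

    IPA(%) = (MPA0 - MPA(t)) / MPA0 * 100 = (1 - P(t)) * 100

exact.  After washout the model is linear and recovery follows
`1 - (1 - P0) exp(-kout t)`; both closed forms serve as solver oracles.
The driving concentration is total plasma AM-H4, with no unbound
correction, mirroring how the PD relationship is usually reported.

## Default parameters and their provenance

Every value in `inst/extdata/default_parameters.yaml` carries a provenance
tag.  The printed anchors are hard constraints:

| anchor | constraint |
|---|---|
| oxidative share of clopidogrel | CYP clint sum / (CYP sum + CES1) = 0.15 |
| AADAC share of gut hydrolysis | AADAC / (AADAC + CES2) = 0.53 |
| CES1 428 G/A clearances | 0.8 x 300 = 240 and 0.8 x 20 = 16 uL/min/mg |
| CES2 defect clearance | 46,100 / 20 = 2,305 uL/min/mg |

Values not printed anywhere (unbound fractions, blood/plasma ratios,
volumes, `ka`, `fa`, perpetrator one-compartment parameters, CYP isoform
splits) are literature-typical defaults chosen once at design time.  Three
deserve explanation:

* **2-oxo-clopidogrel CYP total = 16 uL/min/mg.**  The hepatic fate of
  2-oxo-clopidogrel is a two-way split between CES1 hydrolysis (clint 20)
  and CYP oxidation to AM-H4 (clint 16).  Scaling CES1 to 80% changes the
  AM-H4 formation fraction from 16/36 to 16/32, whose ratio
  (16+16)/(16+20) = 0.889 reproduces the published CES1 G/G-over-G/A
  exposure ratio of about 0.89.  This is a calibration constraint, not a
  measured value, and is documented as such in the config.
* **AM-H4 systemic clearance 300 L/h, hepatic CES1 clint 5 uL/min/mg.**
  The active thiol is chemically reactive and short-lived; its disposition
  is dominated by nonenzymatic degradation, here lumped into the systemic
  (`renal_cl`) clearance.  CES1 hydrolysis of AM-H4 is retained in the
  network but is a minor route, so carboxylesterase genotype effects act
  almost entirely through formation, not elimination.
* **PD constants.**  `kout = 0.0124 1/h` makes washout from about 80%
  inhibition take `ln(8)/kout = 168 h`, i.e. about 7 days, matching the
  reported recovery of platelet function.  `kirre = 40 1/(uM h)` was
  calibrated once so the steady-state maintenance-dose mean IPA falls near
  75% (inside the 60-90% band targeted by the design); with the default PK
  this gives an end-of-dosing population mean IPA of roughly 70-75% and a
  mean recovery time of about 7.5 days at the documented 10%-IPA
  threshold.  `MPA0 = 55%` is a typical ADP-induced baseline aggregation.

## Virtual population

Each subject draws an independent log-normal multiplier (median 1,
`sigma^2 = log(1 + CV^2)`) for every pathway intrinsic clearance (CV 40%),
per-compound `ka` and `v_sys` (CV 30%), and the PD constants (CV 20%).
`kin` and `kout` share one multiplier so the normalised baseline pool stays
at 1 for every subject; `cv_kin` is therefore tied to `cv_kout`.  CYP2C19
phenotypes are point multipliers on enzyme abundance: EM 1, IM 0.5
(gene-dose proportionality, since IM activity is nowhere quantified), PM 0
(null alleles).  Genotype labels rescale enzymes deterministically:
`CES1_428GA` multiplies CES1 by 0.8, `CES2_defect` divides CES2 by 20.
Ethnicity blocks differ only in CYP2C19 phenotype frequencies (Chinese
0.40/0.45/0.15, Caucasian 0.72/0.26/0.02 for EM/IM/PM); no other covariates
are modelled.

Paired-arm design: every comparison reuses the identical sampled subjects
in both arms, changing only the genotype/phenotype/inhibitor factor.
Ratio-of-means estimates are then nearly noise-free at 100 subjects, which
is why the comparison-table ratios reproduce tightly even though the
per-arm SDs are wide.  Cohorts default to 100 subjects in 10 trials of 10.

## Inhibitors

Perpetrators are deterministic one-compartment oral forcing functions
(closed-form Bateman superposition); victim variability dominates ratio
noise under the paired design.  Reversible inhibition multiplies affected
intrinsic clearances by `1/(1 + I_u/Ki)` with `I_u` the unbound plasma
concentration; at gut enzymes the inhibitor concentration is approximated
by the dose remaining in the lumen divided by a 0.25 L luminal volume (no
better gut-level model being available), and both applications can be
toggled in `coadminister()`.  Mechanism-based inhibition integrates an
active-enzyme state `dE/dt = k_deg (1-E) - k_inact I/(KI+I) E` that
multiplies the affected clearances.  Simvastatin carries the published
reversible Ki pair (0.11 uM on CES1, 0.67 uM on CES2); omeprazole carries
literature MBI constants with an enzyme turnover default of
`k_deg = 0.001 1/h` (configurable; hepatic CYP turnover estimates in the
literature are faster, and a larger `k_deg` weakens the simulated
interaction).

Two structural consequences are worth knowing:

* With the luminal surrogate, simvastatin concentrations in the gut exceed
  the CES2 Ki by more than two orders of magnitude across the whole
  published sensitivity range (0.001-0.67 uM), so gut CES2 is effectively
  fully inhibited at every grid point and the AM-H4 AUC ratio is flat
  along the CES2-Ki axis (variation below 1e-5).  The CES1 axis, acting on
  the hepatic fate of 2-oxo-clopidogrel and AM-H4, dominates by orders of
  magnitude - the qualitative conclusion (CES1 sensitivity greatest at low
  Ki) holds, but the CES2 axis carries no usable signal in this reduced
  model.
* Because intact vicagrel has no metabolic route of its own in this
  topology, CES2 knock-down moves vicagrel parent exposure by only about
  2-fold (wild/defect AUC ratio about 0.55), far less than the >300-fold
  change reported for the full proprietary model.  The AM-H4 ratios - the
  quantities with pharmacological meaning - are insensitive to this and
  reproduce at about 1.00.

## Scenario geometry and problem sizes

Dosing follows the published regimens: vicagrel 24 mg loading then
6 mg/day, clopidogrel 300 mg then 75 mg/day; genotype and DDI campaigns
run 4 dosing days, the phenotype comparison 7, the washout study 7 plus a
14-day drug-free window.  Perpetrators run in for 5 days before the victim
loading dose and continue during victim dosing (the alternative -
stopping the perpetrator - is a toggle).  Output grids are 0.1 h during
dosing and 1 h during washout; interval AUCs use the linear trapezoid on
that grid with no extrapolation, "first dose" meaning the 24 h after the
loading dose and "last dose" the 24 h after the final maintenance dose.
Arm-mean ratios are ratios of arithmetic means, not means of ratios.
Scenario campaigns use 100 subjects; unit and property tests exercise the
same code paths at 3-10 subjects and coarser grids, with the full-size
runs reserved for the acceptance checks.

## The synthetic observed-data generator

`generate_observed()` samples the model's own predictions at sparse
clinical-looking times and adds residual error: multiplicative log-normal
noise (default CV 20%) on concentrations, additive truncated-normal noise
(default SD 5 percentage points) on IPA.  It emulates the *structure* of
digitized trial data - sparse sampling, multiplicative scatter, bounded
IPA - but not real between-study heterogeneity, assay bias, digitization
error or model misspecification.  Passing fold-error checks against these
synthetic observations therefore validates the verification *workflow*
(pairing, fold-error arithmetic, acceptance counting), not clinical
accuracy.  `verification_report()` implements the conventional 2-fold and
1.5-fold acceptance counts.

## Degenerate inputs and numerical edges

Zero doses yield identically zero profiles; a zero gut clearance gives
`Fg = 1`; a perpetrator with an empty regimen leaves the victim system
bit-identical; `ka = CL/V` in the Bateman solution switches to the
`D ka t e^{-ka t}/V` limit; `recovery_time()` returns 0 when inhibition is
already below threshold at the last dose, `Inf` when the threshold is
never reached in the window, and warns when the window is shorter than one
platelet turnover time `1/kout`.  Registry validation rejects
out-of-range fields by name, pathway products that name unregistered
compounds, and cycles in the metabolite graph.

## Known limitations

Beyond the two structural notes above: no full tissue distribution,
transporters, or enterohepatic recycling; no perpetrator variability; no
CES1A2 -816A>C or AADAC genotype effects (deliberately out of scope); the
IM multiplier and the perpetrator PK parameters are stand-ins for
unpublished quantities; and absolute exposure levels inherit the
uncertainty of the non-printed defaults, which is why the packaged
comparisons are framed as paired ratios rather than absolute
concentrations.
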