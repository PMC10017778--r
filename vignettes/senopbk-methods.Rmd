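---
title: "Methods: PBK modelling of senecionine N-oxide relative potency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PBK modelling of senecionine N-oxide relative potency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senopbk)
```

## The problem

Pyrrolizidine alkaloid N-oxides (here senecionine N-oxide, SENO) are
protoxicants: they must first be reduced to the parent alkaloid (SEN),
mainly by gut microbiota and hepatic enzymes, before cytochrome-P450
oxidation produces the reactive pyrrole intermediate that forms
glutathione conjugates (7-GS-DHP), protein adducts and DNA adducts.
The relative potency (REP) of the N-oxide versus the parent alkaloid can
be defined on two endpoints — the blood SEN AUC (Method 1) or the amount
of pyrrole-protein adducts (Method 2) — and in rat these disagree at the
high doses used in animal studies (0.88 vs 0.61 at 55 µmol kg⁻¹ bw).
This package implements a kinetic analysis of that discrepancy: if high
internal SEN concentrations deplete hepatic glutathione, the effective
conjugation capacity for the pyrrole intermediate drops, diverting flux
to protein adducts — and this happens preferentially when dosing SEN,
whose blood peak is higher than after an equimolar SENO dose.

## Model structure

The model is a flow-limited compartmental rat PBK model for SENO with a
parallel submodel for SEN: blood, liver, richly perfused, slowly
perfused and fat compartments per compound, plus small- and
large-intestine lumen pools. The topology follows the standard rat PBK
set consistent with the transfer constants it uses: first-order uptake
from the small intestine to the liver (`ka_SENO`, `kb1`), first-order
small-to-large intestine transit (`kt`), Michaelis–Menten microbial
reduction of SENO to SEN in the large-intestine lumen, first-order
uptake of that SEN (`kb2`), hepatic Michaelis–Menten SENO reduction
(cumulated as ALM1) and total hepatic SEN clearance (ALM2), and a
first-order renal clearance of SENO from blood. Tissue exchange is
flow-limited, `Q · (CB − C/P)`.

Three modelling decisions deserve comment:

- **Bioavailability as a t = 0 split.** The oral bioavailability `F`
  (8.2% for SEN from rat data; 100% for comparison) deposits `F · dose`
  in the dosed compound's small-intestine pool and routes the remainder
  to a feces pool. `F` also appears multiplicatively in the adduct
  budget (below); the split makes simulated systemic exposure and budget
  arithmetic consistent, and is isolated in `build_odes()`.
- **Renal SENO clearance.** With no SENO sink other than reduction, all
  absorbed N-oxide would eventually convert to SEN and the Method-1 REP
  would tend to 1 regardless of kinetics. N-oxides are substantially
  excreted unchanged in urine, so the model includes a first-order
  urinary clearance of SENO from blood (`CLu_SENO`); it is what makes
  the conversion — and hence REP — genuinely partial.
- **7-GS-DHP as an observer flux.** Glutathione conjugation of the
  pyrrole is one route within total SEN clearance, so its rate
  `ALM4' = kcat_invivo · residual_kcat_frac · CVL_SEN` (driven by the
  venous-equilibrium liver concentration `CVL = CL/PL`, the
  concentration the flow-limited liver equation is written in) is *not*
  an extra sink: the liver balance carries `− ALM4' + ALM4'`. We exploit
  this analytically: the cancelled pair is omitted from the balance and
  the observer is integrated in unit form (`ICVL' = CVL_SEN`), with
  `ALM4 = kcat_eff · ICVL` recovered at output. The integrated system
  therefore does not contain the conjugation kcat at all, so blood SEN
  kinetics — and the Method-1 REP — are invariant to it to the last bit,
  and its normalized sensitivity coefficient on the SEN AUC computes to
  exactly 0.

Internal units are µmol, µM and hours. AUCs convert to the in vivo
reporting unit min µg mL⁻¹ through the molar masses (SEN 335.44, SENO
351.44 g mol⁻¹, consistent with the equimolar dose pair 55 µmol kg⁻¹ =
18.45 / 19.33 mg kg⁻¹); REP values, as ratios, are unit-invariant.

## Parameters

Cardiac output (15·BW^0.74 L h⁻¹), perfusion fractions and organ
volumes follow standard reference rat physiology; flows are stored as
fractions of cardiac output with the slowly perfused flow as remainder,
so the flow balance holds by construction. The partition coefficients
and the uptake/reduction/clearance constants are *documented
placeholders* on the scale reported for pyrrolizidine alkaloids: the
published parameterization of the predecessor model was not available,
and every compartment constant is config-driven (`pbk_params()`,
`read_params_file()`) so a measured set can be dropped in. None of the
reported headline numbers (REP from the in vivo table, kcat fitting and
scaling, dose conversions) depends on them; the PBK-simulated REP
magnitudes do, which is why the test suite asserts structural and
qualitative properties of the simulated REPs rather than their absolute
values.

Measured quantities at the core of the workflow:

- `Lslope2c = 0.0023` mL min⁻¹ mg⁻¹ S9 — in vitro first-order kcat of
  7-GS-DHP formation (0.5–50 µM SEN, 60 min, 1 mg mL⁻¹ S9);
- scaling 143 mg S9 g⁻¹ liver × 34 g liver kg⁻¹ bw × 0.25 kg × 60/1000
  → `kcat_invivo = 0.1677` L h⁻¹. The combined factor computes to
  72.93; a rounded value of 72.91 circulates in the literature — the
  package always recomputes from the factors, and both roundings give
  0.1677 to four significant figures.

## In vitro kinetics

Below saturation (`[S] ≪ Km`) the Michaelis–Menten rate is
`v = (Vmax/Km)[S] = kcat·[S]`, so the assay's information is a slope.
`fit_kcat()` fits least squares *through the origin* — the physical
model has no intercept; a free-intercept fit is available for comparison
— with every replicate entering individually. The reported standard
error is computed under a relative-error model (constant CV on the
measured metabolite concentration, which is how LC-MS/MS replicate
scatter behaves, and what the synthetic generator produces): the
homoscedastic least-squares SE under-covers severely here because the
top substrate level contributes ~70% of the leverage. Under the
relative-error SE, the fitted slope lies within 3 SE of the generating
value in ≈100% of simulated datasets (the suite checks ≥99% over 200
seeds).

## The adduct budget and the two REP methods

Only a fraction `f` of the systemically available dose is bioactivated
to reactive pyrroles not binding DNA (DNA adducts are assumed neutral to
the split), and that fraction ends up as either 7-GS-DHP or protein
adducts:

```
A_7GSDHP + A_protein = F · f · REP₁ · dose   (SENO arm)
A_7GSDHP + A_protein = F · f · dose          (SEN arm)
```

`run_rep_pair()` simulates both arms at an equimolar dose, takes REP₁
from the ODE-integrated blood SEN AUCs, reads `A_7GSDHP` at 24 h, and
obtains the protein amounts as budget remainders (`adduct_partition()`;
an overshoot of the budget is a configuration error naming the
candidate culprits F, f and the kcat). With `f = 0.20` and the full
kcat, the 7-GS-DHP : protein split is near 1:1. REP₂ is the protein
ratio. The budget identity is asserted to 1e-9 relative on every run.

Glutathione depletion is represented as a residual fraction of the
conjugation kcat applied to the SEN-dosing arm only (the SENO arm stays
at full capacity; a `depletion_arm = "both"` switch allows symmetric
exploration). `residual_kcat_fraction()` is piecewise linear in dose
through (0.1, 100%), (55, 63%), (200, 0.01%), clamped outside — linear
in dose, not log-dose, because the underlying assumption is a linear
recovery/decline between stated anchors. The REP₁ used inside the
SENO-arm budget is the REP₁ at that same dose, keeping scans
self-consistent.

Two exact consequences are worth noting (both are tested):

- because `ALM4` is an observer, REP₁ is bit-identical across residual
  fractions;
- with all kinetics linear, exclusively hepatic SEN elimination and all
  SEN systemic entry via the liver, the integrated flow balance forces
  `AUC_blood = AUC_CVL = input/CLint`, hence REP₂ = REP₁ exactly when
  both arms share the same kcat. The suite verifies this to 1e-6
  relative on a 500-h horizon (the slowest absorption route,
  `kb2 = 0.2 h⁻¹`, needs far more than 24 h to complete; at 24 h the
  identity holds only to ~1e-3).

`fraction_bioactivated_scan()` varies `f` (0.125–0.400) holding the
7-GS-DHP amounts fixed at their `f = 0.200` values (kcat 0.0023 / 63%
of it per arm); protein amounts grow with `f`, so REP₂ rises towards 1.
Grid points whose budget remainder would be negative are flagged
infeasible rather than returned.

## Sensitivity analysis

`normalized_sc()` implements the one-at-a-time normalized coefficient
`SC = ((C′−C)/C)/((P′−P)/P)` at a +5% forward perturbation (central
difference available for diagnostics; forward at 5% and central at 1%
agree within 10% for the smooth outputs, which the suite checks).
`sensitivity_report()` evaluates it for every registered parameter on
the protein-adduct amount (the Method-2 endpoint, computed through the
budget so sensitivities on 7-GS-DHP propagate with flipped sign), the
SEN AUC, or the 7-GS-DHP amount, for both dosing arms at 55 µmol kg⁻¹
bw. With the default parameterization the dominant parameters are those
of SEN clearance (`VmaxLM2c`, `KmLM2`) and 7-GS-DHP formation
(`Lslope2c`), and parameters that increase 7-GS-DHP decrease protein
adducts and vice versa. Flows are perturbed through their fractions of
cardiac output, so the flow balance survives perturbation;
`residual_kcat_frac` is treated as a scenario setting, not a model
parameter, and is excluded from the default registry.

## Numerical choices

- Integrator: `deSolve::ode` with `lsoda` (stiff-capable, adaptive),
  rtol 1e-8, atol 1e-10 µmol, ≥1000 output points per 24 h. The
  contract is tolerance-based, not method-based.
- The blood SEN AUC is carried as an auxiliary ODE state, never
  recovered by post-hoc quadrature. `auc()` on the blood or liver SEN
  concentration differences the corresponding cumulative state (the
  initial blood-mixing transient has a ~3 ms time constant that no
  output-grid quadrature resolves to 1e-6); other series use composite
  Simpson on a spline of the dense grid.
- Mass balance — all compound pools + cumulative SEN clearance + urinary
  SENO + feces = dose — is checked at every output time (tolerance 1e-6
  relative; typical residual ~1e-15). Negative states beyond
  1e-8 · max(1, dose) abort; smaller undershoots are clipped to zero.
- The adaptive solution is cross-checked against an independent
  fixed-step RK4 oracle (step 1e-4 h) on a reduced gut–liver–blood
  configuration, to 1e-4 relative on the 24-h blood concentration.
- Dose-linearity (Km → ∞ at fixed Vmax/Km) holds to <1e-6 relative;
  `linearize_params()` exposes that regime.

## The synthetic generator

`generate_incubation_dataset()` emulates the S9 incubation design: 8
log-spaced substrate levels spanning 0.5–50 µM (the assayed range; the
level count is a generator choice), 3 replicates, 60-min incubations at
1 mg mL⁻¹ S9 in 0.1 mL, NADPH-free blanks, and first-order product
formation with Gaussian noise of CV 0.10 on the measured concentration,
truncated at zero. The CV is a generator default (replicate SDs of the
original assay are not tabulated), noise is placed on concentrations —
not rates — because that is where measurement error arises, and blanks
default to zero background. Generation is a pure function of (spec,
seed) and restores the caller's RNG state. What passing tests show:
the estimator recovers a known truth without bias (<2% over 200 seeds)
under the assumed noise model; they cannot show robustness to
calibration drift, matrix effects, or non-Gaussian outliers that real
LC-MS/MS data may contain. `generate_invivo_profile()` similarly
overlays multiplicative lognormal noise on a simulated blood profile as
an I/O fixture.

## Problem sizes

The default simulation grid is 1001 points over 24 h (one stiff solve
≈ 0.1 s). The test suite uses: a 100001-point grid once (trapezoid
cross-check of the observer integral), a 2000-h horizon for the
zero-frequency-gain identity, 200-seed Monte-Carlo for estimator bias
and coverage, and a 240 000-step RK4 oracle run. Dose scans in tests
use 2–6 doses; the scan functions accept arbitrary grids.

## Known limitations

- Compartment constants are placeholder defaults; simulated REP
  magnitudes (and anything downstream of them, such as matching the in
  vivo 0.88/0.61 quantitatively) are parameter-set dependent.
- No plasma protein binding, biliary recirculation, enterohepatic
  cycling, inter-individual variability, pyrrole-DNA adduct kinetics,
  or human extrapolation.
- The depletion mechanism is phenomenological (a residual-kcat
  multiplier with fixed anchors), not a GSH mass balance.
- `F`, `f` and the residual fraction are scenario inputs chosen to
  match in vivo observations visually, not formally estimated.
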