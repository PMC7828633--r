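---
title: "Methods: the CNS PBPK model and the what-if scenario engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CNS PBPK model and the what-if scenario engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnspbpk)
```

## What the package computes

`cnspbpk` simulates the unbound concentration--time profile of a small
drug molecule in the human central nervous system and asks how that
profile changes when CNS physiology departs from its healthy reference --
the "what-if" questions relevant to traumatic brain injury, ischemia,
brain tumors, epilepsy, and aging: what if cerebral blood flow falls by
30%? what if the blood--brain barrier (BBB) tight junctions widen
five-fold? what if brain extracellular fluid acidifies to pH 5?

The quantities of interest are the rate of brain target-site exposure
(`Cmax`, `Tmax`), its extent (`AUC`), and the two unbound partition
coefficients: `Kp_uu,BBB`, the ratio of unbound AUC in brain
extracellular fluid (ECF) to unbound AUC in microvascular plasma, and
`Kp_uu,cell`, the ICF/ECF analogue. `Kp_uu,BBB = 1` means purely passive,
symmetric barrier transport; deviations quantify net active efflux or
influx, and `Kp_uu,cell != 1` reflects pH-driven partitioning into cells.

## Model structure

A fixed one-compartment plasma model (clearance 297 L/h, central volume
108 L, 1 g infused intravenously over 15 min) acts as an analytic forcing
function. Using the same plasma input for every drug deliberately removes
plasma pharmacokinetics from the comparison: all differences between runs
are CNS-mediated. Plasma is not depleted by CNS uptake; the brain takes
up at most a few milligrams of a 1000 mg dose, so the feedback term would
be below the solver's resolution anyway.

Nine CNS states (amounts, mg) are integrated: microvascular plasma (MV),
brain ECF, brain ICF (cytosol), lysosomes, and the CSF chain -- lateral
ventricles (LV), third+fourth ventricles (TFV), cisterna magna (CM),
subarachnoid space (SAS). Each connection is a clearance (mL/min) acting
on the source concentration:

* plasma <-> MV by cerebral blood flow (689 mL/min);
* MV <-> ECF across the BBB: a symmetric paracellular clearance plus
  directional transcellular influx/efflux;
* ECF <-> ICF and ICF <-> lysosome across cell membranes;
* plasma <-> LV and plasma <-> TFV across the blood--CSF barrier
  (BCSFB), paracellular plus transcellular, areas split 50/50;
* one-way convection: ECF bulk flow (0.2 mL/min) into the LV, then
  LV -> TFV -> CM -> SAS -> plasma at `Q_CSF + Q_ECF_bulk`
  (0.62 mL/min).

Two further states audit the cumulative drug input from plasma and
cumulative return to plasma; total CNS content must equal their
difference at every output time (the mass-balance diagnostic, which runs
at ~1e-15--1e-9 relative in practice and is asserted below 1e-6).

Where the published compartment diagram leaves connectivity open we had
to choose: ECF bulk flow is routed into the lateral ventricles (the
alternative, cisterna magna entry, changes CSF concentrations slightly
but leaves ECF/ICF metrics untouched because the chain is one-way);
there is no diffusive ECF <-> CSF exchange beyond that bulk flow, which
keeps the closed-form `Kp_uu,BBB` exact; and the BCSFB exchanges central
plasma rather than the brain microvascular compartment. The reported ICF
concentration is cytosolic -- lysosomes are a separate sub-compartment.

## Ionization and pH-partitioning

Only the neutral microspecies crosses lipid membranes. Unionized
fractions follow Henderson--Hasselbalch: `1/(1+10^(pH-pka))` for acids,
`1/(1+10^(pkb-pH))` for bases with `pkb` read as the conjugate-acid pKa
(so caffeine's -0.92 "basic" group is effectively never protonated), and
the product of both factors for zwitterions. One acid plus one base group
at most is modelled.

Two distinct uses must not be conflated:

* **BBB/BCSFB transcellular clearances** are calibrated whole-barrier
  inputs, valid at reference pH. A pH scenario multiplies them by the
  *ratio* `fu(pH_new)/fu(pH_ref)` of the source compartment only -- at
  reference conditions the factor is exactly 1 and the printed values are
  used unchanged.
* **Cell and lysosomal membranes** carry the *absolute* unionized
  fraction at the source compartment's current pH on each side of a
  symmetric neutral-species permeability
  `PS = mean(CL_T_in, CL_T_ef) x SA_membrane / SA_BBB`. This makes the
  steady-state ICF/ECF unbound ratio exactly
  `fu(pH_ECF)/fu(pH_ICF)` -- pH-determined and independent of the PS
  magnitude, which only sets the equilibration rate. For morphine
  (pkb 9.12) the ratio is 1.9804, and the lysosome (pH 5) traps bases
  ~99-fold over cytosol.

A consequence worth noting: for drugs with slow cell-membrane
equilibration the slowest eigenmode of the whole system *is* the cellular
mode, so the late-time ICF/ECF concentration ratio exceeds the
equilibrium ratio. The pH-partitioning statement therefore holds -- and is
tested -- in its exact AUC form (`Kp_uu,cell` as the ratio of
`AUC_0-inf`), not as a terminal concentration ratio.

## Paracellular transport and the pore model

The paracellular route is a fixed population of water-filled cylindrical
pores of radius 0.0007 um occupying 0.004% of the BBB surface. A drug's
hydrodynamic radius comes from the diffusivity correlation
`D_aq = 9.9e-5 x Mwt^-0.453` cm^2/s via Stokes--Einstein at 298.15 K and
0.89 mPa s (the conditions such correlations are fitted at; both
configurable). Restricted diffusion follows the Renkin hindrance
polynomial `(1-l)^2 (1 - 2.104 l + 2.09 l^3 - 0.95 l^5)`, `l` the
solute/pore radius ratio.

Published paracellular clearances are taken as inputs, not re-derived;
the pore model exists to *rescale* them when a scenario changes the pore
radius: aperture area scales as `r^2` (pore count fixed) and the
hindrance is re-evaluated, so
`CL_P(r_new) = CL_P(r_ref) (r_new/r_ref)^2 H(l_new)/H(l_ref)`.
Under the half-radius scenario the largest panel drugs (Mwt near 350)
reach `l >= 1` and are fully excluded from the paracellular route; the
grid records those cells as flagged rather than failing. The BCSFB
paracellular clearance is derived from the BBB one by transporting the
permeability-per-effective-area to the BCSFB pore radius (0.0027 um) and
effective area (0.016% of one tenth the BBB surface), split equally
between the LV and TFV interfaces.

## Active transport as calibrated asymmetry

Net active transport is represented by an asymmetry factor (AF >= 1)
multiplying one side of the transcellular route, solved in closed form so
that the steady-state relation

```
Kp_uu,BBB = (CL_P + AF_in CL_T,in) / (CL_P + AF_ef CL_T,ef + Q_bulk)
```

hits the drug's observed `Kp_uu,ECF`. If the passive prediction is
already within 2% both factors stay at 1 (codeine); an overshoot is
corrected on the efflux side (morphine, AF_ef = 4.59; levetiracetam,
AF_ef = 31.6), an undershoot on the influx side. Transporter substrate
flags (BCRP, p-gp, OAT3, MRP4) are carried as metadata only -- expression
-based scaling across species is outside this package's scope, so the
calibration is the model's sole source of asymmetry. One panel drug,
cephalexin, has a target *below* its passive prediction reachable only
through influx reduction, but its influx clearance is printed as below
detection (stored 0): calibration is declared infeasible and the grid
falls back to passive transport with a recorded flag. Six of the eight
published drugs are passively self-consistent, which is why the
reference-condition simulations reproduce their printed `Kp_uu` values
with no extra factors.

## Numerical contract

* `deSolve::lsoda` (stiff-capable) with relative tolerance 1e-8 and
  absolute tolerance 1e-10 in amount units; fixed output grid (default
  1 min, configurable down to 0.25 min where `Tmax` resolution matters,
  as in the blood-flow scenarios).
* Default horizon 600 min. If a monitored trace (brain ECF and ICF by
  default) has not peaked by the final grid point, or its infinite-time
  extrapolation would exceed 20% of the AUC, the run is repeated once at
  20,000 min and flagged. Slow cell equilibration (cephalexin,
  gabapentin, morphine) routinely triggers this.
* `AUC_0-inf` adds `C_last/k_el` to the trapezoidal `AUC`, with `k_el`
  from a log-linear fit of the last 5 post-`Tmax` grid points lying above
  a noise floor of `1e-8 x Cmax`. The floor matters: after ~27 plasma
  half-lives a fully decayed trace sits at the solver's absolute
  tolerance, and regressing on that noise would be meaningless. A
  non-decaying terminal phase is refused; an extrapolated fraction above
  20% is an error (or, inside the pipeline, the cue to extend the
  horizon).
* Tiny negative amounts within 1000x the absolute tolerance are clipped
  to zero; anything larger aborts the run.
* Ties in `Tmax` break to the earliest time; `AUC_0-T` uses the full
  simulated horizon.

## Scenarios

`default_scenarios()` returns the reference plus ten one-at-a-time
perturbations: cerebral blood flow x0.7 / x1.5, BBB pore radius x0.5 /
x5, ECF volume x0.7 / x1.5, ECF pH to 5 / 8, ICF pH to 6 / 7.6. A
perturbation changes exactly one physiology field; notably the ECF-volume
scenarios leave surface areas, bulk flow and ICF volume untouched so the
volume effect is isolated, and pH scenarios act only on
ionization-scaled membrane clearances, never on paracellular or
convective routes. Asymmetry factors are calibrated once per drug at
reference and held fixed across scenarios. The grid output is the log2
fold change ("two-fold change": a value of 1 is a doubling) of each
metric against the reference, per drug and compartment.

```{r grid, eval = FALSE}
grid <- run_whatif_grid(builtin_drugs())
plot_whatif_heatmap(grid, "brain_ECF")
```

## The virtual drug panel

`generate_virtual_drugs()` emulates the statistical structure of a
46-drug CNS panel so every pipeline stage is testable without external
data: molecular weight uniform on 150--500 g/mol, logP on -3.7--4.3,
pk_a on 3--16, pk_b on -9--10, ionization class from a configurable mix,
and `Kp_uu,ECF` log-uniform on [0.01, 3]. The synthesized clearances are
deliberately simple monotone laws -- paracellular from the pore model
anchored at the caffeine value (decreasing in Mwt), transcellular
`2 x 10^(0.6 logP)` mL/min (increasing in lipophilicity) -- chosen so
that every generated drug calibrates feasibly. They are pipeline
exercise, not property prediction; passing tests on the virtual panel
demonstrates the machinery's invariants (directionality of pH effects,
feasibility, schema round-trips), not real-drug accuracy.

## Problem sizes and limitations

The shipped test suite runs the full 8-drug x 11-scenario grid (~90
simulations, a minute or so), single-drug checks at 600 or 20,000 min
horizons, and virtual panels of 5--46 drugs; these sizes were chosen to
exercise every code path at interactive turnaround.

Known limitations: transport is linear (no transporter saturation, no
CNS metabolism, no plasma protein-binding kinetics); brain tissue
non-specific binding is not parameterized, so concentrations are unbound
throughout; physiology is a single adult human reference (no age, sex or
species libraries); perturbations are one-at-a-time with no disease
time-course; and the published surface areas `SA_BCM` and `SA_LYS` are
stored as printed rather than recomputed from cell counts and spherical
geometry (the recomputation lands within ~1% but not exactly, so the
printed constants are canonical).
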