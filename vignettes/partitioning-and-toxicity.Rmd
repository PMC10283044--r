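---
title: "Equilibrium partitioning and dose-response methods in pcbtox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium partitioning and dose-response methods in pcbtox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcbtox)
```

## The problem

In vitro toxicity screens of lower-chlorinated PCBs (LC-PCBs) and their
hydroxylated and sulfated metabolites dose a nominal concentration into
culture medium, but the biologically effective exposure depends on how each
chemical redistributes between medium, headspace air and the cells.  This
vignette documents the models implemented in `pcbtox`, the assumptions and
defaults behind them, and the design decisions taken where the underlying
experimental literature leaves choices open.

## The equilibrium partitioning model

### Assumptions

* Full chemical equilibrium between all phases over the exposure period
  (24 h in the motivating design); no uptake or metabolism kinetics.
* No saturation: partition coefficients are concentration-independent, so
  phase *fractions* are independent of the dose.
* Three phases inside the cell: storage lipid, protein, and cytosolic
  water.  The cytosol is treated as freely dissolved, i.e. at the same
  concentration as the medium water at equilibrium.
* Sorption to plastic labware is excluded (slow diffusion into polystyrene
  relative to the exposure time).
* Exposures are serum-free, so there is no extracellular protein sink.

### Partition coefficients

For each compound the model needs three dimensionless (volume/volume)
coefficients at system temperature: `K_lip/w`, `K_pro/w`, `K_air/w`.

`K_lip/w` and `K_pro/w` are computed from polyparameter linear free-energy
relationships (PP-LFERs) on the Abraham solute descriptors
`E, S, A, B, V, L`:

    log10 K = c + e*E + s*S + a*A + b*B + v*V   (condensed-phase systems)
    log10 K = c + e*E + s*S + a*A + b*B + l*L   (air-side systems)

Published condensed-phase systems usually yield L/kg; the registry
therefore carries a `basis` flag and a phase density, and mass-basis
coefficients are converted to the volume basis by `K_vol = K_mass * rho`
(defaults: storage lipid 0.905 kg/L, protein 1.36 kg/L).  The conversion is
recorded in the output metadata.  Which published system to use for
"lipid" (storage vs membrane) and "protein" (muscle vs albumin) is a
substantive choice that the registry makes explicit configuration rather
than a hidden default.

`K_air/w` is routed by compound class:

* **parents** — preferred route is a compound-specific Henry's law
  constant `H_ref` (Pa·m³/mol at `T_ref`), corrected to system temperature
  by the van't Hoff form
  `H(T) = H_ref * exp(-dU_aw/R * (1/T - 1/T_ref))` and divided by `RT`
  (`R` = 8.314 J/mol/K).  When a compound record carries no internal energy
  of air-water transfer `dU_aw`, a configurable default (55 kJ/mol, typical
  of chlorinated biphenyls) applies — an explicit assumption, since
  congener-specific values are not always available.
* **hydroxylated metabolites** — no reliable Henry constants; the
  registry's air/water PP-LFER is used (their H-bonding makes the result
  negligibly small anyway).
* **sulfated metabolites** — ionized at medium pH, treated as non-volatile:
  `K_air/w = 0` by default (`sulfate_nonvolatile = TRUE`).  The PP-LFER on
  neutral-form descriptors can be enabled per run, but ionic speciation is
  outside the descriptors' domain, so zero is the safer default.

### Phase fractions

With the dimensionless loadings `[Pro] = n_cells*v_pro/V_m`,
`[Lip] = n_cells*v_lip/V_m`, `[Wat] = n_cells*v_wat/V_m` and the headspace
ratio `V_a/V_m`, the mass balance solves in closed form.  Writing

    D = 1 + K_pro/w*[Pro] + K_lip/w*[Lip] + K_air/w*(V_a/V_m)

the fractions are `f_fre = 1/D`, `f_pro = K_pro/w*[Pro]/D`,
`f_lip = K_lip/w*[Lip]/D`, `f_air = K_air/w*(V_a/V_m)/D`; they sum to one
by construction.  The test suite additionally verifies the algebra against
an independent numerical route (fix a total mass, root-solve the freely
dissolved concentration, recompute each phase mass directly) to 1e-10
relative on a thousand random systems.

The grouped cell-associated fraction is

    f_cell = f_pro + f_lip + f_fre*[Wat]

i.e. protein-bound plus lipid-bound plus the cytosolic part of the freely
dissolved pool.  Total cell water is used as the cytosol weighting; since
`[Wat]` is of order 1e-3 under the default geometry this term is a
refinement, not a driver.  The intracellular distribution uses the same
coefficients on a per-cell basis:
`g_lip : g_pro : g_wat = K_lip/w*v_lip : K_pro/w*v_pro : v_wat`.

### Default parameters

| parameter | default | unit | note |
|---|---|---|---|
| `V_m` | 500 | µL | 24-well exposure volume |
| `V_a` | 2000 | µL | headspace of a 24-well |
| `n_cells` | 2e5 | cells/well | near-confluent 24-well |
| `T` | 310.15 | K | 37 °C incubation |
| `v_pro` | 1.18e-4 | µL/cell | measured C6-cell protein |
| `v_lip` | 9.57e-5 | µL/cell | measured C6-cell lipid |
| `v_wat` | 2.84e-6 | µL/cell | measured C6-cell water |
| `dU_aw` default | 55000 | J/mol | applied when a record has none |

The per-cell composition values are measured C6 (rat glioma, astrocyte
model) quantities.  The reported water content is smaller than the protein
and lipid volumes, which is physically surprising for a cell; the values
are nevertheless used exactly as reported and every one of them is
config-overridable.  The well geometry (`V_m`, `V_a`, `n_cells`) is not
fixed by the motivating experiments and was chosen once as a plausible
24-well configuration; all outputs echo the geometry so results are
reproducible from the config alone.

## Dose-response analysis

### Normalization

MTT wells are blank-handled by subtracting the 650 nm reference from the
570 nm formazan absorbance; each well is then 100 × its corrected signal
over the mean corrected signal of that plate's DMSO vehicle-control wells.
LDH wells use the kit convention
`100 * (signal - mean low control) / (mean high control - mean low control)`.
Both normalizations are invariant to rescaling all signals on a plate, and
both classify their failure modes: missing controls are validation errors,
a non-positive control mean or a high control not exceeding the low control
are data-quality errors.  Technical replicates are averaged within
biological replicate before any fitting or testing — the biological
replicate is the unit of replication.

### Four-parameter logistic fit

The response model on log10 concentration is

    y = bottom + (top - bottom) / (1 + 10^(hill*(log10 IC50 - log10 x)))

The vehicle control (0 µM) cannot sit on a log axis and is consumed by
normalization, so it is never a fitted point; at least four distinct
positive concentrations are required.

Numerical strategy: a deterministic profile grid search over
`(log10 IC50, hill)` — midpoints in 0.1-log steps from one decade below the
lowest to two decades above the highest tested concentration, 16 hill
values of both signs — with the two plateaus profiled in closed form
(bottom clamped at its lower bound, 0 % by default), followed by
Levenberg-Marquardt refinement with box constraints from the best grid
point.  The 4PL is symmetric under `(top, bottom, hill) ->
(bottom, top, -hill)`; fits are reported in the canonical orientation
`top >= bottom`, and mirrored grid candidates are discarded since their
counterpart at `-hill` is always present.  A singular or failed refinement
returns the grid solution flagged `converged = FALSE` — never an
exception.

A fit is *censored* when no midpoint within the tested range is
identified: non-convergence, fitted IC50 above the highest tested
concentration, an effect span `top - bottom` below 10 %, or no detectable
concentration effect at all (partial F-test of the 4PL against the
constant model, p > 0.05).  The span and F-test guards exist because a 4PL
fitted to flat-plus-noise data will happily report a meaningless midpoint;
requiring a detectable effect is what justifies printing a number instead
of a bound.  `report_ic50()` renders censored fits as `">bound"` (e.g.
`">50"`), carrying the comparator as a separate field so downstream code
never parses display strings.

### Group comparison

Groups (e.g. male vs female primary cultures) are compared at each shared
concentration with a two-sided Wilcoxon-Mann-Whitney rank-sum test whose
null distribution is obtained by complete enumeration of all
`choose(n1+n2, n1)` assignments, using mid-ranks for ties; the two-sided
p-value is the null probability of a rank sum at least as far from its
expectation as observed.  Enumeration is exact up to 8 per group (12870
assignments); beyond that a normal approximation with continuity
correction takes over.  Holm step-down adjusts across the concentration
grid — conservative, and valid for exact discrete tests.

Discreteness matters at the motivating design's n = 3 biological
replicates per group: the smallest attainable two-sided p is
2/20 = 0.1, so at alpha = 0.05 the per-concentration test can never
reject.  This is a property of any exact test at that sample size, not of
the implementation; the test suite verifies both this (empirical type-I
error exactly 0 at n = 3) and proper calibration at n = 4 per group,
where the attainable size is 2/70 ≈ 0.029.

## The synthetic-data generator

`simulation_scenario()` + `generate_plate()` emulate the study design the
analysis assumes: a 7-point 0/0.5/1/5/10/20/50 µM series, 3 biological × 3
technical replicates, 3 DMSO control wells per plate in a 24-well MTT
layout (96-well with triplicate low/high controls for LDH), with
ground-truth responses from a 4PL per compound.  Well noise is
multiplicative lognormal with 10 % CV by default (plate-reader error
scales with signal), mean exactly 1 so expected signals are unbiased; an
additive gaussian option exists.  Control wells have an expected
blank-corrected signal of 1.0 AU over a 0.05 AU blank — arbitrary
instrument-scale constants, never interpreted as biology.  Everything is
deterministic given the integer seed.

`generate_compound_library()` builds parent/hydroxylated/sulfated triplets
whose descriptor gradients encode the known class structure: V, L and E
grow with chlorination (hydrophobicity), hydroxylation adds H-bond acidity
and basicity, sulfation adds strong basicity and polarity.  The shipped
fixture table under `inst/extdata/` is the deterministic version of the
same scheme for the five named congeners (PCB3, 11, 25, 28, 52) and their
metabolites, with Henry constants decreasing mildly with chlorination.
These fixtures are synthetic and illustrative — real analyses should
supply descriptors and coefficient systems from curated LSER sources — but
they reproduce the qualitative structure the model predicts for the real
panel: cell association of parents rising with chlorination, sulfates
remaining >99 % in the medium, and the mono-chlorinated parent losing the
largest share to the headspace.

What passing tests on synthetic data do *not* show: that real plate noise
is lognormal with constant CV, that real MTT responses follow a 4PL
exactly, or that the fixture descriptors match any real congener.  They
show the machinery is correct conditional on the model; the model-data
match is a scientific question the package cannot settle.

## Problem sizes used in the shipped checks

The property checks run at sizes chosen to make failures obvious while
keeping the suite quick: 1000 random partitioning systems for conservation
and solver agreement, 100 simulated studies × 3 true IC50s (2.2, 8.8,
25 µM) for recovery (median |Δlog10 IC50| ≈ 0.04, comfortably within the
0.1 design target), 2000 null replicates for test calibration, and 20
seeds for the bias check.

## Known limitations

* Equilibrium only: compounds with slow uptake or active transport will
  deviate; the framework has no kinetic mode.
* No metabolism: e.g. intracellular sulfate hydrolysis back to the
  hydroxylated form — observed for some sulfates — is out of scope, which
  is precisely why a sulfate can be more toxic than the partitioning model
  alone would suggest.
* Ionization: PP-LFERs operate on neutral-form descriptors; the sulfate
  class is handled by the non-volatile override, not by true speciation
  modelling.
* No plastic sorption or extracellular protein binding (serum-free
  assumption).
* The exact test's discreteness at n = 3 per group limits per-concentration
  power to detecting nothing below p = 0.1; conclusions of "no significant
  difference" at that design are weak by construction.
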