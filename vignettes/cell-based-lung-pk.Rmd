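---
title: "A cell-based compartmental model of regional drug disposition in the lung"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cell-based compartmental model of regional drug disposition in the lung}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pulmocell)
```

## The model

pulmocell predicts where an ionizable small molecule goes after local
(intratracheal, IT) or systemic (intravenous, IV) administration to the
lung, and how long it stays there. The lung is represented as two lumped
regions — the conducting **airways** and the **alveoli** — each built as a
chain of cellular compartments between air and blood:

    lining fluid <-> epithelium <-> interstitium <-> endothelium <-> regional blood

with smooth muscle (airways only), macrophages and immune cells exchanging
with the interstitium, and mitochondria nested inside the epithelial,
endothelial and smooth-muscle cells. Regional blood connects to a venous and
an arterial pool; the alveoli receive the entire cardiac output, the airways
about 1% of it (the bronchial circulation). A single-compartment elimination
term, $V_b\,dC_b/dt = -CL\,C_b$, acts on the venous pool.

Within each compartment a monoprotic base splits into neutral and
protonated species by the Henderson–Hasselbalch equilibrium,
$f_n = 1/(1+10^{pK_a - pH})$, and each species binds instantaneously to the
compartment's lipid sub-volume so that its free aqueous fraction is
$f_w/(f_w + f_l\,10^{\log P})$. Free aqueous concentration is the driving
force for all transport. The neutral species crosses each bilayer by Fick
diffusion, $J_n = P_n\,(C_{out} - C_{in})$; the ionized species by the
constant-field Nernst–Planck (Goldman) flux

$$J_d = P_d\,N\,\frac{C_{out} - C_{in} e^{N}}{e^{N} - 1},
\qquad N = \frac{zFE}{RT},$$

which collapses to Fick's law as $N \to 0$ and vanishes at the Nernst
equilibrium $C_{in} = C_{out}e^{-N}$. Permeability maps from lipophilicity
as $P = \alpha\,10^{\log P}$ with a single global scale $\alpha$.
Permanent cations (such as the MitoTracker-like probe MTR) have only the
ionized pathway; the two inside-negative potentials — plasma membrane
($-70$ mV) and mitochondrial inner membrane ($-160$ mV) — then act as
ratchets: at $-160$ mV and 310 K the equilibrium free-concentration ratio is
$e^{-N} \approx 399$. This mitochondrial sequestration, multiplied by the
plasma-membrane Boltzmann factor, is the mechanism that retains hydrophilic
permeant cations at their site of absorption.

Because binding and ionization are linear in concentration, the whole
system is a linear constant-coefficient ODE system $\dot M = A M$. The rate
matrix is assembled once per compound and integrated with the stiff `lsoda`
solver (deSolve) using the analytic Jacobian; with clearance zero every
column of $A$ sums to zero, so mass conservation is exact by construction
and is verified numerically in the test suite.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha` | 3.1e-6 | cm/s | global permeability scale at logP = 0; the single calibrated constant (see below) |
| `plasma_potential` | -0.070 | V | inside-negative plasma membrane |
| `mitochondrial_potential` | -0.160 | V | inner-membrane potential driving cation sequestration |
| epithelium area ratio | 100 | — | alveolar surface is two orders of magnitude larger than the airways |
| blood flow | 0.8 / 80 | ml/min | airways ~1% of cardiac output, alveoli 100% |
| `V_venous`, `V_arterial` | 13.6, 6.8 | ml | rat-scale systemic blood pools |
| compartment pH | 6.9 / 7.0 / 7.4 / 8.0 | — | lining, cytosol, interstitium-blood, mitochondrial matrix |
| `sm_mito_fraction` | 0.07 | — | volume fraction of airway smooth muscle that is mitochondria |
| logPd offset | 3.5 | log10 | default ionized-species partition penalty when logPd is not measured |

All baseline numbers live in one shipped file,
`system.file("extdata", "lung_default.yaml", package = "pulmocell")`, and
any subset can be overridden by a user YAML passed to `load_config()`.

The anatomical volumes deserve comment, because regional contrast is driven
almost entirely by three asymmetries between the regions:

1. **Volume and area scale.** The alveolar region is ~100× the airway
   region in both epithelial area and total volume, so the same dose
   instilled into each region starts at a ~100-fold concentration contrast.
2. **Cell density.** Alveolar septa are cell- and membrane-rich per unit
   region volume relative to the thin-walled airway sleeve (whose wall here
   is mostly aqueous interstitium and lining). Lipophilic compounds
   partition into membranes, so at distributional equilibrium they
   concentrate ~2-fold in the alveoli.
3. **Mitochondrial density per unit absorption area.** Airway smooth muscle
   and epithelium carry far more mitochondrial volume per cm² of absorptive
   surface than the alveolar septum, whose surface is dominated by thin,
   organelle-poor type-I pneumocytes. Permeant cations therefore load into
   a large airway sink that empties only slowly through a small membrane
   area, while the alveolar pool drains quickly into the blood.

These volumes were fixed once, by construction against the qualitative
behavior the model is meant to express (the screen's contrast range, the
probe contrasts, and the dominance of smooth-muscle mitochondria in the
exchange analysis), with `alpha` as the only tuned rate constant. They are
a lumped idealization, not a morphometric measurement.

## Dosing and study designs

* **IT probe mode** — 1 mM in the lining fluid of either or both regions
  (`dose_spec("IT", conc_mM = 1, target = "both")`), closed circulation,
  clearance zero; the default 240-min horizon covers the 40–60 min
  observation window with margin.
* **IV probe mode** — the same total mass as a venous bolus,
  $C_0 = \text{dose}\times BW / V_{ven}$, assuming no plasma protein
  binding and a blood:plasma ratio of 1.
* **IT screening** — 1 mg/kg into one region per run, over a
  $\log P_n \times pK_a$ grid of monoprotic bases (ionized-species logP
  derived by the 3.5 offset). The systemic pool is held at zero
  concentration (`options.screen_it_fixed_blood`), so the screen measures
  absorption into an effectively infinite systemic sink. This mirrors the
  fixed-blood-concentration convention of the IV screen; in a fully closed
  system every compound eventually relaxes to the same global equilibrium
  and the regional AUC contrast collapses toward the regions' partition
  ratio, which would erase precisely the contrast the screen is designed to
  rank. The closed recirculating variant remains available by setting the
  option to `FALSE`. The screening horizon defaults to 140 min: long enough
  for the fast-draining corner of the grid to clear its region, short
  enough that slowly-released compounds remain region-bound.
* **IV screening** — blood clamped at $C_0$ (infinite reservoir);
  steady-state regional masses are obtained by a direct linear solve of the
  clamped system.

The airway:alveoli AUC ratio divides the airway AUC of the airway-dosed run
by the alveolar AUC of the alveoli-dosed run, each AUC taken by the
trapezoidal rule over the simulation horizon (reported alongside it).

## The parameter-exchange analysis

`parameter_exchange_analysis()` swaps one named parameter between the
regions at a time, re-simulates the cation probe, and classifies the airway
and alveolar AUC fold changes (1.1–1.5 one sign, 1.5–2 two signs, >5 three
signs; the 2–5 band has no symbol in the source scheme and is flagged
explicitly as `"two-to-five"`). Clearance is scaled ×10 rather than
swapped; because the probe baseline uses zero clearance — and scaling zero
is a no-op — a zero baseline substitutes the configured
`clearance_exchange_value`.

One allocation choice shapes this analysis: the region's
`mitochondria_volume` parameter covers epithelial plus endothelial
mitochondria, while smooth-muscle mitochondria are a fixed fraction of the
smooth-muscle volume and are therefore added and removed *with* the smooth
muscle. If instead the regional mitochondrial total were pinned by the
parameter and re-allocated whenever a cell type disappears, removing the
smooth muscle would leave the airway cation capacity untouched and the
exchange analysis could never attribute retention to it. The cost of this
choice is that swapping the (small) epithelial/endothelial mitochondrial
parameter alone has little effect here, whereas the source analysis reports
a 1.5–2-fold decrease for that row.

## Numerical choices

* Stiff integration with `lsoda`, relative and absolute tolerance
  $10^{-12}$, analytic (constant) Jacobian. The cation parameterization
  spans rate constants over ~9 orders of magnitude and integrates without
  step failures.
* Output on a hybrid geometric-plus-linear time grid (dense early), so the
  trapezoidal AUC of fast initial transients is accurate.
* Negative masses within solver tolerance are clamped to zero; anything
  larger aborts with a diagnostic, since it indicates a mis-assembled
  graph rather than roundoff.
* The Goldman flux uses the numerically stable form on each sign of $N$
  and switches to the Fick limit below $|N| < 10^{-6}$.
* Steady states under clamped blood are computed by a direct solve of the
  clamped linear system rather than by long integration.

Verification is two-route throughout the test suite: trajectories against
the matrix exponential of the assembled rate matrix; closed-system
equilibria against closed-form nested Boltzmann/pH-partition products
computed independently of the assembly; and single-membrane steady states
against two-compartment integrations built directly from the flux
primitives.

## Problem sizes

The shipped analyses use a coarse 13 × 10 screening grid (0.5 logP and
1 pKa steps, 130 points; the full-resolution grid of 61 × 46 = 2806 points
is available through `screen_grid()` defaults), 240-min probe horizons and
a 140-min screening horizon. These sizes keep a complete screen + probe +
exchange cycle under half a minute on one CPU.

## Open questions settled here

* The source material quotes the Hoechst-like probe's pKa as 7.8 in one
  place and 7.5 in another; the shipped fixture uses 7.8, and the compound
  library CSV makes it a one-line change.
* Whether regional blood counts as lung tissue in the mass denominator is
  unstated in the source; here regional blood is part of its region
  (everything anatomically in the region), and systemic venous/arterial
  blood is not.
* Whether IT screening couples the regions through shared blood is
  ambiguous; under the fixed-blood screening boundary the regions decouple,
  and a config switch (`it_isolated_regions`) exists for the closed
  variant.

## Known limitations

* Two lumped regions: no per-generation airway tree, no intra-regional
  gradients.
* Passive transcellular transport only — no transporters, no paracellular
  shunt, no mucociliary clearance, no aerosol deposition physics; IT dosing
  is an instantaneous well-mixed bolus into the lining fluid.
* Linear pharmacology: no saturable binding or clearance; instantaneous
  binding and ionization equilibria.
* Only monoprotic bases, permanent monocations and neutrals; acids,
  zwitterions and polyprotics are out of scope.
* The exchange table reproduces the source's smooth-muscle dominance,
  interstitium row and all "unaffected" rows, but not the sign of the
  epithelium-area row (in a concentration-driven bidirectional model a
  larger exchange area accelerates entry *and* exit) nor the
  mitochondria-parameter row (see the allocation note above); the
  endothelium-area row decreases more strongly than printed. Absolute
  screen magnitudes inherit the calibration caveat: they depend on `alpha`
  and on lumped volumes that stand in for unpublished morphometry.
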