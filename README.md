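# pulmocell

A cell-based, multiscale pharmacokinetic simulator of the lung for
ionizable small molecules. pulmocell is for scientists designing inhaled
drugs or site-directed bioimaging probes who need to know *where in the
lung* a molecule will deposit and persist — conducting airways versus
alveoli — as a function of its physicochemical properties (logP of the
neutral and ionized species, pKa, fixed charge) and of the route of
administration (intratracheal instillation vs intravenous injection).

## The model

Each lung region (airways, alveoli) is a chain of cellular compartments
between air and blood — lining fluid, epithelium, interstitium (with smooth
muscle, macrophages and immune cells in the airways), endothelium, regional
blood, with mitochondria nested inside the cells — coupled to a systemic
venous/arterial circulation with single-compartment clearance
(V_b dC_b/dt = −CL·C_b). In every compartment a monoprotic base ionizes by
Henderson–Hasselbalch, f_n = 1/(1 + 10^(pKa − pH)), and each species binds
lipid so that its free aqueous fraction is f_w/(f_w + f_l·10^logP). The
free neutral species crosses each bilayer by Fick diffusion,
J_n = P_n (C_out − C_in); the ionized species by the Nernst–Planck
(Goldman) flux

    J_d = P_d · N · (C_out − C_in·e^N) / (e^N − 1),   N = zFE/RT

with membrane potentials of −70 mV (plasma) and −160 mV (mitochondrial
inner membrane), and permeability P = α·10^logP. At −160 mV the Boltzmann
factor e^(−N) ≈ 399, which is why membrane-permeant hydrophilic cations are
sequestered by mitochondria — the mechanism that retains them in the
mitochondria-rich airway wall after local administration.

The resulting stiff linear ODE system is integrated with `deSolve::lsoda`
(tolerances 1e−12, analytic Jacobian). On top of the simulator the package
provides the pharmacokinetic indexes (regional tissue concentration,
trapezoidal AUC, mass deposition percentages, time to steady state), a
virtual screen over a logPn × pKa grid for both routes, and a one-at-a-time
airway/alveoli parameter-exchange sensitivity analysis.

## Worked example

Simulate the two fluorescent probes of the screening study — MTR, a
permanently charged hydrophilic cation (logPd 0.16), and Hoe, a lipophilic
weak base (logPn 4.49, pKa 7.8) — instilled at 1 mM into the lining fluid
of both regions:

```r
library(pulmocell)
lung   <- default_lung()
probes <- read_compound_library()

sim <- simulate_lung(lung, probes$MTR,
                     dose_spec("IT", conc_mM = 1, target = "both"))
region_metrics(sim)
#>    region   auc auc_horizon final_concentration mass_percent_end  t_ss
#> 1 airways 15.48         240              0.0584             6.97 144.0
#> 2 alveoli  1.62         240              0.0065            93.03  28.2

conc_aw  <- region_tissue_concentration(sim, "airways")
conc_alv <- region_tissue_concentration(sim, "alveoli")
win <- sim$times >= 40 & sim$times <= 60
mean(conc_aw[win] / conc_alv[win])
#> [1] 10.14
```

Reading: over a 240-min horizon the airway tissue-concentration AUC
(15.5 mg/ml·min) is an order of magnitude above the alveolar one
(1.6 mg/ml·min), and 40–60 min after instillation the airway concentration
is ~10× the alveolar concentration — the cation stays where it was
deposited, even though by mass most of the dose (93%) sits in the much
larger alveolar region. Running the same protocol with `probes$Hoe`
inverts the contrast (the weak base redistributes ~1.7× in favor of the
alveoli), and `run_screen()` maps this contrast over the whole
physicochemical property grid.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "pulmocell", package = "pulmocell"))')" \
    simulate --compound MTR --route IT --out results/
```

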