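Package: pulmocell
Title: Cell-Based Multiscale Lung Pharmacokinetic Simulation for Ionizable Small Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A compartmental, cell-based pharmacokinetic simulator of the lung
    for ionizable small molecules. Airways and alveoli are represented as
    lumped cellular compartment graphs (lining fluid, epithelium,
    interstitium, smooth muscle, immune cells, endothelium, regional blood,
    with nested mitochondria) joined to a single-compartment systemic
    circulation. Transmembrane transport of the neutral and ionized species
    is computed with the Fick and Nernst-Planck equations; ionization follows
    the Henderson-Hasselbalch equation and lipid binding is an instantaneous
    free-fraction equilibrium. The package supports intratracheal and
    intravenous dosing, virtual screening over a logP/pKa property grid,
    regional AUC and mass-deposition metrics, and one-at-a-time
    airway/alveoli parameter-exchange sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
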