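# Default lung model configuration. This file is the single source of truth
# for all baseline anatomical, physiological and biophysical parameter values
# used by pulmocell. All volumes in ml, areas in cm^2, flows in ml/min,
# potentials in volts, pH dimensionless.
#
# The two lumped regions are the conducting airways — a compact wall sleeve
# of epithelium, mitochondria-rich smooth muscle and bronchial
# microcirculation, receiving ~1% of cardiac output — and the alveoli, whose
# epithelial surface area is two orders of magnitude larger and whose thin
# septa are dominated by capillary blood, receiving the entire cardiac
# output. Alveolar cells carry negligible mitochondrial volume (the surface
# is mostly thin type-I pneumocytes); airway epithelium and especially
# airway smooth muscle are mitochondria-rich, so mitochondrial density per
# unit absorption surface area is far higher in the airways. Rat-like
# whole-body scaling (0.25 kg body weight, 20.4 ml total blood).
regions:
  airways:
    epithelium_surface_area: 30.0
    endothelium_surface_area: 12.0
    lining_fluid_volume: 0.0075
    epithelial_cell_volume: 0.0009
    endothelial_cell_volume: 0.0006
    interstitium_volume: 0.012
    smooth_muscle_volume: 0.003
    macrophage_volume: 0.0002
    immune_cell_volume: 0.0002
    mitochondria_volume: 5.0e-6
    regional_blood_volume: 0.004
    blood_flow_rate: 0.8
  alveoli:
    epithelium_surface_area: 3000.0
    endothelium_surface_area: 3000.0
    lining_fluid_volume: 0.08
    epithelial_cell_volume: 1.15
    endothelial_cell_volume: 0.23
    interstitium_volume: 0.04
    smooth_muscle_volume: 0.0
    macrophage_volume: 0.001
    immune_cell_volume: 0.001
    mitochondria_volume: 2.0e-6
    regional_blood_volume: 1.9
    blood_flow_rate: 80.0
systemic:
  V_venous: 13.6
  V_arterial: 6.8
  CL: 0.0
  cardiac_output: 80.0
  body_weight: 0.25
compartment_defaults:
  lining_fluid:        {pH: 6.9, f_w: 0.98, f_l: 0.001}
  epithelial_cytosol:  {pH: 7.0, f_w: 0.70, f_l: 0.05}
  mitochondria:        {pH: 8.0, f_w: 0.70, f_l: 0.05}
  interstitium:        {pH: 7.4, f_w: 0.92, f_l: 0.01}
  smooth_muscle:       {pH: 7.0, f_w: 0.70, f_l: 0.05}
  macrophage:          {pH: 7.0, f_w: 0.70, f_l: 0.05}
  immune_cell:         {pH: 7.0, f_w: 0.70, f_l: 0.05}
  endothelial_cytosol: {pH: 7.0, f_w: 0.70, f_l: 0.05}
  regional_blood:      {pH: 7.4, f_w: 0.82, f_l: 0.002}
  venous_blood:        {pH: 7.4, f_w: 0.82, f_l: 0.002}
  arterial_blood:      {pH: 7.4, f_w: 0.82, f_l: 0.002}
membranes:
  alpha: 3.1e-6
  temperature: 310.0
  plasma_potential: -0.070
  mitochondrial_potential: -0.160
  mito_area_per_ml: 5000.0
  cell_area_per_ml: 2000.0
  sm_mito_fraction: 0.07
options:
  clearance_exchange_value: 0.5
  it_isolated_regions: false
  screen_it_fixed_blood: true
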