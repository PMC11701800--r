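# Reference configuration of the perfused microscaffold chamber study.
# Lengths accept unit suffixes (m, mm, um); flow rates accept uL/min.
chamber:
  length_x: 6 mm
  width_y: 3 mm
  height_z: 0.5 mm
  inlet_diameter: 0.76 mm
  inlet_height: 3 mm
  half_model: true
microstructure:
  footprint_x: 500 um
  footprint_y: 500 um
  height: 40 um
  pore_x: 50 um
  pore_y: 50 um
  pore_z: 20 um
  beam_axial: 4.9 um
  beam_lateral: 1 um
array:
  n_rows: 2
  n_cols: 8
  pitch_x: 750 um
  lateral_offset: 0 um
grid:
  dx: 125 um
  dy: 125 um
  dz_fine: 5 um
  fine_height: 50 um
  growth: 1.6
fluid:
  mu: 6.9e-4          # Pa s, water at 37 C
  rho: 993            # kg/m3
  temperature: 37
oxygen:
  D: 2e-9 m2/s
  C0: 0.2 mol/m3
  Vmax: 4e-17 mol/s   # per cell
  Km: 5.5e-4 mol/m3
loading:
  n_total: 50000
  n_array: 32000
  n_flat: 18000
conversion:
  percent_atm_inlet: 18.6
  hypoxia_percent: 1
  normoxia_percent: 13
ranges:
  velocity_min: 0.1 um/s
  velocity_max: 5 um/s
  velocity_max_broad: 10 um/s
  wss_min: 0.1 mPa
  wss_max: 10 mPa
sweep:
  rates_uL_min: [1, 3, 5, 10]
  rule: largest
unit_cell:
  spacing: 2.5 um
  clearance: 40 um
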