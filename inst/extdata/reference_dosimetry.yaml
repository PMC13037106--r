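# Reference dosimetry configuration: superparticle geometry, field
# generators, force calibrations, and stimulation protocols as published
# for the f-SPION sciatic-nerve stimulation study conditions.
schema_version: "1.0"
seed: 1
moment_mode: calibrated

particle:
  core_diameter_nm: 56.60
  crystallite_diameter_nm: 5.80
  shell_thickness_nm: 5.79
  packing_fraction: 0.62          # calibrated constant, see docs
  magnetite_density_g_cm3: 5.18
  saturation_magnetization_emu_g: 30

cell_iron_uptake_pg: 2.05         # mean ICP-AES uptake per cell

electromagnet_current_A: 3

field_sources:
  electromagnet:
    kind: electromagnet_calibration
    calibration_points:           # [current_A, gradient_T_per_m]
      - [1.0, 1.25]
      - [2.0, 2.25]
      - [3.0, 3.25]
  ring_array:
    kind: ring_array
    inner_radius_mm: 35
    outer_radius_mm: 75
    thickness_mm: 15
    center_z_mm: [-30, -15, 15, 30]   # two pairs, 15 mm apart
    polarity: [1, 1, -1, -1]          # opposed pairs -> gradient at center
    remanence_T: 1.40                 # assumed N48-grade NdFeB

force_calibration:
  invitro: {force_pN: 1.59e-5, gradient_T_m: 3.25}
  invivo:  {force_pN: 1.27e-4, gradient_T_m: 16.0}

protocols:
  invitro:
    mode: cyclic
    on_min: 15
    off_min: 15
    total_span_h: 12
  invivo:
    mode: daily_sessions
    session_start_hours: [6, 12, 18]
    session_min: 15
    n_days: 14

measurements:
  nerve_iron_csv: nerve_iron_timeseries.csv
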