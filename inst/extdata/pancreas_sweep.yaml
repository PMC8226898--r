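# Full-volume pancreas sweep scenario: 50 x 10 mm array, beam focused
# 25-75 mm deep through couplant gel / skin / fat into pancreas.
# Skin, fat and pancreas properties are ASSUMED literature-typical values
# (the source table for this scenario is not available); the operating
# frequency is likewise a configuration choice. Layer thicknesses are
# assumptions.
scenario: pancreas_sweep
description: full-volume couplant/skin/fat/pancreas sweep profile
media:
  couplant:
    density_kg_m3: 1000
    sound_speed_m_s: 1480
    attenuation_db_cm_mhz: 0.00025
    power_law_exponent: 2
    nonlinearity: 0
    specific_heat_j_kg_k: 4180
    thermal_conductivity_w_m_k: 0.615
    blood_perfusion_kg_m3_s: 0
    blood_specific_heat_j_kg_k: 3480
  skin:
    density_kg_m3: 1109
    sound_speed_m_s: 1624
    attenuation_db_cm_mhz: 0.60
    power_law_exponent: 1
    nonlinearity: 1
    specific_heat_j_kg_k: 3391
    thermal_conductivity_w_m_k: 0.37
    blood_perfusion_kg_m3_s: 2.0
    blood_specific_heat_j_kg_k: 3617
  fat:
    density_kg_m3: 911
    sound_speed_m_s: 1440
    attenuation_db_cm_mhz: 0.48
    power_law_exponent: 1
    nonlinearity: 1
    specific_heat_j_kg_k: 2348
    thermal_conductivity_w_m_k: 0.21
    blood_perfusion_kg_m3_s: 0.65
    blood_specific_heat_j_kg_k: 3617
  pancreas:
    density_kg_m3: 1087
    sound_speed_m_s: 1591
    attenuation_db_cm_mhz: 0.58
    power_law_exponent: 1
    nonlinearity: 1
    specific_heat_j_kg_k: 3164
    thermal_conductivity_w_m_k: 0.51
    blood_perfusion_kg_m3_s: 7.0
    blood_specific_heat_j_kg_k: 3617
stack:
  arterial_temperature_c: 37
  layers:                      # thicknesses: assumed
    - {medium: couplant, thickness_mm: 10}
    - {medium: skin, thickness_mm: 2}
    - {medium: fat, thickness_mm: 10}
    - {medium: pancreas, thickness_mm: 74}
grid:
  extent_mm: [80, 60, 90]
  spacing_mm: [0.7, 0.7, 1.0]
array:
  aperture_mm: [50, 10]
  nx: 16
  ny: 16
  kerf_um: 1
  frequency_mhz: 1.0
  focus_mm: [0, 0, 50]
  v0_m_per_s: 1
sweep:
  x_elements: {from: 16, to: 128, by: 4}
  y_elements: {from: 16, to: 64, by: 4}
  focus_mm: {from: 25, to: 75, by: 1}
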