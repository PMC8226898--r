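# Fast pancreas sweep profile: same tissue stack as pancreas_sweep on a
# coarse grid at a lower frequency, sized so one full simulation
# (source plane -> propagation -> bio-heat) runs in seconds. Used by the
# test suite and the scaled-down end-to-end pipeline; the sweep block
# subsamples the full design down to 2 x 2 x 30 = 120 combinations. The
# focus distance stays the densest-sampled dimension, as in the full design
# (51 focus levels vs 29 x 13 element counts); in particular it keeps more
# distinct focus levels than the 20-leaf budget of the regression tree, the
# property that separates piecewise-constant trees from the forest at the
# full design's scale.
scenario: pancreas_sweep_fast
description: coarse-grid fast profile of the pancreas sweep scenario
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
  layers:
    - {medium: couplant, thickness_mm: 10}
    - {medium: skin, thickness_mm: 2}
    - {medium: fat, thickness_mm: 10}
    - {medium: pancreas, thickness_mm: 74}
grid:
  extent_mm: [78.4, 28, 88]
  spacing_mm: [1.4, 1.4, 2.0]
array:
  aperture_mm: [50, 10]
  nx: 16
  ny: 16
  kerf_um: 1
  frequency_mhz: 0.5
  focus_mm: [0, 0, 50]
  v0_m_per_s: 1
  pad_factor: [2, 3]
sweep:
  x_elements: [16, 128]
  y_elements: [16, 64]
  focus_mm: [25, 26.72, 28.45, 30.17, 31.9, 33.62, 35.34, 37.07, 38.79,
             40.52, 42.24, 43.97, 45.69, 47.41, 49.14, 50.86, 52.59,
             54.31, 56.03, 57.76, 59.48, 61.21, 62.93, 64.66, 66.38,
             68.1, 69.83, 71.55, 73.28, 75]
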