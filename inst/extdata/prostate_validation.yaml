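# Endorectal validation scenario: 2.3 MHz phased array focused 40 mm deep
# through water / rectal wall / periprostate / prostate.
# Tissue properties are published values; layer thicknesses and the
# rectangular tiling of the 990-element array are ASSUMPTIONS (the source
# description does not state them numerically). The source velocity v0 is
# arbitrary: absolute pressure/temperature scale with v0 and must be
# calibrated against a known peak rise (see validate_scenario()).
scenario: prostate_validation
description: 2.3 MHz endorectal array, focus 40 mm deep in prostate
validation: true
media:
  water:
    density_kg_m3: 1000
    sound_speed_m_s: 1480
    attenuation_db_cm_mhz: 0.00025
    power_law_exponent: 2
    nonlinearity: 0
    specific_heat_j_kg_k: 4180
    thermal_conductivity_w_m_k: 0.615
    blood_perfusion_kg_m3_s: 0
    blood_specific_heat_j_kg_k: 3480
  rectal_wall:
    density_kg_m3: 1060
    sound_speed_m_s: 1500
    attenuation_db_cm_mhz: 0.5211
    power_law_exponent: 1
    nonlinearity: 1
    specific_heat_j_kg_k: 3500
    thermal_conductivity_w_m_k: 0.56
    blood_perfusion_kg_m3_s: 4
    blood_specific_heat_j_kg_k: 3720
  periprostate:
    density_kg_m3: 1060
    sound_speed_m_s: 1500
    attenuation_db_cm_mhz: 0.4343
    power_law_exponent: 1
    nonlinearity: 1
    specific_heat_j_kg_k: 3500
    thermal_conductivity_w_m_k: 0.50
    blood_perfusion_kg_m3_s: 5
    blood_specific_heat_j_kg_k: 3720
  prostate:
    density_kg_m3: 1060
    sound_speed_m_s: 1500
    attenuation_db_cm_mhz: 0.504
    power_law_exponent: 1
    nonlinearity: 1
    specific_heat_j_kg_k: 3600
    thermal_conductivity_w_m_k: 0.50
    blood_perfusion_kg_m3_s: 2.5
    blood_specific_heat_j_kg_k: 3720
stack:
  arterial_temperature_c: 37
  layers:                      # thicknesses: assumed, not published
    - {medium: water, thickness_mm: 15}
    - {medium: rectal_wall, thickness_mm: 4}
    - {medium: periprostate, thickness_mm: 5}
    - {medium: prostate, thickness_mm: 56}
grid:
  extent_mm: [48, 28, 60]
  spacing_mm: [0.32, 0.32, 1.0]
array:
  aperture_mm: [40, 23]        # 990 elements over 40 x 23 mm (assumed 45 x 22 tiling)
  nx: 45
  ny: 22
  kerf_um: 1
  frequency_mhz: 2.3
  focus_mm: [0, 0, 40]
  v0_m_per_s: 0.05
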