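# Shared fixtures, built in code. Media use the published property table
# of the validation scenario (water / prostate rows).

water_medium <- function(lossless = FALSE) {
  medium("water", density = 1000, sound_speed = 1480,
         attenuation = if (lossless) 0 else 0.00025, power_law_exponent = 2,
         specific_heat = 4180, thermal_conductivity = 0.615,
         blood_perfusion = 0, blood_specific_heat = 3480)
}

prostate_medium <- function() {
  medium("prostate", density = 1060, sound_speed = 1500,
         attenuation = 0.504, power_law_exponent = 1,
         specific_heat = 3600, thermal_conductivity = 0.50,
         blood_perfusion = 2.5, blood_specific_heat = 3720)
}

rectal_wall_medium <- function() {
  medium("rectal_wall", density = 1060, sound_speed = 1500,
         attenuation = 0.5211, power_law_exponent = 1,
         specific_heat = 3500, thermal_conductivity = 0.56,
         blood_perfusion = 4, blood_specific_heat = 3720)
}

water_stack <- function(thickness_mm = 40, lossless = TRUE) {
  layered_stack(list(list(medium = water_medium(lossless = lossless),
                          thickness_mm = thickness_mm)))
}

# build a pressure field object directly (for intensity/metrics tests)
manual_field <- function(p, grid, stack, layer_index, f_mhz = 1,
                         source_index = 1L) {
  structure(list(p = p, grid = grid, stack = stack,
                 layer_index = layer_index, source_index = source_index,
                 source_z = 0, f_mhz = f_mhz),
            class = "fus_field")
}

manual_scalar <- function(values, grid, role, units, layer_index) {
  structure(list(values = values, grid = grid, role = role, units = units,
                 layer_index = layer_index), class = "fus_scalar")
}

# The fast-profile sweep dataset takes minutes to build, and several checks
# consume it; build it once per test run.
.fixture_env <- new.env(parent = emptyenv())

fast_sweep_dataset <- function() {
  if (!is.null(.fixture_env$dataset)) return(.fixture_env$dataset)
  cfg <- load_config(packaged_configs("pancreas_sweep_fast"))
  spec <- sweep_spec(x_elements = unlist(cfg$sweep$x_elements),
                     y_elements = unlist(cfg$sweep$y_elements),
                     focus_mm = unlist(cfg$sweep$focus_mm))
  path <- file.path(tempdir(), "fast_sweep_dataset.csv")
  ds <- run_sweep(spec, cfg, path)
  .fixture_env$dataset <- ds
  ds
}

# synthetic smooth surrogate dataset (cheap stand-in where the physics
# pipeline itself is not under test)
synthetic_dataset <- function(n = 150, seed = 3, noise = 0.01) {
  set.seed(seed)
  nx <- sample(seq(16, 128, 4), n, replace = TRUE)
  ny <- sample(seq(16, 64, 4), n, replace = TRUE)
  fo <- sample(seq(25, 75, 1), n, replace = TRUE)
  base <- exp(-fo / 40) * (1 - exp(-nx / 30)) * (1 - exp(-ny / 20))
  data.frame(
    nx = nx, ny = ny, focus_mm = fo,
    max_pressure_pa = 3e6 * base * (1 + noise * rnorm(n)),
    max_power_w_m3 = 2e7 * base^2 * (1 + noise * rnorm(n)),
    max_temperature_c = 37 + 20 * base^2 * (1 + noise * rnorm(n))
  )
}
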