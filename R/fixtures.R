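# Deterministic small fixtures for tests and demos.

#' Generate a small deterministic fixture
#'
#' `toy_array`: a tiny 4 x 2-element scenario config (YAML).
#' `gaussian_temperature`: a synthetic temperature volume with a known
#' Gaussian rise (peak and sigmas recorded), for contour-width checks.
#' `tiny_sweep`: a 6-combination sweep spec (YAML).
#'
#' @param kind One of `"toy_array"`, `"gaussian_temperature"`,
#'   `"tiny_sweep"`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; fixtures are byte-identical for equal seeds.
#' @return Path of the written fixture file; for `gaussian_temperature`
#'   the known parameters are attached as attribute `params`.
#' @export
make_fixture <- function(kind = c("toy_array", "gaussian_temperature",
                                  "tiny_sweep"),
                         dir = tempdir(), seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  switch(kind,
    toy_array = {
      path <- file.path(dir, "toy_array.yaml")
      writeLines(c(
        "scenario: toy_array",
        "description: 4 x 2-element toy scenario for tests",
        "media:",
        "  water:",
        "    density_kg_m3: 1000",
        "    sound_speed_m_s: 1480",
        "    attenuation_db_cm_mhz: 0.00025",
        "    power_law_exponent: 2",
        "    specific_heat_j_kg_k: 4180",
        "    thermal_conductivity_w_m_k: 0.615",
        "    blood_perfusion_kg_m3_s: 0",
        "    blood_specific_heat_j_kg_k: 3480",
        "  tissue:",
        "    density_kg_m3: 1060",
        "    sound_speed_m_s: 1500",
        "    attenuation_db_cm_mhz: 0.504",
        "    power_law_exponent: 1",
        "    specific_heat_j_kg_k: 3600",
        "    thermal_conductivity_w_m_k: 0.50",
        "    blood_perfusion_kg_m3_s: 2.5",
        "    blood_specific_heat_j_kg_k: 3720",
        "stack:",
        "  arterial_temperature_c: 37",
        "  layers:",
        "    - {medium: water, thickness_mm: 10}",
        "    - {medium: tissue, thickness_mm: 40}",
        "grid:",
        "  extent_mm: [24, 16, 40]",
        "  spacing_mm: [1.2, 1.2, 2]",
        "array:",
        "  aperture_mm: [10, 5]",
        "  nx: 4",
        "  ny: 2",
        "  kerf_um: 1",
        "  frequency_mhz: 0.5",
        "  focus_mm: [0, 0, 25]",
        "  v0_m_per_s: 1"), path)
      path
    },
    gaussian_temperature = {
      path <- file.path(dir, "gaussian_temperature.rds")
      grid <- grid3d(41, 21, 41, 5e-4, 5e-4, 5e-4)
      peak <- 6.2
      sigma <- c(x = 2e-3, y = 1.5e-3, z = 4e-3)
      ta <- 37
      gx <- exp(-grid$x^2 / (2 * sigma[1]^2))
      gy <- exp(-grid$y^2 / (2 * sigma[2]^2))
      zc <- grid$z[ceiling(grid$nz / 2)]
      gz <- exp(-(grid$z - zc)^2 / (2 * sigma[3]^2))
      vol <- ta + peak * outer(gx, gy) %o% gz
      temp <- scalar_field(vol, grid, "temperature", "degC")
      saveRDS(list(field = temp,
                   params = list(peak = peak, sigma_m = sigma, ta = ta)),
              path)
      path
    },
    tiny_sweep = {
      path <- file.path(dir, "tiny_sweep.yaml")
      writeLines(c(
        "x_elements: [4, 8]",
        "y_elements: [2]",
        "focus_mm: [20, 25, 30]"), path)
      path
    })
}

#' Read a sweep spec from YAML
#'
#' @param path YAML file with keys `x_elements`, `y_elements`, `focus_mm`
#'   (each either an explicit list or `{from, to, by}`).
#' @return A [sweep_spec()].
#' @export
read_sweep_spec <- function(path) {
  raw <- yaml::yaml.load_file(path)
  rng <- function(v) {
    if (is.list(v) && !is.null(v$from)) seq(v$from, v$to, by = v$by %||% 1)
    else unlist(v)
  }
  sweep_spec(rng(raw$x_elements), rng(raw$y_elements), rng(raw$focus_mm))
}
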