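# Scenario configuration: YAML parsing, schema validation, unit
# normalisation. Configs use field-conventional units in their key names
# (mm, um, MHz, degC); everything is converted to SI objects here.

MEDIUM_KEYS <- c("density_kg_m3", "sound_speed_m_s", "attenuation_db_cm_mhz",
                 "power_law_exponent", "nonlinearity", "specific_heat_j_kg_k",
                 "thermal_conductivity_w_m_k", "blood_perfusion_kg_m3_s",
                 "blood_specific_heat_j_kg_k")
MEDIUM_REQUIRED <- c("density_kg_m3", "sound_speed_m_s",
                     "specific_heat_j_kg_k", "thermal_conductivity_w_m_k")
TOP_KEYS <- c("scenario", "description", "validation", "media", "stack",
              "grid", "array", "sweep", "surrogate", "seeds", "output")

check_keys <- function(block, allowed, required, path) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stop("config: unknown key(s) at ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(required, names(block))
  if (length(missing))
    stop("config: missing required key(s) at ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
}

parse_medium <- function(name, blk) {
  check_keys(blk, MEDIUM_KEYS, MEDIUM_REQUIRED, paste0("media.", name))
  g <- function(key, default = 0) if (is.null(blk[[key]])) default else blk[[key]]
  medium(name,
         density              = blk$density_kg_m3,
         sound_speed          = blk$sound_speed_m_s,
         attenuation          = g("attenuation_db_cm_mhz"),
         power_law_exponent   = g("power_law_exponent", 1),
         specific_heat        = blk$specific_heat_j_kg_k,
         thermal_conductivity = blk$thermal_conductivity_w_m_k,
         blood_perfusion      = g("blood_perfusion_kg_m3_s"),
         blood_specific_heat  = g("blood_specific_heat_j_kg_k"),
         nonlinearity         = g("nonlinearity"))
}

#' Load and validate a scenario configuration
#'
#' Reads a YAML scenario description (media properties, layered stack,
#' grid, array and excitation, optional sweep and surrogate blocks),
#' validates the schema (unknown keys rejected, units encoded in key
#' names), converts to SI, and records a content hash for provenance.
#'
#' @param path Path to a YAML config file. The configs shipped with the
#'   package can be listed with `packaged_configs()`.
#' @return Object of class `fus_config`: media (named [medium()] list),
#'   `stack`, `grid`, `array` parameters, excitation parameters, and any
#'   sweep/surrogate blocks, plus `hash`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::yaml.load_file(path)
  check_keys(raw, TOP_KEYS, c("media", "stack", "grid", "array"), "top level")

  media <- list()
  for (nm in names(raw$media)) media[[nm]] <- parse_medium(nm, raw$media[[nm]])

  check_keys(raw$stack, c("layers", "arterial_temperature_c"), "layers", "stack")
  layers <- lapply(raw$stack$layers, function(ly) {
    check_keys(ly, c("medium", "thickness_mm"), c("medium", "thickness_mm"),
               "stack.layers")
    if (is.null(media[[ly$medium]]))
      stop("config: stack layer refers to unknown medium '", ly$medium, "'",
           call. = FALSE)
    list(medium = media[[ly$medium]], thickness_mm = ly$thickness_mm)
  })
  ta <- if (is.null(raw$stack$arterial_temperature_c)) 37
        else raw$stack$arterial_temperature_c
  stack <- layered_stack(layers, arterial_temperature_c = ta)

  check_keys(raw$grid, c("extent_mm", "spacing_mm"),
             c("extent_mm", "spacing_mm"), "grid")
  ext <- raw$grid$extent_mm; sp <- raw$grid$spacing_mm
  if (length(ext) != 3 || length(sp) != 3)
    stop("config: grid.extent_mm and grid.spacing_mm must have 3 entries",
         call. = FALSE)
  n <- pmax(2, round(unlist(ext) / unlist(sp)))
  grid <- grid3d(n[1], n[2], n[3] + 1,
                 sp[[1]] * 1e-3, sp[[2]] * 1e-3, sp[[3]] * 1e-3)

  check_keys(raw$array,
             c("aperture_mm", "nx", "ny", "kerf_um", "frequency_mhz",
               "focus_mm", "v0_m_per_s", "pad_factor"),
             c("aperture_mm", "nx", "ny", "frequency_mhz", "focus_mm"),
             "array")
  arr <- raw$array
  arr$kerf_um <- if (is.null(arr$kerf_um)) 1 else arr$kerf_um
  arr$v0_m_per_s <- if (is.null(arr$v0_m_per_s)) 1 else arr$v0_m_per_s
  arr$aperture_mm <- unlist(arr$aperture_mm)
  arr$focus_mm <- unlist(arr$focus_mm)
  if (length(arr$focus_mm) == 1) arr$focus_mm <- c(0, 0, arr$focus_mm)

  cfg <- structure(list(
    scenario = raw$scenario, description = raw$description,
    validation = isTRUE(raw$validation),
    media = media, stack = stack, grid = grid, array = arr,
    sweep = raw$sweep, surrogate = raw$surrogate, seeds = raw$seeds,
    output = raw$output,
    hash = unname(tools::md5sum(path))
  ), class = "fus_config")
  cfg
}

#' @exportS3Method base::print
print.fus_config <- function(x, ...) {
  cat("<fus_config>", x$scenario %||% "(unnamed)", "\n")
  cat("  media:", paste(names(x$media), collapse = ", "), "\n")
  print(x$stack)
  print(x$grid)
  cat(sprintf("  array %d x %d over %s mm, %g MHz, focus (%s) mm\n",
              x$array$nx, x$array$ny,
              paste(x$array$aperture_mm, collapse = " x "),
              x$array$frequency_mhz,
              paste(x$array$focus_mm, collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paths of the scenario configs shipped with the package
#'
#' `prostate_validation`: the 2.3 MHz endorectal validation scenario with
#' published water/rectal-wall/periprostate/prostate properties (layer
#' thicknesses are documented assumptions). `pancreas_sweep`: the
#' full-volume couplant/skin/fat/pancreas sweep scenario.
#' `pancreas_sweep_fast`: the same stack on a coarse grid at a lower
#' frequency, sized so one simulation takes seconds (used by the tests and
#' the scaled-down pipeline).
#'
#' @param name Optional config name (without extension); returns its path.
#' @return Named character vector of paths, or a single path.
#' @export
packaged_configs <- function(name = NULL) {
  dir <- system.file("extdata", package = "focusurf")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  out <- stats::setNames(files, sub("\\.yaml$", "", basename(files)))
  if (is.null(name)) return(out)
  if (!name %in% names(out))
    stop("no packaged config named '", name, "'", call. = FALSE)
  unname(out[name])
}
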