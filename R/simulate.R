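# Full simulation chain for one scenario: array -> Rayleigh source plane ->
# angular-spectrum propagation -> intensity -> power deposition ->
# steady-state temperature -> focal-zone maxima.

#' Run one focused-ultrasound simulation
#'
#' Executes the whole pipeline described by a scenario config, optionally
#' overriding the array element counts and focus depth (the sweep
#' parameters).
#'
#' @param config A [load_config()] object.
#' @param nx,ny Optional element-count overrides.
#' @param focus_mm Optional focus override: scalar depth (mm, on-axis) or
#'   length-3 point.
#' @param thermal Run the bio-heat stage (default TRUE).
#' @param target_layer Medium name of the target tissue for focal metrics;
#'   defaults to the deepest layer.
#' @param bioheat Optional pre-assembled [bioheat_factor()] (reused across
#'   sweep runs).
#' @return Object of class `fus_sim`: the pressure field, intensity, power
#'   deposition and temperature fields, and a `metrics` list with
#'   `max_pressure_pa`, `max_power_w_m3`, `max_temperature_c` over the
#'   target layer.
#' @export
simulate_scenario <- function(config, nx = NULL, ny = NULL, focus_mm = NULL,
                              thermal = TRUE, target_layer = NULL,
                              bioheat = NULL) {
  stopifnot(inherits(config, "fus_config"))
  arr_cfg <- config$array
  if (!is.null(nx)) arr_cfg$nx <- nx
  if (!is.null(ny)) arr_cfg$ny <- ny
  if (!is.null(focus_mm)) {
    if (length(focus_mm) == 1) focus_mm <- c(0, 0, focus_mm)
    arr_cfg$focus_mm <- focus_mm
  }
  array <- build_array(arr_cfg$nx, arr_cfg$ny,
                       aperture_mm = arr_cfg$aperture_mm,
                       kerf_um = arr_cfg$kerf_um)
  couplant <- config$stack$layers[[1]]$medium
  exc <- focused_excitation(array, arr_cfg$focus_mm,
                            c_ref = couplant$sound_speed,
                            f_mhz = arr_cfg$frequency_mhz,
                            v0 = arr_cfg$v0_m_per_s)
  src <- rayleigh_plane(array, exc, couplant, config$grid)
  pad <- arr_cfg$pad_factor %||% 2
  field <- propagate_stack(src, config$stack, config$grid, exc,
                           pad_factor = pad)
  ia <- acoustic_intensity(field)
  q <- power_deposition(ia, config$stack, exc$f_mhz)
  temp <- NULL
  if (thermal) temp <- steady_bioheat(q, config$stack, factor = bioheat)
  if (is.null(target_layer))
    target_layer <- config$stack$layers[[length(config$stack$layers)]]$medium$name
  metrics <- focal_metrics(field, q, temp, target_layer)
  structure(list(config_hash = config$hash, array = array, excitation = exc,
                 field = field, intensity = ia, power = q, temperature = temp,
                 target_layer = target_layer, metrics = metrics),
            class = "fus_sim")
}

#' @exportS3Method base::print
print.fus_sim <- function(x, ...) {
  cat("<fus_sim> target layer:", x$target_layer, "\n")
  m <- x$metrics
  cat(sprintf("  max |p| = %.4g Pa, max Q = %.4g W/m^3, max T = %.4g degC\n",
              m$max_pressure_pa, m$max_power_w_m3,
              m$max_temperature_c %||% NA))
  invisible(x)
}

#' Focal-zone maxima over the target tissue layer
#'
#' Maxima of |p|, Q and T restricted to voxels whose layer is the target
#' tissue (the "focus zone" of the sweep records) -- not the whole grid, so
#' hot spots in shallow layers (e.g. skin) do not leak into the record.
#'
#' @param field A [propagate_stack()] pressure field.
#' @param q A [power_deposition()] field.
#' @param temp A [steady_bioheat()] temperature field, or NULL.
#' @param target_layer Medium name of the target layer.
#' @return List `max_pressure_pa`, `max_power_w_m3`, `max_temperature_c`
#'   (NULL if no temperature field was supplied).
#' @export
focal_metrics <- function(field, q, temp, target_layer) {
  stopifnot(inherits(field, "fus_field"))
  names_l <- vapply(field$stack$layers, function(l) l$medium$name, "")
  sel_layers <- which(names_l == target_layer)
  if (!length(sel_layers))
    stop("target layer '", target_layer, "' not present in the stack",
         call. = FALSE)
  planes <- which(field$layer_index %in% sel_layers)
  planes <- planes[planes >= field$source_index]
  if (!length(planes))
    stop("target layer '", target_layer, "' has no grid planes", call. = FALSE)
  list(
    max_pressure_pa = max(Mod(field$p[, , planes])),
    max_power_w_m3 = max(q$values[, , planes]),
    max_temperature_c = if (!is.null(temp)) max(temp$values[, , planes])
  )
}

#' Save / load a simulated field volume
#'
#' Fields are serialised as a native R container (a list of values, axes,
#' units and provenance attributes such as the config hash) readable with
#' [load_field()].
#'
#' @param x A `fus_field` or `fus_scalar`.
#' @param path Output path (conventionally `.rds`).
#' @param provenance Optional named list stored alongside (config hash,
#'   seed, ...).
#' @export
save_field <- function(x, path, provenance = list()) {
  stopifnot(inherits(x, "fus_field") || inherits(x, "fus_scalar"))
  grid <- x$grid
  obj <- list(
    class = class(x),
    values = if (inherits(x, "fus_field")) x$p else x$values,
    role = if (inherits(x, "fus_scalar")) x$role else "pressure",
    units = if (inherits(x, "fus_scalar")) x$units else "Pa",
    axes = list(x = grid$x, y = grid$y, z = grid$z),
    grid = unclass(grid),
    layer_index = x$layer_index,
    provenance = c(provenance, list(package = "focusurf",
                                    version = as.character(utils::packageVersion("focusurf"))))
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_field
#' @param path Path written by [save_field()].
#' @export
load_field <- function(path) {
  obj <- readRDS(path)
  grid <- structure(obj$grid, class = "fus_grid")
  if ("fus_field" %in% obj$class) {
    structure(list(p = obj$values, grid = grid, stack = NULL,
                   layer_index = obj$layer_index,
                   source_index = 1L, source_z = NA_real_, f_mhz = NA_real_),
              class = "fus_field")
  } else {
    scalar_field(obj$values, grid, obj$role, obj$units, obj$layer_index)
  }
}
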