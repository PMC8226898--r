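# Tissue media, layered stacks, and simulation grids.
#
# Internal units are strict SI (m, s, Pa, W, K). Constructors accept the
# mixed units conventional in the therapeutic-ultrasound literature
# (mm thicknesses, MHz frequencies, dB/cm/MHz attenuation coefficients)
# and convert once at construction time.

#' Define a tissue medium
#'
#' Bundles the acoustic and thermal properties of one homogeneous tissue
#' (or couplant) layer. Attenuation follows the power law
#' \eqn{\alpha(f) = \alpha_0 f^b} with \eqn{\alpha_0} in dB/(cm MHz^b).
#' The nonlinearity parameter is stored for completeness but unused: the
#' propagation model is linear continuous-wave.
#'
#' @param name Character label, e.g. `"water"` or `"prostate"`.
#' @param density Density \eqn{\rho} in kg/m^3.
#' @param sound_speed Speed of sound \eqn{c} in m/s.
#' @param attenuation Attenuation coefficient \eqn{\alpha_0} in dB/(cm MHz^b).
#' @param power_law_exponent Frequency power-law exponent \eqn{b} (dimensionless).
#' @param specific_heat Specific heat capacity \eqn{C} in J/(kg K).
#' @param thermal_conductivity Thermal conductivity \eqn{k_t} in W/(m K).
#' @param blood_perfusion Blood perfusion rate \eqn{W_b} in kg/(m^3 s).
#' @param blood_specific_heat Specific heat of blood \eqn{C_b} in J/(kg K).
#' @param nonlinearity B/A-style nonlinearity parameter (stored, unused).
#' @return An object of class `fus_medium`.
#' @examples
#' water <- medium("water", density = 1000, sound_speed = 1480,
#'                 attenuation = 0.00025, power_law_exponent = 2,
#'                 specific_heat = 4180, thermal_conductivity = 0.615,
#'                 blood_perfusion = 0, blood_specific_heat = 3480)
#' attenuation_np_per_m(water, f_mhz = 2.3)
#' @export
medium <- function(name, density, sound_speed, attenuation = 0,
                   power_law_exponent = 1, specific_heat,
                   thermal_conductivity, blood_perfusion = 0,
                   blood_specific_heat = 0, nonlinearity = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("medium '", name, "': ", nm, " must be a single finite number",
           call. = FALSE)
    as.numeric(x)
  }
  m <- list(
    name                 = name,
    density              = num1(density, "density"),
    sound_speed          = num1(sound_speed, "sound_speed"),
    attenuation          = num1(attenuation, "attenuation"),
    power_law_exponent   = num1(power_law_exponent, "power_law_exponent"),
    specific_heat        = num1(specific_heat, "specific_heat"),
    thermal_conductivity = num1(thermal_conductivity, "thermal_conductivity"),
    blood_perfusion      = num1(blood_perfusion, "blood_perfusion"),
    blood_specific_heat  = num1(blood_specific_heat, "blood_specific_heat"),
    nonlinearity         = num1(nonlinearity, "nonlinearity")
  )
  if (m$density <= 0 || m$sound_speed <= 0 || m$specific_heat <= 0 ||
      m$thermal_conductivity <= 0)
    stop("medium '", name,
         "': density, sound_speed, specific_heat and thermal_conductivity ",
         "must be > 0", call. = FALSE)
  if (m$attenuation < 0 || m$power_law_exponent < 0 ||
      m$blood_perfusion < 0 || m$blood_specific_heat < 0)
    stop("medium '", name,
         "': attenuation, power_law_exponent, blood_perfusion and ",
         "blood_specific_heat must be >= 0", call. = FALSE)
  structure(m, class = "fus_medium")
}

#' @exportS3Method base::print
print.fus_medium <- function(x, ...) {
  cat(sprintf("<fus_medium> %s\n", x$name))
  cat(sprintf("  rho = %g kg/m^3, c = %g m/s, alpha0 = %g dB/(cm MHz^%g)\n",
              x$density, x$sound_speed, x$attenuation, x$power_law_exponent))
  cat(sprintf("  C = %g J/(kg K), k_t = %g W/(m K), Wb = %g kg/(m^3 s), Cb = %g J/(kg K)\n",
              x$specific_heat, x$thermal_conductivity, x$blood_perfusion,
              x$blood_specific_heat))
  invisible(x)
}

# dB -> Np conversion factor: 1 Np = 20/ln(10) dB
DB_PER_NP <- 20 / log(10)

#' Attenuation coefficient in Np/m
#'
#' Evaluates the power law \eqn{\alpha(f) = \alpha_0 f^b} at frequency `f_mhz`
#' and converts from dB/cm to Np/m (factor 100 / 8.6858896...).
#'
#' @param medium A [medium()] object.
#' @param f_mhz Frequency in MHz (> 0).
#' @return Attenuation in Np/m.
#' @export
attenuation_np_per_m <- function(medium, f_mhz) {
  stopifnot(inherits(medium, "fus_medium"))
  if (!is.numeric(f_mhz) || any(f_mhz <= 0))
    stop("frequency must be > 0 MHz", call. = FALSE)
  medium$attenuation * f_mhz^medium$power_law_exponent * 100 / DB_PER_NP
}

#' Characteristic acoustic impedance Z = rho * c
#'
#' @param medium A [medium()] object.
#' @return Impedance in Pa s/m (rayl).
#' @export
acoustic_impedance <- function(medium) {
  stopifnot(inherits(medium, "fus_medium"))
  medium$density * medium$sound_speed
}

#' Complex wavenumber at a given frequency
#'
#' k = omega/c - i*alpha, the lossy plane-wave wavenumber used by the
#' angular-spectrum transfer function.
#'
#' @param medium A [medium()] object.
#' @param f_mhz Frequency in MHz.
#' @return Complex wavenumber in rad/m.
#' @export
wavenumber <- function(medium, f_mhz) {
  stopifnot(inherits(medium, "fus_medium"))
  omega <- 2 * pi * f_mhz * 1e6
  complex(real = omega / medium$sound_speed,
          imaginary = -attenuation_np_per_m(medium, f_mhz))
}

#' Snell refraction of a plane wave across an interface
#'
#' Computes the refraction angle from sin(theta_out) = (cB/cA) sin(theta_in).
#' When the incidence is beyond the critical angle the wave is totally
#' reflected and `NA` is returned (with attribute `total_reflection = TRUE`).
#'
#' @param theta_in Incidence angle in radians, in `[0, pi/2)`.
#' @param c_a Sound speed of the incidence-side medium (m/s).
#' @param c_b Sound speed of the transmission-side medium (m/s).
#' @return Refraction angle in radians, or `NA` on total internal reflection.
#' @export
snell_refraction <- function(theta_in, c_a, c_b) {
  if (!is.numeric(theta_in) || any(theta_in < 0) || any(theta_in >= pi / 2))
    stop("theta_in must lie in [0, pi/2)", call. = FALSE)
  stopifnot(c_a > 0, c_b > 0)
  s <- (c_b / c_a) * sin(theta_in)
  out <- ifelse(s > 1, NA_real_, asin(pmin(s, 1)))
  if (anyNA(out)) attr(out, "total_reflection") <- TRUE
  out
}

#' Define a layered tissue stack
#'
#' Ordered list of media along the beam axis (z), each with a thickness.
#' Layer interfaces are later snapped to grid z-planes by the propagator.
#'
#' @param layers List of `list(medium = <fus_medium>, thickness_mm = <mm>)`
#'   entries, ordered from the transducer face into the body.
#' @param arterial_temperature_c Arterial blood temperature Ta in degrees C
#'   (Pennes sink reference and Dirichlet boundary value). Default 37.
#' @return Object of class `fus_stack`.
#' @export
layered_stack <- function(layers, arterial_temperature_c = 37) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  for (ly in layers) {
    if (!inherits(ly$medium, "fus_medium"))
      stop("each layer needs a 'medium' of class fus_medium", call. = FALSE)
    if (!is.numeric(ly$thickness_mm) || ly$thickness_mm <= 0)
      stop("each layer needs a thickness_mm > 0", call. = FALSE)
  }
  structure(list(layers = layers,
                 arterial_temperature_c = as.numeric(arterial_temperature_c)),
            class = "fus_stack")
}

#' @exportS3Method base::print
print.fus_stack <- function(x, ...) {
  cat("<fus_stack>", length(x$layers), "layers, Ta =",
      x$arterial_temperature_c, "degC\n")
  for (ly in x$layers)
    cat(sprintf("  %-14s %6.2f mm\n", ly$medium$name, ly$thickness_mm))
  invisible(x)
}

#' Total stack thickness in metres
#' @param stack A [layered_stack()] object.
#' @export
stack_depth <- function(stack) {
  stopifnot(inherits(stack, "fus_stack"))
  sum(vapply(stack$layers, function(l) l$thickness_mm, 0)) * 1e-3
}

#' Define a 3D simulation grid
#'
#' x and y are centred on the aperture centre; z = 0 is the transducer face
#' and increases into the tissue, planes at z_j = j * dz for j = 0..nz-1.
#'
#' @param nx,ny,nz Number of grid points per axis.
#' @param dx,dy,dz Grid spacings in metres.
#' @return Object of class `fus_grid` with axis vectors `x`, `y`, `z` (m).
#' @export
grid3d <- function(nx, ny, nz, dx, dy, dz) {
  stopifnot(nx >= 2, ny >= 2, nz >= 2, dx > 0, dy > 0, dz > 0)
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
    dx = dx, dy = dy, dz = dz,
    x = (seq_len(nx) - (nx + 1) / 2) * dx,
    y = (seq_len(ny) - (ny + 1) / 2) * dy,
    z = (seq_len(nz) - 1) * dz
  ), class = "fus_grid")
}

#' @exportS3Method base::print
print.fus_grid <- function(x, ...) {
  cat(sprintf("<fus_grid> %d x %d x %d, spacing %.3g x %.3g x %.3g mm, extent %.1f x %.1f x %.1f mm\n",
              x$nx, x$ny, x$nz, x$dx * 1e3, x$dy * 1e3, x$dz * 1e3,
              x$nx * x$dx * 1e3, x$ny * x$dy * 1e3, (x$nz - 1) * x$dz * 1e3))
  invisible(x)
}

# Map each grid z-plane to a layer index. Interface li (between layer li and
# li+1) is snapped to the nearest grid plane; planes at or beyond a snapped
# interface belong to the deeper layer. Warns when a snap moves an interface
# by more than dz/2 (can only happen for sub-cell layers).
plane_layers <- function(stack, grid) {
  stopifnot(inherits(stack, "fus_stack"), inherits(grid, "fus_grid"))
  bounds_m <- cumsum(vapply(stack$layers, function(l) l$thickness_mm, 0)) * 1e-3
  if (bounds_m[length(bounds_m)] < grid$z[grid$nz] - 1e-12)
    stop("layered stack (", round(bounds_m[length(bounds_m)] * 1e3, 2),
         " mm) does not cover the grid depth (",
         round(grid$z[grid$nz] * 1e3, 2), " mm)", call. = FALSE)
  nlay <- length(stack$layers)
  idx <- rep(1L, grid$nz)
  for (li in seq_len(nlay - 1L)) {
    if (bounds_m[li] > grid$z[grid$nz] + grid$dz / 2) next  # beyond the grid
    snap <- which.min(abs(grid$z - bounds_m[li]))
    if (abs(grid$z[snap] - bounds_m[li]) > grid$dz / 2 + 1e-12)
      warning("interface after layer '", stack$layers[[li]]$medium$name,
              "' snapped by more than dz/2")
    idx[seq_len(grid$nz) >= snap] <- li + 1L
  }
  idx
}
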