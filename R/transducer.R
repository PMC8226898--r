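# Rectangular phased-array geometry and geometric focusing phases.

#' Build a rectangular phased array
#'
#' Tiles a fixed rectangular aperture with `nx * ny` identical rectangular
#' elements separated by a constant kerf, so that
#' `nx * width + (nx - 1) * kerf == aperture_x` exactly (and likewise in y).
#' Element centres are symmetric about the aperture centre.
#'
#' @param nx,ny Element counts along x and y (>= 1).
#' @param aperture_mm Length-2 numeric, aperture extent (x, y) in mm.
#' @param kerf_um Kerf (gap between elements) in micrometres.
#' @return Object of class `fus_array` with element dimensions (m) and an
#'   `n x 2` matrix of element centre coordinates (m).
#' @examples
#' arr <- build_array(16, 16, aperture_mm = c(50, 10), kerf_um = 1)
#' arr$element_w * 1e3  # element width in mm
#' @export
build_array <- function(nx, ny, aperture_mm = c(50, 10), kerf_um = 1) {
  stopifnot(nx >= 1, ny >= 1, length(aperture_mm) == 2, kerf_um >= 0)
  ap <- aperture_mm * 1e-3
  kerf <- kerf_um * 1e-6
  elem_w <- (ap[1] - (nx - 1) * kerf) / nx
  elem_h <- (ap[2] - (ny - 1) * kerf) / ny
  if (elem_w <= 0 || elem_h <= 0)
    stop("kerf too large: non-positive element dimensions", call. = FALSE)
  pitch_x <- elem_w + kerf
  pitch_y <- elem_h + kerf
  cx <- (seq_len(nx) - (nx + 1) / 2) * pitch_x
  cy <- (seq_len(ny) - (ny + 1) / 2) * pitch_y
  centers <- cbind(x = rep(cx, times = ny), y = rep(cy, each = nx))
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny),
    aperture = ap, kerf = kerf,
    element_w = elem_w, element_h = elem_h,
    centers = centers
  ), class = "fus_array")
}

#' @exportS3Method base::print
print.fus_array <- function(x, ...) {
  cat(sprintf("<fus_array> %d x %d elements over %.1f x %.1f mm (kerf %.2g um)\n",
              x$nx, x$ny, x$aperture[1] * 1e3, x$aperture[2] * 1e3,
              x$kerf * 1e6))
  cat(sprintf("  element %.4f x %.4f mm\n", x$element_w * 1e3, x$element_h * 1e3))
  invisible(x)
}

#' Geometric focusing phases
#'
#' Per-element phase `phi_n = mod(k_ref * d_n, 2*pi)` with `d_n` the distance
#' from the element centre to the focus and `k_ref = 2*pi*f / c_ref`. Driving
#' element n with `exp(1i * phi_n)` makes all element contributions
#' (`exp(-1i k R)` propagation) arrive in phase at the focus. The reference
#' sound speed is a straight-ray approximation (couplant speed by default);
#' no layered refraction correction is applied.
#'
#' @param array A [build_array()] object.
#' @param focus Length-3 numeric focus point (x, y, z) in metres, z > 0.
#' @param c_ref Reference sound speed in m/s.
#' @param f_mhz Frequency in MHz.
#' @return Numeric vector of phases in `[0, 2*pi)`, one per element.
#' @export
focus_phases <- function(array, focus, c_ref, f_mhz) {
  stopifnot(inherits(array, "fus_array"), length(focus) == 3)
  if (focus[3] <= 0) stop("focus must lie at z > 0", call. = FALSE)
  k_ref <- 2 * pi * f_mhz * 1e6 / c_ref
  d <- sqrt((array$centers[, 1] - focus[1])^2 +
            (array$centers[, 2] - focus[2])^2 + focus[3]^2)
  unname((k_ref * d) %% (2 * pi))
}

#' Excitation of a phased array
#'
#' Continuous-wave drive: frequency, uniform surface normal velocity
#' amplitude, per-element phases, and the programmed focus.
#'
#' @param f_mhz Frequency in MHz.
#' @param v0 Surface normal velocity amplitude in m/s (uniform, no
#'   apodization). The absolute pressure/temperature scale is proportional
#'   to `v0` / `v0^2`; default 1.
#' @param phases Per-element phases (rad); recycled if length 1.
#' @param focus_mm Optional length-3 focus (mm) recorded for provenance.
#' @return Object of class `fus_excitation`.
#' @export
excitation <- function(f_mhz, v0 = 1, phases = 0, focus_mm = NULL) {
  stopifnot(f_mhz > 0, v0 > 0)
  structure(list(f_mhz = f_mhz, omega = 2 * pi * f_mhz * 1e6,
                 v0 = v0, phases = phases %% (2 * pi),
                 focus_mm = focus_mm),
            class = "fus_excitation")
}

#' Convenience: array + geometric focusing excitation
#'
#' @inheritParams focus_phases
#' @inheritParams excitation
#' @param focus_mm Focus point (x, y, z) in mm.
#' @return A `fus_excitation` whose phases focus `array` at `focus_mm`.
#' @export
focused_excitation <- function(array, focus_mm, c_ref, f_mhz, v0 = 1) {
  ph <- focus_phases(array, focus_mm * 1e-3, c_ref, f_mhz)
  excitation(f_mhz, v0 = v0, phases = ph, focus_mm = focus_mm)
}
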