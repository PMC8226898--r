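# Rayleigh-Sommerfeld integral for a baffled planar rectangular array.
#
# The time-harmonic field of a planar source with normal velocity v_n is
#   p(r) = (i rho c k / 2 pi) * Int v_n(r') exp(-i k R) / R dS,  R = |r - r'|
# with the exp(+i omega t) time factor dropped (phasor convention).
# Elements are subdivided into rectangular sub-sources (midpoint quadrature,
# default spacing lambda/4) and summed directly.

# Sub-source decomposition of the array: each element is divided into cells
# no wider than `spacing`, and each cell carries a 2 x 2 Gauss-Legendre
# point set (nodes at +/- cell/(2*sqrt(3)), equal weights). The tensor
# Gauss rule integrates the oscillatory kernel far more accurately than a
# midpoint rule of the same cost. All elements share the same sub-layout.
subsources <- function(array, phases, spacing) {
  nsx <- max(1L, ceiling(array$element_w / spacing))
  nsy <- max(1L, ceiling(array$element_h / spacing))
  cx <- array$element_w / nsx
  cy <- array$element_h / nsy
  gx <- cx / (2 * sqrt(3))
  gy <- cy / (2 * sqrt(3))
  ox <- rep((seq_len(nsx) - (nsx + 1) / 2) * cx, each = 2) + c(-gx, gx)
  oy <- rep((seq_len(nsy) - (nsy + 1) / 2) * cy, each = 2) + c(-gy, gy)
  off <- cbind(rep(ox, times = length(oy)), rep(oy, each = length(ox)))
  ne <- nrow(array$centers)
  ns <- nrow(off)
  phases <- rep_len(phases, ne)
  list(
    x = rep(array$centers[, 1], each = ns) + rep(off[, 1], times = ne),
    y = rep(array$centers[, 2], each = ns) + rep(off[, 2], times = ne),
    phase = rep(phases, each = ns),
    dS = (cx / 2) * (cy / 2)
  )
}

#' Direct Rayleigh-Sommerfeld field at arbitrary points
#'
#' Brute-force sub-source summation of the Rayleigh integral. Exact up to
#' quadrature, hence the reference for validating the spectral propagator,
#' but O(points x sub-sources).
#'
#' @param array A [build_array()] object.
#' @param exc An [excitation()] object (per-element phases).
#' @param medium The [medium()] the field points lie in (homogeneous
#'   half-space assumption).
#' @param points `n x 3` matrix of field points (m), all at z > 0.
#' @param spacing Sub-source quadrature spacing (m); default `lambda/4`.
#'   A spacing coarser than `lambda/4` triggers a warning.
#' @return Complex vector of pressures (Pa), one per row of `points`.
#' @export
rayleigh_direct <- function(array, exc, medium, points, spacing = NULL) {
  stopifnot(inherits(array, "fus_array"), inherits(exc, "fus_excitation"),
            inherits(medium, "fus_medium"))
  points <- matrix(as.numeric(points), ncol = 3)
  if (any(points[, 3] <= 0))
    stop("all field points must lie at z > 0", call. = FALSE)
  lambda <- medium$sound_speed / (exc$f_mhz * 1e6)
  if (is.null(spacing)) spacing <- lambda / 4
  if (spacing > lambda / 4 + 1e-12)
    warning("sub-source spacing coarser than lambda/4; quadrature may be inaccurate")
  ss <- subsources(array, exc$phases, spacing)
  k_c <- wavenumber(medium, exc$f_mhz)
  k_re <- Re(k_c)
  amp <- 1i * medium$density * medium$sound_speed * k_re / (2 * pi) *
    exc$v0 * ss$dS
  drive <- exp(1i * ss$phase)
  n_pts <- nrow(points)
  p <- complex(n_pts)
  # chunk over sub-sources to bound the n_pts x chunk working matrices
  chunk <- max(1L, floor(4e6 / n_pts))
  s0 <- 1L
  n_ss <- length(ss$x)
  while (s0 <= n_ss) {
    s1 <- min(s0 + chunk - 1L, n_ss)
    idx <- s0:s1
    R <- sqrt(outer(points[, 1], ss$x[idx], "-")^2 +
              outer(points[, 2], ss$y[idx], "-")^2 +
              points[, 3]^2)
    p <- p + (exp(-1i * k_c * R) / R) %*% drive[idx]
    s0 <- s1 + 1L
  }
  as.complex(amp * p)
}

#' Rayleigh-Sommerfeld source plane
#'
#' Evaluates the Rayleigh integral on one x-y grid plane at `z0`
#' (default a quarter wavelength from the transducer face, far enough to
#' avoid the surface singularity while still in the near field). This plane
#' seeds the angular-spectrum propagator.
#'
#' @inheritParams rayleigh_direct
#' @param grid A [grid3d()] (only its x/y lattice is used).
#' @param z0 Plane position in metres; default `lambda/4`.
#' @return Object of class `fus_plane`: complex `nx x ny` pressure matrix
#'   `p` plus grid metadata.
#' @export
rayleigh_plane <- function(array, exc, medium, grid, z0 = NULL,
                           spacing = NULL) {
  stopifnot(inherits(grid, "fus_grid"))
  lambda <- medium$sound_speed / (exc$f_mhz * 1e6)
  if (is.null(z0)) z0 <- lambda / 4
  pts <- cbind(rep(grid$x, times = grid$ny),
               rep(grid$y, each = grid$nx),
               z0)
  p <- matrix(rayleigh_direct(array, exc, medium, pts, spacing = spacing),
              nrow = grid$nx, ncol = grid$ny)
  structure(list(p = p, z = z0, x = grid$x, y = grid$y,
                 dx = grid$dx, dy = grid$dy),
            class = "fus_plane")
}

#' @exportS3Method base::print
print.fus_plane <- function(x, ...) {
  cat(sprintf("<fus_plane> %d x %d at z = %.3f mm, max |p| = %.4g Pa\n",
              nrow(x$p), ncol(x$p), x$z * 1e3, max(Mod(x$p))))
  invisible(x)
}
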