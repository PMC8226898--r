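# Angular-spectrum propagation through a layered stack.
#
# A source plane is decomposed into plane waves by a zero-padded 2D FFT,
# each component is advanced analytically in z by the transfer function
#   H = exp(-i dz sqrt(k^2 - kx^2 - ky^2))   (propagating branch)
#   H = exp(-  dz sqrt(kx^2 + ky^2 - Re(k)^2)) (evanescent branch)
# with attenuation entering through the complex wavenumber k = w/c - i*alpha.
# At a layer interface each component is multiplied by the oblique-incidence
# pressure transmission coefficient for its propagation angle (forward-only
# marching; reflected waves are discarded).

# FFT sample frequencies (cycles per unit), numpy-style ordering.
fft_freq <- function(n, d) {
  pos <- seq(0L, floor((n - 1) / 2))
  neg <- seq(-ceiling((n - 1) / 2), -1L)
  c(pos, neg) / (n * d)
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

#' Angular-spectrum transfer function
#'
#' @param kx,ky Spatial-frequency axes in rad/m (vectors; the result is a
#'   `length(kx) x length(ky)` matrix).
#' @param dz Propagation distance in metres (> 0).
#' @param k Complex wavenumber of the medium (rad/m), `Re(k) = omega/c`,
#'   `Im(k) = -alpha`.
#' @return Complex matrix `H(kx, ky)`.
#' @export
asm_transfer_function <- function(kx, ky, dz, k) {
  stopifnot(dz > 0)
  kr2 <- outer(kx^2, ky^2, "+")
  k_re2 <- Re(k)^2
  prop <- kr2 <= k_re2
  H <- matrix(0i, nrow = length(kx), ncol = length(ky))
  kz <- sqrt(as.complex(k^2 - kr2[prop]))
  H[prop] <- exp(-1i * dz * kz)
  H[!prop] <- exp(-dz * sqrt(kr2[!prop] - k_re2))
  H
}

#' Oblique-incidence pressure transmission coefficient
#'
#' `T = 2 / (rho_a c_a cos(theta_out) / (rho_b c_b cos(theta_in)) + 1)`,
#' with the refraction angle from [snell_refraction()]. Reduces to
#' `2 Z_b / (Z_a + Z_b)` at normal incidence. Returns 0 beyond the critical
#' angle (total internal reflection).
#'
#' @param theta_in Incidence angle(s) in radians, in `[0, pi/2)`.
#' @param medium_a,medium_b Incidence- and transmission-side [medium()]s.
#' @return Numeric transmission coefficient(s).
#' @export
transmission_coeff <- function(theta_in, medium_a, medium_b) {
  sin_out <- (medium_b$sound_speed / medium_a$sound_speed) * sin(theta_in)
  cos_in <- cos(theta_in)
  tr <- sin_out > 1
  cos_out <- sqrt(pmax(1 - pmin(sin_out, 1)^2, 0))
  za <- acoustic_impedance(medium_a)
  zb <- acoustic_impedance(medium_b)
  tc <- 2 / (za * cos_out / (zb * cos_in) + 1)
  tc[tr | !is.finite(tc)] <- 0
  tc
}

#' Spectral transmission matrix at a layer interface
#'
#' Maps each plane-wave component `(kx, ky)` to its incidence angle
#' `sin(theta_in) = sqrt(kx^2+ky^2) / Re(k_a)` and evaluates the
#' transmission coefficient into the next medium. Evanescent components
#' (`sin(theta_in) > 1`) and totally reflected components get 0.
#'
#' @inheritParams asm_transfer_function
#' @param medium_a,medium_b [medium()]s on either side of the interface.
#' @param f_mhz Frequency in MHz (sets `Re(k_a)`).
#' @return Real matrix `T(kx, ky)`.
#' @export
transmission_matrix <- function(kx, ky, medium_a, medium_b, f_mhz) {
  k_a <- Re(wavenumber(medium_a, f_mhz))
  sin_in <- sqrt(outer(kx^2, ky^2, "+")) / k_a
  tm <- matrix(0, nrow = length(kx), ncol = length(ky))
  ok <- sin_in < 1
  tm[ok] <- transmission_coeff(asin(sin_in[ok]), medium_a, medium_b)
  tm
}

# Separable raised-cosine angular taper: suppress components whose lateral
# excursion over the remaining propagation distance would exit the padded
# window. Cutoff per axis: kx_c = k * sin(atan(margin_x / d_remaining)).
angular_taper_axis <- function(kvec, k_re, margin, d_rem) {
  if (d_rem <= 0) return(rep(1, length(kvec)))
  kc <- k_re * margin / sqrt(margin^2 + d_rem^2)
  lo <- 0.85 * kc
  a <- abs(kvec)
  w <- rep(1, length(kvec))
  ramp <- a > lo & a < kc
  w[ramp] <- 0.5 * (1 + cos(pi * (a[ramp] - lo) / (kc - lo)))
  w[a >= kc] <- 0
  w
}

#' Propagate a source plane through a layered stack
#'
#' Marches the angular spectrum plane-by-plane along z through the grid,
#' applying the per-medium transfer function over each step, the spectral
#' transmission matrix whenever a (grid-snapped) layer interface is crossed,
#' and an anti-aliasing angular taper. Grid planes before the source plane
#' are left at zero; the field is defined from the source plane onward
#' (recorded in `source_index`).
#'
#' @param source A [rayleigh_plane()] result (must lie inside the first layer).
#' @param stack A [layered_stack()].
#' @param grid A [grid3d()]; lateral sampling must satisfy
#'   `dx, dy <= lambda/2` in every layer.
#' @param exc The [excitation()] (frequency).
#' @param pad_factor Zero-padding factor per lateral axis (scalar or
#'   length 2, default 2).
#' @param angular_filter Apply the anti-aliasing angular taper (default TRUE).
#' @return Object of class `fus_field`: complex array `p` of dim
#'   `(nx, ny, nz)`, per-plane `layer_index`, `source_index`, grid and stack.
#' @export
propagate_stack <- function(source, stack, grid, exc,
                            pad_factor = 2, angular_filter = TRUE) {
  stopifnot(inherits(source, "fus_plane"), inherits(stack, "fus_stack"),
            inherits(grid, "fus_grid"), inherits(exc, "fus_excitation"))
  pad_factor <- rep_len(pad_factor, 2L)
  # sampling check against the shortest wavelength in the stack
  lmin <- min(vapply(stack$layers,
                     function(l) l$medium$sound_speed, 0)) / (exc$f_mhz * 1e6)
  if (grid$dx > lmin / 2 + 1e-12 || grid$dy > lmin / 2 + 1e-12)
    stop("grid undersampled: dx, dy must be <= lambda/2 = ",
         signif(lmin / 2 * 1e3, 4), " mm at ", exc$f_mhz, " MHz", call. = FALSE)

  layers <- plane_layers(stack, grid)
  z0 <- source$z
  thick1 <- stack$layers[[1]]$thickness_mm * 1e-3
  if (z0 >= thick1)
    stop("source plane must lie inside the first layer", call. = FALSE)

  n1 <- max(2L, round(pad_factor[1] * grid$nx))
  n2 <- max(2L, round(pad_factor[2] * grid$ny))
  ox <- floor((n1 - grid$nx) / 2)
  oy <- floor((n2 - grid$ny) / 2)
  xi <- (ox + 1):(ox + grid$nx)
  yi <- (oy + 1):(oy + grid$ny)
  kx <- 2 * pi * fft_freq(n1, grid$dx)
  ky <- 2 * pi * fft_freq(n2, grid$dy)
  # largest lateral excursion before wrapped energy re-enters the central
  # window: periodic images are Lpad apart, the window is L wide
  margin_x <- (n1 - grid$nx) * grid$dx
  margin_y <- (n2 - grid$ny) * grid$dy

  pad <- matrix(0i, n1, n2)
  pad[xi, yi] <- source$p
  P <- fft2(pad)

  k_of <- function(li) wavenumber(stack$layers[[li]]$medium, exc$f_mhz)

  p3 <- array(0i, dim = c(grid$nx, grid$ny, grid$nz))
  j1 <- which(grid$z > z0 + 1e-12)[1]
  if (is.na(j1)) stop("grid has no planes beyond the source plane", call. = FALSE)
  # if the source plane coincides with a grid plane, store it there directly
  jsame <- which(abs(grid$z - z0) <= 1e-12)
  if (length(jsame)) p3[, , jsame[1]] <- source$p

  cur_z <- z0
  cur_layer <- 1L
  z_end <- grid$z[grid$nz]
  for (j in j1:grid$nz) {
    dz <- grid$z[j] - cur_z
    kc <- k_of(cur_layer)
    P <- P * asm_transfer_function(kx, ky, dz, kc)
    if (angular_filter) {
      d_rem <- z_end - cur_z
      wx <- angular_taper_axis(kx, Re(kc), margin_x, d_rem)
      wy <- angular_taper_axis(ky, Re(kc), margin_y, d_rem)
      P <- P * outer(wx, wy)
    }
    if (layers[j] != cur_layer) {
      for (li in cur_layer:(layers[j] - 1L)) {
        P <- P * transmission_matrix(kx, ky,
                                     stack$layers[[li]]$medium,
                                     stack$layers[[li + 1L]]$medium,
                                     exc$f_mhz)
      }
      cur_layer <- layers[j]
    }
    plane <- ifft2(P)
    p3[, , j] <- plane[xi, yi]
    cur_z <- grid$z[j]
  }

  structure(list(p = p3, grid = grid, stack = stack,
                 layer_index = layers, source_index = j1,
                 source_z = z0, f_mhz = exc$f_mhz),
            class = "fus_field")
}

#' @exportS3Method base::print
print.fus_field <- function(x, ...) {
  i <- which.max(Mod(x$p))
  d <- arrayInd(i, dim(x$p))
  cat(sprintf("<fus_field> %d x %d x %d complex pressure, %g MHz\n",
              dim(x$p)[1], dim(x$p)[2], dim(x$p)[3], x$f_mhz))
  cat(sprintf("  max |p| = %.4g Pa at (%.1f, %.1f, %.1f) mm\n",
              Mod(x$p[i]), x$grid$x[d[1]] * 1e3, x$grid$y[d[2]] * 1e3,
              x$grid$z[d[3]] * 1e3))
  invisible(x)
}
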