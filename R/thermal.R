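# Acoustic intensity, power deposition, and the steady-state Pennes
# bio-heat equation
#   -div(k_t grad T) + Wb Cb (T - Ta) = Q,   T = Ta on the grid boundary,
# discretised with a 7-point finite-difference stencil (harmonic-mean
# conductivity at layer interfaces) and solved as a sparse SPD system.

# role-tagged real field on the grid
scalar_field <- function(values, grid, role, units, layer_index = NULL) {
  structure(list(values = values, grid = grid, role = role, units = units,
                 layer_index = layer_index),
            class = "fus_scalar")
}

#' @exportS3Method base::print
print.fus_scalar <- function(x, ...) {
  cat(sprintf("<fus_scalar> %s (%s), %d x %d x %d, range [%.4g, %.4g]\n",
              x$role, x$units, dim(x$values)[1], dim(x$values)[2],
              dim(x$values)[3], min(x$values), max(x$values)))
  invisible(x)
}

# per-plane property vector helper
layer_prop <- function(stack, layer_index, fun) {
  vals <- vapply(stack$layers, function(l) fun(l$medium), 0)
  vals[layer_index]
}

#' Time-averaged acoustic intensity
#'
#' `I_A = |p|^2 / (2 rho c)` with the local layer's density and sound speed.
#'
#' @param field A [propagate_stack()] pressure field.
#' @return A `fus_scalar` intensity field in W/m^2.
#' @export
acoustic_intensity <- function(field) {
  stopifnot(inherits(field, "fus_field"))
  rc <- layer_prop(field$stack, field$layer_index,
                   function(m) 2 * m$density * m$sound_speed)
  ia <- Mod(field$p)^2
  for (j in seq_along(rc)) ia[, , j] <- ia[, , j] / rc[j]
  scalar_field(ia, field$grid, "intensity", "W/m^2", field$layer_index)
}

#' Volumetric power deposition
#'
#' `Q = 2 alpha I_A` with the local layer's attenuation at the operating
#' frequency; the volumetric heat source of the bio-heat equation.
#'
#' @param ia An [acoustic_intensity()] field.
#' @param stack The [layered_stack()].
#' @param f_mhz Frequency in MHz.
#' @return A `fus_scalar` power-deposition field in W/m^3.
#' @export
power_deposition <- function(ia, stack, f_mhz) {
  stopifnot(inherits(ia, "fus_scalar"), ia$role == "intensity")
  alpha <- layer_prop(stack, ia$layer_index,
                      function(m) attenuation_np_per_m(m, f_mhz))
  q <- ia$values
  for (j in seq_along(alpha)) q[, , j] <- 2 * alpha[j] * q[, , j]
  scalar_field(q, ia$grid, "power_deposition", "W/m^3", ia$layer_index)
}

# Assemble the sparse SPD operator A for u = T - Ta:
#   A u = q,  A = conduction + diag(Wb*Cb)
# Conductivity varies by layer along z; face values use the harmonic mean.
# Dirichlet u = 0 on all boundaries (couplings to outside nodes kept on the
# diagonal). Returns a Matrix::dgCMatrix.
bioheat_operator <- function(stack, grid, layer_index) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  n <- nx * ny * nz
  kt <- layer_prop(stack, layer_index, function(m) m$thermal_conductivity)
  wbcb <- layer_prop(stack, layer_index,
                     function(m) m$blood_perfusion * m$blood_specific_heat)
  kt_p <- rep(kt, each = nx * ny)        # conductivity per node (plane-wise)
  wb_p <- rep(wbcb, each = nx * ny)

  ix <- rep(rep(seq_len(nx), times = ny), times = nz)
  iy <- rep(rep(seq_len(ny), each = nx), times = nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  id <- seq_len(n)

  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  diag_acc <- wb_p

  add_axis <- function(mask_lo, stride, h, kface) {
    # symmetric coupling between node i and i+stride with conductance kface/h^2
    i <- id[mask_lo]
    jn <- i + stride
    g <- kface / h^2
    rows <<- c(rows, i, jn)
    cols <<- c(cols, jn, i)
    vals <<- c(vals, -g, -g)
    diag_acc[i] <<- diag_acc[i] + g
    diag_acc[jn] <<- diag_acc[jn] + g
  }
  # x neighbours (same plane: same conductivity)
  mlo <- ix < nx
  add_axis(mlo, 1L, grid$dx, kt_p[id[mlo]])
  # y neighbours
  mlo <- iy < ny
  add_axis(mlo, nx, grid$dy, kt_p[id[mlo]])
  # z neighbours: harmonic mean across possible layer change
  mlo <- iz < nz
  i <- id[mlo]
  kf <- 2 * kt_p[i] * kt_p[i + nx * ny] / (kt_p[i] + kt_p[i + nx * ny])
  add_axis(mlo, nx * ny, grid$dz, kf)
  # boundary couplings to Dirichlet u = 0 nodes: diagonal only
  diag_acc <- diag_acc +
    (ix == 1) * kt_p / grid$dx^2 + (ix == nx) * kt_p / grid$dx^2 +
    (iy == 1) * kt_p / grid$dy^2 + (iy == ny) * kt_p / grid$dy^2 +
    (iz == 1) * kt_p / grid$dz^2 + (iz == nz) * kt_p / grid$dz^2

  Matrix::sparseMatrix(i = c(id, rows), j = c(id, cols),
                       x = c(diag_acc, vals), dims = c(n, n))
}

# Jacobi-preconditioned conjugate gradient (used above the direct-solve
# size threshold). Deterministic; errors out if not converged.
cg_solve <- function(A, b, tol = 1e-10, maxit = 2000L) {
  d <- Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  b2 <- sqrt(sum(b^2))
  if (b2 == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * b2) return(x)
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("bio-heat CG did not converge: relative residual ",
       signif(sqrt(sum(r^2)) / b2, 3), call. = FALSE)
}

#' Steady-state Pennes temperature field
#'
#' Solves `-div(k_t grad T) + Wb Cb (T - Ta) = Q` with Dirichlet `T = Ta`
#' on all grid boundaries (the standard steady-state far-field condition).
#' Small systems use a sparse Cholesky direct solve; large ones a
#' Jacobi-preconditioned conjugate gradient (tolerance 1e-10).
#'
#' @param q A [power_deposition()] field (W/m^3).
#' @param stack The [layered_stack()] (thermal properties and Ta).
#' @param factor Optional pre-assembled solver from [bioheat_factor()],
#'   reused across repeated solves on the same grid/stack.
#' @param direct_max Largest unknown count for the direct solve
#'   (default 2e4).
#' @return A `fus_scalar` temperature field in degrees C (absolute,
#'   `T = Ta + rise`).
#' @export
steady_bioheat <- function(q, stack, factor = NULL, direct_max = 2e4) {
  stopifnot(inherits(q, "fus_scalar"), q$role == "power_deposition")
  grid <- q$grid
  b <- as.numeric(q$values)
  if (!all(is.finite(b))) stop("Q must be finite", call. = FALSE)
  if (is.null(factor)) factor <- bioheat_factor(stack, grid, q$layer_index,
                                                direct_max = direct_max)
  u <- factor$solve(b)
  ta <- stack$arterial_temperature_c
  scalar_field(array(u + ta, dim = dim(q$values)), grid,
               "temperature", "degC", q$layer_index)
}

#' Pre-assemble the bio-heat solver for a fixed grid and stack
#'
#' The sparse operator (and its Cholesky factorisation, when small enough
#' for a direct solve) depends only on grid, stack and layer assignment, so
#' parameter sweeps factor once and back-substitute per simulation.
#'
#' @inheritParams steady_bioheat
#' @param grid A [grid3d()].
#' @param layer_index Per-plane layer assignment from [plane_layers()].
#' @return List with a `solve(b)` closure.
#' @export
bioheat_factor <- function(stack, grid, layer_index = NULL,
                           direct_max = 2e4) {
  if (is.null(layer_index)) layer_index <- plane_layers(stack, grid)
  A <- bioheat_operator(stack, grid, layer_index)
  n <- nrow(A)
  if (n <= direct_max) {
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
    list(n = n, method = "cholesky",
         solve = function(b) as.numeric(Matrix::solve(ch, b)))
  } else {
    list(n = n, method = "cg",
         solve = function(b) cg_solve(A, b))
  }
}

#' Lateral width of a temperature-rise contour
#'
#' On the axial (x-z) slice through the hottest voxel, finds the connected
#' region (4-neighbour) at or above the given rise that contains the peak,
#' and returns its maximum lateral (x) extent, edge positions refined by
#' linear interpolation between grid columns.
#'
#' @param temp A [steady_bioheat()] temperature field.
#' @param rise_level Contour level as a rise above Ta, in degrees C.
#' @param ta Arterial temperature Ta in degrees C.
#' @return Width in mm (0, with a warning, if the peak rise is below the
#'   level).
#' @export
contour_width <- function(temp, rise_level, ta = 37) {
  stopifnot(inherits(temp, "fus_scalar"), temp$role == "temperature")
  rise <- temp$values - ta
  pk <- arrayInd(which.max(rise), dim(rise))
  if (rise[pk] < rise_level) {
    warning("contour level ", rise_level,
            " degC exceeds the peak rise (", signif(rise[pk], 4), " degC)")
    return(0)
  }
  sl <- rise[, pk[2], ]                 # x-z slice through the peak
  nx <- nrow(sl); nz <- ncol(sl)
  inside <- sl >= rise_level
  # flood fill from the peak (4-connectivity)
  comp <- matrix(FALSE, nx, nz)
  stack_i <- integer(nx * nz); stack_j <- integer(nx * nz)
  top <- 1L
  stack_i[1] <- pk[1]; stack_j[1] <- pk[3]
  comp[pk[1], pk[3]] <- TRUE
  while (top > 0L) {
    ci <- stack_i[top]; cj <- stack_j[top]; top <- top - 1L
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      i <- ci + d[1]; j <- cj + d[2]
      if (i >= 1L && i <= nx && j >= 1L && j <= nz &&
          inside[i, j] && !comp[i, j]) {
        comp[i, j] <- TRUE
        top <- top + 1L
        stack_i[top] <- i; stack_j[top] <- j
      }
    }
  }
  x <- temp$grid$x
  width <- 0
  for (j in seq_len(nz)) {
    idx <- which(comp[, j])
    if (!length(idx)) next
    il <- min(idx); ir <- max(idx)
    xl <- x[il]
    if (il > 1 && sl[il - 1, j] < rise_level)
      xl <- x[il] - (sl[il, j] - rise_level) /
        (sl[il, j] - sl[il - 1, j]) * (x[il] - x[il - 1])
    xr <- x[ir]
    if (ir < nx && sl[ir + 1, j] < rise_level)
      xr <- x[ir] + (sl[ir, j] - rise_level) /
        (sl[ir, j] - sl[ir + 1, j]) * (x[ir + 1] - x[ir])
    width <- max(width, xr - xl)
  }
  width * 1e3
}
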