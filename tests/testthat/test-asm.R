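test_that("transfer function matches plane-wave closed forms", {
  w <- water_medium(lossless = TRUE)
  k <- wavenumber(w, 1)
  expect_equal(Im(k), 0)
  dz <- 1e-3
  # axial lossless: H = exp(-i k dz), unit magnitude
  H0 <- asm_transfer_function(0, 0, dz, k)[1, 1]
  expect_equal(H0, exp(-1i * Re(k) * dz), tolerance = 1e-14)
  expect_equal(Mod(H0), 1, tolerance = 1e-14)
  # evanescent branch at kx^2 + ky^2 = 2 k^2: |H| = exp(-k dz)
  He <- asm_transfer_function(Re(k), Re(k), dz, k)[1, 1]
  expect_equal(Mod(He), exp(-Re(k) * dz), tolerance = 1e-12)
  expect_equal(Im(He), 0)
  # attenuated axial decay: prostate at 2.3 MHz over 10 mm
  pr <- prostate_medium()
  kp <- wavenumber(pr, 2.3)
  Ha <- asm_transfer_function(0, 0, 0.01, kp)[1, 1]
  expect_equal(Mod(Ha), 0.875064367923, tolerance = 1e-9)
})

test_that("propagating components conserve magnitude in a lossless medium", {
  w <- water_medium(lossless = TRUE)
  k <- Re(wavenumber(w, 1))
  kx <- seq(-0.99, 0.99, length.out = 41) * k
  H <- asm_transfer_function(kx, 0, 2e-3, complex(real = k))
  prop <- abs(kx) <= k
  expect_lt(max(abs(Mod(H[prop, 1]) - 1)), 1e-12)
})

test_that("axial plane-wave decay follows exp(-alpha z) through many steps", {
  # pure axial mode: constant plane, no padding, no filter
  pr <- prostate_medium()
  f <- 2.3
  alpha <- attenuation_np_per_m(pr, f)
  stk <- layered_stack(list(list(medium = pr, thickness_mm = 30)))
  grid <- grid3d(8, 8, 26, 3e-4, 3e-4, 1e-3)
  exc <- excitation(f_mhz = f, v0 = 1)
  src <- structure(list(p = matrix(1 + 0i, 8, 8), z = 1e-4,
                        x = grid$x, y = grid$y, dx = grid$dx, dy = grid$dy),
                   class = "fus_plane")
  fld <- propagate_stack(src, stk, grid, exc, pad_factor = 1,
                         angular_filter = FALSE)
  z <- grid$z[2:26]
  got <- Mod(fld$p[4, 4, 2:26])
  expect_equal(got, exp(-alpha * (z - 1e-4)), tolerance = 1e-6)
})

test_that("transmission coefficient matches the oblique-incidence formula", {
  w <- water_medium()
  rw <- rectal_wall_medium()
  same <- transmission_coeff(0, w, w)
  expect_equal(same, 1)
  # normal incidence water -> rectal wall: 2 Zb / (Za + Zb)
  expect_equal(transmission_coeff(0, w, rw), 1.03583061889, tolerance = 1e-9)
  expect_equal(transmission_coeff(0, w, rw), 2 * 1.59e6 / (1.48e6 + 1.59e6))
  # beyond the critical angle into the faster medium: total reflection
  crit <- asin(1480 / 1500)
  expect_equal(transmission_coeff(crit + 0.05, w, rw), 0)
  # grazing incidence into a slower medium: agrees with direct evaluation
  fast <- medium("fast", 1060, 1650, 0, 1, 3600, 0.5, 0, 0)
  th <- pi / 2 - 1e-3
  sin_out <- (1480 / 1650) * sin(th)
  direct <- 2 / ((1060 * 1650 * sqrt(1 - sin_out^2)) /
                 (1000 * 1480 * cos(th)) + 1)
  expect_equal(transmission_coeff(th, fast, w), direct, tolerance = 1e-12)
})

test_that("spectral transmission matrix zeroes evanescent components", {
  w <- water_medium()
  rw <- rectal_wall_medium()
  k <- Re(wavenumber(w, 1))
  kx <- c(0, 0.5 * k, 0.99 * k, 1.5 * k)
  tm <- transmission_matrix(kx, 0, w, rw, 1)
  expect_equal(tm[1, 1], 1.03583061889, tolerance = 1e-9)
  expect_equal(tm[4, 1], 0)             # evanescent
  expect_true(all(tm >= 0 & tm <= 2))
})

test_that("propagation obeys the semigroup property in a homogeneous medium", {
  w <- water_medium(lossless = TRUE)
  stk <- water_stack(30)
  arr <- build_array(8, 4, c(12, 5), 1)
  exc <- focused_excitation(arr, c(0, 0, 15), 1480, 1)
  dz <- 7e-4
  g1 <- grid3d(48, 48, 21, 7e-4, 7e-4, dz)
  g2 <- grid3d(48, 48, 11, 7e-4, 7e-4, 2 * dz)
  src <- rayleigh_plane(arr, exc, w, g1)
  f1 <- propagate_stack(src, stk, g1, exc, angular_filter = FALSE)
  f2 <- propagate_stack(src, stk, g2, exc, angular_filter = FALSE)
  a <- f1$p[, , 21]   # z = 14 mm via 20 steps of dz
  b <- f2$p[, , 11]   # same plane via 10 steps of 2 dz
  expect_lt(sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2)), 1e-10)
})

test_that("an artificial interface between identical media changes nothing", {
  w <- water_medium()
  stk1 <- water_stack(40, lossless = FALSE)
  stk2 <- layered_stack(list(list(medium = water_medium(), thickness_mm = 12),
                             list(medium = water_medium(), thickness_mm = 28)))
  arr <- build_array(8, 4, c(12, 5), 1)
  exc <- focused_excitation(arr, c(0, 0, 20), 1480, 1)
  grid <- grid3d(48, 48, 31, 7e-4, 7e-4, 1e-3)
  src <- rayleigh_plane(arr, exc, w, grid)
  f1 <- propagate_stack(src, stk1, grid, exc)
  f2 <- propagate_stack(src, stk2, grid, exc)
  expect_lt(max(Mod(f1$p - f2$p)) / max(Mod(f1$p)), 1e-9)
})

test_that("undersampled lateral grids are rejected", {
  w <- water_medium()
  stk <- water_stack(20)
  arr <- build_array(4, 2, c(10, 4), 1)
  exc <- excitation(f_mhz = 1, v0 = 1)
  coarse <- grid3d(16, 16, 11, 1e-3, 1e-3, 1e-3)  # dx > lambda/2 = 0.74 mm
  src <- structure(list(p = matrix(0i, 16, 16), z = 3.7e-4, x = coarse$x,
                        y = coarse$y, dx = coarse$dx, dy = coarse$dy),
                   class = "fus_plane")
  expect_error(propagate_stack(src, stk, coarse, exc), "undersampled")
})

test_that("doubling the zero padding leaves the focal region nearly unchanged", {
  w <- water_medium(lossless = TRUE)
  stk <- water_stack(40)
  arr <- build_array(16, 4, c(20, 5), 1)
  exc <- focused_excitation(arr, c(0, 0, 30), 1480, 1)
  grid <- grid3d(64, 64, 44, 7e-4, 7e-4, 7e-4)
  src <- rayleigh_plane(arr, exc, w, grid)
  f2 <- propagate_stack(src, stk, grid, exc, pad_factor = 2)
  f4 <- propagate_stack(src, stk, grid, exc, pad_factor = 4)
  d <- arrayInd(which.max(Mod(f4$p)), dim(f4$p))
  ri <- (d[1] - 5):(d[1] + 5); rj <- (d[2] - 5):(d[2] + 5)
  rk <- (d[3] - 3):(d[3] + 3)
  reg2 <- f2$p[ri, rj, rk]; reg4 <- f4$p[ri, rj, rk]
  expect_lt(sqrt(sum(Mod(reg2 - reg4)^2) / sum(Mod(reg4)^2)), 0.011)
})
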