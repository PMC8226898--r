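test_that("intensity uses the local layer's rho and c", {
  w <- water_medium()
  pr <- prostate_medium()
  stk <- layered_stack(list(list(medium = w, thickness_mm = 10),
                            list(medium = pr, thickness_mm = 10)))
  grid <- grid3d(4, 4, 11, 1e-3, 1e-3, 2e-3)
  p <- array(0i, c(4, 4, 11))
  p[2, 2, 3] <- 1e6          # water plane
  p[2, 2, 9] <- 1e6          # prostate plane
  layer_index <- focusurf:::plane_layers(stk, grid)
  fld <- manual_field(p, grid, stk, layer_index, f_mhz = 2.3)
  ia <- acoustic_intensity(fld)
  # |p|^2 / (2 rho c): 1e12 / (2*1000*1480) and 1e12 / (2*1060*1500)
  expect_equal(ia$values[2, 2, 3], 337837.837838, tolerance = 1e-10)
  expect_equal(ia$values[2, 2, 9], 314465.408805, tolerance = 1e-10)
  expect_equal(sum(ia$values > 0), 2)

  q <- power_deposition(ia, stk, 2.3)
  # water: Q = 2 alpha IA with alpha = 0.0152258 Np/m
  expect_equal(q$values[2, 2, 3], 2 * 0.0152258439274 * 337837.837838,
               tolerance = 1e-9)
  # prostate: 2 * 13.3457832 * 314465.41 = 8.3936e6 W/m^3
  expect_equal(q$values[2, 2, 9], 8393574.33899, tolerance = 1e-8)

  # linearity: doubling the intensity doubles the deposition
  ia2 <- ia; ia2$values <- 2 * ia$values
  q2 <- power_deposition(ia2, stk, 2.3)
  expect_equal(q2$values, 2 * q$values)

  # lossless medium deposits nothing
  stk0 <- water_stack(22, lossless = TRUE)
  ia0 <- manual_scalar(ia$values, grid, "intensity", "W/m^2", rep(1L, 11))
  q0 <- power_deposition(ia0, stk0, 2.3)
  expect_true(all(q0$values == 0))
})

test_that("zero power gives exactly the arterial temperature", {
  pr <- prostate_medium()
  stk <- layered_stack(list(list(medium = pr, thickness_mm = 30)))
  grid <- grid3d(8, 8, 16, 1e-3, 1e-3, 2e-3)
  q <- manual_scalar(array(0, c(8, 8, 16)), grid, "power_deposition",
                     "W/m^3", rep(1L, 16))
  temp <- steady_bioheat(q, stk)
  expect_true(all(temp$values == 37))
})

test_that("temperature rise is linear in Q and respects the maximum principle", {
  pr <- prostate_medium()
  stk <- layered_stack(list(list(medium = pr, thickness_mm = 30)))
  grid <- grid3d(10, 10, 15, 1.5e-3, 1.5e-3, 2e-3)
  set.seed(5)
  qv <- array(stats::runif(10 * 10 * 15, 0, 1e6), c(10, 10, 15))
  q1 <- manual_scalar(qv, grid, "power_deposition", "W/m^3", rep(1L, 15))
  q2 <- manual_scalar(2 * qv, grid, "power_deposition", "W/m^3", rep(1L, 15))
  t1 <- steady_bioheat(q1, stk)
  t2 <- steady_bioheat(q2, stk)
  r1 <- t1$values - 37; r2 <- t2$values - 37
  expect_equal(r2, 2 * r1, tolerance = 1e-8)
  expect_true(all(t1$values >= 37))     # Q >= 0, Dirichlet Ta boundaries
})

test_that("point source matches the perfusion Green's function", {
  # exp(-r/L) / (4 pi k r) with L = sqrt(k_t / (Wb Cb)) = 7.33 mm,
  # compared where the Dirichlet boundary influence is below the tolerance
  pr <- prostate_medium()
  stk <- layered_stack(list(list(medium = pr, thickness_mm = 60)))
  h <- 1.2e-3; n <- 41
  grid <- grid3d(n, n, n, h, h, h)
  L <- sqrt(0.50 / (2.5 * 3720))
  expect_equal(L * 1e3, 7.33235575107, tolerance = 1e-9)
  q <- array(0, c(n, n, n)); ic <- (n + 1) / 2
  q[ic, ic, ic] <- 1 / h^3              # unit point power
  qf <- manual_scalar(q, grid, "power_deposition", "W/m^3", rep(1L, n))
  temp <- steady_bioheat(qf, stk)
  u <- temp$values - 37
  zc <- grid$z[ic]
  r <- sqrt(outer(grid$x^2, grid$y^2, "+") %o% rep(1, n) +
            array(rep((grid$z - zc)^2, each = n * n), c(n, n, n)))
  ua <- exp(-r / L) / (4 * pi * 0.50 * r)
  sel <- r >= 3 * h & r <= 2 * L
  expect_lt(sqrt(mean((u[sel] - ua[sel])^2)) / sqrt(mean(ua[sel]^2)), 0.02)
})

test_that("uniform deep heating approaches the zero-Laplacian limit Q/(Wb Cb)", {
  # short perfusion length (strong perfusion) so boundaries are remote
  hot <- medium("perfused", 1050, 1550, 0.5, 1, 3600, 0.5,
                blood_perfusion = 30, blood_specific_heat = 3720)
  stk <- layered_stack(list(list(medium = hot, thickness_mm = 40)))
  n <- 21; h <- 1.5e-3
  grid <- grid3d(n, n, n, h, h, h)
  q0 <- 5e5
  qf <- manual_scalar(array(q0, c(n, n, n)), grid, "power_deposition",
                      "W/m^3", rep(1L, n))
  temp <- steady_bioheat(qf, stk)
  ic <- (n + 1) / 2
  expect_equal(temp$values[ic, ic, ic] - 37, q0 / (30 * 3720),
               tolerance = 0.01)
})

test_that("refinement changes the solution by little on a smooth source", {
  pr <- prostate_medium()
  stk <- layered_stack(list(list(medium = pr, thickness_mm = 40)))
  peak_of <- function(n, h) {
    grid <- grid3d(n, n, n, h, h, h)
    ctr <- (n + 1) / 2
    zc <- grid$z[ctr]
    r2 <- outer(grid$x^2, grid$y^2, "+") %o% rep(1, n) +
      array(rep((grid$z - zc)^2, each = n * n), c(n, n, n))
    qv <- 1e7 * exp(-r2 / (2 * (4e-3)^2))
    qf <- manual_scalar(qv, grid, "power_deposition", "W/m^3", rep(1L, n))
    max(steady_bioheat(qf, stk)$values) - 37
  }
  coarse <- peak_of(17, 2e-3)
  fine <- peak_of(33, 1e-3)
  expect_lt(abs(coarse - fine) / fine, 0.02)
})

test_that("contour width recovers the closed form for a Gaussian rise", {
  fx <- make_fixture("gaussian_temperature", dir = tempdir(), seed = 2)
  obj <- readRDS(fx)
  temp <- obj$field
  peak <- obj$params$peak
  sx <- obj$params$sigma_m[["x"]]
  # width at level: 2 sigma sqrt(2 ln(peak/level))
  for (level in c(4, 2, 5.5)) {
    expected <- 2 * sx * sqrt(2 * log(peak / level)) * 1e3
    expect_equal(contour_width(temp, level), expected,
                 tolerance = temp$grid$dx * 1e3 / expected)
  }
  # level at the peak: width collapses
  expect_lt(contour_width(temp, peak - 1e-9), 2 * temp$grid$dx * 1e3)
  # level above the peak: zero, with a warning
  expect_warning(w0 <- contour_width(temp, peak + 1), "exceeds the peak")
  expect_identical(w0, 0)
})
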