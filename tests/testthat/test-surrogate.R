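test_that("train/test split uses the ceiling rule and is seed-deterministic", {
  big <- data.frame(nx = seq_len(19227), ny = 1, focus_mm = 1)
  sp <- split_table(big, 0.2, seed = 7)
  expect_equal(nrow(sp$test), 3846)
  expect_equal(nrow(sp$train), 15381)

  small <- data.frame(x = 1:10)
  sp10 <- split_table(small, 0.2, seed = 1)
  expect_equal(nrow(sp10$test), 2)
  expect_equal(nrow(sp10$train), 8)

  expect_equal(split_table(big, 0.2, seed = 7)$test_idx, sp$test_idx)
  expect_false(identical(split_table(big, 0.2, seed = 8)$test_idx,
                         sp$test_idx))
  expect_error(split_table(data.frame(x = 1:4), 0.2, 1), "at least 5")
})

test_that("min-max scaling maps the training range to [0, 1] and inverts", {
  tab <- data.frame(nx = c(16, 40, 128), ny = c(16, 20, 64),
                    focus_mm = c(25, 30, 75),
                    max_pressure_pa = c(1, 2, 3),
                    max_power_w_m3 = c(10, 30, 20),
                    max_temperature_c = c(37, 40, 39))
  sc <- minmax_fit(tab)
  s <- minmax_apply(sc, tab)
  expect_equal(range(s$nx), c(0, 1))
  expect_equal(s$nx[2], (40 - 16) / (128 - 16))
  # extrapolation beyond the training range is not clipped
  out <- minmax_apply(sc, data.frame(nx = 200))
  expect_gt(out$nx, 1)
  # round trip
  back <- minmax_invert(sc, s)
  expect_equal(back, tab, tolerance = 1e-12)
  # constant column rejected
  cst <- tab; cst$ny <- 5
  expect_error(minmax_fit(cst), "constant column")
})

test_that("linear surrogate recovers exact linear relationships", {
  set.seed(2)
  n <- 60
  tab <- data.frame(nx = runif(n), ny = runif(n), focus_mm = runif(n))
  tab$max_pressure_pa <- 2 * tab$nx + 1
  tab$max_power_w_m3 <- -0.5 * tab$ny + 0.2
  tab$max_temperature_c <- 3 * tab$focus_mm - 1
  fit <- fit_surrogate(tab, "linear")
  co <- stats::coef(fit$fits)
  expect_equal(unname(co["nx", "max_pressure_pa"]), 2, tolerance = 1e-8)
  expect_equal(unname(co["(Intercept)", "max_pressure_pa"]), 1,
               tolerance = 1e-8)
  expect_equal(unname(co["ny", "max_power_w_m3"]), -0.5, tolerance = 1e-8)
  expect_equal(unname(co["focus_mm", "max_temperature_c"]), 3,
               tolerance = 1e-8)
  pred <- predict(fit, tab)
  expect_equal(max(abs(pred - as.matrix(tab[4:6]))), 0, tolerance = 1e-10)
})

test_that("a 20-leaf CART fits a 10-plateau piecewise-constant function exactly", {
  set.seed(1)
  n <- 200
  tab <- data.frame(nx = runif(n), ny = runif(n), focus_mm = runif(n))
  plateau <- function(x) floor(x * 10) / 10
  tab$max_pressure_pa <- plateau(tab$focus_mm)
  tab$max_power_w_m3 <- plateau(tab$nx)
  tab$max_temperature_c <- plateau(tab$focus_mm)
  fit <- fit_surrogate(tab, "cart")
  pred <- predict(fit, tab)
  expect_equal(sqrt(mean((as.matrix(tab[4:6]) - pred)^2)), 0,
               tolerance = 1e-12)
  for (f in fit$fits)
    expect_lte(sum(f$frame$var == "<leaf>"), 20)
})

test_that("random-forest predictions stay inside the envelope of their trees", {
  set.seed(4)
  n <- 80
  tab <- data.frame(nx = runif(n), ny = runif(n), focus_mm = runif(n))
  tab$max_pressure_pa <- sin(2 * tab$nx) + tab$focus_mm
  tab$max_power_w_m3 <- tab$nx * tab$ny
  tab$max_temperature_c <- exp(-tab$focus_mm)
  fit <- fit_surrogate(tab, "random_forest", hyper = list(n_trees = 100),
                       seed = 9)
  newx <- tab[1:10, 1:3]
  all_tree <- stats::predict(fit$fits[["max_pressure_pa"]], newx,
                             predict.all = TRUE)
  expect_true(all(all_tree$aggregate >= apply(all_tree$individual, 1, min) &
                  all_tree$aggregate <= apply(all_tree$individual, 1, max)))
  # same seed, same forest
  fit2 <- fit_surrogate(tab, "random_forest", hyper = list(n_trees = 100),
                        seed = 9)
  expect_equal(predict(fit, newx), predict(fit2, newx))
})

test_that("metrics match an independent elementary computation on 5 rows", {
  y <- matrix(c(0.10, 0.55, 0.90, 0.35, 0.70,
                0.20, 0.45, 0.80, 0.25, 0.65,
                0.05, 0.60, 0.95, 0.40, 0.75), nrow = 5)
  yh <- matrix(c(0.12, 0.50, 0.88, 0.40, 0.72,
                 0.18, 0.49, 0.77, 0.20, 0.70,
                 0.10, 0.55, 0.99, 0.38, 0.70), nrow = 5)
  # spreadsheet-style arithmetic, written out independently of the package
  sq <- 0; tot <- 0; s <- 0
  for (j in 1:3) for (i in 1:5) s <- s + y[i, j]
  ybar <- s / 15
  for (j in 1:3) for (i in 1:5) {
    sq <- sq + (y[i, j] - yh[i, j])^2
    tot <- tot + (y[i, j] - ybar)^2
  }
  mse <- sq / 15
  rmse_hand <- sqrt(mse)
  r2_hand <- 1 - sq / tot
  ll_hand <- -(5 / 2) * (log(2 * pi * mse) + 1)
  aic_hand <- 2 * 3 - 2 * ll_hand
  bic_hand <- 3 * log(5) - 2 * ll_hand

  m <- surrogate_metrics(y, yh)
  expect_equal(m$rmse, rmse_hand, tolerance = 1e-9)
  expect_equal(m$r2, r2_hand, tolerance = 1e-9)
  expect_equal(m$loglik, ll_hand, tolerance = 1e-9)
  expect_equal(m$aic, aic_hand, tolerance = 1e-9)
  expect_equal(m$bic, bic_hand, tolerance = 1e-9)

  # perfect prediction and mean predictor
  mp <- surrogate_metrics(y, y)
  expect_identical(mp$rmse, 0)
  expect_identical(mp$r2, 1)
  mm <- surrogate_metrics(y, matrix(mean(y), 5, 3))
  expect_equal(mm$r2, 0)

  expect_error(surrogate_metrics(y, yh[1:4, ]), "identical dimensions")
})

test_that("information criteria share one likelihood: BIC = AIC + k(ln N - 2)", {
  # N = 10, k = 3, MSE = 0.01
  ll <- gaussian_loglik(0.01, 10)
  expect_equal(ll, 8.836465597894, tolerance = 1e-10)
  expect_equal(aic_from_loglik(ll, 3), -11.672931195787, tolerance = 1e-10)
  expect_equal(bic_from_loglik(ll, 10, 3), -10.765175916805, tolerance = 1e-10)
  expect_equal(bic_from_loglik(ll, 10, 3) - aic_from_loglik(ll, 3),
               3 * (log(10) - 2))
  # identity holds for any metric bundle
  set.seed(6)
  for (n in c(7, 24, 3846)) {
    y <- matrix(runif(3 * n), n)
    yh <- y + 0.05 * matrix(rnorm(3 * n), n)
    m <- surrogate_metrics(y, yh)
    expect_equal(m$bic - m$aic, 3 * (log(n) - 2), tolerance = 1e-10)
  }
})

test_that("grid search is deterministic and picks the single candidate", {
  tab <- synthetic_dataset(n = 80, seed = 12)
  sc <- minmax_fit(tab)
  s <- minmax_apply(sc, tab)
  g1 <- grid_search_cv(s, "cart", list(list(max_leaf_nodes = 10L)), seed = 3)
  expect_equal(g1$best$max_leaf_nodes, 10L)
  grid <- list(list(max_leaf_nodes = 5L), list(max_leaf_nodes = 10L),
               list(max_leaf_nodes = 20L))
  g2 <- grid_search_cv(s, "cart", grid, seed = 3)
  g3 <- grid_search_cv(s, "cart", grid, seed = 3)
  expect_equal(g2$cv_mse, g3$cv_mse)
  expect_equal(g2$folds, g3$folds)
  expect_equal(length(g2$cv_mse), 3)
  expect_error(grid_search_cv(s, "cart", list(), seed = 3), "empty")
})

test_that("evaluate_models reports all four models and guards external overlap", {
  tab <- synthetic_dataset(n = 150, seed = 12)
  tab <- tab[!duplicated(tab[1:3]), ]
  hyper <- default_hyperparameters()
  hyper$random_forest$n_trees <- 200L   # plenty for a structure check
  ext <- synthetic_dataset(n = 220, seed = 99)
  ext <- ext[!(paste(ext$nx, ext$ny, ext$focus_mm) %in%
               paste(tab$nx, tab$ny, tab$focus_mm)), ][1:10, ]
  rep <- evaluate_models(tab, seed = 5, external = ext, hyper = hyper)
  expect_s3_class(rep, "fus_report")
  expect_setequal(unique(rep$metrics$model),
                  c("linear", "cart", "svr", "random_forest"))
  expect_setequal(unique(rep$metrics$set), c("test", "external"))
  expect_equal(rep$metrics$n[rep$metrics$set == "external"][1], 10)
  expect_true(all(rep$metrics$rmse >= 0))
  expect_true(all(rep$metrics$r2 <= 1))
  # overlapping external rows rejected
  expect_error(evaluate_models(tab, seed = 5, external = tab[1:3, ]),
               "overlap")
  # report files
  prefix <- file.path(tempdir(), "report_test")
  write_report(rep, prefix)
  expect_true(file.exists(paste0(prefix, ".csv")))
  expect_true(file.exists(paste0(prefix, ".json")))
})
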