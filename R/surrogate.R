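# Surrogate models over the sweep dataset: 80/20 split, min-max scaling
# fitted on the training split, four model families (multi-response linear
# regression, CART, epsilon-SVR, random forest), grid-search with 5-fold
# cross-validation, and pooled evaluation metrics (RMSE, R^2, AIC, BIC).
#
# Metrics are computed on the min-max-scaled targets; AIC and BIC share a
# Gaussian log-likelihood built from the per-row mean squared error:
#   ln L = -(N/2) (ln(2 pi MSE) + 1),
#   AIC  = 2k - 2 ln L,   BIC = k ln N - 2 ln L,   k = 3 features.
# Note BIC - AIC = k (ln N - 2) regardless of the fit.

FEATURES <- c("nx", "ny", "focus_mm")
TARGETS <- c("max_pressure_pa", "max_power_w_m3", "max_temperature_c")

#' Split a dataset into train and test subsets
#'
#' Uniform random split without replacement; the test set has
#' `ceiling(test_fraction * N)` rows.
#'
#' @param table Data frame (the sweep dataset).
#' @param test_fraction Fraction held out (default 0.2).
#' @param seed Integer RNG seed; recorded in the result.
#' @return List with `train`, `test`, `test_idx`, `seed`.
#' @export
split_table <- function(table, test_fraction = 0.2, seed = 1L) {
  n <- nrow(table)
  if (n < 5) stop("need at least 5 rows to split", call. = FALSE)
  n_test <- ceiling(test_fraction * n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test_idx <- sort(sample.int(n, n_test))
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE],
       test_idx = test_idx, seed = seed)
}

# save/restore the global RNG state so package functions that seed locally
# do not disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Fit min-max scaling parameters on the training split
#'
#' @param train Training data frame (features and targets).
#' @param cols Columns to scale (default: the three features and three
#'   targets).
#' @return Object of class `fus_scaler` with per-column min and max.
#' @export
minmax_fit <- function(train, cols = c(FEATURES, TARGETS)) {
  stopifnot(all(cols %in% names(train)))
  mins <- vapply(train[cols], min, 0)
  maxs <- vapply(train[cols], max, 0)
  if (any(maxs <= mins))
    stop("constant column(s): ",
         paste(cols[maxs <= mins], collapse = ", "),
         " cannot be min-max scaled", call. = FALSE)
  structure(list(min = mins, max = maxs, cols = cols), class = "fus_scaler")
}

#' Apply / invert min-max scaling
#'
#' `x' = (x - min) / (max - min)` per column, no clipping (values outside
#' the training range map outside `[0, 1]`).
#'
#' @param scaler A [minmax_fit()] object.
#' @param table Data frame containing (a subset of) the scaled columns.
#' @return The table with scaled (or unscaled) columns.
#' @export
minmax_apply <- function(scaler, table) {
  stopifnot(inherits(scaler, "fus_scaler"))
  for (cl in intersect(scaler$cols, names(table)))
    table[[cl]] <- (table[[cl]] - scaler$min[[cl]]) /
      (scaler$max[[cl]] - scaler$min[[cl]])
  table
}

#' @rdname minmax_apply
#' @export
minmax_invert <- function(scaler, table) {
  stopifnot(inherits(scaler, "fus_scaler"))
  for (cl in intersect(scaler$cols, names(table)))
    table[[cl]] <- table[[cl]] * (scaler$max[[cl]] - scaler$min[[cl]]) +
      scaler$min[[cl]]
  table
}

#' Default model hyperparameters
#'
#' The published settings: CART limited to 20 leaf nodes; epsilon-SVR with
#' an RBF kernel, per-target `(C, epsilon, gamma)` -- `C = 5, epsilon = 0.1`
#' with the variance rule `gamma = 1/(d Var(X))` for pressure and
#' temperature, `C = 100, epsilon = 0.1, gamma = 1/d` for power (d = 3
#' features); random forest with 1000 trees.
#'
#' @return Named list of hyperparameter lists per model kind.
#' @export
default_hyperparameters <- function() {
  list(
    linear = list(),
    cart = list(max_leaf_nodes = 20L),
    svr = list(
      max_pressure_pa = list(C = 5, epsilon = 0.1, gamma = "scale"),
      max_power_w_m3 = list(C = 100, epsilon = 0.1, gamma = "auto"),
      max_temperature_c = list(C = 5, epsilon = 0.1, gamma = "scale")
    ),
    random_forest = list(n_trees = 1000L)
  )
}

svr_gamma <- function(rule, x) {
  if (is.numeric(rule)) return(rule)
  d <- ncol(x)
  switch(rule,
         scale = 1 / (d * stats::var(as.numeric(as.matrix(x)))),
         auto = 1 / d,
         stop("unknown gamma rule: ", rule, call. = FALSE))
}

# grow a CART with rpart and cost-complexity-prune it to at most
# `max_leaves` terminal nodes (the largest subtree in the pruning sequence
# with <= max_leaves leaves)
fit_cart_pruned <- function(x, y, max_leaves) {
  df <- data.frame(x, .y = y)
  fit <- rpart::rpart(.y ~ ., data = df, method = "anova",
                      control = rpart::rpart.control(
                        minsplit = 2, minbucket = 1, cp = 0,
                        maxsurrogate = 0, maxcompete = 0, xval = 0))
  tab <- fit$cptable
  leaves <- tab[, "nsplit"] + 1
  ok <- which(leaves <= max_leaves)
  # smallest subtree in the pruning sequence attaining (to rounding) the best
  # error achievable within the leaf budget; avoids pruning on the noise-level
  # complexity values of an exactly-fit tree
  best_err <- min(tab[ok, "rel error"])
  row <- ok[which(tab[ok, "rel error"] <= best_err + 1e-12)[1]]
  if (row < nrow(tab))
    fit <- rpart::prune(fit, cp = (tab[row, "CP"] + tab[row + 1, "CP"]) / 2)
  fit
}

#' Fit a surrogate model
#'
#' Fits one of the four model families on scaled features/targets. The
#' linear model is a multi-response least-squares fit; CART, SVR and the
#' random forest are fitted per target and their predictions stacked.
#'
#' @param train_scaled Data frame of scaled features and targets
#'   (from [minmax_apply()]).
#' @param kind One of `"linear"`, `"cart"`, `"svr"`, `"random_forest"`.
#' @param hyper Hyperparameter list for this kind (see
#'   [default_hyperparameters()]).
#' @param seed Integer seed (random forest bootstrap).
#' @return Object of class `fus_surrogate` with a [predict()] method.
#' @export
fit_surrogate <- function(train_scaled, kind = c("linear", "cart", "svr",
                                                 "random_forest"),
                          hyper = NULL, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(all(c(FEATURES, TARGETS) %in% names(train_scaled)))
  if (nrow(train_scaled) < 5)
    stop("degenerate training set (< 5 rows)", call. = FALSE)
  if (is.null(hyper)) hyper <- default_hyperparameters()[[kind]]
  x <- train_scaled[FEATURES]
  y <- as.matrix(train_scaled[TARGETS])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  fits <- switch(kind,
    linear = {
      stats::lm(y ~ nx + ny + focus_mm, data = x)
    },
    cart = {
      lapply(TARGETS, function(tg)
        fit_cart_pruned(x, train_scaled[[tg]],
                        hyper$max_leaf_nodes %||% 20L))
    },
    svr = {
      lapply(TARGETS, function(tg) {
        hp <- hyper[[tg]] %||% list(C = 5, epsilon = 0.1, gamma = "scale")
        e1071::svm(x = as.matrix(x), y = train_scaled[[tg]],
                   type = "eps-regression", kernel = "radial",
                   cost = hp$C, epsilon = hp$epsilon,
                   gamma = svr_gamma(hp$gamma, x), scale = FALSE)
      })
    },
    random_forest = {
      lapply(seq_along(TARGETS), function(i) {
        set.seed(seed + i)
        randomForest::randomForest(
          x = x, y = train_scaled[[TARGETS[i]]],
          ntree = hyper$n_trees %||% 1000L,
          mtry = ncol(x), replace = TRUE)
      })
    })
  if (kind != "linear") names(fits) <- TARGETS
  structure(list(kind = kind, fits = fits, hyper = hyper, seed = seed),
            class = "fus_surrogate")
}

#' @export
predict.fus_surrogate <- function(object, newdata, ...) {
  stopifnot(all(FEATURES %in% names(newdata)))
  x <- newdata[FEATURES]
  out <- if (object$kind == "linear") {
    unname(stats::predict(object$fits, newdata = x))
  } else {
    vapply(TARGETS, function(tg) {
      f <- object$fits[[tg]]
      if (object$kind == "svr")
        as.numeric(stats::predict(f, newdata = as.matrix(x)))
      else
        as.numeric(stats::predict(f, newdata = x))
    }, numeric(nrow(x)))
  }
  out <- matrix(out, nrow = nrow(x), ncol = length(TARGETS),
                dimnames = list(NULL, TARGETS))
  out
}

#' @exportS3Method base::print
print.fus_surrogate <- function(x, ...) {
  cat("<fus_surrogate>", x$kind, "\n")
  if (length(x$hyper)) utils::str(x$hyper, give.attr = FALSE)
  invisible(x)
}

#' Pooled evaluation metrics for a surrogate
#'
#' RMSE and R^2 are pooled over the three scaled targets (all `3N` values);
#' AIC and BIC use the Gaussian log-likelihood
#' `ln L = -(N/2)(ln(2 pi MSE) + 1)` with `MSE` the per-row mean squared
#' error and `N` the number of rows, `AIC = 2k - 2 ln L`,
#' `BIC = k ln N - 2 ln L`, `k = 3`.
#'
#' @param y_true,y_pred Numeric matrices `N x 3` of scaled targets.
#' @param k Number of model inputs counted in the information criteria
#'   (default 3).
#' @return Named list: `rmse`, `r2`, `loglik`, `aic`, `bic`, `n`, `k`.
#' @export
surrogate_metrics <- function(y_true, y_pred, k = 3L) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred)))
    stop("y_true and y_pred must have identical dimensions", call. = FALSE)
  n <- nrow(y_true)
  err <- y_true - y_pred
  mse <- mean(err^2)                    # pooled == mean of per-row MSE
  rmse <- sqrt(mse)
  r2 <- 1 - sum(err^2) / sum((y_true - mean(y_true))^2)
  ll <- gaussian_loglik(mse, n)
  list(rmse = rmse, r2 = r2, loglik = ll,
       aic = aic_from_loglik(ll, k), bic = bic_from_loglik(ll, n, k),
       n = n, k = k)
}

#' Information-criterion building blocks
#'
#' The shared Gaussian log-likelihood and the AIC/BIC definitions used
#' throughout: `AIC = 2k - 2 ln L`, `BIC = k ln N - 2 ln L`, so
#' `BIC = AIC + k (ln N - 2)` -- [bic_from_aic()] converts a reported AIC
#' to the matching BIC without refitting.
#'
#' @param mse Mean squared error per row.
#' @param n Number of evaluation rows.
#' @param k Number of estimated parameters / model inputs.
#' @param loglik,aic Log-likelihood or AIC value.
#' @return Numeric scalar.
#' @export
gaussian_loglik <- function(mse, n) -(n / 2) * (log(2 * pi * mse) + 1)

#' @rdname gaussian_loglik
#' @export
aic_from_loglik <- function(loglik, k = 3L) 2 * k - 2 * loglik

#' @rdname gaussian_loglik
#' @export
bic_from_loglik <- function(loglik, n, k = 3L) k * log(n) - 2 * loglik

#' @rdname gaussian_loglik
#' @export
bic_from_aic <- function(aic, n, k = 3L) {
  loglik <- (2 * k - aic) / 2
  bic_from_loglik(loglik, n, k)
}

#' Grid search with 5-fold cross-validation
#'
#' Selects hyperparameters minimising the mean cross-validated pooled MSE.
#' Fold assignment is deterministic given the seed; ties are broken toward
#' the simpler model (candidates are tried in the order given, which should
#' be simplest first).
#'
#' @param train_scaled Scaled training table.
#' @param kind Model kind as in [fit_surrogate()].
#' @param grid List of candidate hyperparameter lists (simplest first).
#' @param folds Number of CV folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return List with `best` (hyperparameter list), `cv_mse` (vector, one
#'   mean CV MSE per candidate) and `folds`.
#' @export
grid_search_cv <- function(train_scaled, kind, grid, folds = 5L, seed = 1L) {
  if (!length(grid)) stop("empty hyperparameter grid", call. = FALSE)
  n <- nrow(train_scaled)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  cv_mse <- vapply(grid, function(hp) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- train_scaled[fold_id != f, , drop = FALSE]
      va <- train_scaled[fold_id == f, , drop = FALSE]
      fit <- fit_surrogate(tr, kind, hyper = hp, seed = seed)
      pred <- predict(fit, va)
      mean((as.matrix(va[TARGETS]) - pred)^2)
    }, 0)
    mean(errs)
  }, 0)
  best <- which(cv_mse <= min(cv_mse) + 1e-15)[1]
  list(best = grid[[best]], best_index = best, cv_mse = cv_mse,
       folds = fold_id)
}

#' Train and compare all four surrogate families
#'
#' Splits the dataset 80/20, fits min-max scaling on the training split
#' (features and targets), trains the linear, CART, SVR and random-forest
#' surrogates with the published hyperparameters, and reports pooled RMSE,
#' R^2, AIC and BIC on the held-out test split (and optionally on an
#' external table of combinations disjoint from the dataset).
#'
#' @param dataset Sweep dataset data frame (see [run_sweep()]).
#' @param seed Seed for the split and forest bootstrap.
#' @param external Optional external data frame with the same columns;
#'   rows whose `(nx, ny, focus_mm)` keys appear in the dataset are
#'   rejected.
#' @param hyper Hyperparameters per kind (default
#'   [default_hyperparameters()]).
#' @return Object of class `fus_report`: `metrics` (data frame, one row
#'   per model per evaluation set), the fitted `models`, the `scaler` and
#'   the split seed.
#' @export
evaluate_models <- function(dataset, seed = 1L, external = NULL,
                            hyper = default_hyperparameters()) {
  stopifnot(all(c(FEATURES, TARGETS) %in% names(dataset)))
  if (!is.null(external)) {
    key <- function(d) paste(d$nx, d$ny, format(d$focus_mm), sep = "|")
    if (any(key(external) %in% key(dataset)))
      stop("external rows overlap the dataset", call. = FALSE)
  }
  sp <- split_table(dataset, 0.2, seed = seed)
  scaler <- minmax_fit(sp$train)
  train_s <- minmax_apply(scaler, sp$train)
  test_s <- minmax_apply(scaler, sp$test)
  ext_s <- if (!is.null(external)) minmax_apply(scaler, external)

  kinds <- c("linear", "cart", "svr", "random_forest")
  models <- lapply(kinds, function(kd)
    fit_surrogate(train_s, kd, hyper = hyper[[kd]], seed = seed))
  names(models) <- kinds

  eval_one <- function(model, tab, set_name) {
    m <- surrogate_metrics(as.matrix(tab[TARGETS]), predict(model, tab))
    data.frame(model = model$kind, set = set_name, rmse = m$rmse, r2 = m$r2,
               aic = m$aic, bic = m$bic, n = m$n, k = m$k)
  }
  metrics <- do.call(rbind, c(
    lapply(models, eval_one, tab = test_s, set_name = "test"),
    if (!is.null(ext_s)) lapply(models, eval_one, tab = ext_s,
                                set_name = "external")))
  rownames(metrics) <- NULL
  structure(list(metrics = metrics, models = models, scaler = scaler,
                 seed = seed), class = "fus_report")
}

#' @exportS3Method base::print
print.fus_report <- function(x, digits = 4, ...) {
  cat("<fus_report> surrogate comparison (seed", x$seed, ")\n")
  for (s in unique(x$metrics$set)) {
    cat("\n ", s, "set (n =", x$metrics$n[x$metrics$set == s][1], "):\n")
    m <- x$metrics[x$metrics$set == s, c("model", "rmse", "r2", "aic", "bic")]
    m[-1] <- lapply(m[-1], signif, digits = digits)
    print(m, row.names = FALSE)
  }
  invisible(x)
}

#' Write a surrogate report to disk
#'
#' Emits the metric table both as CSV and as a structured JSON file.
#'
#' @param report A [evaluate_models()] result.
#' @param prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @export
write_report <- function(report, prefix) {
  stopifnot(inherits(report, "fus_report"))
  utils::write.csv(report$metrics, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = report$seed, metrics = report$metrics),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(prefix)
}
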