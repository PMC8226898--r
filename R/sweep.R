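# Parameter sweep over array element counts and focus depth: enumerate the
# design, run the simulation chain per combination, and write the tabular
# machine-learning dataset (CSV + JSON sidecar).

#' Define a sweep over element counts and focus depth
#'
#' Default ranges are the study design: X elements 16 to 128 step 4,
#' Y elements 16 to 64 step 4, focus depth 25 to 75 mm step 1 mm
#' (inclusive endpoints), i.e. 29 x 13 x 51 = 19,227 combinations.
#'
#' @param x_elements,y_elements Integer vectors of element counts.
#' @param focus_mm Numeric vector of focus depths (mm).
#' @return Object of class `fus_sweep_spec`.
#' @export
sweep_spec <- function(x_elements = seq(16L, 128L, by = 4L),
                       y_elements = seq(16L, 64L, by = 4L),
                       focus_mm = seq(25, 75, by = 1)) {
  if (!length(x_elements) || !length(y_elements) || !length(focus_mm))
    stop("sweep ranges must be non-empty", call. = FALSE)
  stopifnot(all(x_elements >= 1), all(y_elements >= 1), all(focus_mm > 0))
  structure(list(x_elements = as.integer(x_elements),
                 y_elements = as.integer(y_elements),
                 focus_mm = as.numeric(focus_mm)),
            class = "fus_sweep_spec")
}

#' @exportS3Method base::print
print.fus_sweep_spec <- function(x, ...) {
  cat(sprintf("<fus_sweep_spec> %d x %d x %d = %d combinations\n",
              length(x$x_elements), length(x$y_elements), length(x$focus_mm),
              nrow(enumerate_sweep(x))))
  invisible(x)
}

#' Enumerate the sweep combinations
#'
#' Cartesian product in row-major order: `nx` outermost, `ny` next,
#' `focus_mm` innermost.
#'
#' @param spec A [sweep_spec()].
#' @return Data frame with columns `nx`, `ny`, `focus_mm`.
#' @export
enumerate_sweep <- function(spec) {
  stopifnot(inherits(spec, "fus_sweep_spec"))
  data.frame(
    nx = rep(spec$x_elements, each = length(spec$y_elements) * length(spec$focus_mm)),
    ny = rep(rep(spec$y_elements, each = length(spec$focus_mm)),
             times = length(spec$x_elements)),
    focus_mm = rep(spec$focus_mm,
                   times = length(spec$x_elements) * length(spec$y_elements))
  )
}

DATASET_COLS <- c("nx", "ny", "focus_mm", "max_pressure_pa", "max_power_w_m3",
                  "max_temperature_c")

#' Run a parameter sweep and write the dataset
#'
#' Runs [simulate_scenario()] for every combination and appends one row per
#' record to a CSV dataset (columns `nx, ny, focus_mm, max_pressure_pa,
#' max_power_w_m3, max_temperature_c`). The run is deterministic given the
#' config and resumable: completed rows (matched by `nx, ny, focus_mm`) are
#' skipped on rerun. A JSON sidecar records the config hash and grid for
#' provenance. The bio-heat operator is factorised once and reused.
#'
#' @param spec A [sweep_spec()].
#' @param config A [load_config()] scenario.
#' @param out_path Output CSV path; sidecar written to `<out_path>.meta.json`.
#' @param resume Skip already-written rows (default TRUE).
#' @param workers Parallel workers via forked processes (default 1; results
#'   are written in enumeration order either way).
#' @param progress Print progress every `progress` rows (0 = quiet).
#' @return The dataset as a data frame (invisibly also written to
#'   `out_path`).
#' @export
run_sweep <- function(spec, config, out_path, resume = TRUE, workers = 1L,
                      progress = 0L) {
  stopifnot(inherits(spec, "fus_sweep_spec"), inherits(config, "fus_config"))
  combos <- enumerate_sweep(spec)
  done <- NULL
  if (resume && file.exists(out_path)) {
    done <- utils::read.csv(out_path)
    if (!identical(names(done), DATASET_COLS))
      stop("existing dataset at ", out_path, " has unexpected columns",
           call. = FALSE)
  }
  part_path <- paste0(out_path, ".partial.csv")
  if (resume && file.exists(part_path)) {
    # rows salvaged from an interrupted run; malformed trailing lines dropped
    part <- tryCatch(utils::read.csv(part_path), error = function(e) NULL)
    if (!is.null(part) && identical(names(part), DATASET_COLS)) {
      part <- part[stats::complete.cases(part), , drop = FALSE]
      done <- rbind(done, part)
    }
  }
  key <- function(df) paste(df$nx, df$ny, format(df$focus_mm), sep = "|")
  todo <- combos
  if (!is.null(done) && nrow(done))
    todo <- combos[!(key(combos) %in% key(done)), , drop = FALSE]

  fac <- bioheat_factor(config$stack, config$grid)
  target <- config$stack$layers[[length(config$stack$layers)]]$medium$name
  one <- function(i) {
    sim <- simulate_scenario(config, nx = todo$nx[i], ny = todo$ny[i],
                             focus_mm = todo$focus_mm[i],
                             target_layer = target, bioheat = fac)
    unlist(sim$metrics)
  }
  n_todo <- nrow(todo)
  if (n_todo > 0) {
    if (workers > 1L) {
      res <- parallel::mclapply(seq_len(n_todo), one, mc.cores = workers)
    } else {
      # serial path appends each completed row so an interrupted run resumes
      part <- part_path
      if (!file.exists(part))
        utils::write.table(as.data.frame(stats::setNames(rep(list(numeric(0)), 6),
                                                         DATASET_COLS)),
                           part, sep = ",", row.names = FALSE)
      res <- vector("list", n_todo)
      for (i in seq_len(n_todo)) {
        res[[i]] <- one(i)
        row <- data.frame(todo[i, , drop = FALSE], t(res[[i]]))
        utils::write.table(row, part, sep = ",", row.names = FALSE,
                           col.names = FALSE, append = TRUE)
        if (progress > 0 && i %% progress == 0)
          message(sprintf("sweep: %d / %d", i, n_todo))
      }
      unlink(part)
    }
    new <- cbind(todo,
                 max_pressure_pa = vapply(res, `[[`, 0, "max_pressure_pa"),
                 max_power_w_m3 = vapply(res, `[[`, 0, "max_power_w_m3"),
                 max_temperature_c = vapply(res, `[[`, 0, "max_temperature_c"))
    done <- rbind(done, new)
  }
  # keep enumeration order
  done <- done[match(key(combos), key(done)), , drop = FALSE]
  rownames(done) <- NULL
  utils::write.csv(done, out_path, row.names = FALSE)
  meta <- list(config_hash = config$hash,
               scenario = config$scenario,
               grid = list(nx = config$grid$nx, ny = config$grid$ny,
                           nz = config$grid$nz,
                           spacing_mm = c(config$grid$dx, config$grid$dy,
                                          config$grid$dz) * 1e3),
               n_rows = nrow(done),
               package = "focusurf",
               version = as.character(utils::packageVersion("focusurf")))
  jsonlite::write_json(meta, paste0(out_path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(done)
}

#' Read a sweep dataset
#'
#' @param path CSV written by [run_sweep()].
#' @return Data frame with the dataset columns; errors if columns are
#'   missing or values are not finite.
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path)
  if (!all(DATASET_COLS %in% names(d)))
    stop("dataset must have columns ", paste(DATASET_COLS, collapse = ", "),
         call. = FALSE)
  d <- d[DATASET_COLS]
  if (!all(vapply(d, function(col) all(is.finite(col)), TRUE)))
    stop("dataset contains non-finite values", call. = FALSE)
  d
}
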