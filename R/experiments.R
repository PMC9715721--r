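# Sweep runners mirroring the structure of the grid experiments:
# (q, epsilon) grids with repeated networks, hidden-size comparisons, and
# noise-proportion curves.

#' Bundle train/validation/test datasets for an experiment
#'
#' Splits one generated dataset into disjoint training, validation and test
#' parts, seeded by the dataset spec.
#'
#' @param data A `labeled_dataset`.
#' @param n_validation,n_test Held-out example counts.
#' @param seed Integer seed for the split.
#' @return A `task` list with `train`, `validation`, `test` datasets.
#' @export
make_task <- function(data, n_validation, n_test, seed = 1L) {
  m <- n_examples(data)
  if (n_validation + n_test >= m) {
    stop("make_task(): n_validation + n_test must be < number of examples",
         call. = FALSE)
  }
  set.seed(seed)
  idx <- sample.int(m)
  test_idx <- idx[seq_len(n_test)]
  val_idx <- idx[n_test + seq_len(n_validation)]
  train_idx <- idx[(n_test + n_validation + 1L):m]
  structure(list(train = dataset_subset(data, train_idx),
                 validation = dataset_subset(data, val_idx),
                 test = dataset_subset(data, test_idx)),
            class = "task")
}

#' Specify a sweep experiment
#'
#' @param task A `task` from [make_task()].
#' @param mode Update mode (see [update_config()]).
#' @param q_values,epsilon_values Grid values for the masking proportion and
#'   the learning rate.
#' @param noise_values Grid values for the noise proportion (used by
#'   `binary_noisy`; default 0).
#' @param hidden_sizes Hidden-layer sizes; grid sweeps use the first entry,
#'   [run_size_comparison()] iterates over all of them.
#' @param n_repetitions Networks trained per grid cell, each from its own
#'   derived seed (default 10).
#' @param n_trials,validation_every,moving_window Training schedule fields.
#' @param master_seed Integer; repetition seeds are derived from it (see
#'   Details) so a sweep is bit-reproducible.
#' @details Repetition seeds are
#'   `(master_seed + 1000003 * (cell - 1) + 97 * (rep - 1)) mod (2^31 - 1)`,
#'   where `cell` and `rep` are 1-based indices; each run then seeds its own
#'   single RNG stream (initialisation, data order, masks, noise).
#' @return A `sweep_spec`.
#' @export
sweep_spec <- function(task, mode, q_values = 1, epsilon_values,
                       noise_values = 0, hidden_sizes, n_repetitions = 10L,
                       n_trials, validation_every = 500L, moving_window = 100L,
                       master_seed = 1L) {
  stopifnot(inherits(task, "task"))
  if (length(q_values) == 0 || length(epsilon_values) == 0 ||
      length(hidden_sizes) == 0) {
    stop("sweep_spec(): grids must be non-empty", call. = FALSE)
  }
  if (n_repetitions < 1) stop("sweep_spec(): n_repetitions must be >= 1",
                              call. = FALSE)
  structure(list(task = task, mode = mode, q_values = q_values,
                 epsilon_values = epsilon_values, noise_values = noise_values,
                 hidden_sizes = as.integer(hidden_sizes),
                 n_repetitions = as.integer(n_repetitions),
                 n_trials = as.integer(n_trials),
                 validation_every = as.integer(validation_every),
                 moving_window = as.integer(moving_window),
                 master_seed = as.integer(master_seed)),
            class = "sweep_spec")
}

derive_rep_seed <- function(master_seed, cell, rep) {
  as.integer((as.double(master_seed) + 1000003 * (cell - 1) + 97 * (rep - 1)) %%
               2147483647)
}

# one seeded training run; returns test error, final error rate and the curve
run_single <- function(task, mode, q, epsilon, noise_p, hidden, n_trials,
                       validation_every, moving_window, seed,
                       keep_curve = FALSE) {
  set.seed(seed)
  params0 <- init_network(ncol(task$train$inputs), hidden,
                          task$train$n_classes)
  config <- update_config(mode = mode, learning_rate = epsilon, q = q,
                          noise_p = noise_p, seed = NULL)
  schedule <- training_schedule(n_trials, validation_every, moving_window)
  fit <- train_online(params0, task$train, config, schedule,
                      val_data = task$validation)
  list(test_error = evaluate_misclassification(fit$params, task$test),
       final_error_rate = final_error_rate(fit$log),
       curve = if (keep_curve) fit$log$error_rate else NULL)
}

run_cells <- function(spec, grid, keep_curves = FALSE) {
  reps <- vector("list", nrow(grid) * spec$n_repetitions)
  curves <- if (keep_curves) vector("list", nrow(grid)) else NULL
  r <- 0L
  for (cell in seq_len(nrow(grid))) {
    cell_curves <- if (keep_curves) vector("list", spec$n_repetitions) else NULL
    for (rep in seq_len(spec$n_repetitions)) {
      seed <- derive_rep_seed(spec$master_seed, cell, rep)
      res <- run_single(spec$task, grid$mode[cell], grid$q[cell],
                        grid$epsilon[cell], grid$noise_p[cell],
                        grid$hidden[cell], spec$n_trials,
                        spec$validation_every, spec$moving_window, seed,
                        keep_curve = keep_curves)
      r <- r + 1L
      reps[[r]] <- data.frame(cell = cell, q = grid$q[cell],
                              epsilon = grid$epsilon[cell],
                              noise_p = grid$noise_p[cell],
                              hidden = grid$hidden[cell], rep = rep,
                              seed = seed, test_error = res$test_error,
                              final_error_rate = res$final_error_rate)
      if (keep_curves) cell_curves[[rep]] <- res$curve
    }
    if (keep_curves) curves[[cell]] <- cell_curves
  }
  reps <- do.call(rbind, reps)
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(cell) {
    e <- reps$test_error[reps$cell == cell]
    data.frame(cell = cell, q = grid$q[cell], epsilon = grid$epsilon[cell],
               noise_p = grid$noise_p[cell], hidden = grid$hidden[cell],
               mean_test_error = mean(e),
               sd_test_error = if (length(e) > 1) stats::sd(e) else 0)
  }))
  structure(list(cells = cells, reps = reps, curves = curves, spec = spec),
            class = "sweep_result")
}

#' Run a (q, epsilon) grid sweep
#'
#' For every grid cell (`q`, `epsilon`, and `noise_p` when the mode is
#' `binary_noisy`), trains `n_repetitions` networks from derived seeds,
#' evaluates each on the test set, and records the per-repetition test errors
#' together with their mean and standard deviation per cell. Deterministic
#' given `master_seed`.
#'
#' @param spec A `sweep_spec`; the hidden size is `spec$hidden_sizes[1]`.
#' @return A `sweep_result` with data.frames `cells` (per-cell mean/sd) and
#'   `reps` (per-repetition values).
#' @export
run_grid_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  noise <- if (spec$mode == "binary_noisy") spec$noise_values else 0
  grid <- expand.grid(q = spec$q_values, epsilon = spec$epsilon_values,
                      noise_p = noise, KEEP.OUT.ATTRS = FALSE)
  grid$hidden <- spec$hidden_sizes[1]
  grid$mode <- spec$mode
  run_cells(spec, grid)
}

#' Compare hidden-layer sizes at fixed (q, epsilon)
#'
#' One cell per hidden size at `q = q_values[1]`, `epsilon =
#' epsilon_values[1]`; the full moving-average error-rate curve of every
#' repetition is kept so convergence levels can be compared across sizes.
#'
#' @param spec A `sweep_spec`.
#' @return A `sweep_result`; `curves[[cell]][[rep]]` is that run's
#'   moving-average error-rate curve.
#' @export
run_size_comparison <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- data.frame(q = spec$q_values[1], epsilon = spec$epsilon_values[1],
                     noise_p = 0, hidden = spec$hidden_sizes)
  grid$mode <- spec$mode
  run_cells(spec, grid, keep_curves = TRUE)
}

#' Noise-proportion curves in binary_noisy mode
#'
#' One cell per value of the noise proportion `n_p` at fixed
#' `q = q_values[1]` and `epsilon = epsilon_values[1]`; repetition seeds are
#' paired across cells (same rep, same derived base) via the documented seed
#' derivation, and full curves are kept.
#'
#' @param spec A `sweep_spec` with non-empty `noise_values`.
#' @return A `sweep_result` with `curves` as in [run_size_comparison()].
#' @export
run_noise_curves <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (length(spec$noise_values) == 0) {
    stop("run_noise_curves(): noise_values must be non-empty", call. = FALSE)
  }
  grid <- data.frame(q = spec$q_values[1], epsilon = spec$epsilon_values[1],
                     noise_p = spec$noise_values,
                     hidden = spec$hidden_sizes[1])
  grid$mode <- "binary_noisy"
  spec2 <- spec
  # pair repetition seeds across noise levels: same seed for the same rep
  spec2$paired <- TRUE
  res <- local({
    reps <- vector("list", nrow(grid) * spec$n_repetitions)
    curves <- vector("list", nrow(grid))
    r <- 0L
    for (cell in seq_len(nrow(grid))) {
      cell_curves <- vector("list", spec$n_repetitions)
      for (rep in seq_len(spec$n_repetitions)) {
        seed <- derive_rep_seed(spec$master_seed, 1L, rep)  # paired across cells
        one <- run_single(spec$task, "binary_noisy", grid$q[cell],
                          grid$epsilon[cell], grid$noise_p[cell],
                          grid$hidden[cell], spec$n_trials,
                          spec$validation_every, spec$moving_window, seed,
                          keep_curve = TRUE)
        r <- r + 1L
        reps[[r]] <- data.frame(cell = cell, q = grid$q[cell],
                                epsilon = grid$epsilon[cell],
                                noise_p = grid$noise_p[cell],
                                hidden = grid$hidden[cell], rep = rep,
                                seed = seed, test_error = one$test_error,
                                final_error_rate = one$final_error_rate)
        cell_curves[[rep]] <- one$curve
      }
      curves[[cell]] <- cell_curves
    }
    reps <- do.call(rbind, reps)
    cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(cell) {
      e <- reps$test_error[reps$cell == cell]
      data.frame(cell = cell, q = grid$q[cell], epsilon = grid$epsilon[cell],
                 noise_p = grid$noise_p[cell], hidden = grid$hidden[cell],
                 mean_test_error = mean(e),
                 sd_test_error = if (length(e) > 1) stats::sd(e) else 0)
    }))
    structure(list(cells = cells, reps = reps, curves = curves, spec = spec),
              class = "sweep_result")
  })
  res
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result: %d cells x %d repetitions>\n",
              nrow(x$cells), x$spec$n_repetitions))
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Write sweep results to CSV
#'
#' Writes `cells.csv` (per-cell mean and standard deviation of the test
#' error) and `repetitions.csv` (per-run values) into `dir`, plus a
#' `sweep.json` echo of the sweep configuration.
#'
#' @param result A `sweep_result`.
#' @param dir Output directory (created if needed).
#' @export
write_sweep_csv <- function(result, dir) {
  stopifnot(inherits(result, "sweep_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(result$reps, file.path(dir, "repetitions.csv"),
                   row.names = FALSE)
  s <- result$spec
  jsonlite::write_json(
    list(mode = s$mode, q_values = s$q_values,
         epsilon_values = s$epsilon_values, noise_values = s$noise_values,
         hidden_sizes = s$hidden_sizes, n_repetitions = s$n_repetitions,
         n_trials = s$n_trials, validation_every = s$validation_every,
         moving_window = s$moving_window, master_seed = s$master_seed),
    file.path(dir, "sweep.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
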