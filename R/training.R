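# Online training loop, per-trial error, moving-average error rate,
# periodic validation and test-set evaluation.

#' Training schedule
#'
#' @param n_trials Total number of online trials (one example and one weight
#'   update per trial).
#' @param validation_every Validation cadence in trials (default 500).
#' @param moving_window Window length of the moving-average error rate
#'   (default 100 trials).
#' @return A `training_schedule`.
#' @export
training_schedule <- function(n_trials, validation_every = 500L,
                              moving_window = 100L) {
  if (n_trials < 1 || validation_every < 1 || moving_window < 1) {
    stop("training_schedule(): all fields must be positive", call. = FALSE)
  }
  if (validation_every > n_trials) {
    stop("training_schedule(): validation_every must be <= n_trials",
         call. = FALSE)
  }
  structure(list(n_trials = as.integer(n_trials),
                 validation_every = as.integer(validation_every),
                 moving_window = as.integer(moving_window)),
            class = "training_schedule")
}

#' Per-trial classification error
#'
#' 0 if the network output and the one-hot target agree on the index of their
#' largest entry, 1 otherwise (ties broken by the first maximum). Exact
#' real-valued equality of logistic outputs with a 0/1 target never occurs,
#' so "the output matches the target" is operationalised as argmax agreement.
#'
#' @param output Network output vector.
#' @param target One-hot target vector of the same length.
#' @return 0 or 1 (integer).
#' @export
trial_error <- function(output, target) {
  if (length(output) != length(target)) {
    stop("trial_error(): output and target lengths differ", call. = FALSE)
  }
  as.integer(which.max(output) != which.max(target))
}

#' Moving-average error over the most recent trials
#'
#' Mean of the last `min(window, length(errors))` entries; with fewer trials
#' than the window, all available trials are averaged.
#'
#' @param errors Vector of 0/1 per-trial errors (most recent last).
#' @param window Positive window length (default 100).
#' @return Error rate in `[0, 1]`.
#' @export
moving_average_error <- function(errors, window = 100L) {
  n <- length(errors)
  if (n == 0L) stop("moving_average_error(): empty error sequence",
                    call. = FALSE)
  if (window < 1) stop("moving_average_error(): window must be positive",
                       call. = FALSE)
  mean(errors[max(1L, n - window + 1L):n])
}

# full moving-average curve via cumulative sums
error_rate_curve <- function(errors, window) {
  n <- length(errors)
  cs <- cumsum(errors)
  curve <- cs / seq_len(n)
  if (n > window) {
    t_full <- (window + 1L):n
    curve[t_full] <- (cs[t_full] - cs[t_full - window]) / window
  }
  curve
}

#' Misclassification rate of a network on a dataset
#'
#' Mean per-example [trial_error()] over the whole dataset; no weights are
#' updated and no RNG is consumed, so evaluation is idempotent.
#'
#' @param params A `network_params`.
#' @param data A non-empty `labeled_dataset` whose feature dimension matches
#'   `params$n_input`.
#' @return Error rate in `[0, 1]`.
#' @export
evaluate_misclassification <- function(params, data) {
  stopifnot(inherits(params, "network_params"),
            inherits(data, "labeled_dataset"))
  if (n_examples(data) == 0L) {
    stop("evaluate_misclassification(): empty dataset", call. = FALSE)
  }
  if (ncol(data$inputs) != params$n_input) {
    stop("evaluate_misclassification(): feature dimension does not match network",
         call. = FALSE)
  }
  a_in <- cbind(data$inputs, 1)
  h <- logistic(a_in %*% t(params$w_hi))
  o <- logistic(h %*% t(params$w_oh))
  pred <- max.col(o, ties.method = "first")
  truth <- max.col(data$targets, ties.method = "first")
  mean(pred != truth)
}

#' Train a network online
#'
#' Runs the per-trial loop: present one example, forward pass, record the
#' 0/1 trial error, compute the error signals, and apply one weight update
#' under `config`. Every `schedule$validation_every` trials the
#' misclassification rate on `val_data` (if supplied) is recorded.
#'
#' Randomness contract: if `config$seed` is non-`NULL`, `set.seed(config$seed)`
#' is called once at entry; everything random in the run — the example order
#' (a fresh shuffle of the training set per epoch, all epochs drawn up front),
#' then per trial the update masks and noise draws — comes from that single
#' stream in this fixed order. Trials beyond one epoch reshuffle and continue.
#'
#' @param params0 Initial `network_params`.
#' @param train_data Training `labeled_dataset`.
#' @param config An `update_config`.
#' @param schedule A `training_schedule`.
#' @param val_data Optional validation `labeled_dataset`.
#' @param shuffle Shuffle example order each epoch (default `TRUE`; with
#'   `FALSE` examples are presented cyclically in dataset order and the data
#'   order consumes no RNG).
#' @return List with `params` (trained `network_params`) and `log`, a
#'   `training_log` with fields `trial_errors` (0/1 vector), `error_rate`
#'   (moving-average curve), `validation` (data.frame `trial`, `error`).
#' @export
train_online <- function(params0, train_data, config, schedule,
                         val_data = NULL, shuffle = TRUE) {
  stopifnot(inherits(params0, "network_params"),
            inherits(train_data, "labeled_dataset"),
            inherits(config, "update_config"),
            inherits(schedule, "training_schedule"))
  if (ncol(train_data$inputs) != params0$n_input ||
      train_data$n_classes != params0$n_output) {
    stop("train_online(): dataset shape does not match the network",
         call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  m <- n_examples(train_data)
  n_trials <- schedule$n_trials
  n_epochs <- ceiling(n_trials / m)
  order_all <- if (shuffle) {
    unlist(lapply(seq_len(n_epochs), function(e) sample.int(m)))
  } else {
    rep(seq_len(m), n_epochs)
  }
  order_all <- order_all[seq_len(n_trials)]

  params <- params0
  trial_errors <- integer(n_trials)
  val_trials <- integer(0)
  val_errors <- numeric(0)

  for (n in seq_len(n_trials)) {
    i <- order_all[n]
    x <- train_data$inputs[i, ]
    y <- train_data$targets[i, ]
    cache <- forward(params, x)
    trial_errors[n] <- trial_error(cache$a_out, y)
    signals <- compute_error_signals(cache, y, params)
    params <- update_step(params, cache, signals, config)
    if (!is.null(val_data) && n %% schedule$validation_every == 0L) {
      val_trials <- c(val_trials, n)
      val_errors <- c(val_errors, evaluate_misclassification(params, val_data))
    }
  }

  log <- structure(
    list(trial_errors = trial_errors,
         error_rate = error_rate_curve(trial_errors, schedule$moving_window),
         validation = data.frame(trial = val_trials, error = val_errors),
         config = config, schedule = schedule),
    class = "training_log")
  list(params = params, log = log)
}

#' @export
print.training_log <- function(x, ...) {
  n <- length(x$trial_errors)
  cat(sprintf(
    "<training_log: %d trials, final error rate %.3f, %d validation points>\n",
    n, x$error_rate[n], nrow(x$validation)))
  invisible(x)
}

#' Final moving-average error rate of a run
#' @param log A `training_log`.
#' @return The last value of the moving-average error-rate curve.
#' @export
final_error_rate <- function(log) {
  log$error_rate[length(log$error_rate)]
}

#' Write a training log to disk
#'
#' Writes `trials.csv` (columns `trial`, `trial_error`, `error_rate`),
#' `validation.csv` (columns `trial`, `error`) and `summary.json` (config
#' echo, trial count, final moving-average error, final validation error).
#'
#' @param log A `training_log`.
#' @param dir Output directory (created if needed).
#' @param extra Optional named list merged into the JSON summary.
#' @return The directory path, invisibly.
#' @export
write_training_log <- function(log, dir, extra = list()) {
  stopifnot(inherits(log, "training_log"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    data.frame(trial = seq_along(log$trial_errors),
               trial_error = log$trial_errors,
               error_rate = log$error_rate),
    file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(log$validation, file.path(dir, "validation.csv"),
                   row.names = FALSE)
  summary <- c(list(
    mode = log$config$mode, q = log$config$q, noise_p = log$config$noise_p,
    learning_rate = log$config$learning_rate,
    seed = if (is.null(log$config$seed)) NA else log$config$seed,
    n_trials = length(log$trial_errors),
    moving_window = log$schedule$moving_window,
    final_error_rate = final_error_rate(log),
    final_validation_error = if (nrow(log$validation))
      log$validation$error[nrow(log$validation)] else NA
  ), extra)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
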