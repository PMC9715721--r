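# Shared helpers: independent oracles and small fixture builders.

# random small network with weights in (-1, 1)
rand_params <- function(n_input, n_hidden, n_output) {
  network_params(
    matrix(stats::runif(n_hidden * (n_input + 1), -1, 1), nrow = n_hidden),
    matrix(stats::runif(n_output * n_hidden, -1, 1), nrow = n_output)
  )
}

# central finite differences of a loss w.r.t. every weight; independent of
# compute_error_signals / full_gradient. Default loss: the cross-entropy the
# update rules are the exact gradient of.
fd_gradient <- function(params, x, target, h = 1e-6,
                        loss = cross_entropy_loss) {
  loss_at <- function(p) loss(forward(p, x)$a_out, target)
  g_hi <- params$w_hi
  for (i in seq_along(g_hi)) {
    up <- params; up$w_hi[i] <- up$w_hi[i] + h
    dn <- params; dn$w_hi[i] <- dn$w_hi[i] - h
    g_hi[i] <- (loss_at(up) - loss_at(dn)) / (2 * h)
  }
  g_oh <- params$w_oh
  for (i in seq_along(g_oh)) {
    up <- params; up$w_oh[i] <- up$w_oh[i] + h
    dn <- params; dn$w_oh[i] <- dn$w_oh[i] - h
    g_oh[i] <- (loss_at(up) - loss_at(dn)) / (2 * h)
  }
  list(g_hi = g_hi, g_oh = g_oh)
}

rel_err <- function(a, b) {
  max(abs(a - b) / pmax(abs(b), 1e-8))
}

# every step is 0 or +/-eps, up to double-precision subtraction noise
steps_one_bit <- function(steps, eps, fuzz = 1e-12) {
  all(abs(steps) < fuzz | abs(abs(steps) - eps) < fuzz)
}

# family-wise 3-sigma band: per-entry z for n simultaneous comparisons
fw_band <- function(n) stats::qnorm(1 - (2 * stats::pnorm(-3)) / (2 * n))

# small glyph classification task split into train/validation/test
glyph_task <- function(n_classes = 10, n = 2000, seed = 7, noise_sd = 0.1) {
  data <- generate_glyphs(synthetic_task_spec(
    "glyphs", n_classes = n_classes, n_examples = n, glyph_size = 8,
    noise_sd = noise_sd, seed = seed))
  make_task(data, n_validation = round(n / 10), n_test = round(n / 10),
            seed = seed)
}

blob_task <- function(n_classes = 3, n_features = 16, n = 3000, seed = 7,
                      center_sep_sigmas = 4) {
  data <- generate_blobs(synthetic_task_spec(
    "blobs", n_classes = n_classes, n_examples = n, n_features = n_features,
    center_sep_sigmas = center_sep_sigmas, seed = seed))
  make_task(data, n_validation = round(n / 10), n_test = round(n / 10),
            seed = seed)
}

# one seeded training run, returning the final moving-average error rate
seeded_final_error <- function(task, mode, epsilon, q, hidden, n_trials,
                               seed, noise_p = 0) {
  set.seed(seed)
  params0 <- init_network(ncol(task$train$inputs), hidden,
                          task$train$n_classes)
  cfg <- update_config(mode, learning_rate = epsilon, q = q,
                       noise_p = noise_p)
  fit <- train_online(params0, task$train, cfg,
                      training_schedule(n_trials, n_trials, 100))
  fit
}
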