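# Photonic update rules: stochastic q-masked gradient updates, one-bit sign
# updates, and uncorrelated plus/minus noise updates.

#' Three-valued sign function
#'
#' Returns 1 for positive input, 0 for exactly zero, -1 for negative input.
#' This is the quantity a single backward photon is assumed to carry: one bit
#' (increase or decrease by a fixed step), or nothing when the gradient term
#' vanishes.
#'
#' @param x Finite numeric vector or scalar.
#' @return Integer-valued vector in `{-1, 0, 1}`, same shape as `x`.
#' @export
sgn <- function(x) {
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x))) {
    stop("sgn(): input must be finite numeric", call. = FALSE)
  }
  sign(x)
}

#' Update-rule configuration
#'
#' Bundles the update mode and its parameters for one training run.
#'
#' Modes:
#' \describe{
#'   \item{`full`}{standard online backpropagation; every weight moves by
#'     `-learning_rate * gradient` each trial (`q` is ignored).}
#'   \item{`stochastic`}{per trial, a fresh uniformly random subset of
#'     `round(q * n)` weights per layer receives the gradient update; the
#'     rest are untouched. `q = 1` reproduces `full` exactly.}
#'   \item{`binary`}{the masked weights move by exactly
#'     `-learning_rate * sgn(gradient term)`, i.e. one bit per weight.}
#'   \item{`binary_noisy`}{the `binary` update is applied first, then an
#'     independently drawn subset of `round(noise_p * n)` weights per layer
#'     receives `-learning_rate * eta` with `eta` uniform on `{-1, +1}`.
#'     Weights selected by both draws receive both increments.}
#' }
#'
#' @param mode One of `"full"`, `"stochastic"`, `"binary"`, `"binary_noisy"`.
#' @param learning_rate Non-negative step size; 0 is allowed so a run can be
#'   frozen for testing.
#' @param q Proportion of weights updated per trial, in `[0, 1]`. Ignored by
#'   `full`.
#' @param noise_p Proportion of weights receiving a noise update per trial,
#'   in `[0, 1]`. Used only by `binary_noisy`.
#' @param seed Optional integer seed for the run's single RNG stream (consumed
#'   by [train_online()]).
#' @return An `update_config` object.
#' @export
update_config <- function(mode = c("full", "stochastic", "binary", "binary_noisy"),
                          learning_rate, q = 1, noise_p = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(learning_rate) || length(learning_rate) != 1L ||
      !is.finite(learning_rate) || learning_rate < 0) {
    stop("update_config(): learning_rate must be a non-negative number",
         call. = FALSE)
  }
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1) {
    stop("update_config(): q must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(noise_p) || length(noise_p) != 1L || is.na(noise_p) ||
      noise_p < 0 || noise_p > 1) {
    stop("update_config(): noise_p must lie in [0, 1]", call. = FALSE)
  }
  structure(list(mode = mode, learning_rate = learning_rate, q = q,
                 noise_p = noise_p, seed = seed),
            class = "update_config")
}

# round-half-away-from-zero mask size, clamped to [0, n_total]
mask_size <- function(n_total, q) {
  min(max(floor(q * n_total + 0.5), 0L), n_total)
}

#' Sample a random update mask for one layer
#'
#' Draws `round(q * n_total)` distinct indices uniformly without replacement
#' (rounding half away from zero). A fresh mask is drawn every trial; this is
#' the abstract model of which synapses receive a backward photon.
#'
#' The degenerate sizes 0 and `n_total` are returned without consuming the
#' RNG stream, so `q = 0` and `q = 1` runs stay aligned with runs that draw
#' no mask at all.
#'
#' @param n_total Number of weights in the layer (positive integer).
#' @param q Proportion in `[0, 1]`.
#' @return Integer vector of distinct 1-based linear indices.
#' @export
sample_mask <- function(n_total, q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1) {
    stop("sample_mask(): q must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(n_total) || length(n_total) != 1L || n_total < 1) {
    stop("sample_mask(): n_total must be a positive integer", call. = FALSE)
  }
  m <- mask_size(n_total, q)
  if (m == 0L) return(integer(0))
  if (m == n_total) return(seq_len(n_total))
  sample.int(n_total, m)
}

#' Draw a fresh two-layer update mask
#'
#' Independent masks for `w_hi` (including its bias column) and `w_oh`,
#' each sized by the same proportion `q`. RNG order: the `w_hi` mask is drawn
#' first, then the `w_oh` mask.
#'
#' @param params A `network_params` object (sizes only are used).
#' @param q Proportion in `[0, 1]`.
#' @return An `update_mask` object with linear index vectors `idx_hi`,
#'   `idx_oh`.
#' @export
update_mask <- function(params, q) {
  stopifnot(inherits(params, "network_params"))
  structure(list(idx_hi = sample_mask(length(params$w_hi), q),
                 idx_oh = sample_mask(length(params$w_oh), q)),
            class = "update_mask")
}

#' Gradient update restricted to a mask
#'
#' Each masked weight moves by `-learning_rate` times its exact gradient
#' entry; all unmasked weights are unchanged. With a full mask this is
#' bit-identical to unrestricted online backpropagation.
#'
#' @param params A `network_params` object.
#' @param grads A `gradients` object from [full_gradient()].
#' @param mask An `update_mask`.
#' @param learning_rate Positive step size.
#' @return The updated `network_params`.
#' @export
apply_masked_gradient_update <- function(params, grads, mask, learning_rate) {
  stopifnot(inherits(params, "network_params"), inherits(grads, "gradients"),
            inherits(mask, "update_mask"))
  if (!identical(dim(grads$g_hi), dim(params$w_hi)) ||
      !identical(dim(grads$g_oh), dim(params$w_oh))) {
    stop("apply_masked_gradient_update(): gradient shapes do not match",
         call. = FALSE)
  }
  i <- mask$idx_hi
  if (length(i)) params$w_hi[i] <- params$w_hi[i] - learning_rate * grads$g_hi[i]
  i <- mask$idx_oh
  if (length(i)) params$w_oh[i] <- params$w_oh[i] - learning_rate * grads$g_oh[i]
  params
}

#' One-bit (sign) update restricted to a mask
#'
#' Each masked weight moves by exactly `-learning_rate * sgn(g)`, where `g`
#' is the corresponding gradient term: `delta_out_l * a_hidden_k` for the
#' output layer and `(sum_l delta_out_l * w_oh[l, k]) * a_hidden_k *
#' (1 - a_hidden_k) * a_in_j` for the hidden layer, both evaluated with the
#' current trial's pre-update `w_oh`. Every per-weight change is therefore
#' exactly one of `-learning_rate`, `0`, `+learning_rate`.
#'
#' @inheritParams apply_masked_gradient_update
#' @param cache A `forward_cache` for the trial.
#' @param signals The trial's `error_signals`.
#' @return The updated `network_params`.
#' @export
apply_masked_binary_update <- function(params, cache, signals, mask,
                                       learning_rate) {
  stopifnot(inherits(params, "network_params"), inherits(cache, "forward_cache"),
            inherits(signals, "error_signals"), inherits(mask, "update_mask"))
  grads <- full_gradient(cache, signals)
  i <- mask$idx_hi
  if (length(i)) params$w_hi[i] <- params$w_hi[i] - learning_rate * sgn(grads$g_hi[i])
  i <- mask$idx_oh
  if (length(i)) params$w_oh[i] <- params$w_oh[i] - learning_rate * sgn(grads$g_oh[i])
  params
}

#' Draw an uncorrelated noise-photon update
#'
#' Selects `round(noise_p * n)` weights per layer (independently of any
#' signal mask) and assigns each a value `eta` drawn uniformly from
#' `{-1, +1}`, independent across weights and trials. RNG order: `w_hi`
#' indices, `w_hi` signs, `w_oh` indices, `w_oh` signs. With `noise_p = 0`
#' the RNG stream is not consumed.
#'
#' @param params A `network_params` object (sizes only are used).
#' @param noise_p Proportion in `[0, 1]`.
#' @return A `noise_draw` object with fields `idx_hi`, `eta_hi`, `idx_oh`,
#'   `eta_oh`.
#' @export
noise_draw <- function(params, noise_p) {
  stopifnot(inherits(params, "network_params"))
  idx_hi <- sample_mask(length(params$w_hi), noise_p)
  eta_hi <- if (length(idx_hi)) sample(c(-1, 1), length(idx_hi), replace = TRUE)
            else numeric(0)
  idx_oh <- sample_mask(length(params$w_oh), noise_p)
  eta_oh <- if (length(idx_oh)) sample(c(-1, 1), length(idx_oh), replace = TRUE)
            else numeric(0)
  structure(list(idx_hi = idx_hi, eta_hi = eta_hi,
                 idx_oh = idx_oh, eta_oh = eta_oh),
            class = "noise_draw")
}

#' Apply a noise-photon update
#'
#' Each noise-selected weight moves by `-learning_rate * eta` (i.e. by
#' exactly plus or minus the step size); all other weights are unchanged.
#'
#' @param params A `network_params` object.
#' @param noise A `noise_draw`.
#' @param learning_rate Positive step size.
#' @return The updated `network_params`.
#' @export
apply_noise_update <- function(params, noise, learning_rate) {
  stopifnot(inherits(params, "network_params"), inherits(noise, "noise_draw"))
  if (!all(noise$eta_hi %in% c(-1, 1)) || !all(noise$eta_oh %in% c(-1, 1))) {
    stop("apply_noise_update(): eta values must be -1 or +1", call. = FALSE)
  }
  i <- noise$idx_hi
  if (length(i)) params$w_hi[i] <- params$w_hi[i] - learning_rate * noise$eta_hi
  i <- noise$idx_oh
  if (length(i)) params$w_oh[i] <- params$w_oh[i] - learning_rate * noise$eta_oh
  params
}

#' One weight-update step under a configured mode
#'
#' Dispatches on `config$mode`:
#' `full` applies the unrestricted gradient update; `stochastic` draws a
#' fresh mask then applies the masked gradient update; `binary` draws a fresh
#' mask then applies the one-bit update; `binary_noisy` applies the binary
#' update first and then an independent noise draw. All randomness comes from
#' the current RNG stream in the documented order (signal mask, then noise
#' draw), so a fixed seed gives identical update sequences.
#'
#' @param params A `network_params` object.
#' @param cache The trial's `forward_cache`.
#' @param signals The trial's `error_signals`.
#' @param config An `update_config`.
#' @return The updated `network_params`.
#' @export
update_step <- function(params, cache, signals, config) {
  stopifnot(inherits(config, "update_config"))
  eps <- config$learning_rate
  switch(config$mode,
    full = {
      grads <- full_gradient(cache, signals)
      params$w_hi <- params$w_hi - eps * grads$g_hi
      params$w_oh <- params$w_oh - eps * grads$g_oh
      params
    },
    stochastic = {
      mask <- update_mask(params, config$q)
      apply_masked_gradient_update(params, full_gradient(cache, signals),
                                   mask, eps)
    },
    binary = {
      mask <- update_mask(params, config$q)
      apply_masked_binary_update(params, cache, signals, mask, eps)
    },
    binary_noisy = {
      mask <- update_mask(params, config$q)
      params <- apply_masked_binary_update(params, cache, signals, mask, eps)
      apply_noise_update(params, noise_draw(params, config$noise_p), eps)
    },
    stop("update_step(): unknown mode", call. = FALSE)
  )
}
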