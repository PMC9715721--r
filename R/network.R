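# Core three-layer logistic network: forward pass, squared-error loss,
# error signals and exact gradients.

#' Logistic (sigmoid) activation
#'
#' Computes `1 / (1 + exp(-x))` branch-wise so that neither tail overflows:
#' for non-negative `x` the standard form is used, for negative `x` the
#' algebraically equivalent `exp(x) / (1 + exp(x))`.
#'
#' @param x Numeric vector, matrix or scalar; all entries must be finite.
#' @return Values in `[0, 1]`, same shape as `x`. In double precision the
#'   result reaches exactly 0 or 1 for `|x|` beyond roughly 37; callers that
#'   need strictly interior activations (the slope `a (1 - a)` is undefined
#'   at the endpoints) should clamp, as [forward()] does.
#' @seealso [logistic_slope()], [forward()]
#' @export
#' @examples
#' logistic(0)        # 0.5
#' logistic(log(3))   # 0.75
logistic <- function(x) {
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x))) {
    stop("logistic(): input must be finite numeric", call. = FALSE)
  }
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Derivative of the logistic, evaluated from the stored activation
#'
#' For `a = logistic(z)` the derivative with respect to the pre-activation
#' `z` is `a * (1 - a)`; this is how the backward pass recovers the slope
#' without keeping `z` around.
#'
#' @param a Activation value(s) strictly inside `(0, 1)`.
#' @return `a * (1 - a)`, in `(0, 0.25]`.
#' @export
logistic_slope <- function(a) {
  if (!is.numeric(a) || anyNA(a) || any(a <= 0) || any(a >= 1)) {
    stop("logistic_slope(): activations must lie strictly in (0, 1)",
         call. = FALSE)
  }
  a * (1 - a)
}

#' Construct three-layer network parameters
#'
#' The network is input -> hidden -> output with logistic units in the hidden
#' and output layers. The hidden-layer bias is stored as the final column of
#' `w_hi`, acting against a constant input of 1, so it is trained (and
#' masked) exactly like any other hidden-layer weight. The output layer has
#' no bias.
#'
#' @param w_hi Hidden-from-input weight matrix, shape `n_hidden x (n_input + 1)`
#'   (last column is the bias).
#' @param w_oh Output-from-hidden weight matrix, shape `n_output x n_hidden`.
#' @return An object of class `network_params` with fields `w_hi`, `w_oh`,
#'   `n_input`, `n_hidden`, `n_output`.
#' @export
network_params <- function(w_hi, w_oh) {
  if (!is.matrix(w_hi) || !is.matrix(w_oh)) {
    stop("network_params(): w_hi and w_oh must be matrices", call. = FALSE)
  }
  if (!all(is.finite(w_hi)) || !all(is.finite(w_oh))) {
    stop("network_params(): weights must be finite", call. = FALSE)
  }
  n_hidden <- nrow(w_hi)
  n_input <- ncol(w_hi) - 1L
  n_output <- nrow(w_oh)
  if (n_input < 1L || n_hidden < 1L || n_output < 1L) {
    stop("network_params(): all layer sizes must be >= 1", call. = FALSE)
  }
  if (ncol(w_oh) != n_hidden) {
    stop("network_params(): ncol(w_oh) must equal nrow(w_hi)", call. = FALSE)
  }
  structure(
    list(w_hi = w_hi, w_oh = w_oh,
         n_input = n_input, n_hidden = n_hidden, n_output = n_output),
    class = "network_params"
  )
}

#' Randomly initialise a three-layer network
#'
#' Weights are drawn uniformly on `(-r, r)` with `r = sqrt(6 / (fan_in +
#' fan_out))` per layer, which keeps logistic units away from saturation at
#' the start of training. The bias column is initialised like any other
#' weight.
#'
#' @param n_input,n_hidden,n_output Layer sizes (positive integers).
#' @param seed Optional integer; if supplied, `set.seed(seed)` is called
#'   first. If `NULL` (default) the current RNG stream is consumed, which is
#'   what the training and sweep runners rely on for their single-stream
#'   seeding contract.
#' @return A `network_params` object.
#' @export
init_network <- function(n_input, n_hidden, n_output, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r_hi <- sqrt(6 / ((n_input + 1) + n_hidden))
  r_oh <- sqrt(6 / (n_hidden + n_output))
  w_hi <- matrix(stats::runif(n_hidden * (n_input + 1), -r_hi, r_hi),
                 nrow = n_hidden)
  w_oh <- matrix(stats::runif(n_output * n_hidden, -r_oh, r_oh),
                 nrow = n_output)
  network_params(w_hi, w_oh)
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("<network_params %d-%d-%d (%d weights incl. hidden bias)>\n",
              x$n_input, x$n_hidden, x$n_output,
              length(x$w_hi) + length(x$w_oh)))
  invisible(x)
}

# Activations are clamped into the open unit interval so the backward slope
# a(1-a) never hits an exact 0/1 produced by double-precision saturation.
.ACT_EPS <- 1e-12

#' Forward pass through the network
#'
#' `a_in` is the input augmented with a trailing constant 1 (the bias input);
#' hidden activations are `logistic(w_hi %*% a_in)` and output activations
#' `logistic(w_oh %*% a_hidden)`.
#'
#' @param params A `network_params` object.
#' @param x Numeric input vector of length `params$n_input`, finite.
#' @return An object of class `forward_cache` with fields `a_in` (length
#'   `n_input + 1`, last entry 1), `a_hidden`, `a_out`, all activations
#'   strictly inside `(0, 1)`.
#' @export
forward <- function(params, x) {
  stopifnot(inherits(params, "network_params"))
  if (!is.numeric(x) || length(x) != params$n_input || !all(is.finite(x))) {
    stop(sprintf("forward(): x must be a finite numeric vector of length %d",
                 params$n_input), call. = FALSE)
  }
  a_in <- c(as.numeric(x), 1)
  a_hidden <- logistic(as.numeric(params$w_hi %*% a_in))
  a_hidden <- pmin(pmax(a_hidden, .ACT_EPS), 1 - .ACT_EPS)
  a_out <- logistic(as.numeric(params$w_oh %*% a_hidden))
  a_out <- pmin(pmax(a_out, .ACT_EPS), 1 - .ACT_EPS)
  structure(list(a_in = a_in, a_hidden = a_hidden, a_out = a_out),
            class = "forward_cache")
}

#' Squared-error loss
#'
#' One half the sum of squared residuals between the network output and the
#' target: `0.5 * sum((output - target)^2)`.
#'
#' @param output,target Numeric vectors of equal length, finite.
#' @return Non-negative scalar; zero iff `output == target`.
#' @export
squared_error_loss <- function(output, target) {
  if (length(output) != length(target)) {
    stop("squared_error_loss(): output and target lengths differ",
         call. = FALSE)
  }
  if (!all(is.finite(output)) || !all(is.finite(target))) {
    stop("squared_error_loss(): inputs must be finite", call. = FALSE)
  }
  0.5 * sum((output - target)^2)
}

#' Bernoulli cross-entropy loss
#'
#' `-sum_l [ target_l log(output_l) + (1 - target_l) log(1 - output_l) ]`.
#' This is the objective whose exact gradient the update rules descend: with
#' logistic outputs its output-layer error signal is `a_out - target` with no
#' slope factor, which is precisely how the teaching signals here are defined
#' (see [compute_error_signals()]). [squared_error_loss()] is the
#' conventional reporting metric; its exact gradient would carry an extra
#' `a_out (1 - a_out)` factor at the output layer that the update rules do
#' not include.
#'
#' @param output Vector of outputs strictly inside `(0, 1)`.
#' @param target Vector of targets in `[0, 1]`, same length.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(output, target) {
  if (length(output) != length(target)) {
    stop("cross_entropy_loss(): output and target lengths differ",
         call. = FALSE)
  }
  if (any(output <= 0) || any(output >= 1)) {
    stop("cross_entropy_loss(): outputs must lie strictly in (0, 1)",
         call. = FALSE)
  }
  -sum(target * log(output) + (1 - target) * log(1 - output))
}

#' Backpropagated error signals
#'
#' Output-layer signal `delta_out = a_out - target`; hidden-layer signal
#' `delta_hidden_k = (sum_l delta_out_l * w_oh[l, k]) * a_hidden_k *
#' (1 - a_hidden_k)`.
#'
#' This is the standard delta convention for logistic outputs: the pair
#' (`delta_out`, `delta_hidden`) composed into outer products with the
#' upstream activations is the exact gradient of [cross_entropy_loss()]
#' (not of [squared_error_loss()], whose gradient would carry an additional
#' output-slope factor). All update rules in this package are built on these
#' signals.
#'
#' @param cache A `forward_cache` from [forward()].
#' @param target One-hot (or any numeric) target vector of length `n_output`.
#' @param params The `network_params` used to produce `cache`.
#' @return An object of class `error_signals` with fields `delta_out`
#'   (length `n_output`) and `delta_hidden` (length `n_hidden`).
#' @export
compute_error_signals <- function(cache, target, params) {
  stopifnot(inherits(cache, "forward_cache"),
            inherits(params, "network_params"))
  if (length(target) != params$n_output || !all(is.finite(target))) {
    stop("compute_error_signals(): target must be finite of length n_output",
         call. = FALSE)
  }
  delta_out <- cache$a_out - as.numeric(target)
  delta_hidden <- as.numeric(crossprod(params$w_oh, delta_out)) *
    logistic_slope(cache$a_hidden)
  structure(list(delta_out = delta_out, delta_hidden = delta_hidden),
            class = "error_signals")
}

#' Loss gradients for both weight matrices
#'
#' Outer products of the error signals with the upstream activations:
#' `g_oh[l, k] = delta_out_l * a_hidden_k` and `g_hi[k, j] = delta_hidden_k *
#' a_in_j` (the bias column receives `delta_hidden_k * 1`). Exact gradient of
#' [cross_entropy_loss()]; see [compute_error_signals()] for the convention.
#'
#' @param cache A `forward_cache`.
#' @param signals An `error_signals` object for the same trial.
#' @return An object of class `gradients` with matrices `g_hi`, `g_oh`
#'   shaped like the corresponding weights.
#' @export
full_gradient <- function(cache, signals) {
  stopifnot(inherits(cache, "forward_cache"), inherits(signals, "error_signals"))
  g_oh <- tcrossprod(signals$delta_out, cache$a_hidden)
  g_hi <- tcrossprod(signals$delta_hidden, cache$a_in)
  structure(list(g_hi = g_hi, g_oh = g_oh), class = "gradients")
}

#' Serialize network parameters to JSON
#'
#' Writes the two weight matrices and the layer sizes to a plain JSON file so
#' runs can be checkpointed and re-evaluated from the command line.
#'
#' @param params A `network_params` object.
#' @param path Output file path.
#' @export
save_network_json <- function(params, path) {
  stopifnot(inherits(params, "network_params"))
  obj <- list(
    n_input = params$n_input, n_hidden = params$n_hidden,
    n_output = params$n_output,
    w_hi = params$w_hi, w_oh = params$w_oh
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read network parameters back from JSON
#'
#' @param path File written by [save_network_json()].
#' @return A `network_params` object.
#' @export
load_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  network_params(as.matrix(obj$w_hi), as.matrix(obj$w_oh))
}
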