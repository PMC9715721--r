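test_that("sgn is the exact three-valued sign", {
  expect_identical(sgn(0), 0)
  expect_identical(sgn(3.7), 1)
  expect_identical(sgn(-0.001), -1)
  set.seed(1)
  x <- stats::rnorm(100)
  expect_equal(sgn(x), -sgn(-x))
  expect_true(all(sgn(x) %in% c(-1, 0, 1)))
  expect_error(sgn(NaN), "finite")
  expect_error(sgn(-Inf), "finite")
})

test_that("sample_mask has deterministic cardinality and uniform coverage", {
  expect_setequal(sample_mask(10, 1), 1:10)
  expect_identical(sample_mask(10, 0), integer(0))
  expect_error(sample_mask(10, 1.2), "\\[0, 1\\]")

  # cardinality = round-half-away-from-zero of q * n
  set.seed(2)
  for (q in c(0.04, 0.25, 0.5, 0.33)) {
    for (n in c(7, 10, 40)) {
      expect_length(sample_mask(n, q), min(max(floor(q * n + 0.5), 0), n))
    }
  }

  # frequency: each index selected with proportion q +/- 0.02 over 10,000 draws
  set.seed(3)
  counts <- integer(10)
  for (i in 1:10000) {
    idx <- sample_mask(10, 0.5)
    counts[idx] <- counts[idx] + 1L
    expect_length(idx, 5L)
  }
  expect_true(all(abs(counts / 10000 - 0.5) < 0.02))
})

test_that("masked gradient updates touch exactly the masked entries", {
  set.seed(4)
  p <- rand_params(3, 4, 2)
  cache <- forward(p, stats::runif(3))
  sig <- compute_error_signals(cache, c(1, 0), p)
  g <- full_gradient(cache, sig)
  eps <- 0.05

  empty <- structure(list(idx_hi = integer(0), idx_oh = integer(0)),
                     class = "update_mask")
  expect_identical(apply_masked_gradient_update(p, g, empty, eps), p)

  full <- structure(list(idx_hi = seq_along(p$w_hi),
                         idx_oh = seq_along(p$w_oh)),
                    class = "update_mask")
  upd <- apply_masked_gradient_update(p, g, full, eps)
  expect_identical(upd$w_hi, p$w_hi - eps * g$g_hi)
  expect_identical(upd$w_oh, p$w_oh - eps * g$g_oh)

  one <- structure(list(idx_hi = integer(0), idx_oh = 3L),
                   class = "update_mask")
  u1 <- apply_masked_gradient_update(p, g, one, eps)
  expect_identical(u1$w_hi, p$w_hi)
  diff <- u1$w_oh - p$w_oh
  expect_identical(which(diff != 0), 3L)
  expect_equal(diff[3], -eps * g$g_oh[3])
})

test_that("binary updates move each masked weight by exactly -eps, 0 or +eps", {
  set.seed(5)
  p <- rand_params(2, 2, 1)
  x <- c(0.7, 0)  # one zero input: its hidden-weight sign argument is 0
  cache <- forward(p, x)
  sig <- compute_error_signals(cache, 1, p)
  eps <- 0.01
  full <- structure(list(idx_hi = seq_along(p$w_hi),
                         idx_oh = seq_along(p$w_oh)),
                    class = "update_mask")
  upd <- apply_masked_binary_update(p, cache, sig, full, eps)
  d_hi <- upd$w_hi - p$w_hi
  d_oh <- upd$w_oh - p$w_oh
  expect_true(steps_one_bit(c(d_hi, d_oh), eps))
  # signs equal sgn of the exact gradient entries
  g <- full_gradient(cache, sig)
  expect_equal(d_hi, -eps * sgn(g$g_hi))
  expect_equal(d_oh, -eps * sgn(g$g_oh))
  # zero inputs produce exactly zero hidden-weight updates
  expect_true(all(d_hi[, 2] == 0))

  # zero residual: no change even under a full mask
  s0 <- compute_error_signals(cache, cache$a_out, p)
  expect_identical(apply_masked_binary_update(p, cache, s0, full, eps), p)
})

test_that("noise updates are +/-eps on the drawn set and zero-mean overall", {
  set.seed(6)
  p <- rand_params(2, 3, 2)
  eps <- 0.02

  nd0 <- noise_draw(p, 0)
  expect_identical(apply_noise_update(p, nd0, eps), p)

  nd1 <- noise_draw(p, 1)
  u1 <- apply_noise_update(p, nd1, eps)
  expect_true(steps_one_bit(u1$w_hi - p$w_hi, eps, fuzz = 1e-15))
  expect_true(all(u1$w_hi != p$w_hi))
  expect_true(steps_one_bit(u1$w_oh - p$w_oh, eps, fuzz = 1e-15))
  expect_true(all(u1$w_oh != p$w_oh))

  bad <- nd1; bad$eta_hi[1] <- 0.5
  expect_error(apply_noise_update(p, bad, eps), "eta")

  # Monte-Carlo: mean per-weight increment ~ 0 within 3 * eps * sqrt(np/N)
  np <- 0.5; N <- 10000
  acc <- matrix(0, nrow(p$w_hi), ncol(p$w_hi))
  for (i in seq_len(N)) {
    nd <- noise_draw(p, np)
    inc <- matrix(0, nrow(p$w_hi), ncol(p$w_hi))
    inc[nd$idx_hi] <- -eps * nd$eta_hi
    acc <- acc + inc
  }
  expect_true(all(abs(acc / N) < 3 * eps * sqrt(np / N)))
})

test_that("update_step dispatches correctly and degenerates as stated", {
  set.seed(7)
  p <- rand_params(3, 4, 2)
  cache <- forward(p, stats::runif(3))
  sig <- compute_error_signals(cache, c(0, 1), p)

  # q = 1 stochastic is bit-identical to full
  set.seed(11)
  a <- update_step(p, cache, sig, update_config("full", 0.1))
  set.seed(11)
  b <- update_step(p, cache, sig, update_config("stochastic", 0.1, q = 1))
  expect_identical(a$w_hi, b$w_hi)
  expect_identical(a$w_oh, b$w_oh)

  # binary_noisy with noise_p = 0 equals binary under the same stream
  set.seed(12)
  c1 <- update_step(p, cache, sig, update_config("binary", 0.1, q = 0.3))
  set.seed(12)
  c2 <- update_step(p, cache, sig,
                    update_config("binary_noisy", 0.1, q = 0.3, noise_p = 0))
  expect_identical(c1, c2)

  # fixed seed: identical update sequences
  set.seed(13)
  d1 <- update_step(p, cache, sig,
                    update_config("binary_noisy", 0.1, q = 0.5, noise_p = 0.5))
  set.seed(13)
  d2 <- update_step(p, cache, sig,
                    update_config("binary_noisy", 0.1, q = 0.5, noise_p = 0.5))
  expect_identical(d1, d2)

  expect_error(update_config("warp", 0.1), "arg")
})

test_that("stochastic masking is unbiased: mean update converges to q x full update", {
  set.seed(8)
  p <- rand_params(2, 3, 2)
  cache <- forward(p, stats::runif(2))
  sig <- compute_error_signals(cache, c(1, 0), p)
  g <- full_gradient(cache, sig)
  # q chosen so q * n is integral for both layers (9 and 6 weights): the
  # selection probability is then exactly q
  eps <- 1; q <- 1 / 3; N <- 10000

  acc_hi <- matrix(0, nrow(p$w_hi), ncol(p$w_hi))
  acc_oh <- matrix(0, nrow(p$w_oh), ncol(p$w_oh))
  for (i in seq_len(N)) {
    m <- update_mask(p, q)
    u <- apply_masked_gradient_update(p, g, m, eps)
    acc_hi <- acc_hi + (u$w_hi - p$w_hi)
    acc_oh <- acc_oh + (u$w_oh - p$w_oh)
  }
  # per-weight increment is -eps*g w.p. q; SE of the mean = |g| sqrt(q(1-q)/N);
  # family-wise 3-sigma band over the 15 simultaneous comparisons
  z <- fw_band(length(p$w_hi) + length(p$w_oh))
  expect_true(all(abs(acc_hi / N - (-eps * q * g$g_hi)) <=
                    z * abs(eps * g$g_hi) * sqrt(q * (1 - q) / N) + 1e-12))
  expect_true(all(abs(acc_oh / N - (-eps * q * g$g_oh)) <=
                    z * abs(eps * g$g_oh) * sqrt(q * (1 - q) / N) + 1e-12))
})
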