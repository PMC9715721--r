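# IDX fixtures are constructed programmatically with writeBin so the
# repository stays text-only.

write_idx_raw <- function(bytes) {
  path <- tempfile(fileext = ".idx")
  con <- file(path, "wb")
  writeBin(as.integer(bytes), con, size = 1L)
  close(con)
  path
}

test_that("read_idx decodes image and label fixtures", {
  # 1 x 2 x 2 image file: header 0,0,8,3 + dims + payload [0,128,255,64]
  img <- write_idx_raw(c(0, 0, 8, 3,
                         0, 0, 0, 1,  0, 0, 0, 2,  0, 0, 0, 2,
                         0, 128, 255, 64))
  a <- read_idx(img)
  expect_equal(dim(a), c(1, 2, 2))
  expect_equal(a[1, , ], matrix(c(0, 128, 255, 64), 2, 2, byrow = TRUE))

  lab <- write_idx_raw(c(0, 0, 8, 1, 0, 0, 0, 3, 7, 0, 9))
  expect_equal(read_idx(lab), c(7, 0, 9))
})

test_that("read_idx reports malformed files with offsets", {
  trunc <- write_idx_raw(c(0, 0, 8, 1, 0, 0, 0, 5, 7, 0))  # declares 5, has 2
  expect_error(read_idx(trunc), "truncated payload")
  badmagic <- write_idx_raw(c(1, 0, 8, 1, 0, 0, 0, 1, 7))
  expect_error(read_idx(badmagic), "magic")
  baddtype <- write_idx_raw(c(0, 0, 13, 1, 0, 0, 0, 1, 7))
  expect_error(read_idx(baddtype), "dtype")
  expect_error(read_idx(tempfile()), "not found")
})

test_that("write_idx / read_idx round-trip exactly", {
  set.seed(1)
  x <- array(sample(0:255, 3 * 4 * 5, replace = TRUE), dim = c(3, 4, 5))
  path <- tempfile(fileext = ".idx")
  write_idx(x, path)
  expect_identical(read_idx(path), x)
  v <- sample(0:255, 17, replace = TRUE)
  write_idx(v, path)
  expect_identical(read_idx(path), v)
})

test_that("load_digit_dataset scales pixels, one-hot encodes, and validates counts", {
  imgs <- array(0L, dim = c(2, 2, 2))
  imgs[1, , ] <- matrix(c(255L, 0L, 128L, 64L), 2, 2, byrow = TRUE)
  imgs[2, , ] <- matrix(c(0L, 0L, 0L, 255L), 2, 2, byrow = TRUE)
  ip <- tempfile(fileext = ".idx"); lp <- tempfile(fileext = ".idx")
  write_idx(imgs, ip)
  write_idx(c(3L, 9L), lp)
  ds <- load_digit_dataset(ip, lp)
  expect_equal(n_examples(ds), 2L)
  expect_equal(ds$n_classes, 10L)
  # row-major flattening and /255 scaling
  expect_equal(ds$inputs[1, ], c(1, 0, 128 / 255, 64 / 255))
  expect_equal(ds$inputs[2, ], c(0, 0, 0, 1))
  expect_equal(ds$targets[1, ], one_hot(3, 10))
  expect_equal(ds$targets[2, ], one_hot(9, 10))

  write_idx(c(3L, 9L, 1L), lp)
  expect_error(load_digit_dataset(ip, lp), "2 images but 3 labels")
})

test_that("one_hot encodes labels and rejects out-of-range values", {
  expect_equal(one_hot(0, 2), c(1, 0))
  expect_equal(one_hot(9, 10), c(rep(0, 9), 1))
  expect_equal(sum(one_hot(4, 7)), 1)
  expect_error(one_hot(2, 2), "label")
  expect_error(one_hot(-1, 2), "label")
})

test_that("blob generator is seeded, bounded, and classifiable by centroids", {
  spec <- synthetic_task_spec("blobs", n_classes = 3, n_examples = 300,
                              n_features = 16, noise_sd = 0, seed = 5)
  d0 <- generate_blobs(spec)
  # zero noise: all points of a class identical
  for (k in 0:2) {
    rows <- d0$inputs[dataset_labels(d0) == k, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(col) all(col == col[1]))))
  }
  # same seed, same dataset
  expect_identical(generate_blobs(spec)$inputs, d0$inputs)

  spec2 <- synthetic_task_spec("blobs", n_classes = 3, n_examples = 600,
                               n_features = 16, noise_sd = 0.05, seed = 6)
  d <- generate_blobs(spec2)
  expect_true(all(d$inputs >= 0 & d$inputs <= 1))
  expect_true(all(rowSums(d$targets) == 1))
  # nearest-centroid oracle on the known centers
  ctr <- attr(d, "centers")
  d2 <- sapply(seq_len(3), function(k) {
    rowSums(sweep(d$inputs, 2, ctr[k, ])^2)
  })
  acc <- mean(max.col(-d2) - 1L == dataset_labels(d))
  expect_gte(acc, 0.99)
})

test_that("center_sep_sigmas pins the separation-to-noise ratio", {
  spec <- synthetic_task_spec("blobs", n_classes = 3, n_examples = 30,
                              n_features = 16, center_sep_sigmas = 4, seed = 7)
  d <- generate_blobs(spec)
  ctr_raw <- attr(d, "centers") * 2 - 1   # undo the (x+1)/2 map
  expect_equal(min(stats::dist(ctr_raw)) / attr(d, "noise_sd"), 4,
               tolerance = 1e-10)
})

test_that("glyph generator produces seeded, noisy, classifiable digit images", {
  clean <- synthetic_task_spec("glyphs", n_classes = 10, n_examples = 40,
                               glyph_size = 8, noise_sd = 0, seed = 8,
                               translate = FALSE)
  d0 <- generate_glyphs(clean)
  # noise 0, no translation: exactly one distinct input per class
  for (k in 0:9) {
    rows <- unique(d0$inputs[dataset_labels(d0) == k, , drop = FALSE])
    expect_equal(nrow(rows), 1L)
  }
  # templates are pairwise distinct
  tmat <- attr(d0, "templates")
  expect_equal(nrow(unique(tmat)), 10L)

  spec <- synthetic_task_spec("glyphs", n_classes = 10, n_examples = 500,
                              glyph_size = 8, noise_sd = 0.1, seed = 9)
  d <- generate_glyphs(spec)
  expect_identical(generate_glyphs(spec)$inputs, d$inputs)
  expect_true(all(d$inputs >= 0 & d$inputs <= 1))

  # template nearest-neighbor oracle at noise_sd = 0.1: the generator shifts
  # by up to one pixel, so the oracle matches against all 9 shifted variants
  # of each template (min distance over shifts)
  shift_mat <- function(m, dx, dy) {
    n <- nrow(m); out <- matrix(0, n, n)
    sr <- seq_len(n) - dy; sc <- seq_len(n) - dx
    okr <- sr >= 1 & sr <= n; okc <- sc >= 1 & sc <= n
    out[okr, okc] <- m[sr[okr], sc[okc]]
    out
  }
  templates <- glyph_templates(8)
  d2 <- sapply(1:10, function(k) {
    variants <- sapply(expand.grid(dx = -1:1, dy = -1:1) |> asplit(1),
                       function(sh) as.numeric(t(shift_mat(templates[[k]],
                                                           sh[1], sh[2]))))
    apply(sapply(seq_len(ncol(variants)), function(v) {
      rowSums(sweep(d$inputs, 2, variants[, v])^2)
    }), 1, min)
  })
  acc <- mean(max.col(-d2) - 1L == dataset_labels(d))
  expect_gte(acc, 0.95)

  expect_error(synthetic_task_spec("glyphs", n_classes = 10, n_examples = 40,
                                   glyph_size = 4, seed = 1),
               "glyph_size")
  # resized templates keep their shape
  t12 <- glyph_templates(12)
  expect_length(t12, 10L)
  expect_equal(dim(t12[[1]]), c(12L, 12L))
  expect_true(all(vapply(t12, function(m) all(m %in% 0:1), logical(1))))
})

test_that("train/validation split is disjoint, sized, and seeded", {
  spec <- synthetic_task_spec("blobs", n_classes = 3, n_examples = 100,
                              n_features = 4, noise_sd = 0.1, seed = 10)
  d <- generate_blobs(spec)
  sp <- split_train_validation(d, 20, seed = 3)
  expect_equal(n_examples(sp$train), 80L)
  expect_equal(n_examples(sp$validation), 20L)
  both <- rbind(sp$train$inputs, sp$validation$inputs)
  expect_equal(nrow(both), 100L)
  expect_equal(nrow(unique(rbind(both, d$inputs))), 100L)  # same multiset
  sp2 <- split_train_validation(d, 20, seed = 3)
  expect_identical(sp$validation$inputs, sp2$validation$inputs)
  expect_error(split_train_validation(d, 100), "n_validation")
  expect_error(split_train_validation(d, 0), "n_validation")
})

test_that("datasets export to CSV with features then label", {
  spec <- synthetic_task_spec("blobs", n_classes = 2, n_examples = 10,
                              n_features = 3, noise_sd = 0.1, seed = 11)
  d <- generate_blobs(spec)
  path <- tempfile(fileext = ".csv")
  dataset_to_csv(d, path)
  df <- utils::read.csv(path)
  expect_equal(names(df), c("x1", "x2", "x3", "label"))
  expect_equal(df$label, dataset_labels(d))
  expect_equal(as.matrix(df[, 1:3]), d$inputs, ignore_attr = TRUE)
})
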