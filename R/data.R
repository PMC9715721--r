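# Labeled datasets: IDX readers/writers, one-hot encoding, and seeded
# synthetic generators (Gaussian class blobs, low-resolution digit glyphs).

#' Construct a labeled classification dataset
#'
#' @param inputs Numeric matrix, one example per row, all values in `[0, 1]`.
#' @param targets One-hot numeric matrix, one row per example, `n_classes`
#'   columns, each row a single 1 and zeros elsewhere.
#' @param n_classes Number of classes (defaults to `ncol(targets)`).
#' @return A `labeled_dataset` with fields `inputs`, `targets`, `n_classes`.
#' @export
labeled_dataset <- function(inputs, targets, n_classes = ncol(targets)) {
  inputs <- as.matrix(inputs)
  targets <- as.matrix(targets)
  if (nrow(inputs) != nrow(targets)) {
    stop("labeled_dataset(): inputs and targets row counts differ",
         call. = FALSE)
  }
  if (any(inputs < 0) || any(inputs > 1) || anyNA(inputs)) {
    stop("labeled_dataset(): input values must lie in [0, 1]", call. = FALSE)
  }
  if (ncol(targets) != n_classes ||
      !all(targets %in% c(0, 1)) || !all(rowSums(targets) == 1)) {
    stop("labeled_dataset(): targets must be one-hot over n_classes",
         call. = FALSE)
  }
  structure(list(inputs = inputs, targets = targets,
                 n_classes = as.integer(n_classes)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d examples, %d features, %d classes>\n",
              nrow(x$inputs), ncol(x$inputs), x$n_classes))
  invisible(x)
}

#' Number of examples in a dataset
#' @param data A `labeled_dataset`.
#' @return Integer count.
#' @export
n_examples <- function(data) nrow(data$inputs)

#' Integer class labels (0-based) of a dataset
#' @param data A `labeled_dataset`.
#' @return Integer vector of 0-based labels.
#' @export
dataset_labels <- function(data) max.col(data$targets, ties.method = "first") - 1L

#' One-hot encode a class label
#'
#' @param label 0-based integer label, `0 <= label < n_classes`.
#' @param n_classes Number of classes.
#' @return Numeric vector of length `n_classes` with a single 1 at position
#'   `label + 1`.
#' @export
one_hot <- function(label, n_classes) {
  if (length(label) != 1L || is.na(label) || label < 0 || label >= n_classes ||
      label != floor(label)) {
    stop("one_hot(): label must be an integer in [0, n_classes)",
         call. = FALSE)
  }
  v <- numeric(n_classes)
  v[label + 1L] <- 1
  v
}

one_hot_matrix <- function(labels, n_classes) {
  m <- matrix(0, nrow = length(labels), ncol = n_classes)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

# ---------------------------------------------------------------------------
# IDX binary container (the MNIST format): big-endian, header of two zero
# bytes, a dtype byte (0x08 = unsigned byte), a rank byte, then rank int32
# dimension sizes, then the payload in row-major order.

#' Read an IDX-format file
#'
#' Supports the unsigned-byte payloads used by MNIST-style digit files
#' (magic `0x00000803` for images, `0x00000801` for labels, and any other
#' rank with dtype `0x08`).
#'
#' @param path Path to an IDX file.
#' @return For rank 1, an integer vector; otherwise an integer array with the
#'   header's dimensions, indexed so that `a[i, r, c]` is row `r`, column `c`
#'   of item `i` (row-major payload order).
#' @export
read_idx <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_idx(): file not found: %s", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (length(magic) < 4L || magic[1] != 0L || magic[2] != 0L) {
    stop("read_idx(): bad magic at offset 0 (first two bytes must be zero)",
         call. = FALSE)
  }
  if (magic[3] != 8L) {
    stop(sprintf(
      "read_idx(): unsupported dtype byte 0x%02x at offset 2 (only ubyte 0x08)",
      magic[3]), call. = FALSE)
  }
  rank <- magic[4]
  if (rank < 1L) stop("read_idx(): rank byte at offset 3 must be >= 1",
                      call. = FALSE)
  dims <- readBin(con, "integer", n = rank, size = 4L, endian = "big")
  if (length(dims) < rank || any(dims < 0)) {
    stop("read_idx(): truncated or invalid dimension header at offset 4",
         call. = FALSE)
  }
  n <- prod(dims)
  if (n > .Machine$integer.max) {
    stop("read_idx(): dimension overflow in header", call. = FALSE)
  }
  data <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
  if (length(data) != n) {
    stop(sprintf(
      "read_idx(): truncated payload at offset %d (expected %d bytes, got %d)",
      4L + 4L * rank + length(data), n, length(data)), call. = FALSE)
  }
  if (rank == 1L) return(data)
  # payload is row-major (last index fastest); R arrays are column-major
  aperm(array(data, dim = rev(dims)), rev(seq_len(rank)))
}

#' Write an IDX-format file
#'
#' Inverse of [read_idx()]: writes an integer vector or array with values in
#' 0..255 as an unsigned-byte IDX file with a big-endian header.
#'
#' @param x Integer vector or array, values in 0..255.
#' @param path Output file path.
#' @export
write_idx <- function(x, path) {
  if (anyNA(x) || any(x < 0) || any(x > 255)) {
    stop("write_idx(): values must be bytes in 0..255", call. = FALSE)
  }
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  rank <- length(dims)
  payload <- if (rank == 1L) as.integer(x) else {
    as.integer(aperm(x, rev(seq_len(rank))))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(0L, 0L, 8L, rank)), con, size = 1L)
  writeBin(as.integer(dims), con, size = 4L, endian = "big")
  writeBin(payload, con, size = 1L)
  invisible(path)
}

#' Load an MNIST-style digit dataset from IDX files
#'
#' Pixels are scaled into `[0, 1]` by dividing by 255; images are flattened
#' row-major; labels are one-hot encoded over 10 classes.
#'
#' @param images_path Path to an idx3-ubyte image file.
#' @param labels_path Path to an idx1-ubyte label file.
#' @param n_classes Number of classes for the one-hot encoding (default 10).
#' @return A `labeled_dataset`.
#' @export
load_digit_dataset <- function(images_path, labels_path, n_classes = 10L) {
  imgs <- read_idx(images_path)
  labels <- read_idx(labels_path)
  if (length(dim(imgs)) != 3L) {
    stop("load_digit_dataset(): image file must have rank 3", call. = FALSE)
  }
  if (!is.null(dim(labels))) {
    stop("load_digit_dataset(): label file must have rank 1", call. = FALSE)
  }
  n <- dim(imgs)[1]
  if (length(labels) != n) {
    stop(sprintf(
      "load_digit_dataset(): %d images but %d labels", n, length(labels)),
      call. = FALSE)
  }
  if (any(labels >= n_classes)) {
    stop("load_digit_dataset(): label value exceeds n_classes - 1",
         call. = FALSE)
  }
  r <- dim(imgs)[2]; cc <- dim(imgs)[3]
  # row-major flatten of each r x cc image
  inputs <- matrix(aperm(imgs, c(3L, 2L, 1L)), nrow = n, byrow = TRUE) / 255
  labeled_dataset(inputs, one_hot_matrix(labels, n_classes), n_classes)
}

# ---------------------------------------------------------------------------
# Synthetic tasks

#' Specify a synthetic classification task
#'
#' @param kind `"blobs"` (Gaussian class blobs) or `"glyphs"` (noisy
#'   low-resolution digit images).
#' @param n_classes Number of classes (glyphs support up to 10).
#' @param n_examples Total number of examples, balanced across classes.
#' @param n_features Feature dimension (blobs only).
#' @param glyph_size Image side length in pixels (glyphs only; >= 5).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @param translate Glyphs only: apply a uniform random shift of -1, 0 or +1
#'   pixel in each direction (default `TRUE`).
#' @param center_sep_sigmas Blobs only: if non-`NULL`, override `noise_sd` so
#'   that the minimum pairwise distance between class centers equals this
#'   many noise standard deviations (e.g. 4 for well-separated classes).
#' @return A `synthetic_task_spec`.
#' @export
synthetic_task_spec <- function(kind = c("blobs", "glyphs"), n_classes,
                                n_examples, n_features = NULL,
                                glyph_size = 8L, noise_sd = 0.1, seed = 1L,
                                translate = TRUE, center_sep_sigmas = NULL) {
  kind <- match.arg(kind)
  if (n_classes < 2 || n_examples < n_classes) {
    stop("synthetic_task_spec(): need n_classes >= 2 and n_examples >= n_classes",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("synthetic_task_spec(): noise_sd must be >= 0",
                         call. = FALSE)
  if (kind == "blobs" && (is.null(n_features) || n_features < 1)) {
    stop("synthetic_task_spec(): blobs require n_features >= 1", call. = FALSE)
  }
  if (kind == "glyphs" && glyph_size < 5) {
    stop("synthetic_task_spec(): glyph_size must be >= 5 (templates undefined below that)",
         call. = FALSE)
  }
  if (kind == "glyphs" && n_classes > 10) {
    stop("synthetic_task_spec(): glyphs support at most 10 classes",
         call. = FALSE)
  }
  structure(list(kind = kind, n_classes = as.integer(n_classes),
                 n_examples = as.integer(n_examples),
                 n_features = if (is.null(n_features)) NULL else as.integer(n_features),
                 glyph_size = as.integer(glyph_size), noise_sd = noise_sd,
                 seed = as.integer(seed), translate = isTRUE(translate),
                 center_sep_sigmas = center_sep_sigmas),
            class = "synthetic_task_spec")
}

#' Generate a Gaussian class-blob dataset
#'
#' Class centers are drawn uniformly on the unit sphere in `n_features`
#' dimensions; each example is its class center plus isotropic Gaussian noise
#' of standard deviation `noise_sd`. Coordinates are mapped onto `[0, 1]` by
#' the fixed affine map `(x + 1) / 2` and clipped, which preserves the center
#' separation measured in noise standard deviations (up to the rare clipped
#' tails) and does not depend on the realised sample. Classes are balanced
#' (labels cycle 0, 1, ..., n_classes - 1).
#'
#' @param spec A `synthetic_task_spec` with `kind = "blobs"`.
#' @return A `labeled_dataset`; attribute `"centers"` holds the class centers
#'   on the `[0, 1]` scale and attribute `"noise_sd"` the (possibly
#'   `center_sep_sigmas`-derived) raw noise level.
#' @export
generate_blobs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_task_spec"), spec$kind == "blobs")
  set.seed(spec$seed)
  k <- spec$n_classes; d <- spec$n_features; n <- spec$n_examples
  centers <- matrix(stats::rnorm(k * d), nrow = k)
  centers <- centers / sqrt(rowSums(centers^2))
  sd <- spec$noise_sd
  if (!is.null(spec$center_sep_sigmas)) {
    min_dist <- min(stats::dist(centers))
    sd <- min_dist / spec$center_sep_sigmas
  }
  labels <- rep(seq_len(k) - 1L, length.out = n)
  pts <- centers[labels + 1L, , drop = FALSE]
  if (sd > 0) pts <- pts + matrix(stats::rnorm(n * d, sd = sd), nrow = n)
  inputs <- pmin(pmax((pts + 1) / 2, 0), 1)
  out <- labeled_dataset(inputs, one_hot_matrix(labels, k), k)
  attr(out, "centers") <- (centers + 1) / 2
  attr(out, "noise_sd") <- sd
  out
}

# 8x8 digit templates ('#' = ink). Repository-owned bitmaps, not derived from
# any external dataset.
.GLYPH_ROWS <- list(
  c("..####..", ".#....#.", ".#....#.", ".#....#.",
    ".#....#.", ".#....#.", ".#....#.", "..####.."),
  c("...##...", "..###...", "...##...", "...##...",
    "...##...", "...##...", "...##...", "..####.."),
  c("..####..", ".#....#.", "......#.", ".....#..",
    "....#...", "...#....", "..#.....", ".######."),
  c("..####..", ".#....#.", "......#.", "...###..",
    "......#.", "......#.", ".#....#.", "..####.."),
  c("....##..", "...#.#..", "..#..#..", ".#...#..",
    ".######.", ".....#..", ".....#..", ".....#.."),
  c(".######.", ".#......", ".#......", ".#####..",
    "......#.", "......#.", ".#....#.", "..####.."),
  c("..####..", ".#......", ".#......", ".#####..",
    ".#....#.", ".#....#.", ".#....#.", "..####.."),
  c(".######.", "......#.", ".....#..", "....#...",
    "...#....", "...#....", "...#....", "...#...."),
  c("..####..", ".#....#.", ".#....#.", "..####..",
    ".#....#.", ".#....#.", ".#....#.", "..####.."),
  c("..####..", ".#....#.", ".#....#.", "..#####.",
    "......#.", "......#.", "......#.", "..####..")
)

#' Digit glyph templates
#'
#' Binary `size x size` bitmaps of the digits 0-9, produced by
#' nearest-neighbor resampling of fixed 8x8 masters.
#'
#' @param size Side length in pixels (>= 5).
#' @return List of 10 `size x size` 0/1 matrices, in digit order 0-9.
#' @export
glyph_templates <- function(size = 8L) {
  if (size < 5) stop("glyph_templates(): size must be >= 5", call. = FALSE)
  lapply(.GLYPH_ROWS, function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) {
      as.integer(strsplit(r, "")[[1]] == "#")
    }))
    if (size == 8L) return(m)
    idx <- pmin(pmax(ceiling(seq_len(size) * 8 / size), 1L), 8L)
    m[idx, idx, drop = FALSE]
  })
}

shift_glyph <- function(m, dx, dy) {
  # shift right by dx and down by dy, zero fill
  n <- nrow(m)
  out <- matrix(0L, n, n)
  src_r <- seq_len(n) - dy; src_c <- seq_len(n) - dx
  ok_r <- src_r >= 1 & src_r <= n; ok_c <- src_c >= 1 & src_c <= n
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Generate a noisy digit-glyph dataset
#'
#' A miniature stand-in for a handwritten-digit task: each example is a fixed
#' per-class `glyph_size x glyph_size` bitmap, optionally shifted by a random
#' single pixel in each direction (uniform on -1/0/+1, zero fill), plus
#' per-pixel Gaussian noise of standard deviation `noise_sd`, clipped to
#' `[0, 1]`. Images are flattened row-major. Classes are balanced (labels
#' cycle 0 .. n_classes - 1).
#'
#' @param spec A `synthetic_task_spec` with `kind = "glyphs"`.
#' @return A `labeled_dataset`; attribute `"templates"` holds the flattened
#'   class templates (one row per class).
#' @export
generate_glyphs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_task_spec"), spec$kind == "glyphs")
  set.seed(spec$seed)
  k <- spec$n_classes; n <- spec$n_examples; s <- spec$glyph_size
  templates <- glyph_templates(s)[seq_len(k)]
  tmat <- do.call(rbind, lapply(templates, function(m) as.numeric(t(m))))
  labels <- rep(seq_len(k) - 1L, length.out = n)
  inputs <- matrix(0, nrow = n, ncol = s * s)
  for (i in seq_len(n)) {
    m <- templates[[labels[i] + 1L]]
    if (spec$translate) {
      sh <- sample(c(-1L, 0L, 1L), 2L, replace = TRUE)
      m <- shift_glyph(m, sh[1], sh[2])
    }
    v <- as.numeric(t(m))
    if (spec$noise_sd > 0) v <- v + stats::rnorm(s * s, sd = spec$noise_sd)
    inputs[i, ] <- pmin(pmax(v, 0), 1)
  }
  out <- labeled_dataset(inputs, one_hot_matrix(labels, k), k)
  attr(out, "templates") <- tmat
  out
}

#' Generate a synthetic dataset from its spec
#'
#' Dispatcher over [generate_blobs()] and [generate_glyphs()].
#'
#' @param spec A `synthetic_task_spec`.
#' @return A `labeled_dataset`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_task_spec"))
  switch(spec$kind, blobs = generate_blobs(spec), glyphs = generate_glyphs(spec))
}

#' Subset a labeled dataset by example index
#' @param data A `labeled_dataset`.
#' @param idx Integer vector of row indices.
#' @return A `labeled_dataset` with the selected examples.
#' @export
dataset_subset <- function(data, idx) {
  labeled_dataset(data$inputs[idx, , drop = FALSE],
                  data$targets[idx, , drop = FALSE], data$n_classes)
}

#' Randomly split a dataset into training and validation parts
#'
#' @param data A `labeled_dataset` with `m` examples.
#' @param n_validation Number of examples held out, `0 < n_validation < m`.
#' @param seed Optional integer; if supplied, seeds the split.
#' @return List with disjoint `train` (`m - n_validation` examples) and
#'   `validation` (`n_validation` examples) datasets.
#' @export
split_train_validation <- function(data, n_validation, seed = NULL) {
  m <- n_examples(data)
  if (n_validation <= 0 || n_validation >= m) {
    stop("split_train_validation(): need 0 < n_validation < number of examples",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  val_idx <- sample.int(m, n_validation)
  list(train = dataset_subset(data, setdiff(seq_len(m), val_idx)),
       validation = dataset_subset(data, val_idx))
}

#' Export a dataset to CSV
#'
#' One row per example: feature columns `x1, x2, ...` then an integer
#' `label` column (0-based).
#'
#' @param data A `labeled_dataset`.
#' @param path Output CSV path.
#' @export
dataset_to_csv <- function(data, path) {
  df <- as.data.frame(data$inputs)
  names(df) <- paste0("x", seq_len(ncol(df)))
  df$label <- dataset_labels(data)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
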