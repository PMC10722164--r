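#' Specify a synthetic stimulus set
#'
#' Describes a balanced, procedurally generated image classification dataset
#' used in place of a natural-image benchmark. Each class is a distinct
#' procedural pattern family (shape identity crossed with grating orientation,
#' spatial frequency, and a color profile); individual samples vary by random
#' phase, position jitter, and additive Gaussian pixel noise. Structure mirrors
#' the common vision benchmarks: balanced classes, a fixed disjoint train/test
#' split, and pixel values bounded in `[0, 1]`.
#'
#' @param n_classes number of object classes (>= 2).
#' @param image_size image side length in pixels.
#' @param n_channels number of color channels.
#' @param samples_per_class_train training images generated per class.
#' @param samples_per_class_test test images generated per class.
#' @param noise_sd standard deviation of additive pixel noise, in intensity
#'   units on the `[0, 1]` scale; images are clipped back to `[0, 1]`.
#' @param seed integer seed; identical seeds give bitwise-identical datasets.
#' @return an object of class `stimulus_spec`.
#' @seealso [generate_dataset()]
#' @export
stimulus_spec <- function(n_classes = 10, image_size = 32, n_channels = 3,
                          samples_per_class_train = 200,
                          samples_per_class_test = 50,
                          noise_sd = 0.05, seed = 1L) {
  stop_if_not_count(n_classes, "n_classes", min = 2)
  stop_if_not_count(image_size, "image_size", min = 4)
  stop_if_not_count(n_channels, "n_channels", min = 1)
  stop_if_not_count(samples_per_class_train, "samples_per_class_train", min = 1)
  stop_if_not_count(samples_per_class_test, "samples_per_class_test", min = 1)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be a non-negative number", call. = FALSE)
  structure(list(
    n_classes = as.integer(n_classes), image_size = as.integer(image_size),
    n_channels = as.integer(n_channels),
    samples_per_class_train = as.integer(samples_per_class_train),
    samples_per_class_test = as.integer(samples_per_class_test),
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "stimulus_spec")
}

# Deterministic per-class pattern parameters: shape family, grating
# orientation/frequency, and channel gains. Classes are distinct by
# construction so the task is learnable well above chance.
class_params <- function(k, n_classes, n_channels) {
  shapes <- c("disk", "square", "cross", "ring")
  freqs <- c(2, 3, 4, 5, 6)
  # channel gain palette: rotate a bright/dark pattern over channels
  gains <- 0.45 + 0.5 * (0.5 + 0.5 * cos(2 * pi * ((k - 1) / n_classes +
                                                     (seq_len(n_channels) - 1) / n_channels)))
  list(
    shape = shapes[((k - 1) %% length(shapes)) + 1],
    theta = pi * (k - 1) / n_classes,
    freq = freqs[((k - 1) %/% length(shapes)) %% length(freqs) + 1],
    gains = gains
  )
}

shape_mask <- function(shape, S, cx, cy) {
  u <- (seq_len(S) - 0.5) / S
  X <- matrix(u, S, S)
  Y <- t(X)
  dx <- X - cx
  dy <- Y - cy
  r <- sqrt(dx^2 + dy^2)
  switch(shape,
    disk   = (r < 0.28) * 1,
    square = (abs(dx) < 0.24 & abs(dy) < 0.24) * 1,
    cross  = ((abs(dx) < 0.09) | (abs(dy) < 0.09)) * 1,
    ring   = (r > 0.16 & r < 0.3) * 1,
    stop("unknown shape")
  )
}

render_stimulus <- function(p, S, C, phase, cx, cy, noise_sd) {
  u <- (seq_len(S) - 0.5) / S
  X <- matrix(u, S, S)
  Y <- t(X)
  grating <- 0.5 + 0.5 * sin(2 * pi * p$freq * (X * cos(p$theta) + Y * sin(p$theta)) + phase)
  base <- 0.55 * grating + 0.45 * shape_mask(p$shape, S, cx, cy)
  img <- array(0, dim = c(S, S, C))
  for (ch in seq_len(C)) {
    layer <- base * p$gains[ch]
    if (noise_sd > 0) layer <- layer + rnorm(S * S, sd = noise_sd)
    img[, , ch] <- clip01(layer)
  }
  img
}

generate_split <- function(spec, per_class, seed) {
  S <- spec$image_size; C <- spec$n_channels; K <- spec$n_classes
  n <- per_class * K
  x <- array(0, dim = c(S, S, C, n))
  y <- integer(n)
  withr::with_seed(seed, {
    i <- 0L
    for (k in seq_len(K)) {
      p <- class_params(k, K, C)
      for (s in seq_len(per_class)) {
        i <- i + 1L
        phase <- runif(1, 0, 2 * pi)
        cx <- 0.5 + runif(1, -0.08, 0.08)
        cy <- 0.5 + runif(1, -0.08, 0.08)
        x[, , , i] <- render_stimulus(p, S, C, phase, cx, cy, spec$noise_sd)
        y[i] <- k
      }
    }
  })
  # permute so mini-batches mix classes even without shuffling
  perm <- withr::with_seed(derive_seed(seed, 91L), sample.int(n))
  list(x = x[, , , perm, drop = FALSE], y = y[perm])
}

#' Generate a synthetic labeled image dataset
#'
#' Produces balanced train and test splits of procedural stimuli according to
#' a [stimulus_spec()]. The two splits are disjoint by construction (drawn
#' from independent seeded streams) and the whole dataset is bitwise
#' reproducible from `spec$seed`.
#'
#' @param spec a [stimulus_spec()].
#' @return an object of class `stimulus_dataset`: a list with elements
#'   `train` and `test` (each `list(x, y)` where `x` is an
#'   `image_size x image_size x n_channels x n` array and `y` integer labels
#'   in `1..n_classes`), plus the `spec` and `class_names`.
#' @examples
#' d <- generate_dataset(stimulus_spec(n_classes = 3, image_size = 8,
#'   samples_per_class_train = 4, samples_per_class_test = 2, seed = 7))
#' dim(d$train$x)
#' table(d$test$y)
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "stimulus_spec")) spec <- do.call(stimulus_spec, spec)
  train <- generate_split(spec, spec$samples_per_class_train, derive_seed(spec$seed, 1L))
  test <- generate_split(spec, spec$samples_per_class_test, derive_seed(spec$seed, 2L))
  structure(list(train = train, test = test, spec = spec,
                 class_names = paste0("class", seq_len(spec$n_classes))),
            class = "stimulus_dataset")
}

#' @export
print.stimulus_dataset <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<stimulus_dataset> %d classes, %dx%dx%d, train %d / test %d images\n",
              s$n_classes, s$image_size, s$image_size, s$n_channels,
              length(x$train$y), length(x$test$y)))
  invisible(x)
}

#' Write / read a stimulus dataset as PNG files plus a CSV manifest
#'
#' The on-disk layout is one PNG per image under `dir/images/` and a
#' `manifest.csv` with columns `filename,label,split`. Pixels are quantized to
#' 8 bits on write, so a round trip reproduces images to within 1/255.
#'
#' @param dataset a `stimulus_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns a
#'   `stimulus_dataset` (with the original spec lost, a minimal spec is
#'   reconstructed from the images).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "stimulus_dataset"))
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (split in c("train", "test")) {
    d <- dataset[[split]]
    n <- length(d$y)
    for (i in seq_len(n)) {
      fn <- sprintf("%s_%05d_c%02d.png", split, i, d$y[i])
      img <- d$x[, , , i]
      if (length(dim(img)) == 2) dim(img) <- c(dim(img), 1)
      png::writePNG(img, file.path(img_dir, fn))
      rows[[length(rows) + 1]] <- data.frame(filename = fn, label = d$y[i],
                                             split = split)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  read_split <- function(split) {
    m <- manifest[manifest$split == split, , drop = FALSE]
    imgs <- lapply(m$filename, function(fn) {
      a <- png::readPNG(file.path(dir, "images", fn))
      if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1)
      a
    })
    d <- dim(imgs[[1]])
    x <- array(0, dim = c(d, nrow(m)))
    for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]
    list(x = x, y = as.integer(m$label))
  }
  train <- read_split("train")
  test <- read_split("test")
  d <- dim(train$x)
  spec <- stimulus_spec(
    n_classes = length(unique(c(train$y, test$y))), image_size = d[1],
    n_channels = d[3],
    samples_per_class_train = max(table(train$y)),
    samples_per_class_test = max(table(test$y))
  )
  structure(list(train = train, test = test, spec = spec,
                 class_names = paste0("class", seq_len(spec$n_classes))),
            class = "stimulus_dataset")
}

#' Generate synthetic neural recordings from model activations
#'
#' Builds a stimulus-by-neuron response matrix as a fixed random linear map of
#' an activation matrix plus Gaussian noise, emulating the structure of a
#' neural recording benchmark (many neurons, each driven by an unknown linear
#' combination of underlying features). With `noise_sd = 0` every neuron is an
#' exact linear combination of activation features, so a linear predictivity
#' readout can recover it perfectly.
#'
#' @param activations an [extract_activations()] result or a plain
#'   stimuli-by-features matrix.
#' @param n_neurons number of simulated neurons (>= 1).
#' @param noise_sd standard deviation of additive response noise, in units of
#'   the (unit-variance-scaled) linear drive.
#' @param seed integer seed; the linear map and noise are deterministic given
#'   the seed.
#' @param region_label free-text label for the simulated region.
#' @return an object of class `recordings_matrix`: list with `values`
#'   (stimuli x neurons), `region_label`, and `seed`.
#' @export
generate_recordings <- function(activations, n_neurons, noise_sd = 0.1,
                                seed = 1L, region_label = "synthetic") {
  A <- activation_values(activations)
  if (nrow(A) < 1 || ncol(A) < 1) stop("'activations' must be non-empty", call. = FALSE)
  stop_if_not_count(n_neurons, "n_neurons", min = 1)
  vals <- withr::with_seed(seed, {
    M <- matrix(rnorm(ncol(A) * n_neurons, sd = 1 / sqrt(ncol(A))), ncol(A), n_neurons)
    R <- A %*% M
    # scale columns to roughly unit variance so noise_sd is interpretable
    cs <- apply(R, 2, sd)
    cs[cs == 0] <- 1
    R <- sweep(R, 2, cs, "/")
    if (noise_sd > 0) R <- R + matrix(rnorm(length(R), sd = noise_sd), nrow(R))
    R
  })
  colnames(vals) <- sprintf("n%04d", seq_len(n_neurons))
  structure(list(values = vals, region_label = region_label, seed = as.integer(seed)),
            class = "recordings_matrix")
}

#' @export
print.recordings_matrix <- function(x, ...) {
  cat(sprintf("<recordings_matrix> %s: %d stimuli x %d neurons\n",
              x$region_label, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write / read recordings as CSV (stimuli x neurons)
#' @param recordings a `recordings_matrix`.
#' @param path CSV file path.
#' @export
write_recordings <- function(recordings, path) {
  stopifnot(inherits(recordings, "recordings_matrix"))
  df <- as.data.frame(recordings$values)
  attr(df, "region") <- NULL
  write.csv(cbind(region = recordings$region_label, df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recordings
#' @export
read_recordings <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  region <- as.character(df$region[1])
  vals <- as.matrix(df[, setdiff(names(df), "region"), drop = FALSE])
  structure(list(values = vals, region_label = region, seed = NA_integer_),
            class = "recordings_matrix")
}
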