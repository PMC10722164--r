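#' Layer descriptors for sequential convolutional networks
#'
#' A `network_spec` is an ordered list of layer descriptors. Supported layer
#' kinds are 2-d convolution (stride 1, optional zero padding, optional batch
#' normalization, ReLU), max pooling, and dense layers (a flatten is inserted
#' automatically before the first dense layer). The final dense layer is the
#' classification head: its width must equal `n_classes` and its `softmax`
#' activation is applied inside the loss / prediction step, so the network
#' forward pass returns logits.
#'
#' @param filters,units output channels of a convolution / width of a dense layer.
#' @param kernel convolution kernel side length.
#' @param padding zero padding in pixels, or `"same"` for `(kernel - 1) / 2`.
#' @param batch_norm whether the convolution is followed by batch normalization.
#' @param activation `"relu"`, `"linear"`, or (final layer only) `"softmax"`.
#' @param size pooling window (and stride).
#' @return a layer descriptor (list) for use in [network_spec()].
#' @name layer_spec
NULL

#' @rdname layer_spec
#' @export
conv_spec <- function(filters, kernel = 3, padding = "same", batch_norm = TRUE,
                      activation = "relu") {
  stop_if_not_count(filters, "filters")
  stop_if_not_count(kernel, "kernel")
  if (identical(padding, "same")) padding <- (kernel - 1) %/% 2
  list(kind = "conv", filters = as.integer(filters), kernel = as.integer(kernel),
       padding = as.integer(padding), batch_norm = isTRUE(batch_norm),
       activation = match.arg(activation, c("relu", "linear")))
}

#' @rdname layer_spec
#' @export
pool_spec <- function(size = 2) {
  stop_if_not_count(size, "size")
  list(kind = "pool", size = as.integer(size))
}

#' @rdname layer_spec
#' @export
dense_spec <- function(units, activation = "relu") {
  stop_if_not_count(units, "units")
  list(kind = "dense", units = as.integer(units),
       activation = match.arg(activation, c("relu", "linear", "softmax")))
}

#' Define a sequential convolutional classifier architecture
#'
#' @param layers list of layer descriptors from [conv_spec()], [pool_spec()],
#'   [dense_spec()]. The last layer must be a dense layer of width `n_classes`.
#' @param input_shape integer vector `c(height, width, channels)`.
#' @param n_classes number of output classes.
#' @return an object of class `network_spec` with resolved per-layer shapes.
#' @examples
#' spec <- network_spec(
#'   layers = list(conv_spec(4), pool_spec(), dense_spec(3, "softmax")),
#'   input_shape = c(8, 8, 3), n_classes = 3)
#' @export
network_spec <- function(layers, input_shape, n_classes) {
  stop_if_not_count(n_classes, "n_classes", min = 2)
  if (length(input_shape) != 3 || any(input_shape < 1))
    stop("'input_shape' must be c(height, width, channels)", call. = FALSE)
  input_shape <- as.integer(input_shape)
  spec <- structure(list(layers = layers, input_shape = input_shape,
                         n_classes = as.integer(n_classes)),
                    class = "network_spec")
  validate_network_spec(spec)
}

validate_network_spec <- function(spec) {
  shp <- spec$input_shape  # (H, W, C) or scalar feature width after flatten
  seen_dense <- FALSE
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$kind == "conv") {
      if (seen_dense)
        stop(sprintf("layer %d: convolution after a dense layer", i), call. = FALSE)
      ho <- shp[1] + 2 * l$padding - l$kernel + 1
      wo <- shp[2] + 2 * l$padding - l$kernel + 1
      if (ho < 1 || wo < 1)
        stop(sprintf("layer %d: kernel %d too large for %dx%d input",
                     i, l$kernel, shp[1], shp[2]), call. = FALSE)
      shp <- c(ho, wo, l$filters)
    } else if (l$kind == "pool") {
      if (seen_dense)
        stop(sprintf("layer %d: pooling after a dense layer", i), call. = FALSE)
      if (shp[1] %% l$size != 0 || shp[2] %% l$size != 0)
        stop(sprintf("layer %d: pool size %d does not divide %dx%d",
                     i, l$size, shp[1], shp[2]), call. = FALSE)
      shp <- c(shp[1] %/% l$size, shp[2] %/% l$size, shp[3])
    } else if (l$kind == "dense") {
      if (!seen_dense) shp <- prod(shp)  # implicit flatten
      seen_dense <- TRUE
      shp <- l$units
    } else stop(sprintf("layer %d: unknown kind '%s'", i, l$kind), call. = FALSE)
  }
  last <- spec$layers[[length(spec$layers)]]
  if (last$kind != "dense" || last$units != spec$n_classes)
    stop(sprintf("last layer must be a dense layer of width n_classes = %d",
                 spec$n_classes), call. = FALSE)
  spec
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> input %s, %d classes, %d layers\n",
              paste(x$input_shape, collapse = "x"), x$n_classes,
              length(x$layers)))
  invisible(x)
}

#' Desk-scale convolutional classifier architecture
#'
#' Three convolution + batch-norm + ReLU + max-pool blocks followed by one
#' hidden dense layer and a softmax head. Small enough to train on a CPU in
#' minutes, deep enough to expose layered readouts for representational
#' analyses.
#'
#' @param n_classes number of classes.
#' @param input_size input image side length.
#' @param n_channels input channels.
#' @param channels output channels of the three convolution blocks.
#' @param dense_units width of the hidden dense layer.
#' @return a [network_spec()].
#' @export
small_cnn_spec <- function(n_classes = 10, input_size = 16, n_channels = 3,
                           channels = c(8, 16, 32), dense_units = 128) {
  layers <- list()
  for (ch in channels) {
    layers <- c(layers, list(conv_spec(ch), pool_spec(2)))
  }
  layers <- c(layers, list(dense_spec(dense_units, "relu"),
                           dense_spec(n_classes, "softmax")))
  network_spec(layers, c(input_size, input_size, n_channels), n_classes)
}

#' VGG19-class architecture with batch normalization
#'
#' The standard 16-convolution VGG19 feature stack (channel plan
#' 64,64 / 128,128 / 256x4 / 512x4 / 512x4 with five max-pool stages) and a
#' single dense classification head, as commonly used for 10-class 32x32
#' benchmarks. With `n_classes = 10` the total parameter count is about
#' 20.04 million. Provided for parameter-accounting at full scale; training it
#' is not intended on a desktop CPU.
#'
#' @param n_classes number of classes.
#' @param input_size input image side length (must be divisible by 32).
#' @return a [network_spec()].
#' @export
vgg19_bn_spec <- function(n_classes = 10, input_size = 32) {
  plan <- list(c(64, 64), c(128, 128), c(256, 256, 256, 256),
               c(512, 512, 512, 512), c(512, 512, 512, 512))
  layers <- list()
  for (block in plan) {
    for (ch in block) layers <- c(layers, list(conv_spec(ch)))
    layers <- c(layers, list(pool_spec(2)))
  }
  layers <- c(layers, list(dense_spec(n_classes, "softmax")))
  network_spec(layers, c(input_size, input_size, 3), n_classes)
}

#' Serialize a network spec to / from YAML
#'
#' The YAML representation round-trips losslessly through
#' `read_network_spec(write_network_spec(spec, path))`.
#'
#' @param spec a [network_spec()].
#' @param path file path.
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  obj <- list(input_shape = spec$input_shape, n_classes = spec$n_classes,
              layers = spec$layers)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  layers <- lapply(obj$layers, function(l) {
    switch(l$kind,
      conv = conv_spec(l$filters, l$kernel, l$padding, l$batch_norm, l$activation),
      pool = pool_spec(l$size),
      dense = dense_spec(l$units, l$activation),
      stop("unknown layer kind in spec file: ", l$kind)
    )
  })
  network_spec(layers, unlist(obj$input_shape), obj$n_classes)
}
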