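#' Build a sequential convolutional network
#'
#' Instantiates a [network_spec()] with freshly initialized weights
#' (He-scaled Gaussian for multiplicative weights, zeros for biases, unit
#' gain / zero shift for batch normalization). Initialization is deterministic
#' given `seed`.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `conv_network`.
#' @export
build_network <- function(spec, seed = 1L) {
  spec <- validate_network_spec(spec)
  layers <- list()
  counters <- c(conv = 0L, bn = 0L, relu = 0L, pool = 0L, dense = 0L)
  nm <- function(type) {
    counters[type] <<- counters[type] + 1L
    paste0(type, counters[type])
  }
  shp <- spec$input_shape
  seen_dense <- FALSE
  withr::with_seed(seed, {
    for (l in spec$layers) {
      if (l$kind == "conv") {
        fan_in <- l$kernel^2 * shp[3]
        W <- array(rnorm(fan_in * l$filters, sd = sqrt(2 / fan_in)),
                   dim = c(l$kernel, l$kernel, shp[3], l$filters))
        layers[[length(layers) + 1]] <- list(
          type = "conv", name = nm("conv"), W = W, b = numeric(l$filters),
          padding = l$padding)
        shp <- c(shp[1] + 2 * l$padding - l$kernel + 1,
                 shp[2] + 2 * l$padding - l$kernel + 1, l$filters)
        if (l$batch_norm)
          layers[[length(layers) + 1]] <- list(
            type = "bn", name = nm("bn"), gamma = rep(1, l$filters),
            beta = numeric(l$filters), running_mean = numeric(l$filters),
            running_var = rep(1, l$filters), eps = 1e-5, momentum = 0.1)
        if (l$activation == "relu")
          layers[[length(layers) + 1]] <- list(type = "relu", name = nm("relu"))
      } else if (l$kind == "pool") {
        layers[[length(layers) + 1]] <- list(type = "pool", name = nm("pool"),
                                             size = l$size)
        shp <- c(shp[1] %/% l$size, shp[2] %/% l$size, shp[3])
      } else if (l$kind == "dense") {
        if (!seen_dense) {
          layers[[length(layers) + 1]] <- list(type = "flatten", name = "flatten",
                                               in_shape = shp)
          shp <- prod(shp)
          seen_dense <- TRUE
        }
        W <- matrix(rnorm(shp * l$units, sd = sqrt(2 / shp)), shp, l$units)
        layers[[length(layers) + 1]] <- list(
          type = "dense", name = nm("dense"), W = W, b = numeric(l$units),
          activation = l$activation)
        shp <- l$units
        if (l$activation == "relu")
          layers[[length(layers) + 1]] <- list(type = "relu", name = nm("relu"))
      }
    }
  })
  structure(list(spec = spec, layers = layers, seed = as.integer(seed)),
            class = "conv_network")
}

#' @export
print.conv_network <- function(x, ...) {
  acc <- count_parameters(x)
  cat(sprintf("<conv_network> %d layers (%s), %s parameters (%s ablatable)\n",
              length(x$layers),
              paste(vapply(x$layers, `[[`, "", "name"), collapse = " "),
              format(acc$total, big.mark = ","),
              format(acc$eligible_total, big.mark = ",")))
  invisible(x)
}

#' Layer names of a network
#' @param network a `conv_network`.
#' @return character vector of layer names in forward order.
#' @export
network_layer_names <- function(network) {
  vapply(network$layers, `[[`, "", "name")
}

# name of the layer whose output feeds the final dense classification
# transform (the "penultimate" readout layer in the RSA sense)
penultimate_layer_name <- function(network) {
  nms <- network_layer_names(network)
  types <- vapply(network$layers, `[[`, "", "type")
  last_dense <- max(which(types == "dense"))
  if (last_dense == 1) stop("network has no layer before its output layer")
  nms[last_dense - 1]
}

# broadcast a per-channel vector over an (H, W, C, N) array
bcast_channel <- function(v, d) {
  rep(rep(v, each = d[1] * d[2]), times = d[4])
}

bn_channel_stats <- function(x, d) {
  x3 <- x
  dim(x3) <- c(d[1] * d[2], d[3], d[4])
  mu <- numeric(d[3]); v <- numeric(d[3])
  for (c in seq_len(d[3])) {
    z <- x3[, c, ]
    mu[c] <- mean(z)
    v[c] <- mean((z - mu[c])^2)  # biased variance, as in batch training
  }
  list(mu = mu, var = v)
}

layer_forward <- function(l, x, training) {
  if (l$type == "conv") {
    list(out = conv2d_forward_cpp(x, l$W, l$b, l$padding), cache = list(x = x), layer = l)
  } else if (l$type == "bn") {
    d <- dim(x)
    if (training) {
      st <- bn_channel_stats(x, d)
      inv_std <- 1 / sqrt(st$var + l$eps)
      xhat <- (x - bcast_channel(st$mu, d)) * bcast_channel(inv_std, d)
      out <- xhat * bcast_channel(l$gamma, d) + bcast_channel(l$beta, d)
      dim(out) <- d
      l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * st$mu
      l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * st$var
      list(out = out, cache = list(xhat = xhat, inv_std = inv_std, d = d), layer = l)
    } else {
      scale <- l$gamma / sqrt(l$running_var + l$eps)
      shift <- l$beta - scale * l$running_mean
      out <- x * bcast_channel(scale, d) + bcast_channel(shift, d)
      dim(out) <- d
      list(out = out, cache = NULL, layer = l)
    }
  } else if (l$type == "relu") {
    out <- pmax(x, 0)
    if (!is.null(dim(x))) dim(out) <- dim(x)
    list(out = out, cache = list(pos = x > 0), layer = l)
  } else if (l$type == "pool") {
    r <- maxpool_forward_cpp(x, l$size)
    list(out = r$out, cache = list(idx = r$idx, xdim = dim(x)), layer = l)
  } else if (l$type == "flatten") {
    d <- dim(x)
    out <- t(matrix(x, prod(d[1:3]), d[4]))
    list(out = out, cache = list(d = d), layer = l)
  } else if (l$type == "dense") {
    out <- x %*% l$W
    out <- sweep(out, 2, l$b, "+")
    list(out = out, cache = list(x = x), layer = l)
  } else stop("unknown layer type: ", l$type)
}

layer_backward <- function(l, cache, dout) {
  if (l$type == "conv") {
    g <- conv2d_backward_cpp(cache$x, l$W, dout, l$padding)
    list(dx = g$dx, grads = list(W = g$dw, b = g$db))
  } else if (l$type == "bn") {
    d <- cache$d
    m <- d[1] * d[2] * d[4]
    x3 <- dout; dim(x3) <- c(d[1] * d[2], d[3], d[4])
    h3 <- cache$xhat; dim(h3) <- c(d[1] * d[2], d[3], d[4])
    dgamma <- numeric(d[3]); dbeta <- numeric(d[3])
    mean_d <- numeric(d[3]); mean_dh <- numeric(d[3])
    for (c in seq_len(d[3])) {
      dc <- x3[, c, ]; hc <- h3[, c, ]
      dbeta[c] <- sum(dc)
      dgamma[c] <- sum(dc * hc)
      mean_d[c] <- dbeta[c] / m
      mean_dh[c] <- dgamma[c] / m
    }
    dx <- (dout - bcast_channel(mean_d, d) - cache$xhat * bcast_channel(mean_dh, d)) *
      bcast_channel(l$gamma * cache$inv_std, d)
    dim(dx) <- d
    list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
  } else if (l$type == "relu") {
    dx <- dout * cache$pos
    list(dx = dx, grads = NULL)
  } else if (l$type == "pool") {
    list(dx = maxpool_backward_cpp(cache$idx, dout, cache$xdim), grads = NULL)
  } else if (l$type == "flatten") {
    dx <- t(dout)
    dim(dx) <- cache$d
    list(dx = dx, grads = NULL)
  } else if (l$type == "dense") {
    list(dx = dout %*% t(l$W),
         grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
  } else stop("unknown layer type: ", l$type)
}

# Forward pass. Returns logits (or the output of `stop_at`), per-layer caches
# when `keep_cache`, and the network (batch-norm running statistics update
# when `training = TRUE`).
nn_forward <- function(network, x, training = FALSE, stop_at = NULL,
                       keep_cache = FALSE) {
  if (length(dim(x)) != 4)
    stop("input must be a (height, width, channels, n) array", call. = FALSE)
  caches <- if (keep_cache) vector("list", length(network$layers)) else NULL
  for (i in seq_along(network$layers)) {
    r <- layer_forward(network$layers[[i]], x, training)
    x <- r$out
    network$layers[[i]] <- r$layer
    if (keep_cache) caches[[i]] <- r$cache
    if (!is.null(stop_at) && identical(network$layers[[i]]$name, stop_at))
      return(list(out = x, caches = caches, network = network, stopped = i))
  }
  if (!is.null(stop_at))
    stop(sprintf("unknown layer '%s'; valid layers: %s", stop_at,
                 paste(network_layer_names(network), collapse = ", ")),
         call. = FALSE)
  list(out = x, caches = caches, network = network, stopped = length(network$layers))
}

nn_backward <- function(network, caches, dout) {
  grads <- vector("list", length(network$layers))
  for (i in rev(seq_along(network$layers))) {
    r <- layer_backward(network$layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)  # plain [[<- would drop NULL entries
  }
  grads
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy loss and gradient w.r.t. logits
softmax_xent <- function(logits, y) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n)
}

#' Training hyperparameters
#'
#' Defaults follow the common benchmark protocol for this paradigm: SGD with
#' momentum 0.9, learning rate 0.001, batch size 128; retraining after an
#' injury step runs for 3 epochs.
#'
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum coefficient.
#' @param batch_size mini-batch size.
#' @param epochs number of passes over the training set (>= 0).
#' @param seed integer seed controlling batch shuffling.
#' @return an object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.001, momentum = 0.9,
                            batch_size = 128, epochs = 3, seed = 1L) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1)
  stop_if_not_count(batch_size, "batch_size")
  stop_if_not_count(epochs, "epochs", min = 0)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "training_config")
}

as_labeled_set <- function(data, split = c("train", "test")) {
  split <- match.arg(split)
  if (inherits(data, "stimulus_dataset")) data <- data[[split]]
  if (!is.list(data) || is.null(data$x) || is.null(data$y))
    stop("expected a stimulus_dataset or a list(x = array, y = labels)", call. = FALSE)
  if (length(dim(data$x)) != 4 || dim(data$x)[4] != length(data$y))
    stop("images must be a 4-d array with one slice per label", call. = FALSE)
  data
}

init_velocity <- function(network) {
  lapply(network$layers, function(l) {
    switch(l$type,
      conv = list(W = array(0, dim(l$W)), b = numeric(length(l$b))),
      dense = list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b))),
      bn = list(gamma = numeric(length(l$gamma)), beta = numeric(length(l$beta))),
      NULL)
  })
}

# one SGD-with-momentum update; masked weight entries have their gradient
# zeroed and their value re-forced to exactly zero after the update
sgd_step <- function(network, grads, vel, config, mask = NULL) {
  for (i in seq_along(network$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    l <- network$layers[[i]]
    for (p in names(g)) {
      gp <- g[[p]]
      mk <- if (!is.null(mask)) mask$masks[[paste0(l$name, ".", p)]] else NULL
      if (!is.null(mk)) gp[mk] <- 0
      v <- config$momentum * vel[[i]][[p]] + gp
      vel[[i]][[p]] <- v
      l[[p]] <- l[[p]] - config$learning_rate * v
      if (!is.null(mk)) l[[p]][mk] <- 0
    }
    network$layers[[i]] <- l
  }
  list(network = network, vel = vel)
}

#' Train a network with SGD, optionally under an ablation mask
#'
#' Mini-batch stochastic gradient descent with momentum on the softmax
#' cross-entropy loss. When `mask` is given, ablated ("dead") weights take no
#' part in training: their gradients are zeroed and their values re-forced to
#' exactly zero after every optimizer update, so neither momentum nor any
#' other optimizer state can revive them. Optimizer state (velocity) is
#' freshly initialized on every call.
#'
#' @param network a `conv_network`.
#' @param dataset a `stimulus_dataset` (its train split is used) or a
#'   `list(x, y)`.
#' @param config a [training_config()].
#' @param mask optional [new_ablation_mask()] result.
#' @return list with `network` (trained) and `history` (data frame of
#'   per-epoch mean loss and training accuracy; empty for `epochs = 0`).
#' @export
train <- function(network, dataset, config = training_config(), mask = NULL) {
  data <- as_labeled_set(dataset, "train")
  n <- length(data$y)
  if (n == 0) stop("training set is empty", call. = FALSE)
  if (any(data$y < 1 | data$y > network$spec$n_classes))
    stop("labels outside 1..n_classes", call. = FALSE)
  if (!is.null(mask)) network <- apply_mask(network, mask)
  vel <- init_velocity(network)
  hist <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  for (epoch in seq_len(config$epochs)) {
    ord <- withr::with_seed(derive_seed(config$seed, 17L, epoch), sample.int(n))
    losses <- c(); ncorrect <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      xb <- data$x[, , , idx, drop = FALSE]
      yb <- data$y[idx]
      fw <- nn_forward(network, xb, training = TRUE, keep_cache = TRUE)
      network <- fw$network
      ls <- softmax_xent(fw$out, yb)
      losses <- c(losses, ls$loss)
      ncorrect <- ncorrect + sum(max.col(fw$out, ties.method = "first") == yb)
      grads <- nn_backward(network, fw$caches, ls$dlogits)
      st <- sgd_step(network, grads, vel, config, mask)
      network <- st$network
      vel <- st$vel
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                   accuracy = ncorrect / n))
  }
  list(network = network, history = hist)
}

#' Top-1 classification accuracy on a labeled image set
#'
#' Runs the network in inference mode (batch normalization uses running
#' statistics) and returns the fraction of correctly classified images.
#' Deterministic for fixed weights and data.
#'
#' @param network a `conv_network`.
#' @param dataset a `stimulus_dataset` (its test split is used) or `list(x, y)`.
#' @param batch_size evaluation batch size.
#' @return fraction correct in `[0, 1]`.
#' @export
evaluate_accuracy <- function(network, dataset, batch_size = 256) {
  data <- as_labeled_set(dataset, "test")
  n <- length(data$y)
  if (n == 0) stop("evaluation set is empty", call. = FALSE)
  if (any(data$y < 1 | data$y > network$spec$n_classes))
    stop("labels outside 1..n_classes", call. = FALSE)
  ncorrect <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    out <- nn_forward(network, data$x[, , , idx, drop = FALSE])$out
    ncorrect <- ncorrect + sum(max.col(out, ties.method = "first") == data$y[idx])
  }
  ncorrect / n
}

#' Extract a stimuli-by-features activation matrix from a named layer
#'
#' Runs the network in inference mode up to (and including) the named layer
#' and returns its output, flattened to one row per stimulus. The special
#' name `"penultimate"` resolves to the layer feeding the final dense
#' classification transform — the conventional readout layer for
#' representational similarity analyses.
#'
#' @param network a `conv_network`.
#' @param images a 4-d image array, a `stimulus_dataset` (test split), or a
#'   `list(x, y)`.
#' @param layer layer name (see [network_layer_names()]) or `"penultimate"`.
#' @param batch_size forward-pass batch size.
#' @return an object of class `activation_matrix`: list with `values`
#'   (stimuli x features), `layer`, and (if available) `labels`.
#' @export
extract_activations <- function(network, images, layer = "penultimate",
                                batch_size = 256) {
  labels <- NULL
  if (inherits(images, "stimulus_dataset") || (is.list(images) && !is.null(images$x))) {
    d <- as_labeled_set(images, "test")
    labels <- d$y
    images <- d$x
  }
  if (length(dim(images)) != 4)
    stop("images must be a (height, width, channels, n) array", call. = FALSE)
  if (identical(layer, "penultimate")) layer <- penultimate_layer_name(network)
  if (!layer %in% network_layer_names(network))
    stop(sprintf("unknown layer '%s'; valid layers: %s", layer,
                 paste(network_layer_names(network), collapse = ", ")),
         call. = FALSE)
  n <- dim(images)[4]
  rows <- list()
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    out <- nn_forward(network, images[, , , idx, drop = FALSE], stop_at = layer)$out
    if (!is.null(dim(out)) && length(dim(out)) == 4) {
      d <- dim(out)
      out <- t(matrix(out, prod(d[1:3]), d[4]))
    }
    rows[[length(rows) + 1]] <- out
  }
  vals <- do.call(rbind, rows)
  rownames(vals) <- sprintf("s%04d", seq_len(n))
  structure(list(values = vals, layer = layer, labels = labels),
            class = "activation_matrix")
}

activation_values <- function(a) {
  if (inherits(a, "activation_matrix")) a$values
  else if (is.matrix(a)) a
  else stop("expected an activation_matrix or a matrix", call. = FALSE)
}

#' @export
print.activation_matrix <- function(x, ...) {
  cat(sprintf("<activation_matrix> layer %s: %d stimuli x %d features\n",
              x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Count network parameters under an ablation-eligibility policy
#'
#' Tallies every parameter tensor of a network (or the exact counts implied
#' by a spec) and classifies each as ablation-eligible or not. The default
#' policy treats only the multiplicative weights of convolution and dense
#' layers as ablatable synapses; biases and batch-normalization parameters
#' are ineligible. The `"all"` policy treats every parameter as eligible,
#' matching parameter-count arithmetic that uses the full model size as the
#' ablation base.
#'
#' @param x a `conv_network` or a [network_spec()].
#' @param policy `"conv_dense"` (default) or `"all"`.
#' @return an object of class `parameter_account`: list with `table` (one row
#'   per tensor: layer, tensor, count, eligible), `total`, `eligible_total`,
#'   `ineligible_total`, and `policy`.
#' @examples
#' count_parameters(vgg19_bn_spec())$total  # about 20.04 million
#' @export
count_parameters <- function(x, policy = c("conv_dense", "all")) {
  UseMethod("count_parameters")
}

#' @export
count_parameters.conv_network <- function(x, policy = c("conv_dense", "all")) {
  policy <- match.arg(policy)
  rows <- list()
  for (l in x$layers) {
    if (l$type %in% c("conv", "dense")) {
      rows[[length(rows) + 1]] <- data.frame(
        layer = l$name, tensor = "W", count = length(l$W),
        eligible = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        layer = l$name, tensor = "b", count = length(l$b),
        eligible = policy == "all")
    } else if (l$type == "bn") {
      rows[[length(rows) + 1]] <- data.frame(
        layer = l$name, tensor = "gamma", count = length(l$gamma),
        eligible = policy == "all")
      rows[[length(rows) + 1]] <- data.frame(
        layer = l$name, tensor = "beta", count = length(l$beta),
        eligible = policy == "all")
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, total = sum(tab$count),
                 eligible_total = sum(tab$count[tab$eligible]),
                 ineligible_total = sum(tab$count[!tab$eligible]),
                 policy = policy),
            class = "parameter_account")
}

#' @export
count_parameters.network_spec <- function(x, policy = c("conv_dense", "all")) {
  policy <- match.arg(policy)
  # shape walk identical to build_network, without allocating weights
  net <- list(spec = x, layers = list())
  shp <- x$input_shape
  counters <- c(conv = 0L, bn = 0L, dense = 0L)
  rows <- list()
  seen_dense <- FALSE
  for (l in x$layers) {
    if (l$kind == "conv") {
      counters["conv"] <- counters["conv"] + 1L
      nm <- paste0("conv", counters["conv"])
      rows[[length(rows) + 1]] <- data.frame(
        layer = nm, tensor = "W", count = l$kernel^2 * shp[3] * l$filters,
        eligible = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        layer = nm, tensor = "b", count = l$filters, eligible = policy == "all")
      shp <- c(shp[1] + 2 * l$padding - l$kernel + 1,
               shp[2] + 2 * l$padding - l$kernel + 1, l$filters)
      if (l$batch_norm) {
        counters["bn"] <- counters["bn"] + 1L
        nm <- paste0("bn", counters["bn"])
        rows[[length(rows) + 1]] <- data.frame(
          layer = nm, tensor = "gamma", count = l$filters, eligible = policy == "all")
        rows[[length(rows) + 1]] <- data.frame(
          layer = nm, tensor = "beta", count = l$filters, eligible = policy == "all")
      }
    } else if (l$kind == "pool") {
      shp <- c(shp[1] %/% l$size, shp[2] %/% l$size, shp[3])
    } else if (l$kind == "dense") {
      if (!seen_dense) { shp <- prod(shp); seen_dense <- TRUE }
      counters["dense"] <- counters["dense"] + 1L
      nm <- paste0("dense", counters["dense"])
      rows[[length(rows) + 1]] <- data.frame(
        layer = nm, tensor = "W", count = shp * l$units, eligible = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        layer = nm, tensor = "b", count = l$units, eligible = policy == "all")
      shp <- l$units
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, total = sum(tab$count),
                 eligible_total = sum(tab$count[tab$eligible]),
                 ineligible_total = sum(tab$count[!tab$eligible]),
                 policy = policy),
            class = "parameter_account")
}

#' @export
print.parameter_account <- function(x, ...) {
  cat(sprintf("<parameter_account> total %s | ablatable %s | other %s (policy %s)\n",
              format(x$total, big.mark = ","),
              format(x$eligible_total, big.mark = ","),
              format(x$ineligible_total, big.mark = ","), x$policy))
  invisible(x)
}

#' Save / load a network checkpoint (weights, spec, optional mask)
#'
#' @param network a `conv_network`.
#' @param path file path (RDS format).
#' @param mask optional ablation mask stored alongside the weights.
#' @export
save_checkpoint <- function(network, path, mask = NULL) {
  saveRDS(list(network = network, mask = mask), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
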