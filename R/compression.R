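#' Multiply-accumulate (FLOP) account of one forward pass
#'
#' Counts multiply-accumulate operations (MACs) of a single forward pass at a
#' given input shape, the convention commonly used to state pruning speedups.
#' A convolution layer costs `kernel_area * in_channels * out_channels *
#' output_area`; a dense layer costs `in * out`. Normalization, activation,
#' and pooling are not counted.
#'
#' @param x a [network_spec()] or `conv_network`.
#' @param input_shape optional `c(height, width, channels)`; defaults to the
#'   spec's input shape.
#' @return an object of class `flop_account`: list with `table` (one row per
#'   weighted layer: layer, macs) and `total`.
#' @examples
#' estimate_flops(small_cnn_spec())$total
#' @export
estimate_flops <- function(x, input_shape = NULL) {
  spec <- if (inherits(x, "conv_network")) network_to_spec(x) else x
  stopifnot(inherits(spec, "network_spec"))
  shp <- as.integer(input_shape %||% spec$input_shape)
  rows <- list()
  counters <- c(conv = 0L, dense = 0L)
  seen_dense <- FALSE
  for (l in spec$layers) {
    if (l$kind == "conv") {
      counters["conv"] <- counters["conv"] + 1L
      ho <- shp[1] + 2 * l$padding - l$kernel + 1
      wo <- shp[2] + 2 * l$padding - l$kernel + 1
      rows[[length(rows) + 1]] <- data.frame(
        layer = paste0("conv", counters["conv"]),
        macs = l$kernel^2 * shp[3] * l$filters * ho * wo)
      shp <- c(ho, wo, l$filters)
    } else if (l$kind == "pool") {
      shp <- c(shp[1] %/% l$size, shp[2] %/% l$size, shp[3])
    } else if (l$kind == "dense") {
      if (!seen_dense) { shp <- prod(shp); seen_dense <- TRUE }
      counters["dense"] <- counters["dense"] + 1L
      rows[[length(rows) + 1]] <- data.frame(
        layer = paste0("dense", counters["dense"]), macs = shp * l$units)
      shp <- l$units
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame(layer = character(), macs = numeric())
  structure(list(table = tab, total = sum(tab$macs)), class = "flop_account")
}

#' @export
print.flop_account <- function(x, ...) {
  cat(sprintf("<flop_account> %s MACs per forward pass\n",
              format(x$total, big.mark = ",")))
  invisible(x)
}

# reconstruct the (possibly pruned) architectural spec from a network's
# current weight shapes
network_to_spec <- function(network) {
  layers <- list()
  i <- 1
  L <- network$layers
  while (i <= length(L)) {
    l <- L[[i]]
    if (l$type == "conv") {
      j <- which_next(L, i)  # first layer after conv [+ bn] [+ relu]
      trailing <- if (j > i + 1) vapply(L[(i + 1):(j - 1)], `[[`, "", "type") else character()
      layers[[length(layers) + 1]] <- conv_spec(
        dim(l$W)[4], kernel = dim(l$W)[1], padding = l$padding,
        batch_norm = "bn" %in% trailing,
        activation = if ("relu" %in% trailing) "relu" else "linear")
      i <- j
    } else if (l$type == "pool") {
      layers[[length(layers) + 1]] <- pool_spec(l$size)
      i <- i + 1
    } else if (l$type == "dense") {
      layers[[length(layers) + 1]] <- dense_spec(ncol(l$W), l$activation)
      i <- i + 1 + (l$activation == "relu")
    } else i <- i + 1  # flatten / stray relu already consumed
  }
  network_spec(layers, network$spec$input_shape, network$spec$n_classes)
}

# index of the first layer after the conv "block" starting at position i
which_next <- function(L, i) {
  j <- i + 1
  while (j <= length(L) && L[[j]]$type %in% c("bn", "relu")) j <- j + 1
  j
}

#' Rank prunable units by ascending L1 norm
#'
#' Computes, for every convolution filter and every hidden dense unit (the
#' output classification layer is never prunable), the L1 norm of its
#' weights, and returns a stable global ordering from smallest to largest.
#' Ties are broken by layer position, then unit index.
#'
#' @param network a trained `conv_network`.
#' @return data frame with columns `layer`, `index`, `l1`, `kind`, ordered by
#'   ascending L1 norm.
#' @export
rank_filters <- function(network) {
  stopifnot(inherits(network, "conv_network"))
  types <- vapply(network$layers, `[[`, "", "type")
  last_dense <- max(which(types == "dense"))
  rows <- list()
  for (pos in seq_along(network$layers)) {
    l <- network$layers[[pos]]
    if (l$type == "conv") {
      n_f <- dim(l$W)[4]
      W2 <- matrix(l$W, ncol = n_f)
      rows[[length(rows) + 1]] <- data.frame(
        layer = l$name, index = seq_len(n_f), l1 = colSums(abs(W2)),
        kind = "conv", pos = pos)
    } else if (l$type == "dense" && pos != last_dense) {
      rows[[length(rows) + 1]] <- data.frame(
        layer = l$name, index = seq_len(ncol(l$W)), l1 = colSums(abs(l$W)),
        kind = "dense", pos = pos)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$l1, tab$pos, tab$index), ]
  rownames(tab) <- NULL
  tab[, c("layer", "index", "l1", "kind")]
}

# ---- pruning by per-layer keep vectors -------------------------------------

# keep: named list, layer name -> logical vector over that layer's units.
# Dependency propagation: dropping a conv filter removes its bias and
# batch-norm parameters and the matching input channels (or flattened
# features) of the next weighted layer; dropping a dense unit removes the
# matching input rows of the next dense layer.
prune_by_keep <- function(network, keep) {
  L <- network$layers
  in_keep <- NULL  # logical over current input channels/features; NULL = all
  for (i in seq_along(L)) {
    l <- L[[i]]
    if (l$type == "conv") {
      ik <- in_keep %||% rep(TRUE, dim(l$W)[3])
      ok <- keep[[l$name]] %||% rep(TRUE, dim(l$W)[4])
      if (!any(ok)) stop(sprintf("cannot remove every filter of layer '%s'", l$name),
                         call. = FALSE)
      l$W <- l$W[, , ik, ok, drop = FALSE]
      l$b <- l$b[ok]
      L[[i]] <- l
      in_keep <- ok
    } else if (l$type == "bn") {
      ok <- in_keep %||% rep(TRUE, length(l$gamma))
      for (p in c("gamma", "beta", "running_mean", "running_var")) l[[p]] <- l[[p]][ok]
      L[[i]] <- l
    } else if (l$type == "flatten") {
      ok <- in_keep %||% rep(TRUE, l$in_shape[3])
      spatial <- prod(l$in_shape[1:2])
      l$in_shape[3] <- sum(ok)
      L[[i]] <- l
      in_keep <- rep(ok, each = spatial)  # features of channel c are contiguous
    } else if (l$type == "dense") {
      ik <- in_keep %||% rep(TRUE, nrow(l$W))
      ok <- keep[[l$name]] %||% rep(TRUE, ncol(l$W))
      if (!any(ok)) stop(sprintf("cannot remove every unit of layer '%s'", l$name),
                         call. = FALSE)
      l$W <- l$W[ik, ok, drop = FALSE]
      l$b <- l$b[ok]
      L[[i]] <- l
      in_keep <- ok
    }
    # relu / pool: shape-preserving, in_keep passes through
  }
  network$layers <- L
  network$spec <- network_to_spec(structure(list(layers = L, spec = network$spec),
                                            class = "conv_network"))
  network
}

#' Apply a compression plan to a network
#'
#' Removes the filters/units listed in the plan (indices refer to the
#' original, unpruned network) with full dependency propagation. Application
#' is idempotent: a plan always produces the same pruned architecture.
#'
#' @param network the `conv_network` the plan was computed for.
#' @param plan a `compression_plan`.
#' @return the pruned `conv_network`.
#' @export
prune_network <- function(network, plan) {
  stopifnot(inherits(plan, "compression_plan"))
  keep <- list()
  for (nm in names(plan$remove)) {
    l <- network$layers[[which(network_layer_names(network) == nm)]]
    n_units <- if (l$type == "conv") dim(l$W)[4] else ncol(l$W)
    k <- rep(TRUE, n_units)
    k[plan$remove[[nm]]] <- FALSE
    keep[[nm]] <- k
  }
  prune_by_keep(network, keep)
}

#' Compress a network to a target FLOP speedup by L1 filter pruning
#'
#' Greedily removes the globally lowest-L1 convolution filters and hidden
#' dense units, one at a time with dependency propagation and FLOP
#' re-evaluation, until the ratio `FLOP(original) / FLOP(compressed)` reaches
#' the target. The last remaining unit of any layer and the output
#' classification layer are never removed. The pruned network is then
#' fine-tuned on the provided dataset.
#'
#' @param network a trained `conv_network`.
#' @param target desired speedup factor (>= 1).
#' @param dataset dataset for post-pruning fine-tuning, or `NULL` to skip.
#' @param finetune a [training_config()] for the fine-tuning phase.
#' @return an object of class `compression_result`: list with `network` (the
#'   compressed, fine-tuned network), `plan` (a `compression_plan`),
#'   `achieved_speedup`, `flops_before`, `flops_after`, and the fine-tuning
#'   `history`.
#' @export
compress_to_speedup <- function(network, target, dataset = NULL,
                                finetune = training_config()) {
  stopifnot(inherits(network, "conv_network"))
  if (!is.finite(target) || target < 1)
    stop("'target' must be a speedup factor >= 1", call. = FALSE)
  base <- estimate_flops(network)$total
  ranking <- rank_filters(network)
  keep <- list()
  for (i in seq_len(nrow(ranking))) {
    nm <- ranking$layer[i]
    l <- network$layers[[which(network_layer_names(network) == nm)]]
    if (is.null(keep[[nm]]))
      keep[[nm]] <- rep(TRUE, if (l$type == "conv") dim(l$W)[4] else ncol(l$W))
  }
  achieved <- 1
  removed <- 0L
  if (target > 1) {
    for (i in seq_len(nrow(ranking))) {
      nm <- ranking$layer[i]
      if (sum(keep[[nm]]) <= 1) next  # never empty a layer
      keep[[nm]][ranking$index[i]] <- FALSE
      removed <- removed + 1L
      cur <- flops_with_keep(network, keep)
      achieved <- base / cur
      if (achieved >= target) break
    }
    if (achieved < target)
      stop(sprintf("target speedup %.2fx unreachable; best achievable is %.2fx",
                   target, achieved), call. = FALSE)
  }
  remove <- lapply(keep, function(k) which(!k))
  remove <- remove[vapply(remove, length, 1L) > 0]
  plan <- structure(list(remove = remove, target = target,
                         achieved = achieved), class = "compression_plan")
  pruned <- if (removed > 0) prune_by_keep(network, keep) else network
  history <- NULL
  if (!is.null(dataset) && finetune$epochs > 0) {
    ft <- train(pruned, dataset, finetune)
    pruned <- ft$network
    history <- ft$history
  }
  structure(list(network = pruned, plan = plan, achieved_speedup = achieved,
                 flops_before = base, flops_after = base / achieved,
                 history = history),
            class = "compression_result")
}

# FLOP total for the architecture implied by per-layer keep vectors, computed
# arithmetically (no weight slicing)
flops_with_keep <- function(network, keep) {
  shp <- network$spec$input_shape
  total <- 0
  in_ch <- shp[3]
  seen_dense <- FALSE
  feat <- NULL
  for (l in network$layers) {
    if (l$type == "conv") {
      k <- dim(l$W)[1]
      n_out <- sum(keep[[l$name]] %||% rep(TRUE, dim(l$W)[4]))
      ho <- shp[1] + 2 * l$padding - k + 1
      wo <- shp[2] + 2 * l$padding - k + 1
      total <- total + k^2 * in_ch * n_out * ho * wo
      shp <- c(ho, wo, n_out)
      in_ch <- n_out
    } else if (l$type == "pool") {
      shp <- c(shp[1] %/% l$size, shp[2] %/% l$size, shp[3])
    } else if (l$type == "flatten") {
      feat <- prod(shp[1:2]) * in_ch
      seen_dense <- TRUE
    } else if (l$type == "dense") {
      n_out <- sum(keep[[l$name]] %||% rep(TRUE, ncol(l$W)))
      total <- total + feat * n_out
      feat <- n_out
    }
  }
  total
}

#' @export
print.compression_plan <- function(x, ...) {
  n <- sum(vapply(x$remove, length, 1L))
  cat(sprintf("<compression_plan> %d units removed across %d layers (target %.2gx, achieved %.2fx)\n",
              n, length(x$remove), x$target, x$achieved))
  invisible(x)
}

#' @export
print.compression_result <- function(x, ...) {
  cat(sprintf("<compression_result> %.2fx speedup (%s -> %s MACs)\n",
              x$achieved_speedup, format(x$flops_before, big.mark = ","),
              format(round(x$flops_after), big.mark = ",")))
  invisible(x)
}
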