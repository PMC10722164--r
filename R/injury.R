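#' Progressive synaptic injury schedule
#'
#' An injury schedule removes, at each iteration, a fraction `gamma` of the
#' currently surviving ablatable weights, chosen uniformly at random across
#' the whole network. The cumulative fraction of the initial synapses ablated
#' after `n` iterations is therefore `1 - (1 - gamma)^n`.
#'
#' @param gamma per-iteration ablation rate of surviving weights, in `(0, 1]`.
#' @param n_iterations number of injury iterations (>= 0).
#' @return an object of class `injury_schedule`.
#' @export
injury_schedule <- function(gamma = 0.2, n_iterations = 15) {
  check_gamma(gamma)
  stop_if_not_count(n_iterations, "n_iterations", min = 0)
  structure(list(gamma = gamma, n_iterations = as.integer(n_iterations)),
            class = "injury_schedule")
}

check_gamma <- function(gamma) {
  if (length(gamma) != 1 || !is.finite(gamma) || gamma <= 0 || gamma > 1)
    stop("'gamma' must be a single number in (0, 1]", call. = FALSE)
  invisible(gamma)
}

#' Cumulative injured fraction after n iterations
#'
#' Each iteration ablates fraction `gamma` of the surviving weights, so the
#' cumulative fraction of initial synapses removed after `n` iterations is
#' `1 - (1 - gamma)^n`.
#'
#' @param gamma per-iteration ablation rate in `(0, 1]`.
#' @param n iteration count(s), vectorized.
#' @return cumulative injured fraction(s) in `[0, 1]`.
#' @examples
#' cumulative_injured_fraction(0.2, c(1, 3, 15))  # 0.2, 0.488, 0.965
#' @export
cumulative_injured_fraction <- function(gamma, n) {
  check_gamma(gamma)
  if (any(n < 0) || any(n != round(n))) stop("'n' must be non-negative integers", call. = FALSE)
  1 - (1 - gamma)^n
}

#' Parameters remaining after n injury iterations
#'
#' @param total initial parameter count (the ablation base).
#' @param gamma per-iteration ablation rate in `(0, 1]`.
#' @param n iteration count(s), vectorized.
#' @return expected remaining parameter count(s), `total * (1 - gamma)^n`.
#' @examples
#' remaining_parameter_count(20.04e6, 0.2, 8) / 1e6   # ~3.36 million
#' remaining_parameter_count(20.04e6, 0.2, 15) / 1e6  # ~0.705 million
#' @export
remaining_parameter_count <- function(total, gamma, n) {
  check_gamma(gamma)
  if (any(total < 0)) stop("'total' must be non-negative", call. = FALSE)
  if (any(n < 0) || any(n != round(n))) stop("'n' must be non-negative integers", call. = FALSE)
  total * (1 - gamma)^n
}

#' Create an empty ablation mask for a network
#'
#' The mask holds one boolean map per ablation-eligible weight tensor
#' (`TRUE` = ablated, dead synapse). Masks are monotone: entries can only
#' ever flip from `FALSE` to `TRUE` via [apply_injury_step()].
#'
#' @param network a `conv_network`.
#' @param policy ablation-eligibility policy, see [count_parameters()]. The
#'   default ablates only convolution and dense multiplicative weights.
#' @return an object of class `ablation_mask`.
#' @export
new_ablation_mask <- function(network, policy = c("conv_dense", "all")) {
  policy <- match.arg(policy)
  masks <- list()
  for (l in network$layers) {
    if (l$type %in% c("conv", "dense")) {
      masks[[paste0(l$name, ".W")]] <- array(FALSE, dim = dim(l$W) %||% length(l$W))
      if (policy == "all")
        masks[[paste0(l$name, ".b")]] <- array(FALSE, dim = length(l$b))
    } else if (l$type == "bn" && policy == "all") {
      masks[[paste0(l$name, ".gamma")]] <- array(FALSE, dim = length(l$gamma))
      masks[[paste0(l$name, ".beta")]] <- array(FALSE, dim = length(l$beta))
    }
  }
  structure(list(masks = masks, iteration = 0L, policy = policy),
            class = "ablation_mask")
}

#' @export
print.ablation_mask <- function(x, ...) {
  tot <- sum(vapply(x$masks, length, 1L))
  abl <- sum(vapply(x$masks, sum, 1))
  cat(sprintf("<ablation_mask> iteration %d: %d / %d entries ablated (%.1f%%)\n",
              x$iteration, abl, tot, 100 * abl / tot))
  invisible(x)
}

#' Ablated / surviving entry counts of a mask
#' @param mask an `ablation_mask`.
#' @return data frame with one row per tensor (tensor, size, ablated) plus
#'   attribute-free totals in the last row `"total"`.
#' @export
mask_summary <- function(mask) {
  stopifnot(inherits(mask, "ablation_mask"))
  df <- data.frame(
    tensor = names(mask$masks),
    size = vapply(mask$masks, length, 1L),
    ablated = vapply(mask$masks, function(m) sum(m), 1)
  )
  rownames(df) <- NULL
  rbind(df, data.frame(tensor = "total", size = sum(df$size),
                       ablated = sum(df$ablated)))
}

#' Apply one injury iteration to an ablation mask
#'
#' Selects `round(gamma * n_surviving)` of the currently surviving entries
#' uniformly at random without replacement, pooled across all eligible weight
#' tensors of the network, and marks them ablated. Previously ablated entries
#' are never touched, so masks grow monotonically. Rounding is to the nearest
#' integer (ties to even), keeping the realized injury trajectory an unbiased
#' match to `1 - (1 - gamma)^n`.
#'
#' @param mask an `ablation_mask`.
#' @param gamma per-iteration ablation rate in `(0, 1]`.
#' @param seed optional integer seed for the injury draw; when `NULL` the
#'   current RNG state is used. Keeping injury on its own seeded stream makes
#'   the lesion pattern reproducible independently of training randomness.
#' @return the updated `ablation_mask`.
#' @export
apply_injury_step <- function(mask, gamma, seed = NULL) {
  stopifnot(inherits(mask, "ablation_mask"))
  check_gamma(gamma)
  sizes <- vapply(mask$masks, length, 1L)
  flat <- unlist(lapply(mask$masks, as.logical), use.names = FALSE)
  surviving <- which(!flat)
  if (length(surviving) == 0) {
    warning("no surviving weights left; injury step is a no-op")
    mask$iteration <- mask$iteration + 1L
    return(mask)
  }
  k <- round(gamma * length(surviving))
  draw <- function() if (k > 0) sample(surviving, k) else integer(0)
  chosen <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  flat[chosen] <- TRUE
  offset <- 0L
  for (nm in names(mask$masks)) {
    d <- dim(mask$masks[[nm]])
    m <- flat[(offset + 1L):(offset + sizes[[nm]])]
    dim(m) <- d
    mask$masks[[nm]] <- m
    offset <- offset + sizes[[nm]]
  }
  mask$iteration <- mask$iteration + 1L
  mask
}

#' Zero out masked weights in a network
#'
#' Sets every masked (ablated) entry of the network's eligible weight tensors
#' to exactly zero; unmasked entries are untouched.
#'
#' @param network a `conv_network`.
#' @param mask an `ablation_mask` built for a network of the same shape.
#' @return the masked `conv_network`.
#' @export
apply_mask <- function(network, mask) {
  stopifnot(inherits(network, "conv_network"), inherits(mask, "ablation_mask"))
  for (i in seq_along(network$layers)) {
    l <- network$layers[[i]]
    for (p in c("W", "b", "gamma", "beta")) {
      nm <- paste0(l$name %||% "", ".", p)
      mk <- mask$masks[[nm]]
      if (is.null(mk)) next
      if (length(mk) != length(l[[p]]))
        stop(sprintf("mask/network shape mismatch for tensor '%s'", nm), call. = FALSE)
      l[[p]][mk] <- 0
    }
    network$layers[[i]] <- l
  }
  network
}
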