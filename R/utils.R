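#' @useDynLib plastinet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor prcomp rnorm runif sd predict aggregate
#' @importFrom utils head write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a parent seed
#'
#' Hashes a parent seed together with any number of small integer tags into a
#' new seed in `[1, 2^31 - 2]`. Used throughout the package to give each
#' source of randomness (weight initialization, batch shuffling, injury
#' sampling, readout subsampling, ...) its own stream, all traceable to one
#' user-facing seed.
#'
#' @param seed integer parent seed.
#' @param ... additional integer tags (e.g. replicate index, iteration).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  stopifnot(length(ks) >= 1, all(is.finite(ks)))
  h <- 104729
  for (k in ks) h <- (h * 69069 + abs(as.numeric(k)) + 1) %% 2147483629
  as.integer(h %% 2147483645 + 1)
}

stop_if_not_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d (got %s)",
                 name, min, paste(x, collapse = ",")), call. = FALSE)
  invisible(as.integer(x))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
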