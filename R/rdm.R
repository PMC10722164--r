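#' Representational dissimilarity matrix (1 - Pearson)
#'
#' Computes the stimuli-by-stimuli dissimilarity matrix of an activation set:
#' entry (i, j) is one minus the Pearson correlation between the activation
#' vectors of stimuli i and j. The matrix is symmetric with a zero diagonal
#' and entries in `[0, 2]`. A stimulus whose activation vector is constant
#' has no defined correlation with anything; its off-diagonal entries are set
#' to the uninformative dissimilarity 1 and a warning is emitted.
#'
#' @param activations an [extract_activations()] result or a
#'   stimuli-by-features matrix (>= 2 stimuli).
#' @param condition free-text tag describing the network state the
#'   activations came from (e.g. `"healthy"`, `"injured@3"`).
#' @return an object of class `rdm`: list with `values` (the matrix),
#'   `labels` (class labels if available), and `condition`.
#' @export
compute_rdm <- function(activations, condition = "unspecified") {
  A <- activation_values(activations)
  if (nrow(A) < 2) stop("need at least 2 stimuli", call. = FALSE)
  labels <- if (inherits(activations, "activation_matrix")) activations$labels else NULL
  sds <- apply(A, 1, sd)
  flat <- sds == 0
  if (any(flat))
    warning(sprintf("%d stimulus/stimuli with constant activations; their dissimilarities are set to 1",
                    sum(flat)))
  R <- suppressWarnings(cor(t(A)))
  D <- 1 - R
  D[flat, ] <- 1
  D[, flat] <- 1
  D <- (D + t(D)) / 2
  D <- pmin(pmax(D, 0), 2)
  diag(D) <- 0
  dimnames(D) <- list(rownames(A), rownames(A))
  structure(list(values = D, labels = labels, condition = condition),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d stimuli, condition '%s'\n", nrow(x$values), x$condition))
  invisible(x)
}

rdm_upper <- function(rdm) {
  v <- rdm$values
  v[upper.tri(v)]
}

#' Compare two RDMs by Kendall's tau-b
#'
#' Rank-correlates the strictly-upper-triangle entries of two RDMs computed
#' on the same stimulus set, using the tie-adjusted tau-b variant (the common
#' choice in representational similarity analysis).
#'
#' @param a,b `rdm` objects over the same stimuli in the same order.
#' @return Kendall's tau-b in `[-1, 1]`.
#' @export
compare_rdms <- function(a, b) {
  stopifnot(inherits(a, "rdm"), inherits(b, "rdm"))
  if (nrow(a$values) != nrow(b$values))
    stop("RDMs cover different numbers of stimuli", call. = FALSE)
  if (!is.null(a$labels) && !is.null(b$labels) && !identical(a$labels, b$labels))
    stop("RDM stimulus labels do not match", call. = FALSE)
  kendall_taub_cpp(rdm_upper(a), rdm_upper(b))
}

#' Within- versus between-class dissimilarity of an RDM
#'
#' For a labeled RDM, averages the dissimilarities of stimulus pairs sharing
#' a class and of pairs from different classes. A representation that groups
#' stimuli by object class has `within < between`.
#'
#' @param rdm an `rdm` with `labels`.
#' @return list with `within`, `between`, and their difference `contrast`
#'   (`between - within`).
#' @export
rdm_class_contrast <- function(rdm) {
  stopifnot(inherits(rdm, "rdm"))
  if (is.null(rdm$labels)) stop("RDM has no class labels", call. = FALSE)
  same <- outer(rdm$labels, rdm$labels, "==")
  ut <- upper.tri(rdm$values)
  within <- mean(rdm$values[ut & same])
  between <- mean(rdm$values[ut & !same])
  list(within = within, between = between, contrast = between - within)
}

# class-stratified stimulus subsample used for all RDM / predictivity
# readouts of one experiment (fixed per experiment so conditions compare on
# identical stimuli)
stratified_stimulus_subset <- function(labels, per_class, seed) {
  withr::with_seed(seed, {
    idx <- unlist(lapply(sort(unique(labels)), function(k) {
      cand <- which(labels == k)
      sample(cand, min(per_class, length(cand)))
    }))
  })
  sort(idx)
}
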