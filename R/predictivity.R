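#' Configuration of the neural predictivity readout
#'
#' The readout follows the standard neural-benchmark methodology: model
#' activations are reduced by principal components analysis (default 1,000
#' components, automatically capped at the data limits), then a partial least
#' squares regression with 25 components maps the reduced activations onto
#' the recorded neural responses. Prediction quality is the per-neuron
#' Pearson correlation on held-out stimuli, aggregated over neurons by the
#' median and averaged over random train/test splits.
#'
#' @param n_pca_components maximum number of PCA components.
#' @param n_pls_components number of PLS regression components.
#' @param n_splits number of random splits (>= 2).
#' @param train_fraction fraction of stimuli used for fitting in each split.
#' @param seed integer seed controlling the splits.
#' @return an object of class `predictivity_config`.
#' @export
predictivity_config <- function(n_pca_components = 1000, n_pls_components = 25,
                                n_splits = 10, train_fraction = 0.9, seed = 1L) {
  stop_if_not_count(n_pca_components, "n_pca_components")
  stop_if_not_count(n_pls_components, "n_pls_components")
  stop_if_not_count(n_splits, "n_splits", min = 2)
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(n_pca_components = as.integer(n_pca_components),
                 n_pls_components = as.integer(n_pls_components),
                 n_splits = as.integer(n_splits),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "predictivity_config")
}

pearson_safe <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

#' Neural predictivity of model activations for one recorded region
#'
#' Cross-validated linear predictivity: per split, a PCA basis is fit on the
#' training stimuli's activations, activations are projected onto at most
#' `n_pca_components` components, and a partial least squares regression with
#' `n_pls_components` components is fit from the reduced activations to the
#' recorded responses (each neuron standardized on the training stimuli, so
#' the score is invariant to per-neuron affine rescaling of the recordings).
#' Held-out stimuli are predicted, each neuron is scored
#' by the Pearson correlation between predicted and recorded responses
#' (degenerate constant predictions score 0), neurons are aggregated by the
#' median, and scores are averaged over splits.
#'
#' @param activations an [extract_activations()] result or matrix; one row
#'   per stimulus.
#' @param recordings a [generate_recordings()] result or a stimuli-by-neurons
#'   matrix, rows aligned with `activations`.
#' @param config a [predictivity_config()].
#' @return an object of class `predictivity_score`: list with `score`, the
#'   per-split scores `per_split`, their standard deviation `dispersion`, and
#'   `region_label`.
#' @export
neural_predictivity <- function(activations, recordings,
                                config = predictivity_config()) {
  A <- activation_values(activations)
  R <- if (inherits(recordings, "recordings_matrix")) recordings$values else recordings
  region <- if (inherits(recordings, "recordings_matrix")) recordings$region_label else "region"
  if (!is.matrix(R)) stop("'recordings' must be a matrix or recordings_matrix", call. = FALSE)
  if (nrow(A) != nrow(R))
    stop(sprintf("activations (%d stimuli) and recordings (%d stimuli) are misaligned",
                 nrow(A), nrow(R)), call. = FALSE)
  n <- nrow(A)
  n_train <- max(2, floor(config$train_fraction * n))
  if (n_train >= n) stop("too few stimuli to hold any out", call. = FALSE)
  colnames(A) <- sprintf("f%05d", seq_len(ncol(A)))
  per_split <- numeric(config$n_splits)
  for (s in seq_len(config$n_splits)) {
    tr <- withr::with_seed(derive_seed(config$seed, 31L, s), sample.int(n, n_train))
    te <- setdiff(seq_len(n), tr)
    # drop constant features (zero variance on the training stimuli)
    keep <- apply(A[tr, , drop = FALSE], 2, sd) > 0
    if (!any(keep)) { per_split[s] <- 0; next }
    At <- A[, keep, drop = FALSE]
    ncomp_pca <- min(config$n_pca_components, ncol(At), n_train - 1)
    pca <- prcomp(At[tr, , drop = FALSE], center = TRUE, scale. = FALSE,
                  rank. = ncomp_pca)
    Xtr <- pca$x[, seq_len(ncomp_pca), drop = FALSE]
    Xte <- predict(pca, At[te, , drop = FALSE])[, seq_len(ncomp_pca), drop = FALSE]
    ncomp_pls <- min(config$n_pls_components, ncol(Xtr), n_train - 1)
    if (ncomp_pls < config$n_pls_components)
      warning(sprintf("PLS components capped at %d by data size", ncomp_pls))
    colnames(Xtr) <- colnames(Xte) <- sprintf("pc%04d", seq_len(ncol(Xtr)))
    # standardize each neuron on the training stimuli so the score is exactly
    # invariant to per-neuron affine rescaling of the recordings
    Ytr <- R[tr, , drop = FALSE]
    ym <- colMeans(Ytr)
    ysd <- apply(Ytr, 2, sd)
    ysd[ysd == 0] <- 1
    Ytr <- sweep(sweep(Ytr, 2, ym), 2, ysd, "/")
    fit <- mixOmics::pls(Xtr, Ytr, ncomp = ncomp_pls, mode = "regression",
                         scale = FALSE)
    pred <- predict(fit, Xte)$predict[, , ncomp_pls, drop = FALSE]
    dim(pred) <- c(length(te), ncol(R))
    rs <- vapply(seq_len(ncol(R)), function(j) pearson_safe(pred[, j], R[te, j]),
                 numeric(1))
    per_split[s] <- stats::median(rs)
  }
  structure(list(score = mean(per_split), per_split = per_split,
                 dispersion = sd(per_split), region_label = region),
            class = "predictivity_score")
}

#' @export
print.predictivity_score <- function(x, ...) {
  cat(sprintf("<predictivity_score> %s: %.3f (sd over splits %.3f)\n",
              x$region_label, x$score, x$dispersion %||% NA))
  invisible(x)
}

#' Composite predictivity over regions
#'
#' Averages per-region predictivity scores into a single composite score, the
#' arithmetic mean over regions, with split dispersion propagated as the mean
#' of the per-region dispersions.
#'
#' @param scores a list of `predictivity_score` objects (or a numeric vector
#'   of region scores), at least one.
#' @return a `predictivity_score` with `region_label = "composite"` and a
#'   `per_region` element.
#' @export
composite_score <- function(scores) {
  if (length(scores) == 0) stop("need at least one region score", call. = FALSE)
  if (is.numeric(scores)) {
    vals <- scores
    disp <- NA_real_
    labs <- names(scores) %||% paste0("region", seq_along(scores))
  } else {
    stopifnot(all(vapply(scores, inherits, TRUE, "predictivity_score")))
    vals <- vapply(scores, `[[`, numeric(1), "score")
    disp <- mean(vapply(scores, function(s) s$dispersion %||% NA_real_, numeric(1)))
    labs <- vapply(scores, `[[`, "", "region_label")
  }
  names(vals) <- labs
  structure(list(score = mean(vals), per_region = vals, dispersion = disp,
                 region_label = "composite"),
            class = "predictivity_score")
}
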