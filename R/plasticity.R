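#' Retrain the surviving weights of an injured network
#'
#' The neuroplasticity mechanism: after an injury step, the surviving weights
#' are retrained on the original training split while dead synapses stay
#' pinned at exactly zero. The optimizer (SGD momentum state) is freshly
#' initialized on every call, and masked entries are re-forced to zero after
#' every parameter update, so no optimizer state can leak value back into an
#' ablated synapse.
#'
#' @param network a `conv_network`; masked weights are (re-)zeroed on entry.
#' @param mask an `ablation_mask`.
#' @param dataset a `stimulus_dataset` or `list(x, y)` (training data).
#' @param config a [training_config()]; its default of 3 epochs is the
#'   standard retraining budget of this paradigm.
#' @return the retrained `conv_network`.
#' @export
retrain <- function(network, mask, dataset, config = training_config()) {
  stopifnot(inherits(mask, "ablation_mask"))
  network <- apply_mask(network, mask)  # enforce the precondition exactly
  train(network, dataset, config, mask = mask)$network
}

#' Readout configuration for degeneration experiments
#'
#' Controls which readouts are evaluated at each injury iteration beyond test
#' accuracy: representational dissimilarity (RDM Kendall-tau versus the
#' healthy baseline) and neural predictivity against synthetic regional
#' recordings generated from the healthy network's own layers.
#'
#' @param rdm evaluate the RDM trajectory?
#' @param rdm_per_class stimuli per class in the fixed, class-stratified test
#'   subset used for all RDM / predictivity readouts of the experiment.
#' @param predictivity evaluate neural predictivity?
#' @param predictivity_iterations iterations at which predictivity is scored
#'   (it is by far the most expensive readout).
#' @param region_layers layer names acting as synthetic "regions"; `NULL`
#'   picks the pooling stages plus the hidden dense activation, giving a
#'   V1/V2/V4/IT-like hierarchy of readout depths.
#' @param n_neurons simulated neurons per region.
#' @param recordings_noise_sd response noise of the synthetic recordings.
#' @param predictivity_config a [predictivity_config()].
#' @return an object of class `readout_config`.
#' @export
readout_config <- function(rdm = TRUE, rdm_per_class = 20,
                           predictivity = FALSE,
                           predictivity_iterations = 1:5,
                           region_layers = NULL, n_neurons = 40,
                           recordings_noise_sd = 0.1,
                           predictivity_config = plastinet::predictivity_config(n_splits = 5)) {
  stop_if_not_count(rdm_per_class, "rdm_per_class")
  stop_if_not_count(n_neurons, "n_neurons")
  structure(list(rdm = isTRUE(rdm), rdm_per_class = as.integer(rdm_per_class),
                 predictivity = isTRUE(predictivity),
                 predictivity_iterations = as.integer(predictivity_iterations),
                 region_layers = region_layers, n_neurons = as.integer(n_neurons),
                 recordings_noise_sd = recordings_noise_sd,
                 predictivity_config = predictivity_config),
            class = "readout_config")
}

default_region_layers <- function(network) {
  nms <- network_layer_names(network)
  types <- vapply(network$layers, `[[`, "", "type")
  pools <- nms[types == "pool"]
  # deepest post-flatten ReLU (the hidden dense activation), if any
  after_flatten <- if ("flatten" %in% nms) {
    fi <- which(nms == "flatten")
    nms[types == "relu" & seq_along(nms) > fi]
  } else character()
  unique(c(pools, utils::tail(after_flatten, 1)))
}

score_regions <- function(network, images, regions, config) {
  scores <- lapply(regions, function(r) {
    act <- extract_activations(network, images, layer = r$layer)
    neural_predictivity(act, r$recordings, config)
  })
  composite_score(scores)
}

#' Run a progressive injury + retraining experiment
#'
#' The core paradigm: starting from a trained ("healthy") baseline network,
#' each iteration (i) ablates fraction `gamma` of the surviving weights
#' uniformly at random, (ii) evaluates the injured network, (iii) retrains
#' the surviving weights for the configured number of epochs with dead
#' synapses pinned at zero, and (iv) evaluates again. The whole cycle is
#' repeated independently for each replicate seed from the same pristine
#' baseline, so replicates differ only in the random ablation order (and
#' retraining shuffles). Iteration 0 records the healthy baseline.
#'
#' @param network the trained baseline `conv_network`.
#' @param schedule an [injury_schedule()].
#' @param dataset a `stimulus_dataset` providing both splits.
#' @param retrain_config a [training_config()] for the retraining phases.
#' @param readout a [readout_config()].
#' @param seeds integer vector of replicate seeds.
#' @return an object of class `degeneration_result`: list with `records` (one
#'   row per replicate and iteration: injured fraction, pre/post-retraining
#'   accuracy, optional RDM taus and predictivity scores), `schedule`,
#'   `seeds`, and the configs used.
#' @export
run_degeneration_experiment <- function(network, schedule, dataset,
                                        retrain_config = training_config(),
                                        readout = readout_config(),
                                        seeds = 1:3) {
  stopifnot(inherits(network, "conv_network"), inherits(schedule, "injury_schedule"),
            inherits(dataset, "stimulus_dataset"))
  test <- dataset$test
  sub_seed <- derive_seed(seeds[1], 777L)
  sub_idx <- stratified_stimulus_subset(test$y, readout$rdm_per_class, sub_seed)
  sub <- list(x = test$x[, , , sub_idx, drop = FALSE], y = test$y[sub_idx])

  baseline_acc <- evaluate_accuracy(network, test)
  rdm_healthy <- NULL
  if (readout$rdm || readout$predictivity)
    act_healthy <- extract_activations(network, sub)
  if (readout$rdm)
    rdm_healthy <- compute_rdm(act_healthy, condition = "healthy")

  regions <- NULL
  pred_healthy <- NA_real_
  if (readout$predictivity) {
    layer_names <- readout$region_layers %||% default_region_layers(network)
    regions <- lapply(seq_along(layer_names), function(i) {
      act <- extract_activations(network, sub, layer = layer_names[i])
      rec <- generate_recordings(act, readout$n_neurons,
                                 noise_sd = readout$recordings_noise_sd,
                                 seed = derive_seed(sub_seed, 5L, i),
                                 region_label = layer_names[i])
      list(layer = layer_names[i], recordings = rec)
    })
    pred_healthy <- score_regions(network, sub, regions,
                                  readout$predictivity_config)$score
  }

  records <- list()
  for (r in seq_along(seeds)) {
    rep_seed <- seeds[r]
    net <- network  # restore the pristine baseline for every replicate
    mask <- new_ablation_mask(net)
    records[[length(records) + 1]] <- data.frame(
      replicate = r, seed = rep_seed, iteration = 0, injured_fraction = 0,
      accuracy_injured = baseline_acc, accuracy_retrained = baseline_acc,
      tau_injured = if (readout$rdm) 1 else NA_real_,
      tau_retrained = if (readout$rdm) 1 else NA_real_,
      pred_injured = pred_healthy, pred_retrained = pred_healthy)
    for (it in seq_len(schedule$n_iterations)) {
      mask <- apply_injury_step(mask, schedule$gamma,
                                seed = derive_seed(rep_seed, 11L, it))
      net <- apply_mask(net, mask)
      ms <- mask_summary(mask)
      frac <- ms$ablated[ms$tensor == "total"] / ms$size[ms$tensor == "total"]
      acc_inj <- evaluate_accuracy(net, test)
      tau_inj <- tau_ret <- NA_real_
      pred_inj <- pred_ret <- NA_real_
      do_pred <- readout$predictivity && it %in% readout$predictivity_iterations
      if (readout$rdm)
        tau_inj <- compare_rdms(compute_rdm(extract_activations(net, sub),
                                            condition = sprintf("injured@%d", it)),
                                rdm_healthy)
      if (do_pred)
        pred_inj <- score_regions(net, sub, regions, readout$predictivity_config)$score
      cfg <- retrain_config
      cfg$seed <- derive_seed(rep_seed, 23L, it)
      net <- retrain(net, mask, dataset, cfg)
      acc_ret <- evaluate_accuracy(net, test)
      if (readout$rdm)
        tau_ret <- compare_rdms(compute_rdm(extract_activations(net, sub),
                                            condition = sprintf("retrained@%d", it)),
                                rdm_healthy)
      if (do_pred)
        pred_ret <- score_regions(net, sub, regions, readout$predictivity_config)$score
      records[[length(records) + 1]] <- data.frame(
        replicate = r, seed = rep_seed, iteration = it, injured_fraction = frac,
        accuracy_injured = acc_inj, accuracy_retrained = acc_ret,
        tau_injured = tau_inj, tau_retrained = tau_ret,
        pred_injured = pred_inj, pred_retrained = pred_ret)
    }
  }
  structure(list(records = do.call(rbind, records), schedule = schedule,
                 seeds = seeds, retrain_config = retrain_config,
                 readout = readout, baseline_accuracy = baseline_acc),
            class = "degeneration_result")
}

#' @export
print.degeneration_result <- function(x, ...) {
  cat(sprintf("<degeneration_result> gamma %.2f, %d iterations, %d replicate(s); baseline accuracy %.3f\n",
              x$schedule$gamma, x$schedule$n_iterations, length(x$seeds),
              x$baseline_accuracy))
  invisible(x)
}
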