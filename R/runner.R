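#' Full experiment configuration
#'
#' Bundles everything a degeneration experiment needs: the stimulus spec (or
#' a dataset directory), the network architecture, baseline and retraining
#' hyperparameters, the injury schedule, readout toggles, replicate seeds,
#' and an optional compression target for the parameter-optimized baseline.
#' Configurations serialize to YAML and round-trip losslessly, and every
#' random draw of a run is traceable to the seeds recorded here.
#'
#' @param stimulus a [stimulus_spec()] or a directory written by
#'   [write_dataset()].
#' @param network a [network_spec()].
#' @param schedule an [injury_schedule()].
#' @param baseline_training a [training_config()] for training the healthy
#'   baseline from scratch.
#' @param retrain_config a [training_config()] for each retraining phase.
#' @param readout a [readout_config()].
#' @param compress_target optional FLOP speedup factor; when set, the
#'   baseline is structurally pruned (and fine-tuned) before injury.
#' @param seeds replicate seeds.
#' @param output_dir directory for result files, or `NULL` to skip writing.
#' @return an object of class `run_config`.
#' @export
run_config <- function(stimulus, network, schedule = injury_schedule(),
                       baseline_training = training_config(),
                       retrain_config = training_config(),
                       readout = readout_config(),
                       compress_target = NULL, seeds = 1:3,
                       output_dir = NULL) {
  if (!inherits(stimulus, "stimulus_spec") && !is.character(stimulus))
    stop("'stimulus' must be a stimulus_spec or a dataset directory", call. = FALSE)
  stopifnot(inherits(network, "network_spec"), inherits(schedule, "injury_schedule"),
            inherits(baseline_training, "training_config"),
            inherits(retrain_config, "training_config"),
            inherits(readout, "readout_config"))
  if (!is.null(compress_target) && (!is.finite(compress_target) || compress_target < 1))
    stop("'compress_target' must be a speedup factor >= 1", call. = FALSE)
  if (length(seeds) < 1) stop("need at least one replicate seed", call. = FALSE)
  structure(list(stimulus = stimulus, network = network, schedule = schedule,
                 baseline_training = baseline_training,
                 retrain_config = retrain_config, readout = readout,
                 compress_target = compress_target,
                 seeds = as.integer(seeds), output_dir = output_dir),
            class = "run_config")
}

#' Desk-scale default configuration
#'
#' The package's reference study conditions: a 10-class procedural stimulus
#' set (16x16x3 pixels, 100 training and 30 test images per class, pixel
#' noise sd 0.1), the three-block [small_cnn_spec()] classifier, SGD with
#' learning rate 0.01 / momentum 0.9 / batch 64 (20 epochs for the baseline,
#' 3 epochs per retraining phase), the canonical injury schedule
#' `gamma = 0.2, n = 15`, and 3 replicates. A full run takes a few minutes on
#' one CPU core.
#'
#' @param seed master seed; stimulus and replicate seeds derive from it.
#' @param predictivity enable the neural-predictivity readout.
#' @param output_dir passed through to [run_config()].
#' @return a [run_config()].
#' @export
desk_run_config <- function(seed = 1L, predictivity = FALSE, output_dir = NULL) {
  run_config(
    stimulus = stimulus_spec(n_classes = 10, image_size = 16, n_channels = 3,
                             samples_per_class_train = 100,
                             samples_per_class_test = 30,
                             noise_sd = 0.1, seed = derive_seed(seed, 1L)),
    network = small_cnn_spec(n_classes = 10, input_size = 16),
    schedule = injury_schedule(gamma = 0.2, n_iterations = 15),
    baseline_training = training_config(learning_rate = 0.01, momentum = 0.9,
                                        batch_size = 64, epochs = 20,
                                        seed = derive_seed(seed, 2L)),
    retrain_config = training_config(learning_rate = 0.01, momentum = 0.9,
                                     batch_size = 64, epochs = 3),
    readout = readout_config(rdm = TRUE, rdm_per_class = 20,
                             predictivity = predictivity),
    seeds = derive_seed(seed, 3L) + 0:2,
    output_dir = output_dir
  )
}

#' Serialize a run configuration to / from YAML
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  strip <- function(x) { attributes(x) <- attributes(x)["names"]; x }
  obj <- list(
    stimulus = if (is.character(config$stimulus)) config$stimulus else strip(config$stimulus),
    network = list(input_shape = config$network$input_shape,
                   n_classes = config$network$n_classes,
                   layers = config$network$layers),
    schedule = strip(config$schedule),
    baseline_training = strip(config$baseline_training),
    retrain_config = strip(config$retrain_config),
    readout = {
      r <- strip(config$readout)
      r$predictivity_config <- strip(r$predictivity_config)
      r
    },
    compress_target = config$compress_target,
    seeds = config$seeds, output_dir = config$output_dir)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  o <- yaml::read_yaml(path)
  spec_layers <- lapply(o$network$layers, function(l) {
    switch(l$kind,
      conv = conv_spec(l$filters, l$kernel, l$padding, l$batch_norm, l$activation),
      pool = pool_spec(l$size),
      dense = dense_spec(l$units, l$activation))
  })
  ro <- o$readout
  run_config(
    stimulus = if (is.character(o$stimulus)) o$stimulus else do.call(stimulus_spec, o$stimulus),
    network = network_spec(spec_layers, unlist(o$network$input_shape), o$network$n_classes),
    schedule = do.call(injury_schedule, o$schedule),
    baseline_training = do.call(training_config, o$baseline_training),
    retrain_config = do.call(training_config, o$retrain_config),
    readout = readout_config(
      rdm = ro$rdm, rdm_per_class = ro$rdm_per_class,
      predictivity = ro$predictivity,
      predictivity_iterations = unlist(ro$predictivity_iterations),
      region_layers = ro$region_layers, n_neurons = ro$n_neurons,
      recordings_noise_sd = ro$recordings_noise_sd,
      predictivity_config = do.call(predictivity_config, ro$predictivity_config)),
    compress_target = o$compress_target,
    seeds = unlist(o$seeds), output_dir = o$output_dir)
}

#' Run a configured degeneration experiment end to end
#'
#' Generates (or loads) the dataset, trains the healthy baseline, optionally
#' compresses it to the configured FLOP speedup, runs the progressive
#' injury + retraining experiment, and (if `output_dir` is set) writes a tidy
#' results CSV (`results.csv`: replicate, iteration, injured_fraction,
#' metric, phase, value), a JSON run manifest, and a per-iteration summary
#' table. Identical configurations produce byte-identical CSV output.
#'
#' @param config a [run_config()].
#' @return the `degeneration_result`, with extra fields `baseline`,
#'   `compression` (if any), and `dataset` attached.
#' @export
run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dataset <- if (is.character(config$stimulus)) read_dataset(config$stimulus)
             else generate_dataset(config$stimulus)
  net <- build_network(config$network, seed = derive_seed(config$baseline_training$seed, 7L))
  trained <- train(net, dataset, config$baseline_training)
  baseline <- trained$network
  compression <- NULL
  if (!is.null(config$compress_target) && config$compress_target > 1) {
    ft <- config$retrain_config
    ft$epochs <- config$baseline_training$epochs
    ft$seed <- derive_seed(config$baseline_training$seed, 9L)
    compression <- compress_to_speedup(baseline, config$compress_target,
                                       dataset = dataset, finetune = ft)
    baseline <- compression$network
  }
  result <- run_degeneration_experiment(baseline, config$schedule, dataset,
                                        retrain_config = config$retrain_config,
                                        readout = config$readout,
                                        seeds = config$seeds)
  result$baseline <- baseline
  result$compression <- compression
  result$dataset <- dataset
  result$config <- config
  if (!is.null(config$output_dir)) write_result_files(result, config$output_dir)
  result
}

tidy_records <- function(records) {
  metrics <- list(accuracy = c("accuracy_injured", "accuracy_retrained"),
                  rdm_tau = c("tau_injured", "tau_retrained"),
                  predictivity = c("pred_injured", "pred_retrained"))
  rows <- list()
  for (m in names(metrics)) {
    for (ph in 1:2) {
      col <- metrics[[m]][ph]
      rows[[length(rows) + 1]] <- data.frame(
        replicate = records$replicate, iteration = records$iteration,
        injured_fraction = records$injured_fraction, metric = m,
        phase = c("injured", "retrained")[ph], value = records[[col]])
    }
  }
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$value), ]
  out <- out[order(out$metric, out$phase, out$replicate, out$iteration), ]
  rownames(out) <- NULL
  out
}

write_result_files <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(tidy_records(result$records), file.path(dir, "results.csv"),
            row.names = FALSE)
  s <- summarize_experiment(result)
  write.csv(s, file.path(dir, "summary.csv"), row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("plastinet")),
    schedule = list(gamma = result$schedule$gamma,
                    n_iterations = result$schedule$n_iterations),
    seeds = result$seeds,
    baseline_accuracy = result$baseline_accuracy,
    compressed = !is.null(result$compression),
    achieved_speedup = if (!is.null(result$compression)) result$compression$achieved_speedup)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Per-iteration summary of a degeneration experiment
#'
#' Means and standard deviations across replicates for every recorded metric
#' and phase, with injury levels labelled as cumulative percent of initial
#' synapses removed (computed from the schedule's `1 - (1 - gamma)^n`).
#'
#' @param result a `degeneration_result`, or a tidy results data frame /
#'   `results.csv` path produced by [run()].
#' @param schedule required when `result` is a data frame or path.
#' @return data frame with columns `iteration`, `injury_percent`, `metric`,
#'   `phase`, `mean`, `sd`, `n`.
#' @export
summarize_experiment <- function(result, schedule = NULL) {
  if (inherits(result, "degeneration_result")) {
    tidy <- tidy_records(result$records)
    schedule <- result$schedule
  } else if (is.character(result)) {
    tidy <- read.csv(result)
  } else tidy <- result
  if (is.null(schedule)) stop("'schedule' is required when summarizing raw records",
                              call. = FALSE)
  agg <- aggregate(value ~ iteration + metric + phase, data = tidy,
                   FUN = function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  out <- data.frame(iteration = agg$iteration,
                    injury_percent = round(100 * cumulative_injured_fraction(
                      schedule$gamma, agg$iteration), 1),
                    metric = agg$metric, phase = agg$phase,
                    mean = agg$value[, "mean"],
                    sd = ifelse(is.na(agg$value[, "sd"]), 0, agg$value[, "sd"]),
                    n = agg$value[, "n"])
  out <- out[order(out$metric, out$phase, out$iteration), ]
  rownames(out) <- NULL
  out
}

#' Benchmark-style report table at odd iterations
#'
#' Reformats a summary as one row per metric/phase with columns at the
#' canonical reporting iterations (1, 3, ..., 15 by default), headed by
#' cumulative injury percent — for `gamma = 0.2`: 20%, 48.8%, 67.2%, 79%,
#' 86.6%, 91.4%, 94.5%, 96.5%.
#'
#' @param result a `degeneration_result`.
#' @param iterations iterations to report as columns.
#' @return data frame; first two columns `metric` and `phase`, remaining
#'   columns named `"<percent>%"` holding `mean (sd)` strings.
#' @export
report_table <- function(result, iterations = seq(1, 15, by = 2)) {
  stopifnot(inherits(result, "degeneration_result"))
  s <- summarize_experiment(result)
  s <- s[s$iteration %in% iterations, ]
  combos <- unique(s[, c("metric", "phase")])
  pct <- round(100 * cumulative_injured_fraction(result$schedule$gamma, iterations), 1)
  out <- combos
  for (j in seq_along(iterations)) {
    col <- paste0(pct[j], "%")
    out[[col]] <- vapply(seq_len(nrow(combos)), function(i) {
      row <- s[s$metric == combos$metric[i] & s$phase == combos$phase[i] &
                 s$iteration == iterations[j], ]
      if (nrow(row) == 0) return(NA_character_)
      sprintf("%.3f (%.3f)", row$mean, row$sd)
    }, character(1))
  }
  rownames(out) <- NULL
  out
}
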