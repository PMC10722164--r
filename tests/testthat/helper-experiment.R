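# The shared desk-scale study: full and compressed baselines run once and
# reused by the acceptance suite. Conditions follow desk_run_config().

desk_study <- function() {
  memo("desk_study", {
    cfg <- desk_run_config(seed = 1, predictivity = TRUE)
    dataset <- generate_dataset(cfg$stimulus)
    net <- build_network(cfg$network,
                         seed = derive_seed(cfg$baseline_training$seed, 7L))
    baseline <- train(net, dataset, cfg$baseline_training)$network
    result <- run_degeneration_experiment(
      baseline, cfg$schedule, dataset,
      retrain_config = cfg$retrain_config, readout = cfg$readout,
      seeds = cfg$seeds)
    list(config = cfg, dataset = dataset, baseline = baseline, result = result)
  })
}

desk_compressed_study <- function() {
  memo("desk_compressed_study", {
    st <- desk_study()
    cfg <- st$config
    ft <- cfg$retrain_config
    ft$epochs <- 10L
    ft$seed <- derive_seed(cfg$baseline_training$seed, 9L)
    comp <- compress_to_speedup(st$baseline, 2, dataset = st$dataset,
                                finetune = ft)
    readout <- cfg$readout
    readout$predictivity <- FALSE
    result <- run_degeneration_experiment(
      comp$network, cfg$schedule, st$dataset,
      retrain_config = cfg$retrain_config, readout = readout,
      seeds = cfg$seeds + 50L)
    list(compression = comp, result = result)
  })
}

# per-iteration mean of a record column across replicates
iter_mean <- function(records, col, iterations) {
  vapply(iterations, function(it) {
    mean(records[[col]][records$iteration == it])
  }, numeric(1))
}
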