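test_that("masked weights stay exactly zero through momentum updates", {
  d <- tiny_dataset()
  net <- build_network(tiny_net_spec(), seed = 8)
  mask <- new_ablation_mask(net)
  # ablate one specific conv weight and one dense weight
  mask$masks[["conv1.W"]][3] <- TRUE
  mask$masks[["dense1.W"]][10] <- TRUE
  net <- apply_mask(net, mask)
  cfg <- training_config(learning_rate = 0.05, momentum = 0.9, batch_size = 160,
                         epochs = 1)
  for (step in 1:5) {
    cfg$seed <- step
    net <- train(net, d, cfg, mask = mask)$network
    expect_identical(net$layers[[1]]$W[3], 0)   # after every optimizer step
    dense_i <- which(network_layer_names(net) == "dense1")
    expect_identical(net$layers[[dense_i]]$W[10], 0)
    # unmasked neighbours moved
    expect_false(net$layers[[1]]$W[4] == 0)
  }
})

test_that("training under an all-FALSE mask equals plain training bitwise", {
  d <- tiny_dataset()
  net <- build_network(tiny_net_spec(), seed = 12)
  cfg <- training_config(learning_rate = 0.01, epochs = 2, batch_size = 32, seed = 5)
  plain <- train(net, d, cfg)$network
  masked <- train(net, d, cfg, mask = new_ablation_mask(net))$network
  expect_identical(plain$layers, masked$layers)
  # retrain() with an empty mask matches too
  re <- retrain(net, new_ablation_mask(net), d, cfg)
  expect_identical(plain$layers, re$layers)
})

test_that("a fully ablated network performs at chance even after retraining", {
  d <- tiny_dataset()
  net <- tiny_trained()
  mask <- apply_injury_step(new_ablation_mask(net), 1.0, seed = 3)
  re <- retrain(net, mask, d, training_config(epochs = 2, batch_size = 32))
  expect_equal(evaluate_accuracy(re, d), 0.25, tolerance = 1e-12)
})

test_that("degeneration experiments are reproducible and well-formed", {
  d <- tiny_dataset()
  net <- tiny_trained()
  sched <- injury_schedule(gamma = 0.3, n_iterations = 3)
  ro <- readout_config(rdm = TRUE, rdm_per_class = 8, predictivity = FALSE)
  cfg <- training_config(learning_rate = 0.01, epochs = 1, batch_size = 32)
  r1 <- run_degeneration_experiment(net, sched, d, retrain_config = cfg,
                                    readout = ro, seeds = c(4, 9))
  r2 <- run_degeneration_experiment(net, sched, d, retrain_config = cfg,
                                    readout = ro, seeds = c(4, 9))
  expect_identical(r1$records, r2$records)
  expect_equal(nrow(r1$records), 2 * (3 + 1))  # baseline + 3 iterations, 2 replicates
  # injured fraction non-decreasing within each replicate, accuracies in [0,1]
  for (rep in 1:2) {
    rr <- r1$records[r1$records$replicate == rep, ]
    expect_true(all(diff(rr$injured_fraction) >= 0))
  }
  expect_true(all(r1$records$accuracy_injured >= 0 & r1$records$accuracy_injured <= 1))
  # iteration 0 is the healthy baseline: tau = 1, both phases equal
  base_rows <- r1$records[r1$records$iteration == 0, ]
  expect_true(all(base_rows$tau_injured == 1 & base_rows$tau_retrained == 1))
  expect_equal(base_rows$accuracy_injured, base_rows$accuracy_retrained)
})

test_that("a zero-iteration schedule yields a baseline-only result", {
  d <- tiny_dataset()
  net <- tiny_trained()
  r <- run_degeneration_experiment(net, injury_schedule(0.2, 0), d,
                                   retrain_config = training_config(epochs = 1),
                                   readout = readout_config(rdm = FALSE),
                                   seeds = 1L)
  expect_equal(nrow(r$records), 1)
  expect_equal(r$records$iteration, 0)
  expect_equal(r$records$accuracy_injured, r$baseline_accuracy)
})

test_that("retraining recovers accuracy lost to injury (recovery property)", {
  d <- tiny_dataset()
  net <- tiny_trained()
  sched <- injury_schedule(gamma = 0.2, n_iterations = 4)
  cfg <- training_config(learning_rate = 0.01, epochs = 2, batch_size = 32)
  r <- run_degeneration_experiment(net, sched, d, retrain_config = cfg,
                                   readout = readout_config(rdm = FALSE),
                                   seeds = c(1, 2, 3))
  rr <- r$records[r$records$iteration > 0, ]
  gain <- rr$accuracy_retrained - rr$accuracy_injured
  expect_gt(mean(gain), 0)
  # one-sided paired sign test over iteration-by-replicate pairs
  n_pos <- sum(gain > 0); n_eff <- sum(gain != 0)
  p <- stats::pbinom(n_pos - 1, n_eff, 0.5, lower.tail = FALSE)
  expect_lt(p, 0.05)
})
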