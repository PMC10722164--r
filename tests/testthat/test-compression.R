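test_that("FLOP accounting matches hand formulas", {
  # single conv 3 -> 4 channels, 3x3 kernel, padding-preserving, 8x8 input
  spec <- network_spec(list(conv_spec(4, kernel = 3, padding = 1, batch_norm = FALSE),
                            dense_spec(2, "softmax")),
                       input_shape = c(8, 8, 3), n_classes = 2)
  fl <- estimate_flops(spec)
  conv_macs <- fl$table$macs[fl$table$layer == "conv1"]
  expect_equal(conv_macs, 3 * 4 * 9 * 64)  # 6912
  dense_macs <- fl$table$macs[fl$table$layer == "dense1"]
  expect_equal(dense_macs, 8 * 8 * 4 * 2)
  expect_equal(fl$total, conv_macs + dense_macs)
  # halving out_channels halves that layer's count
  spec2 <- network_spec(list(conv_spec(2, kernel = 3, padding = 1, batch_norm = FALSE),
                             dense_spec(2, "softmax")),
                        input_shape = c(8, 8, 3), n_classes = 2)
  expect_equal(estimate_flops(spec2)$table$macs[1], conv_macs / 2)
})

test_that("filters are ranked by ascending L1 norm with stable tie-breaks", {
  spec <- network_spec(list(conv_spec(3, kernel = 2, padding = 0, batch_norm = FALSE),
                            dense_spec(2, "softmax")),
                       input_shape = c(4, 4, 1), n_classes = 2)
  net <- build_network(spec, seed = 1)
  W <- net$layers[[1]]$W
  W[, , , 1] <- 0.5   # L1 = 2
  W[, , , 2] <- 0     # all-zero filter: must rank first
  W[, , , 3] <- 0.5   # identical to filter 1: tie broken by index
  net$layers[[1]]$W <- W
  rk <- rank_filters(net)
  conv_rows <- rk[rk$layer == "conv1", ]
  expect_equal(conv_rows$index[1], 2)
  tied <- conv_rows[conv_rows$l1 == 2, ]
  expect_equal(tied$index, c(1, 3))
  # hand-computed norms
  expect_equal(sort(conv_rows$l1), c(0, 2, 2))
})

test_that("target speedup 1 returns the network unchanged with an empty plan", {
  net <- tiny_trained()
  r <- compress_to_speedup(net, 1)
  expect_identical(r$network$layers, net$layers)
  expect_equal(length(r$plan$remove), 0)
  expect_equal(r$achieved_speedup, 1)
})

test_that("compression reaches the FLOP target and preserves a valid graph", {
  net <- tiny_trained()
  r <- compress_to_speedup(net, 2)
  expect_gte(r$achieved_speedup, 2)
  # FLOP verified against independent recomputation from the pruned spec
  expect_equal(estimate_flops(r$network)$total, r$flops_after, tolerance = 1e-9)
  # forward pass on random input runs without shape errors
  x <- array(runif(12 * 12 * 3 * 4), c(12, 12, 3, 4))
  out <- plastinet:::nn_forward(r$network, x)$out
  expect_equal(dim(out), c(4, 4))
  # parameter count matches recomputation from the pruned spec
  expect_equal(count_parameters(r$network)$total,
               count_parameters(r$network$spec)$total)
})

test_that("plans apply idempotently and reproducibly", {
  net <- tiny_trained()
  r <- compress_to_speedup(net, 1.5)
  p1 <- prune_network(net, r$plan)
  p2 <- prune_network(net, r$plan)
  expect_identical(p1$layers, p2$layers)
  expect_identical(vapply(p1$layers, function(l) length(l$W %||% 0), 1L),
                   vapply(r$network$layers, function(l) length(l$W %||% 0), 1L))
})

test_that("higher targets never retain more parameters", {
  net <- tiny_trained()
  base <- count_parameters(net)$eligible_total
  kept <- vapply(c(1, 1.5, 2, 3), function(tg) {
    count_parameters(compress_to_speedup(net, tg)$network)$eligible_total / base
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("unreachable targets fail reporting the best achievable factor", {
  net <- tiny_trained()
  expect_error(compress_to_speedup(net, 1e6), "best achievable")
  expect_error(compress_to_speedup(net, 0.5), ">= 1")
})

test_that("compressed and fine-tuned networks stay close to baseline accuracy", {
  d <- tiny_dataset()
  net <- tiny_trained()
  ft <- training_config(learning_rate = 0.01, momentum = 0.9, batch_size = 32,
                        epochs = 6, seed = 31)
  r <- compress_to_speedup(net, 2, dataset = d, finetune = ft)
  acc0 <- evaluate_accuracy(net, d)
  acc1 <- evaluate_accuracy(r$network, d)
  expect_gte(acc1, acc0 - 0.05)
})
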