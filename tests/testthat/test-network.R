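test_that("parameter accounting matches hand counts on a toy convolution", {
  spec <- network_spec(list(conv_spec(4, kernel = 3, batch_norm = FALSE),
                            dense_spec(2, "softmax")),
                       input_shape = c(5, 5, 3), n_classes = 2)
  net <- build_network(spec, seed = 1)
  acc <- count_parameters(net)
  conv_rows <- acc$table[acc$table$layer == "conv1", ]
  expect_equal(conv_rows$count[conv_rows$tensor == "W"], 3 * 4 * 3 * 3)  # 108
  expect_equal(conv_rows$count[conv_rows$tensor == "b"], 4)
  expect_false(conv_rows$eligible[conv_rows$tensor == "b"])
  expect_true(conv_rows$eligible[conv_rows$tensor == "W"])
})

test_that("parameter accounting agrees with brute-force enumeration", {
  for (spec in list(tiny_net_spec(), small_cnn_spec())) {
    net <- build_network(spec, seed = 2)
    for (policy in c("conv_dense", "all")) {
      acc <- count_parameters(net, policy)
      ref <- enumerate_parameters(net, policy)
      expect_equal(acc$total, ref$total)
      expect_equal(acc$eligible_total, ref$eligible)
      # spec-level counting agrees with the instantiated network
      acc_spec <- count_parameters(spec, policy)
      expect_equal(acc_spec$total, acc$total)
      expect_equal(acc_spec$eligible_total, acc$eligible_total)
    }
  }
})

test_that("the VGG19-class spec totals about 20.04 million parameters", {
  acc <- count_parameters(vgg19_bn_spec(n_classes = 10))
  expect_equal(acc$total, 20040522)
  expect_equal(round(acc$total / 1e6, 2), 20.04)
})

test_that("initialization is deterministic given the seed", {
  s <- tiny_net_spec()
  n1 <- build_network(s, seed = 9)
  n2 <- build_network(s, seed = 9)
  n3 <- build_network(s, seed = 10)
  expect_identical(n1$layers, n2$layers)
  expect_false(identical(n1$layers[[1]]$W, n3$layers[[1]]$W))
})

test_that("shape-inconsistent specs are rejected naming the layer", {
  expect_error(network_spec(list(conv_spec(4, kernel = 9, padding = 0),
                                 dense_spec(2, "softmax")),
                            c(6, 6, 3), 2), "layer 1")
  expect_error(network_spec(list(pool_spec(5), dense_spec(2, "softmax")),
                            c(6, 6, 3), 2), "layer 1")
  expect_error(network_spec(list(dense_spec(3)), c(4, 4, 1), 2), "last layer")
})

test_that("network specs round-trip through YAML", {
  spec <- tiny_net_spec()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_network_spec(spec, path)
  spec2 <- read_network_spec(path)
  expect_equal(spec2, spec)
})

test_that("training for zero epochs is a no-op with empty history", {
  d <- tiny_dataset()
  net <- build_network(tiny_net_spec(), seed = 3)
  r <- train(net, d, training_config(epochs = 0))
  expect_identical(r$network$layers, net$layers)
  expect_equal(nrow(r$history), 0)
})

test_that("training rejects empty data and out-of-range labels", {
  net <- build_network(tiny_net_spec(), seed = 3)
  empty <- list(x = array(0, c(12, 12, 3, 0)), y = integer(0))
  expect_error(train(net, empty, training_config(epochs = 1)), "empty")
  bad <- list(x = array(0.5, c(12, 12, 3, 2)), y = c(1L, 9L))
  expect_error(train(net, bad, training_config(epochs = 1)), "labels")
  expect_error(evaluate_accuracy(net, bad), "labels")
})

test_that("a small network learns the synthetic task well above chance", {
  net <- tiny_trained()
  acc <- evaluate_accuracy(net, tiny_dataset())
  expect_gt(acc, 0.8)
})

test_that("a constant-output network scores exactly chance on balanced data", {
  net <- build_network(tiny_net_spec(), seed = 4)
  # zero every weight and bias: logits identical for all classes and stimuli
  for (i in seq_along(net$layers)) {
    for (p in c("W", "b")) {
      if (!is.null(net$layers[[i]][[p]])) net$layers[[i]][[p]][] <- 0
    }
  }
  d <- tiny_dataset()
  expect_equal(evaluate_accuracy(net, d), 1 / 4)
})

test_that("accuracy matches brute-force enumeration on a hand-built set", {
  net <- tiny_trained()
  d <- tiny_dataset()
  idx <- c(2, 7, 11)
  small <- list(x = d$test$x[, , , idx, drop = FALSE], y = d$test$y[idx])
  probs <- plastinet:::nn_forward(net, small$x)$out
  by_hand <- mean(apply(probs, 1, which.max) == small$y)
  expect_equal(evaluate_accuracy(net, small), by_hand)
  # a perfect oracle labelling scores 1
  oracle <- list(x = small$x, y = apply(probs, 1, which.max))
  expect_equal(evaluate_accuracy(net, oracle), 1)
})

test_that("untrained networks score near chance over seeds", {
  d <- tiny_dataset()
  accs <- vapply(1:8, function(s) {
    evaluate_accuracy(build_network(tiny_net_spec(), seed = 100 + s), d)
  }, numeric(1))
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.25), 3 * max(se, 0.01))
})

test_that("activation extraction is row-ordered and duplicate-consistent", {
  net <- tiny_trained()
  d <- tiny_dataset()
  x <- d$test$x[, , , c(1, 5, 1), drop = FALSE]
  act <- extract_activations(net, x, layer = "penultimate")
  expect_equal(act$values[1, ], act$values[3, ])
  expect_false(isTRUE(all.equal(act$values[1, ], act$values[2, ])))
  expect_equal(nrow(act$values), 3)
})

test_that("unknown layer names are rejected listing valid ones", {
  net <- tiny_trained()
  x <- tiny_dataset()$test$x[, , , 1:2, drop = FALSE]
  expect_error(extract_activations(net, x, layer = "conv99"), "conv1")
})

test_that("convolution output matches a hand-computed convolution", {
  spec <- network_spec(list(conv_spec(2, kernel = 2, padding = 0,
                                      batch_norm = FALSE, activation = "linear"),
                            dense_spec(2, "softmax")),
                       input_shape = c(3, 3, 1), n_classes = 2)
  net <- build_network(spec, seed = 1)
  W <- array(c(1, 2, 3, 4, -1, 0, 1, 0.5), dim = c(2, 2, 1, 2))
  net$layers[[1]]$W <- W
  net$layers[[1]]$b <- c(0.5, -0.5)
  x <- array(seq(0.1, 0.9, by = 0.1), c(3, 3, 1, 1))
  out <- plastinet:::nn_forward(net, x, stop_at = "conv1")$out
  # direct summation oracle
  ref <- array(0, c(2, 2, 2, 1))
  for (f in 1:2) for (i in 1:2) for (j in 1:2) {
    patch <- x[i:(i + 1), j:(j + 1), 1, 1]
    ref[i, j, f, 1] <- sum(patch * W[, , 1, f]) + net$layers[[1]]$b[f]
  }
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("zero-weight zero-bias networks give all-zero pre-normalization activations", {
  spec <- network_spec(list(conv_spec(3, batch_norm = TRUE),
                            dense_spec(2, "softmax")),
                       input_shape = c(6, 6, 2), n_classes = 2)
  net <- build_network(spec, seed = 2)
  net$layers[[1]]$W[] <- 0
  net$layers[[1]]$b[] <- 0
  x <- array(runif(6 * 6 * 2 * 3), c(6, 6, 2, 3))
  out <- plastinet:::nn_forward(net, x, stop_at = "conv1")$out
  expect_true(all(out == 0))
})

test_that("evaluation mode is deterministic for fixed weights", {
  net <- tiny_trained()
  d <- tiny_dataset()
  a1 <- evaluate_accuracy(net, d)
  a2 <- evaluate_accuracy(net, d)
  expect_identical(a1, a2)
  act1 <- extract_activations(net, d$test$x[, , , 1:5, drop = FALSE])
  act2 <- extract_activations(net, d$test$x[, , , 1:5, drop = FALSE])
  expect_identical(act1$values, act2$values)
})
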