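# Small fixtures shared across test files. Everything is generated in code;
# heavyweight runs are memoised so several test files can share one result.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a 4-class, 12x12 stimulus set that trains in seconds
tiny_dataset <- function(seed = 11L) {
  memo(paste0("tiny_dataset_", seed), generate_dataset(stimulus_spec(
    n_classes = 4, image_size = 12, n_channels = 3,
    samples_per_class_train = 40, samples_per_class_test = 25,
    noise_sd = 0.08, seed = seed)))
}

tiny_net_spec <- function(n_classes = 4, input_size = 12) {
  network_spec(
    list(conv_spec(6), pool_spec(2), conv_spec(12), pool_spec(2),
         dense_spec(32, "relu"), dense_spec(n_classes, "softmax")),
    input_shape = c(input_size, input_size, 3), n_classes = n_classes)
}

# a trained tiny baseline shared by several suites
tiny_trained <- function() {
  memo("tiny_trained", {
    d <- tiny_dataset()
    net <- build_network(tiny_net_spec(), seed = 5L)
    cfg <- training_config(learning_rate = 0.01, momentum = 0.9,
                           batch_size = 32, epochs = 8, seed = 2L)
    train(net, d, cfg)$network
  })
}

# brute-force parameter enumeration, independent of count_parameters()
enumerate_parameters <- function(network, policy = "conv_dense") {
  total <- 0; eligible <- 0
  for (l in network$layers) {
    for (p in c("W", "b", "gamma", "beta")) {
      if (is.null(l[[p]])) next
      total <- total + length(l[[p]])
      is_mult <- p == "W" && l$type %in% c("conv", "dense")
      if (policy == "all" || is_mult) eligible <- eligible + length(l[[p]])
    }
  }
  list(total = total, eligible = eligible)
}

# O(n^2) pair-counting Kendall tau-b oracle
kendall_pairs <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# ridge one-vs-all linear classifier on raw pixels (learnability oracle)
linear_probe_accuracy <- function(dataset) {
  flat <- function(x) t(matrix(x, prod(dim(x)[1:3]), dim(x)[4]))
  Xtr <- flat(dataset$train$x); Xte <- flat(dataset$test$x)
  K <- max(dataset$train$y)
  Y <- outer(dataset$train$y, seq_len(K), "==") * 1
  G <- crossprod(Xtr) + diag(1e-2, ncol(Xtr))
  W <- solve(G, crossprod(Xtr, Y))
  pred <- max.col(Xte %*% W, ties.method = "first")
  mean(pred == dataset$test$y)
}
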