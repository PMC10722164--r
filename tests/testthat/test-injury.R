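test_that("cumulative injured fraction follows 1 - (1 - gamma)^n", {
  expect_equal(round(cumulative_injured_fraction(0.2, 3), 3), 0.488)
  expect_equal(round(cumulative_injured_fraction(0.2, 15), 3), 0.965)
  expect_equal(cumulative_injured_fraction(0.37, 0), 0)
  expect_equal(cumulative_injured_fraction(1.0, 1), 1)
  expect_error(cumulative_injured_fraction(0, 3), "gamma")
  expect_error(cumulative_injured_fraction(1.2, 3), "gamma")
})

test_that("remaining parameter counts reproduce the geometric decay", {
  expect_equal(round(remaining_parameter_count(20.04e6, 0.2, 8) / 1e6, 2), 3.36)
  expect_equal(round(remaining_parameter_count(20.04e6, 0.2, 15) / 1e6, 3), 0.705)
  expect_equal(remaining_parameter_count(12345, 0.5, 0), 12345)
})

test_that("each injury step ablates round(gamma * surviving) pooled entries", {
  spec <- network_spec(list(conv_spec(2, kernel = 3, padding = 0, batch_norm = FALSE),
                            dense_spec(2, "softmax")),
                       input_shape = c(7, 7, 2), n_classes = 2)
  net <- build_network(spec, seed = 1)
  mask <- new_ablation_mask(net)
  total <- sum(vapply(mask$masks, length, 1L))
  m1 <- apply_injury_step(mask, 0.2, seed = 4)
  s1 <- mask_summary(m1)
  expect_equal(s1$ablated[s1$tensor == "total"], round(0.2 * total))
  # gamma = 1 kills everything at once
  mall <- apply_injury_step(mask, 1.0, seed = 4)
  sall <- mask_summary(mall)
  expect_equal(sall$ablated[sall$tensor == "total"], total)
  # a dead network warns and no-ops
  expect_warning(m2 <- apply_injury_step(mall, 0.5, seed = 1), "no-op")
  expect_equal(mask_summary(m2)$ablated, sall$ablated)
})

test_that("masks are monotone and deterministic given the seed", {
  net <- build_network(tiny_net_spec(), seed = 1)
  m1 <- new_ablation_mask(net)
  m2 <- new_ablation_mask(net)
  prev <- m1
  for (it in 1:6) {
    m1 <- apply_injury_step(m1, 0.3, seed = 100 + it)
    m2 <- apply_injury_step(m2, 0.3, seed = 100 + it)
    for (nm in names(m1$masks)) {
      expect_true(all(m1$masks[[nm]][prev$masks[[nm]]]))  # once dead, stays dead
    }
    prev <- m1
  }
  expect_identical(m1$masks, m2$masks)
})

test_that("surviving counts follow the geometric recursion within rounding", {
  net <- build_network(network_spec(
    list(dense_spec(100, "relu"), dense_spec(10, "softmax")),
    c(10, 10, 1), 10), seed = 1)
  mask <- new_ablation_mask(net)
  total <- sum(vapply(mask$masks, length, 1L))  # 10000 + 1000
  surv_exact <- total
  mask_it <- mask
  for (it in 1:10) {
    mask_it <- apply_injury_step(mask_it, 0.2, seed = it)
    surv_exact <- surv_exact - round(0.2 * surv_exact)
    s <- mask_summary(mask_it)
    surv_obs <- total - s$ablated[s$tensor == "total"]
    expect_lte(abs(surv_obs - surv_exact), 1)
  }
  # realized trajectory tracks 1 - (1 - gamma)^n within n/total
  frac_obs <- 1 - surv_obs / total
  expect_lt(abs(frac_obs - cumulative_injured_fraction(0.2, 10)), 10 / total + 1e-3)
})

test_that("step-1 ablation is uniformly dispersed across coordinates", {
  net <- build_network(network_spec(
    list(dense_spec(23, "relu"), dense_spec(2, "softmax")),
    c(2, 2, 1), 2), seed = 1)
  mask0 <- new_ablation_mask(net)
  total <- sum(vapply(mask0$masks, length, 1L))
  n_rep <- 400
  hits <- numeric(total)
  for (r in seq_len(n_rep)) {
    m <- apply_injury_step(mask0, 0.2, seed = 5000 + r)
    hits <- hits + unlist(lapply(m$masks, as.numeric), use.names = FALSE)
  }
  k <- round(0.2 * total)
  p <- k / total
  chisq <- sum((hits - n_rep * p)^2) / (n_rep * p * (1 - p))
  # under uniformity, chisq ~ chi-square with about `total` df
  expect_lt(chisq, stats::qchisq(0.999, df = total))
  expect_gt(chisq, stats::qchisq(0.001, df = total))
})

test_that("apply_mask zeroes exactly the masked coordinates", {
  net <- build_network(tiny_net_spec(), seed = 6)
  mask <- apply_injury_step(new_ablation_mask(net), 0.25, seed = 77)
  netm <- apply_mask(net, mask)
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]; lm <- netm$layers[[i]]
    nm <- paste0(l$name %||% "", ".W")
    mk <- mask$masks[[nm]]
    if (is.null(mk)) next
    expect_true(all(lm$W[mk] == 0))
    expect_identical(lm$W[!mk], l$W[!mk])
  }
  # empty mask leaves the network bitwise unchanged
  expect_identical(apply_mask(net, new_ablation_mask(net))$layers, net$layers)
})

test_that("mask/network shape mismatches are rejected naming the tensor", {
  net <- build_network(tiny_net_spec(), seed = 6)
  other <- build_network(small_cnn_spec(), seed = 6)
  mask <- new_ablation_mask(other)
  expect_error(apply_mask(net, mask), "conv1.W")
})
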