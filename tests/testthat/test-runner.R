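test_that("injury-percent labels reproduce the canonical schedule table", {
  pct <- round(100 * cumulative_injured_fraction(0.2, seq(1, 15, by = 2)), 1)
  expect_equal(pct, c(20.0, 48.8, 67.2, 79.0, 86.6, 91.4, 94.5, 96.5))
})

test_that("summaries match hand arithmetic on a constructed two-replicate result", {
  tidy <- data.frame(
    replicate = rep(1:2, each = 2), iteration = rep(c(1, 2), 2),
    injured_fraction = rep(c(0.2, 0.36), 2), metric = "accuracy",
    phase = "retrained", value = c(0.9, 0.8, 0.7, 0.6))
  s <- summarize_experiment(tidy, schedule = injury_schedule(0.2, 2))
  r1 <- s[s$iteration == 1, ]
  expect_equal(r1$mean, mean(c(0.9, 0.7)))
  expect_equal(r1$sd, sd(c(0.9, 0.7)))
  expect_equal(r1$injury_percent, 20.0)
  expect_equal(s$n, c(2, 2))
  # a single replicate gives sd = 0
  s1 <- summarize_experiment(tidy[tidy$replicate == 1, ],
                             schedule = injury_schedule(0.2, 2))
  expect_true(all(s1$sd == 0))
})

test_that("run configurations round-trip through YAML", {
  cfg <- desk_run_config(seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$stimulus, cfg$stimulus)
  expect_equal(cfg2$network, cfg$network)
  expect_equal(cfg2$schedule, cfg$schedule)
  expect_equal(cfg2$baseline_training, cfg$baseline_training)
  expect_equal(cfg2$retrain_config, cfg$retrain_config)
  expect_equal(cfg2$seeds, cfg$seeds)
})

tiny_run_config <- function(outdir = NULL, n_iterations = 2) {
  run_config(
    stimulus = stimulus_spec(n_classes = 4, image_size = 12,
                             samples_per_class_train = 30,
                             samples_per_class_test = 15,
                             noise_sd = 0.08, seed = 3L),
    network = tiny_net_spec(),
    schedule = injury_schedule(0.25, n_iterations),
    baseline_training = training_config(learning_rate = 0.01, batch_size = 32,
                                        epochs = 4, seed = 6L),
    retrain_config = training_config(learning_rate = 0.01, batch_size = 32,
                                     epochs = 1),
    readout = readout_config(rdm = TRUE, rdm_per_class = 6),
    seeds = c(2L, 3L), output_dir = outdir)
}

test_that("a zero-iteration run yields a baseline-only report", {
  cfg <- tiny_run_config(n_iterations = 0)
  res <- run(cfg)
  expect_equal(nrow(res$records), length(cfg$seeds))
  expect_true(all(res$records$iteration == 0))
  s <- summarize_experiment(res)
  expect_true(all(s$iteration == 0))
})

test_that("identical run configurations write byte-identical result files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg1 <- tiny_run_config(d1)
  cfg2 <- tiny_run_config(d2)
  r1 <- run(cfg1)
  r2 <- run(cfg2)
  expect_identical(readLines(file.path(d1, "results.csv")),
                   readLines(file.path(d2, "results.csv")))
  expect_identical(readLines(file.path(d1, "summary.csv")),
                   readLines(file.path(d2, "summary.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  # tidy CSV has the documented grammar
  tidy <- utils::read.csv(file.path(d1, "results.csv"))
  expect_setequal(names(tidy), c("replicate", "iteration", "injured_fraction",
                                 "metric", "phase", "value"))
  expect_setequal(unique(tidy$phase), c("injured", "retrained"))
})

test_that("report tables label columns by cumulative injury percent", {
  cfg <- tiny_run_config(n_iterations = 3)
  res <- run(cfg)
  tab <- report_table(res, iterations = c(1, 3))
  expect_true(all(c("25%", "57.8%") %in% names(tab)))
  expect_true("accuracy" %in% tab$metric)
  acc_ret <- tab[tab$metric == "accuracy" & tab$phase == "retrained", "25%"]
  expect_match(acc_ret, "^\\d\\.\\d{3} \\(\\d\\.\\d{3}\\)$")
})

test_that("experiment summaries agree with the raw records", {
  cfg <- tiny_run_config(n_iterations = 2)
  res <- run(cfg)
  s <- summarize_experiment(res)
  acc1 <- res$records$accuracy_retrained[res$records$iteration == 1]
  row <- s[s$metric == "accuracy" & s$phase == "retrained" & s$iteration == 1, ]
  expect_equal(row$mean, mean(acc1))
  expect_equal(row$sd, sd(acc1))
})
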