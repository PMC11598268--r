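test_that("structural rank sweeps order reductions and validate inputs", {
  rep <- slr_sweep("cnn2d", ranks = c(8, 12, 16))
  tab <- rep$table
  expect_equal(colnames(tab),
               c("rank_8", "rank_12", "rank_16", "no_reduction"))
  expect_true(all(diff(tab["param_reduction_values", 1:3]) < 0))
  expect_true(all(diff(tab["param_reduction_with_indices", 1:3]) < 0))
  expect_equal(tab["param_reduction_values", "no_reduction"], 0)
  expect_error(slr_sweep("cnn2d", ranks = integer(0)), "non-empty")
  expect_error(slr_sweep("cnn2d", ranks = c(8, NA)), "non-empty|positive")

  # density 1 stores more than density 0.5 at the same rank
  a1 <- attr(param_account(build_cnn2d(11),
                           prune_config(c(FC6 = 8, FC7 = 8), density = 1)),
             "totals")[["stored_values"]]
  a5 <- attr(param_account(build_cnn2d(11),
                           prune_config(c(FC6 = 8, FC7 = 8), density = 0.5)),
             "totals")[["stored_values"]]
  expect_gt(a1, a5)
})

test_that("sweep reports export as CSV", {
  rep <- slr_sweep("cnn_lstm", ranks = c(4, 8))
  path <- withr::local_tempfile(fileext = ".csv")
  export_sweep_report(rep, path)
  back <- utils::read.csv(path)
  expect_equal(back$metric[nrow(back)], "param_reduction_with_indices")
  expect_equal(back$rank_4[back$metric == "param_reduction_values"],
               rep$table["param_reduction_values", "rank_4"])
})

test_that("size report totals agree with the parameter table", {
  out <- capture.output(acc <- size_report("cnn2d", num_classes = 11))
  expect_equal(attr(acc, "totals")[["original"]],
               sum(param_count_table(build_cnn2d(11))$params))
  expect_true(any(grepl("4 bytes/value", out)))
})

test_that("model containers round-trip byte- and prediction-identically", {
  toy <- toy_separable(n = 60)
  model <- train_model(mlp_spec(), toy$x, toy$y,
                       hyper_params(epochs = 10, seed = 6))
  pruned <- prune_model(model, prune_config(c(FC6 = 2, FC7 = 3), 0.5))
  p1 <- file.path(withr::local_tempdir(), "m1.rds")
  p2 <- file.path(withr::local_tempdir(), "m2.rds")
  save_pruned_model(pruned, p1)
  expect_true(file.exists(paste0(p1, ".manifest.json")))
  back <- load_pruned_model(p1)
  save_pruned_model(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_identical(predict(back, toy$x), predict(pruned, toy$x))
  man <- jsonlite::read_json(paste0(p1, ".manifest.json"))
  expect_equal(unlist(man$pruned_layers), c("FC6", "FC7"))
  # unpruned models round-trip too
  save_pruned_model(model, p2)
  back0 <- load_pruned_model(p2)
  expect_identical(predict(back0, toy$x), predict(model, toy$x))
})

test_that("the synthetic experiment writes reports, containers and manifest", {
  dir <- withr::local_tempdir()
  cfg <- list(n_per_class = 2, n_frames = 12, H = 18, W = 18,
              models = c("cnn2d", "cnn_lstm"), k_folds = 2,
              ranks = c(FC6 = 2, FC7 = 2), epochs = 1, batch_size = 8,
              seed = 3, out_dir = dir)
  res <- run_synthetic_experiment(cfg)
  expect_true(file.exists(file.path(dir, "cv_cnn2d.csv")))
  expect_true(file.exists(file.path(dir, "cv_cnn_lstm.csv")))
  expect_true(file.exists(file.path(dir, "model_cnn2d_pruned.rds")))
  expect_true(file.exists(file.path(dir, "model_cnn_lstm_pruned.rds")))
  man <- jsonlite::read_json(file.path(dir, "run_manifest.json"))
  expect_equal(man$config$seed, 3)
  expect_equal(nrow(res$results$cnn2d$cv$folds), 2)
  expect_error(run_synthetic_experiment(list(bogus = 1)),
               "unknown config field: bogus")
  expect_error(run_synthetic_experiment("no/such/file.yaml"), "not readable")
})

test_that("the CLI returns documented exit codes", {
  expect_equal(capture_status(c("size", "--model", "cnn2d")), 0L)
  expect_equal(capture_status(c("sweep", "--model", "cnn2d",
                                "--ranks", "4,8")), 0L)
  expect_equal(capture_status(character(0)), 2L)
  expect_equal(capture_status("frobnicate"), 2L)
  expect_equal(capture_status(c("sweep", "--model", "cnn2d")), 2L)
  expect_equal(capture_status(c("build", "--model", "cnn_lstm",
                                "--classes", "5")), 0L)
})
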