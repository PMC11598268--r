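test_that("confusion metrics match hand counts", {
  m <- confusion_metrics(c(1, 1, 2, 2), c(1, 1, 2, 2), 2)
  expect_equal(m$accuracy, 1)
  expect_equal(m$precision_macro, 1)
  expect_equal(m$recall_micro, 1)

  # rows truth: [[2,1],[1,2]]
  m <- confusion_metrics(c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 2, 2, 1), 2)
  expect_equal(m$confusion, matrix(c(2L, 1L, 1L, 2L), 2))
  expect_equal(m$accuracy, 4 / 6)
  expect_equal(m$precision_macro, 2 / 3)
  expect_equal(m$recall_macro, 2 / 3)

  expect_error(confusion_metrics(integer(0), integer(0), 2), "empty")
  expect_error(confusion_metrics(1:3, 1:2, 3), "3 true vs 2")
  expect_error(confusion_metrics(c(1, 4), c(1, 1), 3), "1..3")
})

test_that("micro precision, micro recall and accuracy coincide exactly", {
  set.seed(13)
  for (i in 1:25) {
    K <- sample(2:6, 1)
    n <- sample(5:60, 1)
    y <- sample(K, n, replace = TRUE)
    p <- sample(K, n, replace = TRUE)
    m <- confusion_metrics(y, p, K)
    expect_identical(m$precision_micro, m$accuracy)
    expect_identical(m$recall_micro, m$accuracy)
  }
})

test_that("macro averaging excludes classes absent from the truth", {
  # class 3 never occurs in the truth
  m <- confusion_metrics(c(1, 1, 2), c(1, 3, 2), 3)
  expect_equal(m$recall_macro, mean(c(1 / 2, 1)))
})

test_that("stratified folds partition the data exactly once", {
  y <- rep(1:3, each = 10)
  folds <- slrprune:::fold_assignment(y, 10, seed = 2)
  expect_equal(sort(unique(folds)), 1:10)
  expect_true(all(table(folds) == 3))
  # stratification: every fold holds one sample of each class
  for (f in 1:10) expect_equal(sort(y[folds == f]), 1:3)
  # reproducible
  expect_identical(folds, slrprune:::fold_assignment(y, 10, seed = 2))
  expect_warning(slrprune:::fold_assignment(rep(1:2, c(5, 25)), 10, seed = 1),
                 "unstratified")
})

test_that("constant predictions score the majority share of each fold", {
  set.seed(4)
  y <- sample(1:3, 30, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  folds <- slrprune:::fold_assignment(y, 5, seed = 3)
  for (f in 1:5) {
    yt <- y[folds == f]
    m <- confusion_metrics(yt, rep(1L, length(yt)), 3)
    expect_equal(m$accuracy, sum(yt == 1L) / length(yt))
  }
})

test_that("k-fold cross-validation trains and evaluates every sample once", {
  toy <- toy_separable(n = 60)
  cv <- kfold_cv(mlp_spec(), toy$x, toy$y, k = 5,
                 hp = hyper_params(epochs = 30, seed = 2), seed = 7)
  expect_equal(nrow(cv$folds), 5)
  expect_true(all(cv$folds$accuracy >= 0 & cv$folds$accuracy <= 1))
  expect_gt(cv$mean[["accuracy"]], 0.7)
  expect_equal(sort(unique(cv$assignment)), 1:5)
  # builder-function interface
  cv2 <- kfold_cv(function(K) mlp_spec(K), toy$x, toy$y, k = 5,
                  hp = hyper_params(epochs = 30, seed = 2), seed = 7)
  expect_identical(cv$folds, cv2$folds)
})

test_that("cross-validation results export as CSV and JSON", {
  toy <- toy_separable(n = 30)
  cv <- kfold_cv(mlp_spec(), toy$x, toy$y, k = 3,
                 hp = hyper_params(epochs = 3, seed = 2), seed = 7)
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  export_cv_result(cv, csv = csv, json = json)
  back <- utils::read.csv(csv)
  expect_equal(back$accuracy, cv$folds$accuracy)
  js <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(js$mean$accuracy, unname(cv$mean[["accuracy"]]))
})

test_that("lossless pruning leaves predictions and metrics unchanged", {
  toy <- toy_separable(n = 80)
  cmp <- prune_and_compare(mlp_spec(), toy$x, toy$y,
                           prune_config(c(FC6 = 4, FC7 = 8), density = 1),
                           hp = hyper_params(epochs = 15, seed = 3))
  expect_lt(abs(cmp$original$accuracy - cmp$pruned$accuracy), 1e-6)
  expect_lt(abs(cmp$original$recall_macro - cmp$pruned$recall_macro), 1e-6)
})

test_that("pruning touches only the configured layers", {
  set.seed(5)
  x <- array(runif(18 * 18 * 6 * 12), c(18, 18, 6, 12))
  y <- rep(1:3, 4)
  model <- train_model(tiny_cnn2d_spec(), x, y,
                       hyper_params(epochs = 1, batch_size = 6, seed = 2))
  pruned <- prune_model(model, prune_config(c(FC6 = 2, FC7 = 2), 0.5))
  nm <- vapply(model$layers, function(l) l$spec$name, "")
  for (i in which(!nm %in% c("FC6", "FC7"))) {
    expect_identical(pruned$layers[[i]]$params, model$layers[[i]]$params)
  }
  expect_true(pruned$layers[[match("FC6", nm)]]$pruned)
  # stored counts grow with rank
  p2 <- prune_model(model, prune_config(c(FC6 = 4, FC7 = 4), 0.5))
  t1 <- attr(pruned$account, "totals")[["stored_values"]]
  t2 <- attr(p2$account, "totals")[["stored_values"]]
  expect_gt(t2, t1)
})
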