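#' Classification metrics from predicted and true labels
#'
#' Builds the confusion matrix (rows: truth, columns: prediction) and
#' computes accuracy plus micro- and macro-averaged precision and recall.
#' Micro averaging pools per-sample counts, so for single-label multiclass
#' data micro precision, micro recall and accuracy coincide exactly. Macro
#' averaging takes the unweighted mean of per-class values; classes absent
#' from the truth are excluded from the macro means, and a class that is
#' never predicted contributes precision 0.
#'
#' @param y_true integer labels in `1..n_classes` (or factor).
#' @param y_pred integer labels in `1..n_classes` (or factor).
#' @param n_classes number of classes.
#' @return An object of class `class_metrics`: accuracy, `precision_micro`,
#'   `recall_micro`, `precision_macro`, `recall_macro`, and the integer
#'   `confusion` matrix.
#' @examples
#' confusion_metrics(c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 2, 2, 1), 2)
#' @export
confusion_metrics <- function(y_true, y_pred, n_classes) {
  y_true <- as.integer(if (is.factor(y_true)) unclass(y_true) else y_true)
  y_pred <- as.integer(if (is.factor(y_pred)) unclass(y_pred) else y_pred)
  if (length(y_true) == 0L) stop("empty evaluation", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop_dim("%d true vs %d predicted labels", length(y_true), length(y_pred))
  }
  if (any(c(y_true, y_pred) < 1L | c(y_true, y_pred) > n_classes)) {
    stop(sprintf("labels must lie in 1..%d", n_classes), call. = FALSE)
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  tp <- diag(cm)
  row_tot <- rowSums(cm)   # true counts per class
  col_tot <- colSums(cm)   # predicted counts per class
  present <- row_tot > 0L
  acc <- sum(tp) / sum(cm)
  prec_c <- ifelse(col_tot > 0L, tp / col_tot, 0)
  rec_c <- ifelse(row_tot > 0L, tp / row_tot, 0)
  structure(list(
    accuracy = acc,
    precision_micro = sum(tp) / sum(col_tot),
    recall_micro = sum(tp) / sum(row_tot),
    precision_macro = mean(prec_c[present]),
    recall_macro = mean(rec_c[present]),
    confusion = cm), class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | micro P/R %.4f/%.4f | macro P/R %.4f/%.4f\n",
    x$accuracy, x$precision_micro, x$recall_micro,
    x$precision_macro, x$recall_macro))
  invisible(x)
}

metrics_row <- function(m) {
  data.frame(accuracy = m$accuracy,
             precision_micro = m$precision_micro,
             recall_micro = m$recall_micro,
             precision_macro = m$precision_macro,
             recall_macro = m$recall_macro)
}

# stratified fold assignment; falls back to unstratified with a warning when
# some class has fewer members than folds
fold_assignment <- function(y, k, seed) {
  set.seed(seed)
  n <- length(y)
  folds <- integer(n)
  if (min(table(y)) < k) {
    warning("a class has fewer members than folds; using unstratified folds",
            call. = FALSE)
    folds <- sample(rep_len(seq_len(k), n))
  } else {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  }
  folds
}

#' Stratified k-fold cross-validation
#'
#' Partitions the data into `k` stratified folds, trains a fresh model on
#' each training split and evaluates on the held-out fold, so every sample
#' is tested exactly once.
#'
#' @param spec a `model_spec`, or a function `(num_classes) -> model_spec`.
#' @param x input array/matrix in the model's layout.
#' @param y integer labels in `1..num_classes`.
#' @param k number of folds (default 10).
#' @param hp a [hyper_params()]; fold `f` trains with seed `hp$seed + f`.
#' @param seed seed for the fold assignment.
#' @return An object of class `cv_result`: data frame `folds` (one metrics
#'   row per fold), `mean` and `sd` per metric, and the fold assignment.
#' @export
kfold_cv <- function(spec, x, y, k = 10, hp = hyper_params(), seed = 1) {
  y <- as.integer(if (is.factor(y)) unclass(y) else y)
  n <- length(y)
  if (n < k) stop("need at least k samples", call. = FALSE)
  if (is.function(spec)) spec <- spec(max(y))
  stopifnot(inherits(spec, "model_spec"))
  folds <- fold_assignment(y, k, seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    hp_f <- hp
    hp_f$seed <- hp$seed + f
    model <- train_model(spec, slice_input(x, train), y[train], hp_f)
    pred <- predict(model, slice_input(x, test), type = "class")
    rows[[f]] <- cbind(fold = f,
                       metrics_row(confusion_metrics(y[test], pred,
                                                     spec$num_classes)))
  }
  tab <- do.call(rbind, rows)
  structure(list(folds = tab,
                 mean = colMeans(tab[-1L]),
                 sd = apply(tab[-1L], 2L, stats::sd),
                 assignment = folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (fold seed %d)\n",
              nrow(x$folds), x$seed))
  print.data.frame(x$folds, row.names = FALSE, digits = 4)
  cat("mean:\n")
  print(round(x$mean, 4))
  invisible(x)
}

#' Export cross-validation results
#'
#' Writes one CSV row per fold and a JSON summary (means, standard
#' deviations, fold seed).
#'
#' @param cv a `cv_result`.
#' @param csv,json output paths (`NULL` to skip either).
#' @return invisibly, the paths written.
#' @export
export_cv_result <- function(cv, csv = NULL, json = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  if (!is.null(csv)) {
    utils::write.csv(cv$folds, csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(mean = as.list(cv$mean), sd = as.list(cv$sd),
                              fold_seed = cv$seed),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv = csv, json = json))
}

#' Train once, then compare original vs SLR-pruned predictions
#'
#' Splits the data into stratified train/test parts, trains one model,
#' evaluates it, prunes the trained weights per `config` and re-evaluates
#' the pruned model on the same test data.
#'
#' @param spec a `model_spec`.
#' @param x,y data in the model's layout.
#' @param config a [prune_config()].
#' @param hp a [hyper_params()].
#' @param test_fraction held-out fraction (stratified).
#' @param model optionally, an already trained `fallnet_model` to reuse
#'   (its spec must match); training is then skipped.
#' @return list with `class_metrics` fields `original` and `pruned`, the
#'   `param_account`, the trained `model`, the pruned model and the test
#'   indices.
#' @export
prune_and_compare <- function(spec, x, y, config, hp = hyper_params(),
                              test_fraction = 0.2, model = NULL) {
  y <- as.integer(if (is.factor(y)) unclass(y) else y)
  folds <- fold_assignment(y, k = max(2L, round(1 / test_fraction)),
                           seed = hp$seed)
  test <- which(folds == 1L)
  train <- which(folds != 1L)
  if (is.null(model)) {
    model <- train_model(spec, slice_input(x, train), y[train], hp)
  }
  xt <- slice_input(x, test)
  pred0 <- predict(model, xt, type = "class")
  pruned <- prune_model(model, config)
  pred1 <- predict(pruned, xt, type = "class")
  list(original = confusion_metrics(y[test], pred0, spec$num_classes),
       pruned = confusion_metrics(y[test], pred1, spec$num_classes),
       account = pruned$account,
       model = model, pruned_model = pruned, test_idx = test)
}
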