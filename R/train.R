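#' Training hyper-parameters
#'
#' Defaults follow the reference training protocol: Adadelta with learning
#' rate 0.98, categorical cross-entropy loss, batch size 32, 50 epochs.
#' Adadelta's decay and stabiliser are rho = 0.95 and eps = 1e-7.
#'
#' @param optimizer only `"adadelta"` is implemented.
#' @param learning_rate positive scaling of the Adadelta update.
#' @param loss only `"categorical_crossentropy"` is implemented.
#' @param batch_size mini-batch size.
#' @param epochs number of passes over the training data.
#' @param seed integer seed controlling initialization, shuffling and dropout.
#' @return An object of class `hyper_params`.
#' @export
hyper_params <- function(optimizer = "adadelta", learning_rate = 0.98,
                         loss = "categorical_crossentropy",
                         batch_size = 32, epochs = 50, seed = 1) {
  optimizer <- match.arg(optimizer, "adadelta")
  loss <- match.arg(loss, "categorical_crossentropy")
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 0)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 loss = loss, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "hyper_params")
}

n_samples <- function(x) {
  if (is.matrix(x)) nrow(x) else dim(x)[length(dim(x))]
}

slice_input <- function(x, idx) {
  if (is.matrix(x)) return(x[idx, , drop = FALSE])
  d <- length(dim(x))
  if (d == 4L) x[, , , idx, drop = FALSE] else x[, , idx, drop = FALSE]
}

check_input_shape <- function(spec, x) {
  expected <- if (spec$name == "cnn2d") {
    c(spec$input_shape[2L], spec$input_shape[3L],
      spec$input_shape[4L] * spec$input_shape[1L])
  } else if (spec$name == "cnn_lstm") {
    spec$input_shape
  } else {
    spec$input_shape
  }
  got <- if (is.matrix(x)) ncol(x) else dim(x)[-length(dim(x))]
  if (!identical(as.integer(got), as.integer(expected))) {
    stop_dim("input shape (%s) does not match model '%s' input (%s)",
             paste(got, collapse = "x"), spec$name,
             paste(expected, collapse = "x"))
  }
  invisible(TRUE)
}

#' Train a network
#'
#' Mini-batch Adadelta training with categorical cross-entropy. All
#' randomness (weight initialization, epoch shuffling, dropout masks)
#' derives from `hp$seed`, so a repeated call returns identical weights.
#'
#' @param spec a `model_spec`.
#' @param x input array in the model's layout: `(H, W, C, B)` for the
#'   2D-CNN (see [dataset_to_cnn2d()]), `(T, F, B)` for the CNN-LSTM.
#' @param y integer class labels in `1..num_classes` (or a factor).
#' @param hp a [hyper_params()] object.
#' @param verbose print per-epoch loss.
#' @return A trained `fallnet_model`; `$history` holds the per-epoch mean
#'   training loss (length `hp$epochs`).
#' @export
train_model <- function(spec, x, y, hp = hyper_params(), verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(hp, "hyper_params"))
  check_input_shape(spec, x)
  y <- as.integer(if (is.factor(y)) unclass(y) else y)
  n <- n_samples(x)
  if (length(y) != n) stop_dim("%d labels for %d samples", length(y), n)
  if (any(y < 1L | y > spec$num_classes)) {
    stop(sprintf("labels must lie in 1..%d", spec$num_classes), call. = FALSE)
  }
  set.seed(hp$seed)
  net <- init_network(spec)
  net$hp <- hp
  if (hp$epochs == 0L) {
    net$history <- numeric(0)
    return(net)
  }
  K <- spec$num_classes
  history <- numeric(hp$epochs)
  state <- adadelta_init(net)
  for (epoch in seq_len(hp$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = hp$batch_size)) {
      bi <- ord[start:min(start + hp$batch_size - 1L, n)]
      xb <- slice_input(x, bi)
      yb <- y[bi]
      fw <- net_forward(net, xb, training = TRUE, keep_cache = TRUE)
      p <- fw$out
      loss <- -mean(log(pmax(p[cbind(seq_along(bi), yb)], 1e-12)))
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss)", call. = FALSE)
      }
      losses <- c(losses, loss)
      Yb <- matrix(0, length(bi), K)
      Yb[cbind(seq_along(bi), yb)] <- 1
      dlogits <- (p - Yb) / length(bi)
      grads <- net_backward(net, fw$caches, dlogits)
      # update batch-norm running statistics; exponential moving averages
      # with bias correction so inference works after short trainings
      for (nm in names(fw$bn_updates)) {
        i <- as.integer(nm)
        u <- fw$bn_updates[[nm]]
        st_l <- net$layers[[i]]
        cnt <- (st_l$bn_count %||% 0L) + 1L
        raw_m <- bn_momentum * (st_l$bn_raw_mean %||% 0) +
          (1 - bn_momentum) * u$mean
        raw_v <- bn_momentum * (st_l$bn_raw_var %||% 0) +
          (1 - bn_momentum) * u$var
        corr <- 1 - bn_momentum^cnt
        net$layers[[i]]$bn_count <- cnt
        net$layers[[i]]$bn_raw_mean <- raw_m
        net$layers[[i]]$bn_raw_var <- raw_v
        net$layers[[i]]$run_mean <- raw_m / corr
        net$layers[[i]]$run_var <- raw_v / corr
      }
      st <- adadelta_step(net, grads, state, hp$learning_rate)
      net <- st$net
      state <- st$state
    }
    history[epoch] <- mean(losses)
    if (verbose) {
      message(sprintf("epoch %d/%d  loss %.4f", epoch, hp$epochs,
                      history[epoch]))
    }
  }
  net$history <- history
  net
}

#' Predict from a trained network
#'
#' @param object a `fallnet_model`.
#' @param x input array/matrix in the model's layout.
#' @param type `"prob"` for class probabilities, `"class"` for hard labels.
#' @param batch_size samples per forward chunk.
#' @param ... unused.
#' @return probability matrix (samples x classes) or integer label vector.
#' @export
predict.fallnet_model <- function(object, x, type = c("prob", "class"),
                                  batch_size = 64, ...) {
  type <- match.arg(type)
  check_input_shape(object$spec, x)
  n <- n_samples(x)
  out <- matrix(0, n, object$spec$num_classes)
  for (start in seq(1L, n, by = batch_size)) {
    bi <- start:min(start + batch_size - 1L, n)
    out[bi, ] <- net_forward(object, slice_input(x, bi))$out
  }
  if (type == "class") max.col(out, ties.method = "first") else out
}

#' Apply SLR pruning to a trained network
#'
#' Replaces each configured dense layer's weight matrix by its sparse
#' low-rank factors; every other layer is left untouched (bit-identical
#' weights). The final classifier is rejected by [prune_config()] policy.
#'
#' @param model a trained `fallnet_model`.
#' @param config a [prune_config()].
#' @return The pruned `fallnet_model` (inference-only); field `$account`
#'   holds the [param_account()] of the pruning.
#' @export
prune_model <- function(model, config) {
  stopifnot(inherits(model, "fallnet_model"), inherits(config, "prune_config"))
  check_prunable(model$spec, config)
  for (nm in names(config$layer_ranks)) {
    i <- match(nm, vapply(model$spec$layers, function(l) l$name, ""))
    st <- model$layers[[i]]
    lyr <- dense_layer(st$params$W, st$params$b, name = nm)
    model$layers[[i]]$slr <- slr_prune(lyr, config$layer_ranks[[nm]],
                                       config$density)
    model$layers[[i]]$pruned <- TRUE
    model$layers[[i]]$params <- NULL
  }
  model$account <- param_account(model$spec, config)
  model$prune_config <- config
  model
}
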