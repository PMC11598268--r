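# Minimal executable network engine for the two backbones.
#
# Layout conventions (column-major friendly, batch last):
#   2D path:   activations are (H, W, C, B) arrays
#   1D path:   activations are (T, F, B) arrays
#   dense head: (B, features) matrices
# Convolutions are "valid", stride 1, implemented with im2col so the inner
# product runs through BLAS. Max pooling is window 2 / stride 2 with floor
# division; ties send the gradient to the earliest element of the window.

# ---- initialization ---------------------------------------------------------

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Instantiate an executable network from a model spec
#'
#' Allocates weights for every layer of the spec using uniform fan-based
#' (Glorot) initialization driven by the current RNG state (call
#' `set.seed()` first, or use [train_model()] which seeds everything from
#' its hyper-parameters). LSTM forget-gate biases start at 1.
#'
#' @param spec a `model_spec` built by [build_cnn2d()] or [build_cnn_lstm()].
#' @param init_params draw initial weights (set `FALSE` to allocate a
#'   zero-weight skeleton without touching the RNG, e.g. before loading
#'   saved weights).
#' @return An object of class `fallnet_model` (untrained).
#' @export
init_network <- function(spec, init_params = TRUE) {
  glorot_ <- if (init_params) glorot else function(nr, nc, ...) matrix(0, nr, nc)
  stopifnot(inherits(spec, "model_spec"))
  shapes <- shape_propagate(spec)
  if (identical(spec$conventions$flatten, "table")) {
    # the nominal-width convention is for accounting; an executable model
    # needs the propagated flatten width
    prop <- spec
    prop$conventions$flatten <- "propagated"
    ps <- shape_propagate(prop)
    fl <- match("flatten", shapes$kind)
    if (!is.na(fl) && ps$size[fl] != shapes$size[fl]) {
      stop(sprintf(
        "spec uses the nominal flatten width %d but shape propagation gives %d; rebuild with flatten = \"propagated\" to get an executable model",
        shapes$size[fl], ps$size[fl]), call. = FALSE)
    }
  }
  shape <- if (spec$name == "cnn2d") {
    c(spec$input_shape[2L], spec$input_shape[3L],
      spec$input_shape[4L] * spec$input_shape[1L])
  } else {
    spec$input_shape
  }
  layers <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    st <- list(spec = l, in_shape = shape)
    st$params <- switch(l$kind,
      conv2d = {
        k <- l$kernel; cin <- shape[3L]; cout <- l$units
        list(W = glorot_(k * k * cin, cout, k * k * cin, k * k * cout),
             b = numeric(cout))
      },
      conv1d = {
        k <- l$kernel; cin <- shape[2L]; cout <- l$units
        list(W = glorot_(k * cin, cout, k * cin, k * cout),
             b = numeric(cout))
      },
      batchnorm = {
        ch <- shape[length(shape)]
        list(gamma = rep(1, ch), beta = numeric(ch))
      },
      dense = {
        m <- shape[1L]; n <- l$units
        list(W = glorot_(m, n, m, n), b = numeric(n))
      },
      lstm = {
        f <- shape[2L]; u <- l$units
        b <- numeric(4L * u)
        b[(u + 1L):(2L * u)] <- 1  # forget gate bias
        list(W = glorot_(f, 4L * u, f, 4L * u),
             R = glorot_(u, 4L * u, u, 4L * u),
             b = b)
      },
      NULL
    )
    if (l$kind == "batchnorm") {
      ch <- shape[length(shape)]
      st$run_mean <- numeric(ch)
      st$run_var <- rep(1, ch)
    }
    shape <- shape_after(l, shape, spec)
    st$out_shape <- shape
    layers[[i]] <- st
  }
  structure(list(spec = spec, layers = layers, history = NULL),
            class = "fallnet_model")
}

#' @export
print.fallnet_model <- function(x, ...) {
  cat(sprintf("fallnet_model '%s' (%d classes, %s)\n",
              x$spec$name, x$spec$num_classes,
              if (is.null(x$history)) "untrained" else
                sprintf("trained %d epochs, final loss %.4f",
                        length(x$history), x$history[length(x$history)])))
  pruned <- vapply(x$layers, function(l) isTRUE(l$pruned), TRUE)
  if (any(pruned)) {
    nm <- vapply(x$layers[pruned], function(l) l$spec$name, "")
    ks <- vapply(x$layers[pruned], function(l) l$slr$k, 1L)
    cat("SLR-pruned layers:",
        paste(sprintf("%s (rank %d)", nm, ks), collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- im2col -----------------------------------------------------------------

im2col_index <- function(H, W, C, k) {
  Ho <- H - k + 1L; Wo <- W - k + 1L
  base <- rep(seq_len(Ho), Wo) + (rep(seq_len(Wo), each = Ho) - 1L) * H
  offs <- as.vector(outer(
    as.vector(outer(seq_len(k) - 1L, (seq_len(k) - 1L) * H, "+")),
    (seq_len(C) - 1L) * H * W, "+"))
  # P x K matrix of element indices into an (H, W, C) sample
  matrix(rep(base, length(offs)) + rep(offs, each = length(base)),
         nrow = Ho * Wo)
}

im2col_index_1d <- function(Tn, Fn, k) {
  P <- Tn - k + 1L
  offs <- as.vector(outer(seq_len(k) - 1L, (seq_len(Fn) - 1L) * Tn, "+"))
  matrix(rep(seq_len(P), length(offs)) + rep(offs, each = P), nrow = P)
}

# ---- layer forward/backward -------------------------------------------------

fwd_conv2d <- function(st, x, training) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]; B <- d[4L]
  k <- st$spec$kernel
  idx <- im2col_index(H, W, C, k)
  Ho <- H - k + 1L; Wo <- W - k + 1L; cout <- st$spec$units
  out <- array(0, c(Ho, Wo, cout, B))
  for (i in seq_len(B)) {
    xi <- x[, , , i]
    z <- matrix(xi[idx], nrow = nrow(idx)) %*% st$params$W
    out[, , , i] <- array(z, c(Ho, Wo, cout))
  }
  out <- sweep(out, 3L, st$params$b, "+")
  mask <- out > 0
  list(out = out * mask, cache = list(x = x, mask = mask, idx = idx))
}

bwd_conv2d <- function(st, dout, cache) {
  dz <- dout * cache$mask
  x <- cache$x; idx <- cache$idx
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]; B <- d[4L]
  k <- st$spec$kernel
  Ho <- H - k + 1L; Wo <- W - k + 1L; cout <- st$spec$units
  P <- Ho * Wo
  dW <- matrix(0, nrow(st$params$W), cout)
  dx <- array(0, d)
  for (i in seq_len(B)) {
    xi <- x[, , , i]
    cols <- matrix(xi[idx], nrow = P)
    dzi <- matrix(dz[, , , i], nrow = P)
    dW <- dW + crossprod(cols, dzi)
    dcols <- tcrossprod(dzi, st$params$W)          # P x (k*k*C)
    dxi <- array(0, c(H, W, C))
    col <- 0L
    for (c_ in seq_len(C)) for (kw in seq_len(k)) for (kh in seq_len(k)) {
      col <- col + 1L
      dxi[kh:(kh + Ho - 1L), kw:(kw + Wo - 1L), c_] <-
        dxi[kh:(kh + Ho - 1L), kw:(kw + Wo - 1L), c_] +
        matrix(dcols[, col], Ho, Wo)
    }
    dx[, , , i] <- dxi
  }
  db <- apply(dz, 3L, sum)
  list(dx = dx, grads = list(W = dW, b = db))
}

fwd_conv1d <- function(st, x, training) {
  d <- dim(x); Tn <- d[1L]; Fn <- d[2L]; B <- d[3L]
  k <- st$spec$kernel; cout <- st$spec$units
  idx <- im2col_index_1d(Tn, Fn, k)
  P <- Tn - k + 1L
  out <- array(0, c(P, cout, B))
  for (i in seq_len(B)) {
    xi <- x[, , i]
    out[, , i] <- matrix(xi[idx], nrow = P) %*% st$params$W
  }
  out <- sweep(out, 2L, st$params$b, "+")
  mask <- out > 0
  list(out = out * mask, cache = list(x = x, mask = mask, idx = idx))
}

bwd_conv1d <- function(st, dout, cache) {
  dz <- dout * cache$mask
  x <- cache$x; idx <- cache$idx
  d <- dim(x); Tn <- d[1L]; Fn <- d[2L]; B <- d[3L]
  k <- st$spec$kernel; cout <- st$spec$units
  P <- Tn - k + 1L
  dW <- matrix(0, nrow(st$params$W), cout)
  dx <- array(0, d)
  for (i in seq_len(B)) {
    xi <- x[, , i]
    cols <- matrix(xi[idx], nrow = P)
    dzi <- matrix(dz[, , i], nrow = P)
    dW <- dW + crossprod(cols, dzi)
    dcols <- tcrossprod(dzi, st$params$W)          # P x (k*F)
    dxi <- matrix(0, Tn, Fn)
    col <- 0L
    for (f_ in seq_len(Fn)) for (kt in seq_len(k)) {
      col <- col + 1L
      dxi[kt:(kt + P - 1L), f_] <- dxi[kt:(kt + P - 1L), f_] + dcols[, col]
    }
    dx[, , i] <- dxi
  }
  db <- apply(dz, 2L, sum)
  list(dx = dx, grads = list(W = dW, b = db))
}

fwd_maxpool <- function(st, x, training) {
  d <- dim(x)
  if (length(d) == 4L) {
    Hc <- d[1L] %/% 2L; Wc <- d[2L] %/% 2L
    oh <- seq_len(Hc) * 2L - 1L; ow <- seq_len(Wc) * 2L - 1L
    x11 <- x[oh, ow, , , drop = FALSE]; x21 <- x[oh + 1L, ow, , , drop = FALSE]
    x12 <- x[oh, ow + 1L, , , drop = FALSE]; x22 <- x[oh + 1L, ow + 1L, , , drop = FALSE]
    out <- pmax(x11, x21, x12, x22)
    list(out = out, cache = list(parts = list(x11, x21, x12, x22), dim = d))
  } else {
    Tc <- d[1L] %/% 2L
    ot <- seq_len(Tc) * 2L - 1L
    x1 <- x[ot, , , drop = FALSE]; x2 <- x[ot + 1L, , , drop = FALSE]
    out <- pmax(x1, x2)
    list(out = out, cache = list(parts = list(x1, x2), dim = d))
  }
}

bwd_maxpool <- function(st, dout, cache) {
  d <- cache$dim
  p <- cache$parts
  out <- do.call(pmax, p)
  dx <- array(0, d)
  taken <- array(FALSE, dim(out))
  if (length(d) == 4L) {
    Hc <- dim(out)[1L]; Wc <- dim(out)[2L]
    oh <- seq_len(Hc) * 2L - 1L; ow <- seq_len(Wc) * 2L - 1L
    rows <- list(oh, oh + 1L, oh, oh + 1L)
    colsl <- list(ow, ow, ow + 1L, ow + 1L)
    for (j in seq_along(p)) {
      m <- (p[[j]] == out) & !taken
      taken <- taken | m
      dx[rows[[j]], colsl[[j]], , ] <-
        dx[rows[[j]], colsl[[j]], , , drop = FALSE] + dout * m
    }
  } else {
    Tc <- dim(out)[1L]
    ot <- seq_len(Tc) * 2L - 1L
    rows <- list(ot, ot + 1L)
    for (j in seq_along(p)) {
      m <- (p[[j]] == out) & !taken
      taken <- taken | m
      dx[rows[[j]], , ] <- dx[rows[[j]], , , drop = FALSE] + dout * m
    }
  }
  list(dx = dx, grads = NULL)
}

bn_eps <- 1e-3
bn_momentum <- 0.99

# flatten all non-channel axes into rows of an N x C matrix
bn_to_mat <- function(x) {
  d <- dim(x); ch <- length(d) - 1L
  perm <- c(setdiff(seq_along(d), ch), ch)
  list(mat = matrix(aperm(x, perm), ncol = d[ch]), perm = perm, dim = d)
}

bn_from_mat <- function(mat, perm, d) {
  ch <- length(d) - 1L
  aperm(array(mat, d[perm]), order(perm))
}

fwd_batchnorm <- function(st, x, training) {
  b <- bn_to_mat(x)
  if (training) {
    mu <- colMeans(b$mat)
    xc <- sweep(b$mat, 2L, mu)
    v <- colMeans(xc^2)
  } else {
    mu <- st$run_mean
    v <- st$run_var
    xc <- sweep(b$mat, 2L, mu)
  }
  inv_std <- 1 / sqrt(v + bn_eps)
  xhat <- sweep(xc, 2L, inv_std, "*")
  out <- sweep(sweep(xhat, 2L, st$params$gamma, "*"), 2L, st$params$beta, "+")
  cache <- list(xhat = xhat, inv_std = inv_std, perm = b$perm, dim = b$dim,
                batch_mu = if (training) mu, batch_var = if (training) v)
  list(out = bn_from_mat(out, b$perm, b$dim), cache = cache)
}

bwd_batchnorm <- function(st, dout, cache) {
  db <- bn_to_mat(dout)
  dmat <- db$mat
  xhat <- cache$xhat
  N <- nrow(dmat)
  dgamma <- colSums(dmat * xhat)
  dbeta <- colSums(dmat)
  dxhat <- sweep(dmat, 2L, st$params$gamma, "*")
  dx <- sweep(
    dxhat - matrix(colSums(dxhat) / N, N, ncol(dmat), byrow = TRUE) -
      xhat * matrix(colSums(dxhat * xhat) / N, N, ncol(dmat), byrow = TRUE),
    2L, cache$inv_std, "*")
  list(dx = bn_from_mat(dx, cache$perm, cache$dim),
       grads = list(gamma = dgamma, beta = dbeta))
}

fwd_lstm <- function(st, x, training) {
  d <- dim(x); Tn <- d[1L]; Fn <- d[2L]; B <- d[3L]
  U <- st$spec$units
  W <- st$params$W; R <- st$params$R; bias <- st$params$b
  h <- matrix(0, B, U); cst <- matrix(0, B, U)
  out <- array(0, c(Tn, U, B))
  steps <- if (training) vector("list", Tn)
  iU <- seq_len(U)
  for (t in seq_len(Tn)) {
    Xt <- t(matrix(x[t, , ], Fn, B))
    z <- sweep(Xt %*% W + h %*% R, 2L, bias, "+")
    ig <- 1 / (1 + exp(-z[, iU, drop = FALSE]))
    fg <- 1 / (1 + exp(-z[, U + iU, drop = FALSE]))
    gg <- tanh(z[, 2L * U + iU, drop = FALSE])
    og <- 1 / (1 + exp(-z[, 3L * U + iU, drop = FALSE]))
    c_prev <- cst; h_prev <- h
    cst <- fg * c_prev + ig * gg
    h <- og * tanh(cst)
    out[t, , ] <- t(h)
    if (training) {
      steps[[t]] <- list(Xt = Xt, ig = ig, fg = fg, gg = gg, og = og,
                         c = cst, c_prev = c_prev, h_prev = h_prev)
    }
  }
  list(out = out, cache = if (training) list(steps = steps, dim = d))
}

bwd_lstm <- function(st, dout, cache) {
  d <- cache$dim; Tn <- d[1L]; Fn <- d[2L]; B <- d[3L]
  U <- st$spec$units
  W <- st$params$W; R <- st$params$R
  dW <- matrix(0, Fn, 4L * U); dR <- matrix(0, U, 4L * U)
  db <- numeric(4L * U)
  dh_next <- matrix(0, B, U); dc_next <- matrix(0, B, U)
  dx <- array(0, d)
  for (t in rev(seq_len(Tn))) {
    s <- cache$steps[[t]]
    dh <- t(matrix(dout[t, , ], U, B)) + dh_next
    tc <- tanh(s$c)
    do_ <- dh * tc
    dc <- dc_next + dh * s$og * (1 - tc^2)
    di <- dc * s$gg
    dg <- dc * s$ig
    df <- dc * s$c_prev
    dc_next <- dc * s$fg
    dz <- cbind(di * s$ig * (1 - s$ig),
                df * s$fg * (1 - s$fg),
                dg * (1 - s$gg^2),
                do_ * s$og * (1 - s$og))
    dW <- dW + crossprod(s$Xt, dz)
    dR <- dR + crossprod(s$h_prev, dz)
    db <- db + colSums(dz)
    dx[t, , ] <- t(tcrossprod(dz, W))
    dh_next <- tcrossprod(dz, R)
  }
  list(dx = dx, grads = list(W = dW, R = dR, b = db))
}

fwd_flatten <- function(st, x, training) {
  d <- dim(x)
  B <- d[length(d)]
  list(out = t(matrix(x, prod(d[-length(d)]), B)), cache = list(dim = d))
}

bwd_flatten <- function(st, dout, cache) {
  list(dx = array(t(dout), cache$dim), grads = NULL)
}

fwd_dense_layer <- function(st, x, training, final = FALSE) {
  act <- st$spec$activation
  if (isTRUE(st$pruned)) {
    z <- as.matrix((x %*% st$slr$U_k) %*% (st$slr$S_k * st$slr$Vt_k))
    z <- sweep(z, 2L, st$slr$b, "+")
  } else {
    z <- sweep(x %*% st$params$W, 2L, st$params$b, "+")
  }
  out <- apply_activation(z, act)
  cache <- list(x = x,
                mask = if (identical(act, "relu")) z > 0)
  list(out = out, cache = cache)
}

bwd_dense_layer <- function(st, dout, cache) {
  # for the softmax classifier the incoming gradient is already w.r.t. the
  # pre-activation (softmax + cross-entropy combined); relu layers carry a mask
  dz <- if (is.null(cache$mask)) dout else dout * cache$mask
  if (isTRUE(st$pruned)) {
    stop(sprintf("layer '%s' is SLR-pruned; pruned models are inference-only",
                 st$spec$name), call. = FALSE)
  }
  list(dx = tcrossprod(dz, st$params$W),
       grads = list(W = crossprod(cache$x, dz), b = colSums(dz)))
}

fwd_dropout <- function(st, x, training) {
  if (!training || is.na(st$spec$rate) || st$spec$rate <= 0) {
    return(list(out = x, cache = NULL))
  }
  keep <- 1 - st$spec$rate
  mask <- array((stats::runif(length(x)) < keep) / keep, dim(x))
  list(out = x * mask, cache = list(mask = mask))
}

bwd_dropout <- function(st, dout, cache) {
  list(dx = if (is.null(cache)) dout else dout * cache$mask, grads = NULL)
}

# ---- whole-network forward/backward ----------------------------------------

net_forward <- function(net, x, training = FALSE, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net$layers))
  updates <- list()
  for (i in seq_along(net$layers)) {
    st <- net$layers[[i]]
    r <- switch(st$spec$kind,
      conv2d = fwd_conv2d(st, x, training),
      conv1d = fwd_conv1d(st, x, training),
      maxpool = fwd_maxpool(st, x, training),
      batchnorm = fwd_batchnorm(st, x, training),
      lstm = fwd_lstm(st, x, training),
      flatten = fwd_flatten(st, x, training),
      dense = fwd_dense_layer(st, x, training),
      dropout = fwd_dropout(st, x, training))
    x <- r$out
    if (keep_cache) caches[[i]] <- r$cache
    if (training && st$spec$kind == "batchnorm") {
      updates[[as.character(i)]] <-
        list(mean = r$cache$batch_mu, var = r$cache$batch_var)
    }
  }
  list(out = x, caches = caches, bn_updates = updates)
}

net_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    st <- net$layers[[i]]
    r <- switch(st$spec$kind,
      conv2d = bwd_conv2d(st, dout, caches[[i]]),
      conv1d = bwd_conv1d(st, dout, caches[[i]]),
      maxpool = bwd_maxpool(st, dout, caches[[i]]),
      batchnorm = bwd_batchnorm(st, dout, caches[[i]]),
      lstm = bwd_lstm(st, dout, caches[[i]]),
      flatten = bwd_flatten(st, dout, caches[[i]]),
      dense = bwd_dense_layer(st, dout, caches[[i]]),
      dropout = bwd_dropout(st, dout, caches[[i]]))
    dout <- r$dx
    grads[i] <- list(r$grads)
  }
  grads
}

# ---- Adadelta ---------------------------------------------------------------

adadelta_init <- function(net) {
  lapply(net$layers, function(st) {
    if (is.null(st$params)) return(NULL)
    lapply(st$params, function(p) list(Eg = p * 0, Ex = p * 0))
  })
}

adadelta_step <- function(net, grads, state, lr, rho = 0.95, eps = 1e-7) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      s <- state[[i]][[nm]]
      s$Eg <- rho * s$Eg + (1 - rho) * g[[nm]]^2
      upd <- -sqrt(s$Ex + eps) / sqrt(s$Eg + eps) * g[[nm]]
      s$Ex <- rho * s$Ex + (1 - rho) * upd^2
      net$layers[[i]]$params[[nm]] <- net$layers[[i]]$params[[nm]] + lr * upd
      state[[i]][[nm]] <- s
    }
  }
  list(net = net, state = state)
}
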