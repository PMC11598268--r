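#' Dense (fully-connected) layer weights
#'
#' Bundles the weight matrix `W` (one column per output neuron) and bias
#' vector `b` of a fully-connected layer. For an input vector `X` of length
#' `m` the layer computes `g(t(W) %*% X + b)`, so `W` has `m` rows (input
#' neurons) and `n` columns (output neurons).
#'
#' @param W numeric matrix, `m x n`, finite entries.
#' @param b numeric bias vector of length `n` (default all zero).
#' @param name layer identifier used in error messages and accounting tables.
#' @return An object of class `dense_layer`.
#' @examples
#' dense_layer(matrix(rnorm(12), 4, 3), name = "FC6")
#' @export
dense_layer <- function(W, b = numeric(ncol(W)), name = "dense") {
  W <- as.matrix(W)
  if (nrow(W) < 1L || ncol(W) < 1L) {
    stop("dense layer needs at least one input and one output neuron",
         call. = FALSE)
  }
  check_finite(W, sprintf("weights of layer '%s'", name))
  check_finite(b, sprintf("bias of layer '%s'", name))
  if (length(b) != ncol(W)) {
    stop_dim("layer '%s': bias length %d does not match %d output neurons",
             name, length(b), ncol(W))
  }
  structure(list(W = W, b = as.numeric(b), name = name),
            class = "dense_layer")
}

#' @export
print.dense_layer <- function(x, ...) {
  cat(sprintf("Dense layer '%s': %d -> %d (%s parameters)\n",
              x$name, nrow(x$W), ncol(x$W),
              fmt_count(stored_param_count(x))))
  invisible(x)
}

#' Dense forward pass
#'
#' Evaluates `g(t(W) %*% X + b)` for a single input vector or a batch given
#' as a matrix with one row per sample.
#'
#' @param layer a [dense_layer()].
#' @param X numeric vector of length `m`, or a matrix with `m` columns.
#' @param g activation: `"relu"`, `"softmax"` or `"identity"`.
#' @return numeric vector of length `n` (or a matrix with `n` columns).
#' @examples
#' lyr <- dense_layer(diag(2))
#' forward_dense(lyr, c(3, -1), "relu")
#' @export
forward_dense <- function(layer, X, g = "identity") {
  stopifnot(inherits(layer, "dense_layer"))
  m <- nrow(layer$W)
  if (is.matrix(X)) {
    if (ncol(X) != m) {
      stop_dim("layer '%s': input has %d features, expected %d",
               layer$name, ncol(X), m)
    }
    z <- sweep(X %*% layer$W, 2L, layer$b, "+")
    apply_activation(z, g)
  } else {
    if (length(X) != m) {
      stop_dim("layer '%s': input length %d, expected %d",
               layer$name, length(X), m)
    }
    z <- drop(crossprod(layer$W, X)) + layer$b
    apply_activation(z, g)
  }
}

#' Singular value decomposition of a dense layer
#'
#' Economy-form SVD `W = U diag(S) Vt` with `r = min(m, n)` components,
#' singular values sorted non-increasing.
#'
#' @param layer a [dense_layer()] (or a bare numeric matrix).
#' @return An object of class `svd_factors` with fields `U` (m x r), `S`
#'   (length r), `Vt` (r x n), plus the layer bias and name.
#' @export
svd_decompose <- function(layer) {
  if (is.matrix(layer)) layer <- dense_layer(layer)
  stopifnot(inherits(layer, "dense_layer"))
  check_finite(layer$W, sprintf("weights of layer '%s'", layer$name))
  s <- svd(layer$W)
  structure(list(U = s$u, S = s$d, Vt = t(s$v),
                 b = layer$b, name = layer$name),
            class = "svd_factors")
}

#' @export
print.svd_factors <- function(x, ...) {
  cat(sprintf("SVD factors of '%s': U %dx%d, %d singular values, Vt %dx%d\n",
              x$name, nrow(x$U), ncol(x$U), length(x$S),
              nrow(x$Vt), ncol(x$Vt)))
  invisible(x)
}

#' Keep the k leading singular components
#'
#' Truncates SVD factors to the `k` components with the largest singular
#' values. By the Eckart-Young theorem the reconstruction
#' `U_k diag(S_k) Vt_k` is the best rank-k approximation of the original
#' matrix in Frobenius norm, with error `sqrt(sum(S[-(1:k)]^2))`.
#'
#' @param f an `svd_factors` object.
#' @param k number of components to keep, `1 <= k <= length(f$S)`.
#' @return `svd_factors` with `k` components.
#' @export
truncate_components <- function(f, k) {
  stopifnot(inherits(f, "svd_factors"))
  r <- length(f$S)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > r) {
    stop(sprintf("reduction rank k = %s out of range [1, %d] for layer '%s'",
                 as.character(k), r, f$name), call. = FALSE)
  }
  structure(list(U = f$U[, seq_len(k), drop = FALSE],
                 S = f$S[seq_len(k)],
                 Vt = f$Vt[seq_len(k), , drop = FALSE],
                 b = f$b, name = f$name),
            class = "svd_factors")
}

#' Sparsify truncated singular vectors by absolute magnitude
#'
#' In each retained column of `U` and each retained row of `Vt`, only the
#' `ceiling(density * length)` entries with the largest absolute values are
#' kept (ties broken by lowest index); all other entries become structural
#' zeros. Singular values and the bias stay dense.
#'
#' @param f truncated `svd_factors`.
#' @param density fraction of entries kept per singular vector, in (0, 1].
#' @return An object of class `slr_factors` with sparse `U_k` (m x k) and
#'   `Vt_k` (k x n) (`Matrix::dgCMatrix`), dense `S_k` and `b`, the rank `k`,
#'   the `density`, and `kept_entry_indices` (per-vector index lists).
#' @export
sparsify_factors <- function(f, density) {
  stopifnot(inherits(f, "svd_factors"))
  if (!is.numeric(density) || length(density) != 1L ||
      is.na(density) || density <= 0 || density > 1) {
    stop("density must be a single number in (0, 1]", call. = FALSE)
  }
  k <- length(f$S)
  m <- nrow(f$U)
  n <- ncol(f$Vt)

  u_idx <- lapply(seq_len(k), function(j) top_abs_indices(f$U[, j], density))
  v_idx <- lapply(seq_len(k), function(j) top_abs_indices(f$Vt[j, ], density))

  U_k <- Matrix::sparseMatrix(
    i = unlist(u_idx),
    j = rep(seq_len(k), times = vapply(u_idx, length, 1L)),
    x = unlist(lapply(seq_len(k), function(j) f$U[u_idx[[j]], j])),
    dims = c(m, k))
  Vt_k <- Matrix::sparseMatrix(
    i = rep(seq_len(k), times = vapply(v_idx, length, 1L)),
    j = unlist(v_idx),
    x = unlist(lapply(seq_len(k), function(j) f$Vt[j, v_idx[[j]]])),
    dims = c(k, n))

  structure(list(k = k, density = density,
                 U_k = U_k, S_k = f$S, Vt_k = Vt_k, b = f$b,
                 kept_entry_indices = list(U = u_idx, Vt = v_idx),
                 name = f$name),
            class = "slr_factors")
}

#' Sparse low-rank pruning of a dense layer
#'
#' Full SLR pipeline: SVD decomposition, truncation to the reduction rank
#' `k`, and intra-vector sparsification to `density`. The bias passes
#' through unchanged. Equivalent to
#' `sparsify_factors(truncate_components(svd_decompose(layer), k), density)`.
#'
#' @param layer a [dense_layer()].
#' @param k reduction rank (number of singular components kept).
#' @param density fraction of entries kept per singular vector, in (0, 1].
#' @return An `slr_factors` object.
#' @examples
#' lyr <- dense_layer(matrix(rnorm(12), 4, 3), name = "toy")
#' slr_prune(lyr, k = 1, density = 1)
#' @export
slr_prune <- function(layer, k, density = 0.5) {
  sparsify_factors(truncate_components(svd_decompose(layer), k), density)
}

#' @export
print.slr_factors <- function(x, ...) {
  cat(sprintf(
    "SLR factors of '%s': rank %d, density %.2f, %d -> %d\n",
    x$name, x$k, x$density, nrow(x$U_k), ncol(x$Vt_k)))
  cat(sprintf("  stored values: %s (dense layer: %s)\n",
              fmt_count(stored_param_count(x)),
              fmt_count(nrow(x$U_k) * ncol(x$Vt_k) + ncol(x$Vt_k))))
  invisible(x)
}

#' Reconstruct the (approximate) dense weight matrix
#'
#' @param slr an `slr_factors` object.
#' @return dense numeric matrix `U_k diag(S_k) Vt_k` of the original shape.
#' @export
reconstruct <- function(slr) {
  stopifnot(inherits(slr, "slr_factors"))
  as.matrix(slr$U_k %*% (slr$S_k * slr$Vt_k))
}

#' Forward pass through SLR factors
#'
#' Computes the layer activation with the compressed factors without
#' materialising the reconstructed weight matrix: three small products
#' `((X U_k) * S_k) Vt_k + b`.
#'
#' @param slr an `slr_factors` object.
#' @param X input vector of length `m`, or matrix with `m` columns.
#' @param g activation id as in [forward_dense()].
#' @return activation vector of length `n` (or matrix with `n` columns).
#' @export
forward_pruned <- function(slr, X, g = "identity") {
  stopifnot(inherits(slr, "slr_factors"))
  m <- nrow(slr$U_k)
  vec <- !is.matrix(X)
  if (vec) X <- matrix(X, nrow = 1L)
  if (ncol(X) != m) {
    stop_dim("layer '%s': input has %d features, expected %d",
             slr$name, ncol(X), m)
  }
  z <- as.matrix((X %*% slr$U_k) %*% (slr$S_k * slr$Vt_k))
  z <- sweep(z, 2L, slr$b, "+")
  out <- apply_activation(z, g)
  if (vec) drop(out) else out
}
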