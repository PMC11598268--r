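test_that("dense forward matches the per-neuron sum", {
  lyr <- dense_layer(diag(2))
  expect_equal(forward_dense(lyr, c(3, -1), "identity"), c(3, -1))
  expect_equal(forward_dense(lyr, c(3, -1), "relu"), c(3, 0))

  lyr <- random_dense_layer(4, 3, seed = 7)
  set.seed(8)
  x <- rnorm(4)
  # independent loop-sum oracle
  oracle <- vapply(1:3, function(j) {
    sum(vapply(1:4, function(i) lyr$W[i, j] * x[i], 0)) + lyr$b[j]
  }, 0)
  expect_equal(forward_dense(lyr, x), oracle)
  expect_equal(forward_dense(lyr, x, "relu"), pmax(oracle, 0))
  # softmax normalises
  expect_equal(sum(forward_dense(lyr, x, "softmax")), 1)
})

test_that("dense forward rejects mismatched input, naming the layer", {
  lyr <- random_dense_layer(4, 3, name = "FC6")
  expect_error(forward_dense(lyr, rnorm(5)), "FC6.*length 5.*expected 4")
  expect_error(dense_layer(matrix(1, 2, 2), b = c(1, 2, 3)),
               "bias length 3")
})

test_that("svd_decompose yields sorted, orthonormal, reconstructing factors", {
  expect_equal(svd_decompose(dense_layer(diag(c(2, 1))))$S, c(2, 1))
  expect_equal(svd_decompose(dense_layer(diag(3)))$S, c(1, 1, 1))

  lyr <- random_dense_layer(5, 4, seed = 2)
  f <- svd_decompose(lyr)
  # independent eigenvalue oracle: singular values of W are the square roots
  # of the eigenvalues of W'W
  ev <- eigen(crossprod(lyr$W), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(f$S, sqrt(sort(ev, decreasing = TRUE)), tolerance = 1e-10)
  expect_true(all(diff(f$S) <= 0))
  expect_equal(crossprod(f$U), diag(4), tolerance = 1e-6)
  expect_equal(tcrossprod(f$Vt), diag(4), tolerance = 1e-6)
  relerr <- norm(f$U %*% diag(f$S) %*% f$Vt - lyr$W, "F") / norm(lyr$W, "F")
  expect_lt(relerr, 1e-8)

  bad <- lyr
  bad$W[1, 1] <- NaN
  expect_error(svd_decompose(bad), "non-finite")
})

test_that("truncation keeps leading components and attains the Eckart-Young error", {
  lyr <- random_dense_layer(6, 5, seed = 3)
  f <- svd_decompose(lyr)
  # full rank: exact reconstruction
  fr <- truncate_components(f, 5)
  expect_lt(norm(fr$U %*% diag(fr$S) %*% fr$Vt - lyr$W, "F") /
              norm(lyr$W, "F"), 1e-8)

  # rank-1 input reconstructs exactly at k = 1
  u <- rnorm(6); v <- rnorm(5)
  r1 <- truncate_components(svd_decompose(dense_layer(outer(u, v))), 1)
  expect_equal(r1$U %*% (r1$S * r1$Vt), outer(u, v),
               tolerance = 1e-10, ignore_attr = TRUE)

  # closed-form error + brute-force random-search oracle
  tk <- truncate_components(f, 2)
  err <- norm(tk$U %*% diag(tk$S) %*% tk$Vt - lyr$W, "F")
  expect_equal(err, sqrt(sum(f$S[3:5]^2)), tolerance = 1e-10)
  set.seed(9)
  for (i in 1:50) {
    A <- matrix(rnorm(12), 6, 2)
    Bm <- matrix(rnorm(10), 2, 5)
    expect_gte(norm(A %*% Bm - lyr$W, "F"), err - 1e-10)
  }

  expect_error(truncate_components(f, 0), "out of range")
  expect_error(truncate_components(f, 6), "out of range")
})

test_that("sparsification keeps exactly the top-|value| entries per vector", {
  lyr <- random_dense_layer(4, 4, seed = 4)
  f <- truncate_components(svd_decompose(lyr), 2)

  # density 1 changes nothing
  s1 <- sparsify_factors(f, 1)
  expect_equal(as.matrix(s1$U_k), f$U, ignore_attr = TRUE)
  expect_equal(as.matrix(s1$Vt_k), f$Vt, ignore_attr = TRUE)

  # hand example: keep ceil(0.5*4) = 2 entries, largest |values|
  expect_equal(slrprune:::top_abs_indices(c(0.1, -0.5, 0.3, 0.2), 0.5),
               c(2L, 3L))

  # exact per-vector stored counts at several densities and lengths
  for (dens in c(0.3, 0.5, 0.8)) {
    sp <- sparsify_factors(f, dens)
    for (j in 1:2) {
      expect_length(sp$kept_entry_indices$U[[j]], ceiling(dens * 4))
      expect_length(sp$kept_entry_indices$Vt[[j]], ceiling(dens * 4))
      # kept entries really are the largest in absolute value
      kept <- sp$kept_entry_indices$U[[j]]
      if (length(kept) < 4) {
        expect_gte(min(abs(f$U[kept, j])), max(abs(f$U[-kept, j])))
      }
    }
  }

  # information loss is monotone in density
  W <- lyr$W
  err05 <- norm(reconstruct(sparsify_factors(f, 0.5)) - W, "F")
  err10 <- norm(reconstruct(sparsify_factors(f, 1)) - W, "F")
  expect_gte(err05, err10)

  expect_error(sparsify_factors(f, 0), "density")
  expect_error(sparsify_factors(f, 1.2), "density")
})

test_that("slr_prune composes the pipeline and passes the bias through", {
  lyr <- random_dense_layer(4, 3, seed = 5)
  # lossless configuration
  full <- slr_prune(lyr, k = 3, density = 1)
  set.seed(6)
  for (i in 1:5) {
    x <- rnorm(4)
    expect_equal(forward_pruned(full, x, "relu"),
                 forward_dense(lyr, x, "relu"), tolerance = 1e-6)
  }
  expect_equal(full$b, lyr$b)

  # stored structure at k = 1, density 1: m + k + n values plus n bias
  one <- slr_prune(lyr, k = 1, density = 1)
  expect_equal(stored_param_count(one), 4 + 1 + 3 + 3)
  expect_equal(stored_param_count(lyr), 4 * 3 + 3)

  # FC6-sized layer: factor shapes at rank 8
  big <- random_dense_layer(1472, 1200, seed = 6, name = "FC6")
  slr <- slr_prune(big, 8, 0.5)
  expect_equal(dim(slr$U_k), c(1472L, 8L))
  expect_length(slr$S_k, 8)
  expect_equal(dim(slr$Vt_k), c(8L, 1200L))
  expect_equal(stored_param_count(slr), 8 * 736 + 8 + 8 * 600 + 1200)
})

test_that("forward through factors equals forward through the reconstruction", {
  set.seed(10)
  for (i in 1:200) {
    m <- sample(3:8, 1); n <- sample(3:8, 1)
    k <- sample(seq_len(min(m, n)), 1)
    dens <- runif(1, 0.3, 1)
    g <- sample(c("identity", "relu", "softmax"), 1)
    lyr <- dense_layer(matrix(rnorm(m * n), m, n), rnorm(n))
    slr <- slr_prune(lyr, k, dens)
    x <- rnorm(m)
    expect_equal(forward_pruned(slr, x, g),
                 forward_dense(dense_layer(reconstruct(slr), lyr$b), x, g),
                 tolerance = 1e-12)
  }
})

test_that("pruned forward handles zero input and dimension errors", {
  lyr <- random_dense_layer(5, 4, seed = 11, name = "FC7")
  slr <- slr_prune(lyr, 2, 0.5)
  expect_equal(forward_pruned(slr, numeric(5), "relu"), pmax(lyr$b, 0))
  expect_error(forward_pruned(slr, numeric(3)), "FC7.*3.*expected 5")
})
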