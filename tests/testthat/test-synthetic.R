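test_that("the catalogue has five fall and six ADL classes", {
  cat11 <- class_catalogue()
  expect_equal(nrow(cat11), 11)
  expect_equal(sum(cat11$kind == "fall"), 5)
  expect_equal(sum(cat11$kind == "adl"), 6)
  expect_equal(nrow(class_catalogue(binary = TRUE)), 2)
})

test_that("sequence generation is deterministic in (class, seed)", {
  a <- generate_sequence(3, n_frames = 8, H = 12, W = 12, seed = 42)
  b <- generate_sequence(3, n_frames = 8, H = 12, W = 12, seed = 42)
  expect_identical(a$frames, b$frames)
  c <- generate_sequence(3, n_frames = 8, H = 12, W = 12, seed = 43)
  expect_false(identical(a$frames, c$frames))
  expect_true(all(a$frames >= 0 & a$frames <= 1))
  expect_error(generate_sequence(99, seed = 1), "unknown class")
  expect_error(generate_sequence(1, n_frames = 2, seed = 1), ">= 4")
})

test_that("noise-free figureless sequences are constant background", {
  s <- generate_sequence(1, n_frames = 6, H = 8, W = 8, seed = 1,
                         noise_sd = 0, figure = FALSE)
  expect_equal(max(s$frames), min(s$frames))
})

test_that("fall classes end lower in the image than they start", {
  for (cl in 1:5) {
    s <- generate_sequence(cl, n_frames = 24, H = 32, W = 32, seed = cl * 7,
                           noise_sd = 0)
    ctr <- sequence_centroids(s)
    expect_gt(ctr$row[24], ctr$row[1])
  }
  # standing stays level
  s <- generate_sequence(7, n_frames = 24, H = 32, W = 32, seed = 3,
                         noise_sd = 0)
  ctr <- sequence_centroids(s)
  expect_lt(abs(ctr$row[24] - ctr$row[1]), 2)
})

test_that("datasets are balanced, reproducible and seed-disjoint", {
  ds <- make_dataset(3, n_frames = 6, H = 8, W = 8, seed = 5)
  expect_length(ds$sequences, 33)
  expect_true(all(table(ds$labels) == 3))
  ds2 <- make_dataset(3, n_frames = 6, H = 8, W = 8, seed = 5)
  expect_identical(lapply(ds$sequences, `[[`, "frames"),
                   lapply(ds2$sequences, `[[`, "frames"))
  expect_identical(ds$labels, ds2$labels)
  # disjoint master seeds share no identical tensors (hash comparison)
  ds3 <- make_dataset(3, n_frames = 6, H = 8, W = 8, seed = 6)
  shared <- outer(seq_along(ds$sequences), seq_along(ds3$sequences),
                  Vectorize(function(i, j) {
                    identical(ds$sequences[[i]]$frames,
                              ds3$sequences[[j]]$frames)
                  }))
  expect_false(any(shared))
})

test_that("fall vs non-fall is linearly separable from centroid features", {
  feat <- function(ds) {
    t(vapply(ds$sequences, function(s) {
      ctr <- sequence_centroids(s)
      r <- ctr$row
      r[is.na(r)] <- mean(r, na.rm = TRUE)
      r / dim(s$frames)[2L]
    }, numeric(ds$geometry[["n_frames"]])))
  }
  is_fall <- function(ds) as.integer(ds$labels <= 5)
  train <- make_dataset(20, n_frames = 12, H = 16, W = 16, seed = 21)
  test <- make_dataset(19, n_frames = 12, H = 16, W = 16, seed = 22)
  df_tr <- data.frame(y = is_fall(train), feat(train))
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df_tr, family = stats::binomial()))
  p <- suppressWarnings(
    stats::predict(fit, data.frame(feat(test)), type = "response"))
  held_out <- seq_len(200)
  acc <- mean((p[held_out] > 0.5) == (is_fall(test)[held_out] == 1))
  expect_gt(acc, 0.9)
})

test_that("datasets convert to the two model input layouts", {
  ds <- make_dataset(2, n_frames = 6, H = 8, W = 8, seed = 9)
  d2 <- dataset_to_cnn2d(ds)
  expect_equal(dim(d2$x), c(8, 8, 18, 22))
  d1 <- dataset_to_sequence(ds)
  expect_equal(dim(d1$x), c(6, 192, 22))
  # same pixels, both layouts: spot-check one sequence
  fr <- ds$sequences[[5]]$frames
  expect_equal(d1$x[3, , 5], as.vector(fr[3, , , ]))
  expect_equal(d2$x[, , 7, 5], fr[3, , , 1])  # frame 3, channel 1
})

test_that("PNG export/import round-trips the layout", {
  skip_if_not_installed("png")
  ds <- make_dataset(1, n_frames = 4, H = 8, W = 8, seed = 2,
                     noise_sd = 0)
  dir <- withr::local_tempdir()
  export_frames(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- import_frames(dir)
  expect_length(back$sequences, 11)
  expect_equal(back$labels, ds$labels)
  # 8-bit PNG quantisation: equal to within half a grey level
  expect_equal(back$sequences[[1]]$frames, ds$sequences[[1]]$frames,
               tolerance = 1 / 255)
})
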