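# fixtures built in code; all randomness seeded locally

random_dense_layer <- function(m, n, seed = 1, name = "fc") {
  set.seed(seed)
  dense_layer(matrix(rnorm(m * n), m, n), rnorm(n), name = name)
}

# tiny geometry that all three conv/pool stages of the 2D backbone survive
tiny_cnn2d_spec <- function(num_classes = 3) {
  build_cnn2d(num_classes, input_shape = c(2, 18, 18, 3), dropout = 0)
}

tiny_cnn_lstm_spec <- function(num_classes = 3, T = 12, F = 36) {
  build_cnn_lstm(num_classes, input_shape = c(T, F, 1), dropout = 0)
}

mlp_spec <- function(num_classes = 2, width = 4) {
  slrprune:::build_mlp(num_classes, width)
}

# linearly separable 2-class toy set
toy_separable <- function(n = 120, width = 4, seed = 3) {
  set.seed(seed)
  x <- matrix(rnorm(n * width), n, width)
  list(x = x, y = ifelse(x[, 1] + x[, 2] > 0, 1L, 2L))
}

# run the CLI in-process, discarding its printed output
capture_status <- function(args) {
  status <- NULL
  invisible(capture.output(
    status <- suppressMessages(slrprune_cli(args))))
  status
}
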