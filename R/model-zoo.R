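# Declarative backbone descriptions: ordered layer specs from which shapes,
# parameter counts and the executable network are derived.

layer_spec <- function(name, kind, units = NA_integer_, kernel = NA_integer_,
                       stride = NA_integer_, activation = NA_character_,
                       rate = NA_real_) {
  list(name = name, kind = kind, units = units, kernel = kernel,
       stride = stride, activation = activation, rate = rate)
}

new_model_spec <- function(name, input_shape, num_classes, layers,
                           conventions) {
  structure(list(name = name, input_shape = input_shape,
                 num_classes = num_classes, layers = layers,
                 conventions = conventions),
            class = "model_spec")
}

#' 2D-CNN fall-detection backbone
#'
#' Three convolutional stages (8, 32 and 128 feature maps, 3x3 kernels,
#' stride 1, valid padding; the first two followed by 2x2 max pooling and
#' batch normalization) feeding three dense layers FC6 (1200, relu),
#' FC7 (600, relu) and the softmax classifier FC8. The input is a stack of
#' `T` RGB frames; the frames are stacked along the channel axis so that 2D
#' convolutions slide over the spatial axes (`H x W` with `3*T` channels).
#'
#' @param num_classes number of activity classes (>= 2); default 11
#'   (5 fall types + 6 activities of daily living).
#' @param input_shape `c(T, H, W, 3)` frames; default `c(36, 32, 32, 3)`.
#' @param flatten `"propagated"` uses the flatten width implied by shape
#'   propagation for FC6's input; `"table"` forces the nominal width 1472 of
#'   the published architecture table (accounting only: with the default
#'   input the propagated width differs, and such a spec cannot be
#'   instantiated as an executable network).
#' @param dropout dropout rate after FC6 and FC7.
#' @return A `model_spec`.
#' @examples
#' build_cnn2d(11)
#' @export
build_cnn2d <- function(num_classes = 11,
                        input_shape = c(36, 32, 32, 3),
                        flatten = c("propagated", "table"),
                        dropout = 0.3) {
  flatten <- match.arg(flatten)
  num_classes <- as.integer(num_classes)
  if (is.na(num_classes) || num_classes < 2L) {
    stop("num_classes must be an integer >= 2", call. = FALSE)
  }
  if (length(input_shape) != 4L) {
    stop("input_shape must be c(frames, height, width, 3)", call. = FALSE)
  }
  layers <- list(
    layer_spec("Conv-1", "conv2d", units = 8L, kernel = 3L, stride = 1L,
               activation = "relu"),
    layer_spec("Pool1", "maxpool", kernel = 2L, stride = 2L),
    layer_spec("BN1", "batchnorm"),
    layer_spec("Conv-2", "conv2d", units = 32L, kernel = 3L, stride = 1L,
               activation = "relu"),
    layer_spec("Pool2", "maxpool", kernel = 2L, stride = 2L),
    layer_spec("BN2", "batchnorm"),
    layer_spec("Conv-3", "conv2d", units = 128L, kernel = 3L, stride = 1L,
               activation = "relu"),
    layer_spec("Flatten", "flatten"),
    layer_spec("FC6", "dense", units = 1200L, activation = "relu"),
    layer_spec("Drop6", "dropout", rate = dropout),
    layer_spec("FC7", "dense", units = 600L, activation = "relu"),
    layer_spec("Drop7", "dropout", rate = dropout),
    layer_spec("FC8", "dense", units = num_classes, activation = "softmax")
  )
  spec <- new_model_spec(
    "cnn2d", input_shape = as.integer(input_shape),
    num_classes = num_classes, layers = layers,
    conventions = list(flatten = flatten, table_flatten = 1472L,
                       frame_axis = "channels"))
  shape_propagate(spec)  # fail fast on impossible shapes
  spec
}

#' CNN-LSTM fall-detection backbone
#'
#' Two 1D convolutional stages (8 and 32 feature maps, kernel 3, stride 1,
#' each followed by window-2/stride-2 max pooling and batch normalization),
#' an LSTM with 32 units returning the full sequence, then the same dense
#' head as the 2D-CNN (FC6 1200, FC7 600, softmax FC8). Each input frame is
#' flattened to one step of a feature sequence (`T` steps of `H*W*3`
#' features), so the convolutions slide over time.
#'
#' @param num_classes number of activity classes (>= 2).
#' @param input_shape `c(T, features)` or `c(T, pixels, 3)`; default
#'   `c(192, 1024, 3)`, i.e. a 192-step sequence of 3072-wide features.
#' @param dropout dropout rate after FC6 and FC7.
#' @return A `model_spec`.
#' @examples
#' shape_propagate(build_cnn_lstm(11))
#' @export
build_cnn_lstm <- function(num_classes = 11,
                           input_shape = c(192, 1024, 3),
                           dropout = 0.3) {
  num_classes <- as.integer(num_classes)
  if (is.na(num_classes) || num_classes < 2L) {
    stop("num_classes must be an integer >= 2", call. = FALSE)
  }
  if (length(input_shape) == 3L) {
    input_shape <- c(input_shape[1L], input_shape[2L] * input_shape[3L])
  }
  if (length(input_shape) != 2L) {
    stop("input_shape must be c(steps, features) or c(steps, pixels, 3)",
         call. = FALSE)
  }
  layers <- list(
    layer_spec("Conv-1", "conv1d", units = 8L, kernel = 3L, stride = 1L,
               activation = "relu"),
    layer_spec("Pool1", "maxpool", kernel = 2L, stride = 2L),
    layer_spec("BN1", "batchnorm"),
    layer_spec("Conv-2", "conv1d", units = 32L, kernel = 3L, stride = 1L,
               activation = "relu"),
    layer_spec("Pool2", "maxpool", kernel = 2L, stride = 2L),
    layer_spec("BN2", "batchnorm"),
    layer_spec("LSTM", "lstm", units = 32L),
    layer_spec("Flatten", "flatten"),
    layer_spec("FC6", "dense", units = 1200L, activation = "relu"),
    layer_spec("Drop6", "dropout", rate = dropout),
    layer_spec("FC7", "dense", units = 600L, activation = "relu"),
    layer_spec("Drop7", "dropout", rate = dropout),
    layer_spec("FC8", "dense", units = num_classes, activation = "softmax")
  )
  spec <- new_model_spec(
    "cnn_lstm", input_shape = as.integer(input_shape),
    num_classes = num_classes, layers = layers,
    conventions = list(flatten = "propagated",
                       frame_axis = "sequence"))
  shape_propagate(spec)
  spec
}

# small dense-only model over flat feature vectors; used for fast training
# experiments and tests (input: a samples x features matrix)
#' @noRd
build_mlp <- function(num_classes, input_width, hidden = c(16, 8),
                      dropout = 0) {
  stopifnot(num_classes >= 2, length(hidden) == 2)
  layers <- list(
    layer_spec("FC6", "dense", units = as.integer(hidden[1L]),
               activation = "relu"),
    layer_spec("Drop6", "dropout", rate = dropout),
    layer_spec("FC7", "dense", units = as.integer(hidden[2L]),
               activation = "relu"),
    layer_spec("Drop7", "dropout", rate = dropout),
    layer_spec("FC8", "dense", units = as.integer(num_classes),
               activation = "softmax")
  )
  new_model_spec("mlp", as.integer(input_width), as.integer(num_classes),
                 layers, conventions = list(flatten = "propagated"))
}

#' Layer-by-layer shape propagation
#'
#' Walks a model spec and derives every layer's output shape: valid
#' convolutions with stride 1 give `L_out = L_in - kernel + 1`; max pooling
#' uses window 2, stride 2 with floor division; batch normalization,
#' dropout and the sequence-returning LSTM preserve shape.
#'
#' @param spec a `model_spec`.
#' @return data frame with one row per layer: `layer`, `kind`, `output`
#'   (printed shape), `size` (total output width) and, for dense layers,
#'   `fan_in`/`fan_out`.
#' @export
shape_propagate <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  shape <- if (spec$name == "cnn2d") {
    c(spec$input_shape[2L], spec$input_shape[3L],
      spec$input_shape[4L] * spec$input_shape[1L])
  } else {
    spec$input_shape
  }
  rows <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    fan_in <- NA_integer_
    shape <- switch(l$kind,
      conv2d = {
        out <- c(shape[1L] - l$kernel + 1L, shape[2L] - l$kernel + 1L, l$units)
        if (any(out[1:2] < 1L)) {
          stop(sprintf("layer %s: non-positive output size", l$name),
               call. = FALSE)
        }
        out
      },
      conv1d = {
        out <- c(shape[1L] - l$kernel + 1L, l$units)
        if (out[1L] < 1L) {
          stop(sprintf("layer %s: non-positive output length", l$name),
               call. = FALSE)
        }
        out
      },
      maxpool = {
        n_sp <- length(shape) - 1L
        out <- c(shape[seq_len(n_sp)] %/% 2L, shape[length(shape)])
        if (any(out[seq_len(n_sp)] < 1L)) {
          stop(sprintf("layer %s: non-positive output size", l$name),
               call. = FALSE)
        }
        out
      },
      batchnorm = shape,
      lstm = c(shape[1L], l$units),
      flatten = {
        width <- prod(shape)
        if (identical(spec$conventions$flatten, "table")) {
          width <- spec$conventions$table_flatten
        }
        width
      },
      dense = {
        fan_in <- shape[1L]
        l$units
      },
      dropout = shape,
      stop(sprintf("unknown layer kind '%s'", l$kind), call. = FALSE)
    )
    rows[[i]] <- data.frame(
      layer = l$name, kind = l$kind,
      output = paste(shape, collapse = " x "),
      size = prod(shape),
      fan_in = fan_in,
      fan_out = if (l$kind == "dense") l$units else NA_integer_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Per-layer parameter counts
#'
#' Standard counts per layer kind: dense `m*n + n`; 2D convolution
#' `k*k*c_in*c_out + c_out`; 1D convolution `k*c_in*c_out + c_out`; batch
#' normalization `4*channels` (scale, shift and the two running moments);
#' LSTM `4*(u*(u + f) + u)` for the four gates; pooling, flatten and
#' dropout store nothing.
#'
#' @param spec a `model_spec`.
#' @return data frame with columns `layer`, `kind`, `params`.
#' @export
param_count_table <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  shapes <- shape_propagate(spec)
  shape <- if (spec$name == "cnn2d") {
    c(spec$input_shape[2L], spec$input_shape[3L],
      spec$input_shape[4L] * spec$input_shape[1L])
  } else {
    spec$input_shape
  }
  params <- integer(length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    c_in <- shape[length(shape)]
    params[i] <- switch(l$kind,
      conv2d = l$kernel * l$kernel * c_in * l$units + l$units,
      conv1d = l$kernel * c_in * l$units + l$units,
      batchnorm = 4L * c_in,
      lstm = 4L * (l$units * (l$units + c_in) + l$units),
      dense = shapes$fan_in[i] * l$units + l$units,
      0L
    )
    # advance the running shape exactly as shape_propagate does
    shape <- shape_after(l, shape, spec)
  }
  data.frame(layer = shapes$layer, kind = shapes$kind, params = params,
             stringsAsFactors = FALSE)
}

shape_after <- function(l, shape, spec) {
  switch(l$kind,
    conv2d = c(shape[1L] - l$kernel + 1L, shape[2L] - l$kernel + 1L, l$units),
    conv1d = c(shape[1L] - l$kernel + 1L, l$units),
    maxpool = c(shape[-length(shape)] %/% 2L, shape[length(shape)]),
    lstm = c(shape[1L], l$units),
    flatten = if (identical(spec$conventions$flatten, "table"))
      spec$conventions$table_flatten else prod(shape),
    dense = l$units,
    shape)
}

#' @export
print.model_spec <- function(x, ...) {
  shapes <- shape_propagate(x)
  counts <- param_count_table(x)
  cat(sprintf("Model '%s' | input %s | %d classes\n",
              x$name, paste(x$input_shape, collapse = " x "), x$num_classes))
  tab <- data.frame(layer = shapes$layer, kind = shapes$kind,
                    output = shapes$output, params = counts$params)
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf("total parameters: %s\n", fmt_count(sum(counts$params))))
  invisible(x)
}

#' Serialize / read a model spec as JSON
#'
#' @param spec a `model_spec`.
#' @param path file path; for `model_spec_from_json` a path or JSON string.
#' @return `model_spec_to_json` returns `path` invisibly;
#'   `model_spec_from_json` returns a `model_spec`.
#' @export
model_spec_to_json <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  x <- unclass(spec)
  x$layers <- lapply(x$layers, function(l) l[!vapply(l, function(v)
    length(v) == 1L && is.na(v), TRUE)])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname model_spec_to_json
#' @export
model_spec_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  layers <- lapply(x$layers, function(l) {
    layer_spec(l$name, l$kind,
               units = as.integer(l$units %||% NA),
               kernel = as.integer(l$kernel %||% NA),
               stride = as.integer(l$stride %||% NA),
               activation = as.character(l$activation %||% NA),
               rate = as.numeric(l$rate %||% NA))
  })
  conv <- x$conventions
  if (!is.null(conv$table_flatten)) conv$table_flatten <- as.integer(conv$table_flatten)
  new_model_spec(x$name, as.integer(x$input_shape), as.integer(x$num_classes),
                 layers, conv)
}
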