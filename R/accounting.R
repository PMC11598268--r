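#' Pruning configuration
#'
#' Names the dense layers to prune and the per-layer reduction ranks. The
#' final softmax classifier (`FC8`) is never pruned and is explicitly
#' rejected, as are non-dense layers.
#'
#' @param layer_ranks named integer vector, e.g. `c(FC6 = 8, FC7 = 8)`.
#' @param density fraction of entries kept per singular vector, in (0, 1].
#' @param criterion component-selection rule; only `"absolute-weight"` is
#'   defined (entries are ranked by absolute value).
#' @return An object of class `prune_config`.
#' @examples
#' prune_config(c(FC6 = 8, FC7 = 8), density = 0.5)
#' @export
prune_config <- function(layer_ranks, density = 0.5,
                         criterion = "absolute-weight") {
  if (is.null(names(layer_ranks)) || any(!nzchar(names(layer_ranks)))) {
    stop("layer_ranks must be a named vector (layer name -> rank)",
         call. = FALSE)
  }
  ranks <- as.integer(layer_ranks)
  if (any(is.na(ranks)) || any(ranks < 1L)) {
    stop("reduction ranks must be positive integers", call. = FALSE)
  }
  if (!is.numeric(density) || density <= 0 || density > 1) {
    stop("density must be in (0, 1]", call. = FALSE)
  }
  criterion <- match.arg(criterion, "absolute-weight")
  structure(list(layer_ranks = stats::setNames(ranks, names(layer_ranks)),
                 density = density, criterion = criterion),
            class = "prune_config")
}

#' @export
print.prune_config <- function(x, ...) {
  cat("SLR prune config:",
      paste(sprintf("%s=%d", names(x$layer_ranks), x$layer_ranks),
            collapse = ", "),
      sprintf("| density %.2f | criterion %s\n", x$density, x$criterion))
  invisible(x)
}

#' Stored parameter count
#'
#' Counts the numeric values that must be stored to represent an object:
#' a dense layer stores `m*n + n`; SLR factors store the kept entries of
#' `U_k` and `Vt_k` (`k * ceiling(density*m)` and `k * ceiling(density*n)`),
#' the `k` singular values and the dense bias. With
#' `mode = "values+indices"` every structurally stored sparse entry
#' additionally counts two integer coordinates, modelling what a
#' coordinate-format sparse container writes to disk.
#'
#' @param x a `dense_layer`, `slr_factors`, `model_spec` or `fallnet_model`.
#' @param ... passed to methods.
#' @return integer count of stored values.
#' @export
stored_param_count <- function(x, ...) UseMethod("stored_param_count")

#' @export
stored_param_count.dense_layer <- function(x, ...) {
  nrow(x$W) * ncol(x$W) + length(x$b)
}

#' @rdname stored_param_count
#' @param mode `"values"` counts stored numeric values only;
#'   `"values+indices"` adds 2 integer indices per sparse entry.
#' @export
stored_param_count.slr_factors <- function(x, mode = c("values", "values+indices"),
                                           ...) {
  mode <- match.arg(mode)
  slr_stored_count(nrow(x$U_k), ncol(x$Vt_k), x$k, x$density, mode)
}

# closed-form stored count of an SLR-pruned m x n dense layer
slr_stored_count <- function(m, n, k, density,
                             mode = c("values", "values+indices")) {
  mode <- match.arg(mode)
  per_entry <- if (mode == "values") 1L else 3L
  entries <- k * ceiling(density * m) + k * ceiling(density * n)
  as.integer(per_entry * entries + k + n)
}

#' Percentage reduction in stored parameters
#'
#' @param original stored count before pruning (positive).
#' @param stored stored count after pruning (`<= original`).
#' @return `100 * (1 - stored / original)`.
#' @examples
#' reduction_percent(15, 11)
#' @export
reduction_percent <- function(original, stored) {
  if (any(original <= 0)) stop("original count must be positive", call. = FALSE)
  if (any(stored > original)) {
    stop("stored count exceeds original count", call. = FALSE)
  }
  100 * (1 - stored / original)
}

#' Per-layer parameter accounting of a pruned model
#'
#' Builds the accounting table behind a rank sweep: per layer the original
#' parameter count and the count stored after SLR pruning (untouched layers
#' keep their original count), with model totals and the percentage
#' reduction under both storage conventions.
#'
#' @param spec a [model_spec] (see [build_cnn2d()], [build_cnn_lstm()]).
#' @param config a [prune_config()], or `NULL` for no pruning.
#' @param basis `"model"` computes the reduction over all layers;
#'   `"fc"` over the pruned layers only.
#' @return An object of class `param_account`: a data frame with columns
#'   `layer`, `kind`, `original`, `stored_values`, `stored_with_indices`,
#'   plus attributes `totals` and `reduction_percent` (named by mode).
#' @export
param_account <- function(spec, config = NULL, basis = c("model", "fc")) {
  basis <- match.arg(basis)
  stopifnot(inherits(spec, "model_spec"))
  counts <- param_count_table(spec)
  stored_v <- counts$params
  stored_i <- counts$params
  pruned <- rep(FALSE, nrow(counts))
  if (!is.null(config)) {
    stopifnot(inherits(config, "prune_config"))
    check_prunable(spec, config)
    for (nm in names(config$layer_ranks)) {
      i <- match(nm, counts$layer)
      k <- config$layer_ranks[[nm]]
      dims <- dense_dims(spec, nm)
      r <- min(dims$m, dims$n)
      if (k > r) {
        stop(sprintf("rank %d exceeds min(m, n) = %d for layer %s", k, r, nm),
             call. = FALSE)
      }
      stored_v[i] <- slr_stored_count(dims$m, dims$n, k, config$density,
                                      "values")
      stored_i[i] <- slr_stored_count(dims$m, dims$n, k, config$density,
                                      "values+indices")
      pruned[i] <- TRUE
    }
  }
  tab <- data.frame(layer = counts$layer, kind = counts$kind,
                    original = counts$params,
                    stored_values = stored_v,
                    stored_with_indices = stored_i,
                    pruned = pruned,
                    stringsAsFactors = FALSE)
  sel <- if (basis == "fc" && any(pruned)) pruned else rep(TRUE, nrow(tab))
  totals <- c(original = sum(tab$original[sel]),
              stored_values = sum(tab$stored_values[sel]),
              stored_with_indices = sum(tab$stored_with_indices[sel]))
  # computed directly (not via reduction_percent): a full-rank lossless
  # factorisation can store more than the dense layer, giving a negative
  # reduction, which is legal here
  red <- c(values = 100 * (1 - totals[["stored_values"]] /
                             totals[["original"]]),
           `values+indices` = 100 * (1 - totals[["stored_with_indices"]] /
                                       totals[["original"]]))
  structure(tab, class = c("param_account", "data.frame"),
            totals = totals, reduction_percent = red, basis = basis)
}

#' @export
print.param_account <- function(x, ...) {
  cat(sprintf("Parameter account (basis: %s)\n", attr(x, "basis")))
  print.data.frame(x, row.names = FALSE)
  tot <- attr(x, "totals")
  red <- attr(x, "reduction_percent")
  cat(sprintf("totals: original %s | stored %s (values) / %s (values+indices)\n",
              fmt_count(tot[["original"]]), fmt_count(tot[["stored_values"]]),
              fmt_count(tot[["stored_with_indices"]])))
  cat(sprintf("reduction: %.2f%% (values) / %.2f%% (values+indices)\n",
              red[["values"]], red[["values+indices"]]))
  invisible(x)
}

# validate a prune config against a model spec: layers must exist, be dense,
# and must not be the final classifier
check_prunable <- function(spec, config) {
  dense_names <- vapply(spec$layers, function(l) l$name, "")
  kinds <- vapply(spec$layers, function(l) l$kind, "")
  last_dense <- rev(dense_names[kinds == "dense"])[1L]
  for (nm in names(config$layer_ranks)) {
    i <- match(nm, dense_names)
    if (is.na(i)) {
      stop(sprintf("prune config names unknown layer '%s'", nm), call. = FALSE)
    }
    if (kinds[i] != "dense") {
      stop(sprintf("layer '%s' is a %s layer; only dense layers can be SLR-pruned",
                   nm, kinds[i]), call. = FALSE)
    }
    if (identical(nm, last_dense)) {
      stop(sprintf("layer '%s' is the final classifier and is never pruned", nm),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# input/output widths of a named dense layer in a model spec
dense_dims <- function(spec, name) {
  shapes <- shape_propagate(spec)
  i <- match(name, shapes$layer)
  if (is.na(i)) stop(sprintf("no layer named '%s'", name), call. = FALSE)
  list(m = shapes$fan_in[i], n = shapes$fan_out[i])
}
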