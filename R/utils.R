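# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dim <- function(...) stop(sprintf(...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite entries in %s", what), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
apply_activation <- function(x, g) {
  switch(g,
    identity = x,
    relu = pmax(x, 0),
    softmax = {
      if (is.matrix(x)) {
        e <- exp(x - apply(x, 1L, max))
        e / rowSums(e)
      } else {
        e <- exp(x - max(x))
        e / sum(e)
      }
    },
    stop(sprintf("unknown activation '%s' (use relu, softmax or identity)", g),
         call. = FALSE)
  )
}

# indices of the ceil(density * length) largest |values|; ties broken by
# lowest index (order() with |x| descending is stable on ties)
top_abs_indices <- function(x, density) {
  n_keep <- as.integer(ceiling(density * length(x)))
  sort(order(-abs(x))[seq_len(n_keep)])
}

fmt_count <- function(x) formatC(x, big.mark = ",", format = "d")
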