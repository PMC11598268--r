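# Synthetic fall / ADL frame-sequence generator.
#
# Each sequence shows a bright ellipsoidal figure moving over a noisy grey
# background. The eleven default classes mirror the standard benchmark
# class structure: five fall types (accelerating downward trajectories that
# end in a horizontal posture, each with a distinct direction/timing) and
# six activities of daily living (level or slow, non-accelerating motion).
# All trajectory equations and the noise level are artifact choices of this
# generator; they are documented in the methods vignette.

#' Catalogue of synthetic activity classes
#'
#' @param binary collapse to two classes (`fall`, `non_fall`).
#' @return data frame with columns `class_id`, `name`, `kind`.
#' @examples
#' class_catalogue()
#' @export
class_catalogue <- function(binary = FALSE) {
  if (binary) {
    return(data.frame(class_id = 1:2, name = c("fall", "non_fall"),
                      kind = c("fall", "adl"), stringsAsFactors = FALSE))
  }
  data.frame(
    class_id = 1:11,
    name = c("fall_forward_hands", "fall_forward_knees", "fall_backward",
             "fall_lateral", "fall_sitting",
             "walk", "stand", "sit", "pick_up", "jump", "lie_down"),
    kind = c(rep("fall", 5), rep("adl", 6)),
    stringsAsFactors = FALSE)
}

# smooth 0..1 ramp of s over [lo, hi]
ramp <- function(s, lo, hi) pmin(1, pmax(0, (s - lo) / (hi - lo)))

# figure state (cx, cy, theta, scale) at phase s in [0, 1];
# jit: per-sequence jitter list (x0, speed, dir)
motion_profile <- function(name, s, jit) {
  x0 <- jit$x0; sp <- jit$speed
  cy_up <- 0.62; cy_floor <- 0.80
  th <- 0; cx <- x0; cy <- cy_up; sc <- 1
  switch(name,
    fall_forward_hands = {
      q <- ramp(s, 0.5, 0.9)^2 * sp
      cx <- x0 + 0.04 * pmin(s / 0.5, 1) + 0.18 * q
      th <- (pi / 2) * q
      cy <- cy_up + (cy_floor - cy_up) * q
    },
    fall_forward_knees = {
      kneel <- ramp(s, 0.35, 0.6)
      q <- ramp(s, 0.6, 0.95)^2 * sp
      sc <- 1 - 0.15 * kneel
      cx <- x0 + 0.10 * q
      th <- (pi / 2) * q
      cy <- cy_up + 0.08 * kneel + (cy_floor + 0.02 - cy_up - 0.08) * q
    },
    fall_backward = {
      q <- ramp(s, 0.5, 0.9)^2 * sp
      cx <- x0 - 0.18 * q
      th <- -(pi / 2) * q
      cy <- cy_up + (cy_floor - cy_up) * q
    },
    fall_lateral = {
      q <- ramp(s, 0.6, 0.95)^2 * sp
      th <- (pi / 2) * q
      cy <- cy_up + (cy_floor - cy_up) * q
    },
    fall_sitting = {
      sit <- ramp(s, 0.25, 0.55)
      q <- ramp(s, 0.55, 0.9)^2 * sp
      cx <- x0 - 0.06 * q
      th <- 0.15 * sit + (1.25 - 0.15) * q
      cy <- cy_up + 0.10 * sit + (cy_floor + 0.02 - cy_up - 0.10) * q
    },
    walk = {
      cx <- x0 + 0.45 * s * sp * jit$dir
      cy <- cy_up + 0.012 * sin(8 * pi * s)
      th <- 0.06 * sin(8 * pi * s)
    },
    stand = {
      cx <- x0 + 0.01 * sin(2 * pi * s)
      th <- 0.04 * sin(2 * pi * s)
    },
    sit = {
      d <- ramp(s, 0.25, 0.7)
      d <- d * d * (3 - 2 * d)        # smoothstep: no terminal acceleration
      cy <- cy_up + 0.10 * d
      th <- 0.12 * d
      sc <- 1 - 0.1 * d
    },
    pick_up = {
      bend <- sin(pi * ramp(s, 0.2, 0.8))^2
      th <- 0.9 * bend
      cy <- cy_up + 0.07 * bend
    },
    jump = {
      h <- sin(pi * s)^2
      cy <- cy_up - 0.16 * h * sp
      sc <- 1 - 0.05 * h
    },
    lie_down = {
      d <- ramp(s, 0.1, 0.9) * sp     # slow, constant-rate descent
      d <- pmin(d, 1)
      th <- (pi / 2) * d
      cy <- cy_up + (cy_floor - cy_up) * d
    },
    stop(sprintf("unknown activity class '%s'", name), call. = FALSE)
  )
  list(cx = cx, cy = cy, theta = th, scale = sc)
}

render_frame <- function(H, W, state, rx = 0.075, ry = 0.22) {
  yy <- matrix((seq_len(H) - 0.5) / H, H, W)
  xx <- matrix((seq_len(W) - 0.5) / W, H, W, byrow = TRUE)
  dx <- xx - state$cx
  dy <- yy - state$cy
  l <- dx * sin(state$theta) + dy * cos(state$theta)
  tr <- dx * cos(state$theta) - dy * sin(state$theta)
  inside <- (l / (ry * state$scale))^2 + (tr / (rx * state$scale))^2 <= 1
  inside
}

#' Generate one labelled synthetic frame sequence
#'
#' Renders `n_frames` RGB frames of a moving bright figure on a constant
#' grey background with additive Gaussian pixel noise. Identical
#' `(class_id, seed)` and parameters give a bit-identical tensor.
#'
#' @param class_id class id from the `catalogue`.
#' @param n_frames,H,W sequence length and frame size (all >= 4).
#' @param seed integer seed for the per-sequence jitter and noise.
#' @param noise_sd Gaussian pixel noise standard deviation (default 0.05).
#' @param figure render the moving figure (set `FALSE` for a pure
#'   background sequence).
#' @param catalogue a [class_catalogue()].
#' @return An object of class `frame_sequence`: list with `frames`
#'   (`n_frames x H x W x 3` array in `[0, 1]`), `label`, `seed`.
#' @examples
#' s <- generate_sequence(1, n_frames = 8, H = 16, W = 16, seed = 1)
#' dim(s$frames)
#' @export
generate_sequence <- function(class_id, n_frames = 36, H = 32, W = 32,
                              seed = 1, noise_sd = 0.05, figure = TRUE,
                              catalogue = class_catalogue()) {
  if (n_frames < 4 || H < 4 || W < 4) {
    stop("n_frames, H and W must all be >= 4", call. = FALSE)
  }
  i <- match(class_id, catalogue$class_id)
  if (is.na(i)) {
    stop(sprintf("unknown class id %s", as.character(class_id)), call. = FALSE)
  }
  name <- catalogue$name[i]
  set.seed(as.integer(seed))
  jit <- list(x0 = 0.35 + stats::runif(1, 0, 0.3),
              speed = stats::runif(1, 0.9, 1.1),
              dir = sample(c(-1, 1), 1))
  bg <- 0.25
  col_fig <- c(0.95, 0.9, 0.82)
  frames <- array(bg, c(n_frames, H, W, 3))
  if (figure) {
    for (t in seq_len(n_frames)) {
      s <- (t - 1) / (n_frames - 1)
      st <- motion_profile(name, s, jit)
      inside <- render_frame(H, W, st)
      for (ch in 1:3) {
        f <- frames[t, , , ch]
        f[inside] <- col_fig[ch]
        frames[t, , , ch] <- f
      }
    }
  }
  if (noise_sd > 0) {
    frames <- frames + array(stats::rnorm(length(frames), 0, noise_sd),
                             dim(frames))
    frames[frames < 0] <- 0
    frames[frames > 1] <- 1
  }
  structure(list(frames = frames, label = catalogue$class_id[i],
                 class_name = name, kind = catalogue$kind[i], seed = seed),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_sequence '%s' (class %d, %s): %d frames of %dx%dx%d, seed %d\n",
              x$class_name, x$label, x$kind, d[1L], d[2L], d[3L], d[4L],
              x$seed))
  invisible(x)
}

#' Figure centroid per frame
#'
#' Row/column centroid of the bright-figure pixels (luminance threshold
#' halfway between background and figure), in pixel units; rows grow
#' downward.
#'
#' @param seq a `frame_sequence`.
#' @return data frame with columns `frame`, `row`, `col`.
#' @export
sequence_centroids <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  d <- dim(seq$frames)
  out <- data.frame(frame = seq_len(d[1L]), row = NA_real_, col = NA_real_)
  for (t in seq_len(d[1L])) {
    lum <- (seq$frames[t, , , 1] + seq$frames[t, , , 2] +
              seq$frames[t, , , 3]) / 3
    hit <- which(lum > 0.55, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      out$row[t] <- mean(hit[, 1L])
      out$col[t] <- mean(hit[, 2L])
    }
  }
  out
}

#' Generate a balanced synthetic dataset
#'
#' `n_per_class` sequences per catalogue class; per-sequence seeds are
#' derived deterministically from the master seed and the order is shuffled
#' reproducibly.
#'
#' @param n_per_class sequences per class (>= 1).
#' @param catalogue a [class_catalogue()].
#' @param n_frames,H,W sequence geometry.
#' @param seed master seed.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @return An object of class `fall_dataset`: list with `sequences` (list
#'   of `frame_sequence`), `labels` (integer vector), `catalogue`, `seed`.
#' @examples
#' ds <- make_dataset(1, n_frames = 8, H = 8, W = 8, seed = 1)
#' table(ds$labels)
#' @export
make_dataset <- function(n_per_class = 40, catalogue = class_catalogue(),
                         n_frames = 36, H = 32, W = 32, seed = 1,
                         noise_sd = 0.05) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  combos <- expand.grid(rep = seq_len(n_per_class),
                        class = catalogue$class_id)
  seq_seed <- (abs(as.integer(seed)) %% 20000L) * 100000L +
    combos$class * 1000L + combos$rep
  sequences <- mapply(function(cl, ss) {
    generate_sequence(cl, n_frames = n_frames, H = H, W = W, seed = ss,
                      noise_sd = noise_sd, catalogue = catalogue)
  }, combos$class, seq_seed, SIMPLIFY = FALSE)
  set.seed(as.integer(seed))
  ord <- sample(seq_along(sequences))
  structure(list(sequences = sequences[ord],
                 labels = combos$class[ord],
                 catalogue = catalogue, seed = seed,
                 geometry = c(n_frames = n_frames, H = H, W = W)),
            class = "fall_dataset")
}

#' @export
print.fall_dataset <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("fall_dataset: %d sequences (%d classes), %d frames of %dx%d, seed %d\n",
              length(x$sequences), nrow(x$catalogue), g[["n_frames"]],
              g[["H"]], g[["W"]], x$seed))
  invisible(x)
}

#' Convert a dataset to model input arrays
#'
#' `dataset_to_cnn2d` stacks the frames of each sequence along the channel
#' axis, producing an `(H, W, 3*T, N)` array for [build_cnn2d()];
#' `dataset_to_sequence` flattens each frame to one step of a feature
#' sequence, producing a `(T, H*W*3, N)` array for [build_cnn_lstm()].
#'
#' @param ds a `fall_dataset`.
#' @return list with `x` (input array) and `y` (integer labels).
#' @export
dataset_to_cnn2d <- function(ds) {
  stopifnot(inherits(ds, "fall_dataset"))
  g <- ds$geometry
  N <- length(ds$sequences)
  x <- array(0, c(g[["H"]], g[["W"]], 3L * g[["n_frames"]], N))
  for (i in seq_len(N)) {
    # (T,H,W,3) -> (H,W,3,T) -> channels (3*T)
    x[, , , i] <- aperm(ds$sequences[[i]]$frames, c(2, 3, 4, 1))
  }
  list(x = x, y = ds$labels)
}

#' @rdname dataset_to_cnn2d
#' @export
dataset_to_sequence <- function(ds) {
  stopifnot(inherits(ds, "fall_dataset"))
  g <- ds$geometry
  N <- length(ds$sequences)
  Fn <- g[["H"]] * g[["W"]] * 3L
  x <- array(0, c(g[["n_frames"]], Fn, N))
  for (i in seq_len(N)) {
    x[, , i] <- matrix(ds$sequences[[i]]$frames, g[["n_frames"]], Fn)
  }
  list(x = x, y = ds$labels)
}

#' Export / import a dataset as PNG frames plus a CSV manifest
#'
#' Writes each frame as `seq<i>_frame<t>.png` under `dir` with a
#' `manifest.csv` (sequence, frame file, label, class name, seed), so real
#' extracted frames can later be substituted in the same layout. Requires
#' the `png` package.
#'
#' @param ds a `fall_dataset`.
#' @param dir output/input directory.
#' @return `export_frames` returns `dir` invisibly; `import_frames` a
#'   `fall_dataset`.
#' @export
export_frames <- function(ds, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for frame export", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(ds$sequences)) {
    sq <- ds$sequences[[i]]
    Tn <- dim(sq$frames)[1L]
    for (t in seq_len(Tn)) {
      file <- sprintf("seq%04d_frame%03d.png", i, t)
      png::writePNG(sq$frames[t, , , ], file.path(dir, file))
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = i, frame = t, file = file, label = sq$label,
        class_name = sq$class_name, kind = sq$kind, seed = sq$seed)
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname export_frames
#' @export
import_frames <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for frame import", call. = FALSE)
  }
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  ids <- sort(unique(man$sequence))
  sequences <- vector("list", length(ids))
  labels <- integer(length(ids))
  for (j in seq_along(ids)) {
    rows <- man[man$sequence == ids[j], ]
    rows <- rows[order(rows$frame), ]
    first <- png::readPNG(file.path(dir, rows$file[1L]))
    frames <- array(0, c(nrow(rows), dim(first)))
    for (t in seq_len(nrow(rows))) {
      frames[t, , , ] <- png::readPNG(file.path(dir, rows$file[t]))
    }
    sequences[[j]] <- structure(
      list(frames = frames, label = rows$label[1L],
           class_name = rows$class_name[1L], kind = rows$kind[1L],
           seed = rows$seed[1L]),
      class = "frame_sequence")
    labels[j] <- rows$label[1L]
  }
  d <- dim(sequences[[1L]]$frames)
  structure(list(sequences = sequences, labels = labels,
                 catalogue = class_catalogue(), seed = NA_integer_,
                 geometry = c(n_frames = d[1L], H = d[2L], W = d[3L])),
            class = "fall_dataset")
}
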