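#' Windowed multichannel time-series batch
#'
#' The universal data container of the pipeline: `N` fixed-length windows of
#' an `S`-channel signal, each `T` samples long, with one integer class label
#' per window. Stored as a dense array `X` of dimension `N x S x T` together
#' with an integer label vector `y` (class ids in `0..C-1`) and metadata
#' recording the window length, the overlap fraction used during segmentation
#' and the seed of the generating process.
#'
#' @param X numeric array of dimension `N x S x T`; all values finite.
#' @param y integer vector of length `N` with class ids in `0..C-1`.
#' @param window window length `T` (defaults to `dim(X)[3]`).
#' @param overlap overlap fraction in `[0, 1)` recorded from segmentation.
#' @param seed integer seed of the generating process (bookkeeping only).
#'
#' @return An object of class `window_batch` with elements `X`, `y` and
#'   `meta` (list with `window`, `overlap`, `seed`).
#' @export
window_batch <- function(X, y, window = NULL, overlap = NA_real_, seed = NA_integer_) {
  if (!is.array(X) || length(dim(X)) != 3L) {
    stop_invalid("X must be a 3-d array (windows x channels x time)")
  }
  if (!all(is.finite(X))) stop_invalid("X contains non-finite values")
  y <- as.integer(y)
  if (length(y) != dim(X)[1L]) {
    stop_invalid("length(y) (%d) does not match number of windows (%d)",
                 length(y), dim(X)[1L])
  }
  if (is.null(window)) window <- dim(X)[3L]
  if (window != dim(X)[3L]) {
    stop_invalid("window metadata (%d) does not match time axis (%d)",
                 window, dim(X)[3L])
  }
  structure(
    list(X = X, y = y,
         meta = list(window = as.integer(window), overlap = overlap,
                     seed = seed)),
    class = "window_batch"
  )
}

#' @export
print.window_batch <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<window_batch> %d windows x %d channel(s) x %d samples, %d class(es)\n",
              d[1L], d[2L], d[3L], length(unique(x$y))))
  invisible(x)
}

#' @export
dim.window_batch <- function(x) dim(x$X)

#' Number of windows in a batch
#' @param batch a [window_batch()].
#' @return Integer count of windows.
#' @export
n_windows <- function(batch) dim(batch$X)[1L]

# Extract window i as an S x T matrix (robust to S == 1 dimension dropping).
win_matrix <- function(batch_or_X, i) {
  X <- if (is.list(batch_or_X)) batch_or_X$X else batch_or_X
  matrix(X[i, , ], nrow = dim(X)[2L])
}

#' Subset a window batch by window index
#' @param batch a [window_batch()].
#' @param idx integer window indices.
#' @return A [window_batch()] containing the selected windows.
#' @export
subset_windows <- function(batch, idx) {
  window_batch(batch$X[idx, , , drop = FALSE], batch$y[idx],
               window = batch$meta$window, overlap = batch$meta$overlap,
               seed = batch$meta$seed)
}

#' A raw (unsegmented) labeled recording
#'
#' A long `S x L` multichannel signal carrying a single class label, standing
#' in for e.g. a whole-night polysomnography trace before windowing.
#'
#' @param values numeric matrix `S x L` (channels by samples), all finite.
#' @param sampling_rate sampling rate in Hz (bookkeeping only).
#' @param label integer class id for the whole recording.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(values, sampling_rate = 100, label = 0L) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  if (!is.matrix(values) || !all(is.finite(values))) {
    stop_invalid("values must be a finite channels x length matrix")
  }
  if (nrow(values) < 1L) stop_invalid("at least one channel required")
  structure(list(values = values, sampling_rate = sampling_rate,
                 label = as.integer(label)),
            class = "raw_recording")
}

#' Write a window batch to a plain-text dataset file
#'
#' The on-disk format is a self-describing CSV: a short header of
#' `#key=value` lines (`window`, `overlap`, `seed`, `channels`) followed by
#' one row per window holding the label and the channel-major flattened
#' samples (`ch1_t1..ch1_tT, ch2_t1..`).
#'
#' @param batch a [window_batch()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_window_batch <- function(batch, path) {
  S <- dim(batch$X)[2L]
  flat <- flatten_windows(batch)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("#window=%d", batch$meta$window),
    sprintf("#overlap=%s", format(batch$meta$overlap, digits = 17)),
    sprintf("#seed=%s", format(batch$meta$seed)),
    sprintf("#channels=%d", S)
  ), con)
  utils::write.table(
    cbind(label = batch$y, as.data.frame(flat)),
    con, sep = ",", row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a window batch written by [write_window_batch()]
#' @param path dataset file path.
#' @return A [window_batch()].
#' @export
read_window_batch <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  get_attr <- function(key) {
    m <- grep(sprintf("^#%s=", key), hdr, value = TRUE)
    if (!length(m)) return(NA)
    sub(sprintf("^#%s=", key), "", m[1L])
  }
  window <- as.integer(get_attr("window"))
  overlap <- as.numeric(get_attr("overlap"))
  seed <- suppressWarnings(as.integer(get_attr("seed")))
  S <- as.integer(get_attr("channels"))
  tab <- utils::read.table(path, sep = ",", comment.char = "#")
  y <- as.integer(tab[[1L]])
  flat <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(flat) <- NULL
  X <- unflatten_windows(flat, n_channels = S, window = window)
  window_batch(X, y, window = window, overlap = overlap, seed = seed)
}
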