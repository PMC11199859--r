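#' Flatten windows to a matrix (channel-major)
#'
#' Reshapes an `N x S x T` batch to an `N x (S*T)` matrix in channel-major
#' order: channel 1's `T` samples first, then channel 2's, and so on. The
#' operation is exactly invertible given `(S, T)` via [unflatten_windows()].
#'
#' @param batch a [window_batch()] or a plain `N x S x T` array.
#' @return A numeric `N x (S*T)` matrix.
#' @export
flatten_windows <- function(batch) {
  X <- if (is.list(batch)) batch$X else batch
  d <- dim(X)
  M <- aperm(X, c(3L, 2L, 1L))   # T x S x N; column-major = channel-major rows
  dim(M) <- c(d[3L] * d[2L], d[1L])
  t(M)
}

#' Inverse of [flatten_windows()]
#' @param flat numeric `N x (S*T)` matrix in channel-major layout.
#' @param n_channels number of channels `S`.
#' @param window window length `T`.
#' @return An `N x S x T` array.
#' @export
unflatten_windows <- function(flat, n_channels, window) {
  if (ncol(flat) != n_channels * window) {
    stop_invalid("ncol(flat) = %d does not equal S*T = %d",
                 ncol(flat), n_channels * window)
  }
  M <- t(flat)
  dim(M) <- c(window, n_channels, nrow(flat))
  aperm(M, c(3L, 2L, 1L))
}

#' Kernel-PCA fusion model
#'
#' Holds one kernel-PCA branch for the time-augmented view and one for the
#' frequency-augmented view. Each branch is fitted independently on a matrix
#' of flattened augmented windows; fused outputs concatenate the two
#' `n_components`-dimensional projections.
#'
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param gamma RBF bandwidth parameter of `exp(-gamma * |x - y|^2)`;
#'   `NULL` (default) uses the median heuristic per branch at fit time,
#'   `1 / median(|x_i - x_j|^2)` over the fit rows, which keeps the kernel
#'   matrix informative whatever the signal scale (a fixed `1/(S*T)`
#'   bandwidth degenerates toward an identity kernel matrix when the
#'   per-sample variance is far from 1).
#' @param n_components number of components `C` per branch; `NULL` (default)
#'   resolves at fit time to `min(floor(S*T/2), n_fit - 1, fit_cap - 1)`.
#' @param fit_cap maximum number of rows used to fit each branch
#'   (default 1000); larger fit sets are subsampled with `fit_seed`.
#' @param fit_seed seed for the fit subsample (default 1).
#' @return An unfitted object of class `fusion_model`.
#' @export
fusion_model <- function(kernel = c("rbf", "linear"), gamma = NULL,
                         n_components = NULL, fit_cap = 1000L, fit_seed = 1L) {
  kernel <- match.arg(kernel)
  if (!is.null(n_components) && n_components < 1L) {
    stop_invalid("n_components must be >= 1")
  }
  structure(list(kernel = kernel, gamma = gamma,
                 n_components = n_components,
                 fit_cap = as.integer(fit_cap),
                 fit_seed = as.integer(fit_seed),
                 fitted = FALSE, branches = NULL, fit_sample_size = NA_integer_),
            class = "fusion_model")
}

# Median-heuristic RBF bandwidth: 1 / median squared pairwise distance,
# estimated on at most 200 deterministic-subsampled rows.
median_gamma <- function(mat) {
  n <- nrow(mat)
  if (n > 200L) {
    keep <- round(seq(1L, n, length.out = 200L))
    mat <- mat[keep, , drop = FALSE]
  }
  med <- stats::median(stats::dist(mat)^2)
  if (!is.finite(med) || med <= 0) med <- ncol(mat)
  1 / med
}

branch_kernel <- function(model, mat) {
  if (model$kernel == "rbf") {
    g <- if (is.null(model$gamma)) median_gamma(mat) else model$gamma
    kernlab::rbfdot(sigma = g)
  } else {
    kernlab::vanilladot()
  }
}

# Fit one branch with kernlab and normalize eigenvector signs so the
# largest-magnitude loading of each component is positive.
fit_branch <- function(model, mat, n_comp) {
  kp <- kernlab::kpca(mat, kernel = branch_kernel(model, mat),
                      features = n_comp)
  pcv <- kernlab::pcv(kp)
  if (ncol(pcv) < n_comp) {
    warning(sprintf("kernel PCA branch rank-limited: %d component(s) retained instead of %d",
                    ncol(pcv), n_comp), call. = FALSE)
  }
  flip <- apply(pcv, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  kp@pcv <- sweep(pcv, 2L, flip, `*`)
  kp@rotated <- sweep(kernlab::rotated(kp), 2L, flip, `*`)
  kp
}

#' Fit the two kernel-PCA branches of a fusion model
#'
#' Each branch is fitted independently: the kernel matrix of its flattened
#' view is centered in feature space and the top `n_components` eigenvectors
#' are retained (eigenvalues in non-increasing order; the component sign is
#' fixed so the largest-magnitude loading is positive). If either view has
#' more rows than `fit_cap`, a seeded subsample of `fit_cap` rows is used.
#'
#' @param model an unfitted [fusion_model()].
#' @param time_flat numeric matrix of flattened time-augmented windows.
#' @param freq_flat numeric matrix of flattened frequency-augmented windows.
#' @return The fitted `fusion_model`.
#' @export
fit_fusion <- function(model, time_flat, freq_flat) {
  stopifnot(inherits(model, "fusion_model"))
  if (nrow(time_flat) != nrow(freq_flat)) {
    stop_invalid("time and frequency views must have the same number of rows")
  }
  n <- nrow(time_flat)
  if (n > model$fit_cap) {
    keep <- with_seed(mix_seed(model$fit_seed, 3511L),
                      sample.int(n, model$fit_cap))
    time_flat <- time_flat[keep, , drop = FALSE]
    freq_flat <- freq_flat[keep, , drop = FALSE]
    n <- model$fit_cap
  }
  d <- ncol(time_flat)
  n_comp <- model$n_components
  if (is.null(n_comp)) n_comp <- floor(d / 2)
  n_comp <- min(n_comp, n - 1L)
  if (n_comp < 1L) stop_invalid("need at least 2 fit rows")
  if (!is.null(model$n_components) && n_comp < model$n_components) {
    warning(sprintf("n_components reduced to %d (fit sample has %d rows)",
                    n_comp, n), call. = FALSE)
  }
  model$n_components <- n_comp
  model$branches <- list(time = fit_branch(model, time_flat, n_comp),
                         freq = fit_branch(model, freq_flat, n_comp))
  model$fit_sample_size <- n
  model$fitted <- TRUE
  model
}

# Project new rows through a fitted branch. kernlab scores are sqrt(n)
# times the conventional kernel-PCA scores (eigenvector-of-centered-Gram
# scaled by sqrt(eigenvalue)); rescale so the linear kernel reproduces
# classical PCA scores exactly.
branch_transform <- function(kp, flat, n_comp, n_fit) {
  sc <- kernlab::predict(kp, flat)
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = nrow(flat))
  sc[, seq_len(min(n_comp, ncol(sc))), drop = FALSE] / sqrt(n_fit)
}

#' Project flattened views through one fitted branch
#' @param model a fitted [fusion_model()].
#' @param flat numeric matrix of flattened windows.
#' @param branch `"time"` or `"freq"`.
#' @return Numeric `nrow(flat) x n_components` score matrix.
#' @export
fusion_transform <- function(model, flat, branch = c("time", "freq")) {
  branch <- match.arg(branch)
  if (!isTRUE(model$fitted)) stop_invalid("fusion model is not fitted")
  branch_transform(model$branches[[branch]], flat, model$n_components,
                   model$fit_sample_size)
}

#' Eigenvalues of a fitted branch
#' @param model a fitted [fusion_model()].
#' @param branch `"time"` or `"freq"`.
#' @return Numeric vector of kernel-PCA eigenvalues, non-increasing.
#' @export
fusion_eig <- function(model, branch = c("time", "freq")) {
  branch <- match.arg(branch)
  if (!isTRUE(model$fitted)) stop_invalid("fusion model is not fitted")
  kernlab::eig(model$branches[[branch]])
}

#' Fuse a time-augmented and a frequency-augmented view
#'
#' Each window's flattened time view and frequency view are projected
#' through their respective fitted kernel-PCA branches (giving `C`
#' coordinates each), the projections are concatenated to a `2C`-vector,
#' zero-padded up to the nearest multiple of the channel count `S`, and
#' reshaped to `S x ceiling(2C/S)`. The result is a valid encoder input of
#' the original channel count; the encoder's adaptive pooling absorbs the
#' changed length.
#'
#' @param model a fitted [fusion_model()].
#' @param t_aug time-augmented [window_batch()].
#' @param f_aug frequency-augmented [window_batch()] of the same shape.
#' @return A [window_batch()] of dimension `N x S x ceiling(2C/S)`.
#' @export
fuse_views <- function(model, t_aug, f_aug) {
  if (!isTRUE(model$fitted)) stop_invalid("fusion model is not fitted; call fit_fusion() first")
  if (!identical(dim(t_aug$X)[1L], dim(f_aug$X)[1L])) {
    stop_invalid("views disagree on the number of windows")
  }
  S <- dim(t_aug$X)[2L]
  C <- model$n_components
  zt <- branch_transform(model$branches$time, flatten_windows(t_aug), C,
                         model$fit_sample_size)
  zf <- branch_transform(model$branches$freq, flatten_windows(f_aug), C,
                         model$fit_sample_size)
  fused <- cbind(zt, zf)                      # N x 2C
  L <- ceiling(ncol(fused) / S)
  pad <- L * S - ncol(fused)
  if (pad > 0L) fused <- cbind(fused, matrix(0, nrow(fused), pad))
  X <- unflatten_windows(fused, n_channels = S, window = L)
  window_batch(X, t_aug$y, window = L, overlap = t_aug$meta$overlap,
               seed = t_aug$meta$seed)
}
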