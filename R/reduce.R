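#' Variance-threshold decomposition (PCA / SVD)
#'
#' Fits a linear decomposition on the training rows only and keeps the
#' minimal number of leading components whose cumulative explained variance
#' reaches the threshold (default: over 90% contribution to the variance).
#' PCA centers the data before decomposing; the SVD variant decomposes the
#' raw matrix. The returned projection transforms any row-compatible matrix
#' (e.g. validation and test rows) into the reduced space.
#'
#' @param X Numeric training matrix (or feature tibble); at least two rows.
#' @param threshold Cumulative explained-variance fraction to reach
#'   (default 0.9).
#' @param method `"pca"` (centered) or `"svd"` (uncentered).
#' @return Object of class `variance_reduction`: list with `k` (components
#'   kept), `explained` (cumulative fraction at `k`), `rotation`, `center`,
#'   `method`, `threshold` and `transform` (a function of a matrix).
#' @examples
#' X <- matrix(rnorm(200), 20)
#' red <- variance_reduce(X, threshold = 0.9, method = "pca")
#' red$k
#' @export
variance_reduce <- function(X, threshold = 0.9, method = c("pca", "svd")) {
  method <- match.arg(method)
  X <- as_feature_matrix(X)
  if (nrow(X) < 2) abort("variance reduction needs >= 2 rows.")
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  center <- if (method == "pca") colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, center)
  if (all(abs(Xc) < 1e-12)) abort("constant matrix: no variance to decompose.")
  dec <- svd(Xc)
  ev <- dec$d^2
  ev <- ev[ev > max(ev) * 1e-12]   # components with nonzero variance
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= threshold - 1e-12)[1]
  rotation <- dec$v[, seq_len(k), drop = FALSE]
  transform <- function(M) {
    M <- as_feature_matrix(M)
    sweep(M, 2, center) %*% rotation
  }
  structure(
    list(k = k, explained = cum[k], rotation = rotation, center = center,
         method = method, threshold = threshold, transform = transform),
    class = "variance_reduction"
  )
}

#' @export
print.variance_reduction <- function(x, ...) {
  cat(sprintf("<variance_reduction> %s: %d components, %.1f%% variance (threshold %.0f%%)\n",
              toupper(x$method), x$k, 100 * x$explained, 100 * x$threshold))
  invisible(x)
}
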