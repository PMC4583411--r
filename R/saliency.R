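#' Fixation-density saliency map
#'
#' Pools the fixations of all observers of one image into a per-pixel count
#' map, smooths it with an isotropic Gaussian kernel (sigma = 10 px by
#' default, about 2 degrees of visual angle in the reference viewing setup)
#' and rescales the result so its maximum is 1. The smoothing is separable
#' with a kernel truncated at 4 sigma and zero-padded borders. A coarse
#' 15 x 20 version, obtained by area-weighted block averaging and min-max
#' rescaled to \[0, 1\], is carried along for the 300-dimensional map feature.
#'
#' @param fixations Data frame of one image's pooled fixations (needs `x`,
#'   `y`); at least one row.
#' @param sigma Gaussian kernel standard deviation in pixels.
#' @param width,height Image size in pixels.
#' @param coarse_dim Rows and columns of the coarse map (default 15 x 20).
#' @return An object of class `saliency_map`: list with `full_map`
#'   (height x width matrix in \[0, 1\], max 1), `coarse_map` (15 x 20 matrix
#'   in \[0, 1\]), `sigma`, `width`, `height`.
#' @examples
#' fx <- tibble::tibble(x = c(20, 40), y = c(12, 30))
#' m <- compute_saliency_map(fx, sigma = 4, width = 64, height = 48)
#' max(m$full_map)
#' @export
compute_saliency_map <- function(fixations, sigma = 10,
                                 width = 1024, height = 768,
                                 coarse_dim = c(15, 20)) {
  if (nrow(fixations) == 0) {
    abort("saliency map undefined: no fixations supplied.")
  }
  if (any(fixations$x < 0 | fixations$x >= width |
            fixations$y < 0 | fixations$y >= height)) {
    abort("fixation outside image bounds.")
  }
  # pixel-center count map: fixation (x, y) falls in pixel (floor(x), floor(y));
  # smoothing adds one truncated separable Gaussian bump per fixation, which
  # is equivalent to convolving the count map but exploits its sparsity
  px <- floor(fixations$x) + 1L
  py <- floor(fixations$y) + 1L
  r <- max(1L, ceiling(4 * sigma))
  kern <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  full <- matrix(0, nrow = height, ncol = width)
  for (k in seq_along(px)) {
    rr <- max(1L, py[k] - r):min(height, py[k] + r)
    cc <- max(1L, px[k] - r):min(width, px[k] + r)
    full[rr, cc] <- full[rr, cc] +
      outer(kern[rr - py[k] + r + 1L], kern[cc - px[k] + r + 1L])
  }
  full <- full / max(full)
  coarse <- block_average(full, coarse_dim[1], coarse_dim[2])
  rng <- range(coarse)
  coarse <- if (rng[2] > rng[1]) (coarse - rng[1]) / (rng[2] - rng[1]) else coarse * 0
  structure(
    list(full_map = full, coarse_map = coarse, sigma = sigma,
         width = width, height = height),
    class = "saliency_map"
  )
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %d x %d px, sigma = %g, coarse %d x %d\n",
              x$height, x$width, x$sigma,
              nrow(x$coarse_map), ncol(x$coarse_map)))
  invisible(x)
}

# area-weighted reduction of a matrix to nr x nc cells (cells may span
# fractional pixels, e.g. 51.2 px for 768 -> 15)
block_average <- function(m, nr, nc) {
  w_rows <- fractional_weights(nrow(m), nr)
  w_cols <- fractional_weights(ncol(m), nc)
  w_rows %*% m %*% t(w_cols)
}

# nr x n matrix of averaging weights mapping n fine cells onto nr coarse ones
fractional_weights <- function(n, nr) {
  size <- n / nr
  w <- matrix(0, nr, n)
  for (i in seq_len(nr)) {
    lo <- (i - 1) * size
    hi <- i * size
    j0 <- floor(lo) + 1L
    j1 <- ceiling(hi)
    for (j in j0:min(j1, n)) {
      overlap <- min(hi, j) - max(lo, j - 1)
      if (overlap > 0) w[i, j] <- overlap / size
    }
  }
  w
}

#' Spatial fixation histogram on a 16 x 16 grid
#'
#' Counts fixations per cell of a 16 x 16 grid over the image (64 x 48 px
#' cells for the reference 1024 x 768 size), flattens row-major (reading
#' order: left to right, then top to bottom) and normalizes to a probability
#' mass function.
#'
#' @param fixations Pooled fixations of one image (needs `x`, `y`).
#' @param width,height Image size in pixels.
#' @param grid_dim Cells per side (default 16).
#' @param normalize Divide by the number of fixations (default `TRUE`).
#' @return Numeric vector of length `grid_dim^2`.
#' @export
fixation_histogram <- function(fixations, width = 1024, height = 768,
                               grid_dim = 16L, normalize = TRUE) {
  geom <- fixation_grid_geometry(width, height, grid_dim)
  counts <- numeric(geom$n_cells)
  if (nrow(fixations)) {
    col <- pmin(floor(fixations$x / geom$cell_width), grid_dim - 1L)
    row <- pmin(floor(fixations$y / geom$cell_height), grid_dim - 1L)
    idx <- row * grid_dim + col + 1L   # row-major
    counts <- as.numeric(tabulate(idx, nbins = geom$n_cells))
    if (normalize) counts <- counts / sum(counts)
  }
  counts
}

#' Geometry of the spatial fixation grid
#'
#' @param width,height Image size in pixels.
#' @param grid_dim Cells per side (default 16).
#' @return List with `n_cells`, `cell_width`, `cell_height` (pixels).
#' @examples
#' fixation_grid_geometry(1024, 768) # 256 cells of 64 x 48 px
#' @export
fixation_grid_geometry <- function(width = 1024, height = 768, grid_dim = 16L) {
  list(
    n_cells = as.integer(grid_dim) * as.integer(grid_dim),
    cell_width = width / grid_dim,
    cell_height = height / grid_dim
  )
}

#' Histogram of saliency values at fixation locations
#'
#' Samples the full-resolution saliency map at each pooled fixation's pixel
#' and bins the sampled values over \[0, 1\] into 10 uniform bins, normalized
#' to a probability mass function.
#'
#' @param map A [compute_saliency_map()] result for the same image.
#' @param fixations Pooled fixations of that image.
#' @param n_bins Number of bins over \[0, 1\] (default 10).
#' @param normalize Divide by the number of fixations (default `TRUE`).
#' @return Numeric vector of length `n_bins`.
#' @export
saliency_histogram <- function(map, fixations, n_bins = 10L, normalize = TRUE) {
  stopifnot(inherits(map, "saliency_map"))
  if (nrow(fixations) == 0) return(numeric(n_bins))
  px <- floor(fixations$x) + 1L
  py <- floor(fixations$y) + 1L
  vals <- map$full_map[cbind(py, px)]
  build_histogram(vals, binning_scheme("saliency", n_bins, 0, 1),
                  normalize = normalize)
}

#' Top-10 salient locations via inhibition of return
#'
#' Iteratively extracts the ten strongest local maxima of the saliency map:
#' at each step the global maximum of a working copy is recorded and a disk
#' of radius `2 * sigma` around it is suppressed (set to zero) before the
#' next pick. Ties are broken toward the smallest row-major index (topmost
#' row first, then leftmost column).
#' Coordinates are normalized by the image size so the 20-dimensional block
#' is resolution independent.
#'
#' @param map A [compute_saliency_map()] result.
#' @param n_peaks Number of maxima to extract (default 10).
#' @param radius Suppression radius in pixels (default `2 * map$sigma`).
#' @return Numeric vector `c(x1, y1, ..., x10, y10)` with entries in \[0, 1\],
#'   in extraction order.
#' @export
top10_salient <- function(map, n_peaks = 10L, radius = 2 * map$sigma) {
  stopifnot(inherits(map, "saliency_map"))
  work <- map$full_map
  h <- nrow(work); w <- ncol(work)
  out <- numeric(2L * n_peaks)
  for (k in seq_len(n_peaks)) {
    # row-major tie-break: scan the transpose so the topmost, then leftmost,
    # maximum wins
    best <- which.max(t(work))
    row <- ((best - 1L) %/% w) + 1L
    col <- ((best - 1L) %% w) + 1L
    out[2L * k - 1L] <- (col - 1L) / w
    out[2L * k] <- (row - 1L) / h
    rr <- max(1L, row - ceiling(radius)):min(h, row + ceiling(radius))
    cc <- max(1L, col - ceiling(radius)):min(w, col + ceiling(radius))
    dist2 <- outer((rr - row)^2, (cc - col)^2, "+")
    sub <- work[rr, cc, drop = FALSE]
    sub[dist2 <= radius^2] <- 0
    work[rr, cc] <- sub
  }
  out
}
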