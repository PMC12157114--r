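#' Normalized 2-D Gaussian smoothing kernel
#'
#' `weights[i, j]` is proportional to `exp(-((i-c)^2 + (j-c)^2) / (2*sigma^2))`
#' with `c` the centre index, normalized to sum to one. The default 9x9
#' kernel with unit standard deviation is the refinement filter applied to
#' prediction masks.
#'
#' @param size odd kernel side length, at least 1.
#' @param sigma positive standard deviation in pixels.
#' @return a `size` x `size` numeric matrix summing to 1, symmetric under
#'   horizontal, vertical and diagonal reflection.
#' @examples
#' k <- gaussian_kernel(9, 1)
#' sum(k)
#' @export
gaussian_kernel <- function(size = 9L, sigma = 1.0) {
  size <- as.integer(size)
  if (is.na(size) || size < 1L || size %% 2L == 0L) {
    stop("kernel size must be an odd integer >= 1", call. = FALSE)
  }
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("sigma must be positive", call. = FALSE)
  }
  c0 <- (size + 1L) / 2L
  d <- (seq_len(size) - c0)
  w <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  w / sum(w)
}

# Symmetric (reflect) boundary index for positions 1-r .. n+r. Each
# out-of-range position is folded back into 1..n by mirror reflection, with
# the edge sample repeated, so constant images stay constant after padding.
reflect_index <- function(n, r) {
  p <- seq.int(1L - r, n + r)
  q <- ((p - 1L) %% (2L * n))
  q <- ifelse(q < 0L, q + 2L * n, q)
  ifelse(q < n, q + 1L, 2L * n - q)
}

#' Smooth a binary mask and re-binarize
#'
#' Treats the mask as real values in `{0, 1}`, convolves it with a
#' normalized smoothing kernel using reflect padding at the image borders,
#' then thresholds: response strictly greater than `threshold` becomes
#' foreground. With the default 9x9, sigma 1, threshold 0.5 settings this
#' removes isolated foreground specks and fills isolated holes while leaving
#' large solid regions (and constant masks) unchanged — the mechanism that
#' cleans false-positive noise near predicted boundaries.
#'
#' Reflect padding is used because it preserves constant regions at the
#' image edge: zero padding would erode foreground that touches the border,
#' which genuinely happens in skull-stripped slices.
#'
#' @param mask a binary mask.
#' @param kernel smoothing kernel from [gaussian_kernel()] (any normalized
#'   odd-sized kernel works).
#' @param threshold binarization threshold; strictly-greater comparison.
#' @return a [binary_mask()] of the same dimensions.
#' @export
smooth_binarize <- function(mask, kernel = gaussian_kernel(9L, 1.0),
                            threshold = 0.5) {
  mask <- binary_mask(mask)
  if (!is.matrix(kernel) || nrow(kernel) != ncol(kernel) ||
      nrow(kernel) %% 2L == 0L) {
    stop("kernel must be a square odd-sized matrix", call. = FALSE)
  }
  r <- (nrow(kernel) - 1L) %/% 2L
  x <- matrix(as.double(mask), nrow(mask), ncol(mask))
  if (r > 0L) {
    ri <- reflect_index(nrow(x), r)
    ci <- reflect_index(ncol(x), r)
    padded <- x[ri, ci, drop = FALSE]
    sm <- EBImage::filter2(padded, kernel, boundary = "circular")
    sm <- sm[r + seq_len(nrow(x)), r + seq_len(ncol(x)), drop = FALSE]
  } else {
    sm <- x * kernel[1L, 1L]
  }
  binary_mask((sm > threshold) + 0L)
}

#' Smooth-and-binarize every slice of a series
#'
#' @param series a [mask_series()].
#' @inheritParams smooth_binarize
#' @return a [mask_series()] with the same `series_id`.
#' @export
smooth_series <- function(series, kernel = gaussian_kernel(9L, 1.0),
                          threshold = 0.5) {
  stopifnot(inherits(series, "mask_series"))
  mask_series(lapply(series$slices, smooth_binarize,
                     kernel = kernel, threshold = threshold),
              series$series_id)
}
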