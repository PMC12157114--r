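#' Binary segmentation masks and mask series
#'
#' A binary mask is stored as an integer matrix of 0s and 1s with 1 marking
#' foreground (brain tissue). Rows index image rows top-to-bottom, columns
#' index image columns left-to-right; indexing is the usual R 1-based
#' `[row, col]`. A mask series is an ordered stack of equally sized masks
#' for one head scan, slice 1 at the bottom of the head.
#'
#' @param x numeric or logical matrix; every value must be exactly 0 or 1
#'   (logical matrices are coerced).
#' @return `binary_mask()` returns an integer matrix of class `binary_mask`.
#' @examples
#' m <- binary_mask(matrix(c(0, 1, 1, 0), 2, 2))
#' mask_dim(m)
#' @export
binary_mask <- function(x) {
  if (is.logical(x)) x <- x + 0L
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("a binary mask must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("a binary mask must have at least one row and one column", call. = FALSE)
  }
  if (anyNA(x) || !all(x == 0 | x == 1)) {
    stop("mask values must all be exactly 0 or 1", call. = FALSE)
  }
  m <- matrix(as.integer(x), nrow(x), ncol(x))
  class(m) <- c("binary_mask", class(m))
  m
}

#' @rdname binary_mask
#' @param m a `binary_mask`
#' @export
mask_dim <- function(m) {
  c(height = nrow(m), width = ncol(m))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%d, %d foreground px>\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

is_binary_mask <- function(x) {
  is.matrix(x) && is.numeric(x) && !anyNA(x) && all(x == 0 | x == 1)
}

# Stops unless a and b share dimensions; `what` names the operands in errors.
check_same_dim <- function(a, b, what = "masks") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s have mismatched dimensions: %dx%d vs %dx%d",
                 what, nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a mask series
#'
#' @param slices list of binary masks (matrices of 0/1), ordered bottom of
#'   the head first. All slices must share identical dimensions.
#' @param series_id character label for the series.
#' @return An object of class `mask_series`: a list with elements `slices`
#'   (list of `binary_mask`) and `series_id`.
#' @examples
#' s <- mask_series(list(matrix(0, 4, 4), matrix(1, 4, 4)), "demo")
#' length(s)
#' @export
mask_series <- function(slices, series_id = "series") {
  if (!is.list(slices) || length(slices) < 1L) {
    stop("a mask series needs at least one slice", call. = FALSE)
  }
  slices <- lapply(slices, binary_mask)
  d1 <- dim(slices[[1L]])
  for (i in seq_along(slices)) {
    if (!identical(dim(slices[[i]]), d1)) {
      stop(sprintf(
        "slice %d has dimensions %dx%d but slice 1 has %dx%d",
        i, nrow(slices[[i]]), ncol(slices[[i]]), d1[1L], d1[2L]),
        call. = FALSE)
    }
  }
  structure(list(slices = slices, series_id = as.character(series_id)),
            class = "mask_series")
}

#' @export
length.mask_series <- function(x) length(x$slices)

#' @export
print.mask_series <- function(x, ...) {
  d <- dim(x$slices[[1L]])
  cat(sprintf("<mask_series '%s': %d slices of %dx%d>\n",
              x$series_id, length(x$slices), d[1L], d[2L]))
  invisible(x)
}

# Stops unless two series are comparable slice-by-slice.
check_same_series <- function(a, b, what = "series") {
  if (length(a) != length(b)) {
    stop(sprintf("%s have different lengths: %d vs %d",
                 what, length(a), length(b)), call. = FALSE)
  }
  check_same_dim(a$slices[[1L]], b$slices[[1L]], what)
  invisible(TRUE)
}

# Runs expr with the RNG seeded to `seed`, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
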