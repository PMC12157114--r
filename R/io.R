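#' Read a binary mask from disk
#'
#' PNG files are read as 8-bit grayscale; a pixel becomes foreground when its
#' 8-bit value exceeds 127 (the midpoint convention, so anti-aliased inputs
#' binarize deterministically). NIfTI slices use a threshold of 0.5 on the
#' stored values. Multi-channel PNGs are reduced to their first channel.
#'
#' @param path path to the image file.
#' @param format `"png"` or `"nifti-slice"` (a single-slice NIfTI file, or a
#'   volume whose third dimension is 1).
#' @return a [binary_mask()].
#' @seealso [write_mask()], [read_series()]
#' @export
read_mask <- function(path, format = c("png", "nifti-slice")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("cannot read mask: no such file '%s'", path), call. = FALSE)
  }
  if (format == "png") {
    img <- tryCatch(png::readPNG(path),
                    error = function(e) stop(sprintf(
                      "failed to decode PNG '%s': %s", path, conditionMessage(e)),
                      call. = FALSE))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    if (length(dim(img)) != 2L) {
      stop(sprintf("'%s' is not a 2-D image", path), call. = FALSE)
    }
    # readPNG scales 8-bit values to [0,1]; recover the integer level first
    binary_mask((round(img * 255) > 127) + 0L)
  } else {
    vol <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop(sprintf(
                      "failed to decode NIfTI '%s': %s", path, conditionMessage(e)),
                      call. = FALSE))
    a <- as.array(vol)
    if (length(dim(a)) == 3L && dim(a)[3L] == 1L) a <- a[, , 1L]
    if (length(dim(a)) != 2L) {
      stop(sprintf("'%s' is not a single 2-D slice", path), call. = FALSE)
    }
    binary_mask((a > 0.5) + 0L)
  }
}

#' Write a binary mask to disk
#'
#' Writes foreground as 255 and background as 0 (PNG, 8-bit grayscale) or as
#' 1 and 0 (NIfTI), so that [read_mask()] recovers the mask exactly.
#'
#' @param mask a [binary_mask()] or plain 0/1 matrix.
#' @inheritParams read_mask
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path, format = c("png", "nifti-slice")) {
  format <- match.arg(format)
  mask <- binary_mask(mask)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop(sprintf("cannot write mask: no such directory '%s'", dir), call. = FALSE)
  }
  if (format == "png") {
    png::writePNG(matrix(as.double(mask), nrow(mask), ncol(mask)), path)
  } else {
    RNifti::writeNifti(array(as.double(mask), c(dim(mask), 1L)), path)
  }
  invisible(path)
}

#' Read a mask series
#'
#' Either a character vector of per-slice image paths (in slice order, bottom
#' of the head first) or the path of a single NIfTI volume whose third axis
#' is the slice axis, split in ascending index order. When reading a
#' directory of PNGs, pass `sort(list.files(...))` so lexicographic file
#' order defines slice order. NIfTI orientation headers are deliberately
#' ignored: masks are treated as raw pixel grids and the method is
#' orientation-agnostic.
#'
#' @param paths character vector of slice image paths, or one NIfTI volume path.
#' @param series_id label for the series.
#' @param format `"png"` for per-slice images, `"nifti"` for one volume.
#' @return a [mask_series()].
#' @export
read_series <- function(paths, series_id = "series", format = c("png", "nifti")) {
  format <- match.arg(format)
  if (length(paths) < 1L) stop("need at least one path", call. = FALSE)
  if (format == "nifti") {
    if (length(paths) != 1L) {
      stop("format 'nifti' expects a single volume path", call. = FALSE)
    }
    vol <- as.array(RNifti::readNifti(paths))
    if (length(dim(vol)) == 2L) vol <- array(vol, c(dim(vol), 1L))
    if (length(dim(vol)) != 3L) {
      stop(sprintf("'%s' is not a 2-D or 3-D volume", paths), call. = FALSE)
    }
    slices <- lapply(seq_len(dim(vol)[3L]),
                     function(k) binary_mask((vol[, , k] > 0.5) + 0L))
    return(mask_series(slices, series_id))
  }
  slices <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    slices[[i]] <- read_mask(paths[[i]], "png")
    if (i > 1L && !identical(dim(slices[[i]]), dim(slices[[1L]]))) {
      stop(sprintf(
        "slice %d ('%s') has dimensions %dx%d but slice 1 has %dx%d",
        i, paths[[i]], nrow(slices[[i]]), ncol(slices[[i]]),
        nrow(slices[[1L]]), ncol(slices[[1L]])), call. = FALSE)
    }
  }
  mask_series(slices, series_id)
}

#' Write a mask series
#'
#' With `format = "png"`, writes one zero-padded `slice_###.png` per slice
#' into `dir` so that lexicographic order preserves slice order. With
#' `format = "nifti"`, writes a single `<series_id>.nii.gz` volume with the
#' slice index on the third axis.
#'
#' @param series a [mask_series()].
#' @param dir output directory (created if absent).
#' @param format `"png"` or `"nifti"`.
#' @return character vector of files written, invisibly.
#' @export
write_series <- function(series, dir, format = c("png", "nifti")) {
  format <- match.arg(format)
  stopifnot(inherits(series, "mask_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "nifti") {
    vol <- array(0, c(dim(series$slices[[1L]]), length(series)))
    for (k in seq_len(length(series))) vol[, , k] <- as.double(series$slices[[k]])
    path <- file.path(dir, paste0(series$series_id, ".nii.gz"))
    RNifti::writeNifti(vol, path)
    return(invisible(path))
  }
  paths <- file.path(dir, sprintf("slice_%03d.png", seq_len(length(series))))
  for (i in seq_along(paths)) write_mask(series$slices[[i]], paths[[i]], "png")
  invisible(paths)
}
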