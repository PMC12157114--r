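#' Pixel-wise confusion counts between a prediction and ground truth
#'
#' Counts true positives, false positives (over-segmented pixels), false
#' negatives (missed foreground pixels) and true negatives. The false
#' positive count is one slice's contribution to a model's total
#' over-segmentation, the false negative count its contribution to the
#' total missed-pixel count.
#'
#' @param pred,gt binary masks of identical dimensions.
#' @return named integer vector with elements `tp`, `fp`, `fn`, `tn`.
#' @examples
#' p <- binary_mask(matrix(c(1, 0, 1, 0), 2, 2))
#' g <- binary_mask(matrix(c(0, 0, 1, 1), 2, 2))
#' confusion_counts(p, g)
#' @export
confusion_counts <- function(pred, gt) {
  pred <- binary_mask(pred); gt <- binary_mask(gt)
  check_same_dim(pred, gt, "pred and gt")
  tp <- sum(pred == 1L & gt == 1L)
  fp <- sum(pred == 1L & gt == 0L)
  fn <- sum(pred == 0L & gt == 1L)
  tn <- length(pred) - tp - fp - fn
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Intersection over union (Jaccard index) of two masks
#'
#' `|pred & gt| / |pred | gt|`, in `[0, 1]`, higher is better. When both
#' masks are empty the union is empty and the score is 1 by convention: a
#' slice with no brain tissue that is predicted all-background is a perfect
#' prediction and must score as one.
#'
#' @inheritParams confusion_counts
#' @return a single number in `[0, 1]`.
#' @export
iou <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  denom <- cc[["tp"]] + cc[["fp"]] + cc[["fn"]]
  if (denom == 0L) return(1.0)
  cc[["tp"]] / denom
}

#' Boundary pixels of a mask
#'
#' A foreground pixel is a boundary pixel when at least one of its
#' 4-neighbours (up/down/left/right) is background; positions outside the
#' image count as background, so foreground touching the image border is
#' always boundary. These contour sets are the point sets over which the
#' Hausdorff distance is computed.
#'
#' @param mask a binary mask.
#' @return integer matrix with columns `row`, `col`, one boundary pixel per
#'   row (0 rows for an empty mask).
#' @export
boundary_pixels <- function(mask) {
  mask <- binary_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  # shift the mask in each direction, padding with background
  up    <- rbind(mask[-1L, , drop = FALSE], matrix(0L, 1L, w))
  down  <- rbind(matrix(0L, 1L, w), mask[-h, , drop = FALSE])
  left  <- cbind(mask[, -1L, drop = FALSE], matrix(0L, h, 1L))
  right <- cbind(matrix(0L, h, 1L), mask[, -w, drop = FALSE])
  on_boundary <- mask == 1L & (up == 0L | down == 0L | left == 0L | right == 0L)
  idx <- which(on_boundary, arr.ind = TRUE)
  colnames(idx) <- c("row", "col")
  idx
}

#' Directed Hausdorff distance between two point sets
#'
#' `h(A, B) = max over a in A of (min over b in B of ||a - b||)`, the exact
#' max/min form with Euclidean point distances, in pixel units. No
#' percentile approximation is applied.
#'
#' @param A,B numeric matrices with two columns (`row`, `col`); both must be
#'   non-empty.
#' @return a non-negative number.
#' @export
directed_hausdorff <- function(A, B) {
  if (NROW(A) == 0L || NROW(B) == 0L) {
    stop("directed Hausdorff distance needs non-empty point sets", call. = FALSE)
  }
  A <- matrix(as.numeric(A), NROW(A)); B <- matrix(as.numeric(B), NROW(B))
  # exact: full pairwise squared distances, max of row minima
  d2 <- outer(A[, 1L], B[, 1L], "-")^2 + outer(A[, 2L], B[, 2L], "-")^2
  sqrt(max(apply(d2, 1L, min)))
}

#' Symmetric Hausdorff distance between two masks' boundaries
#'
#' The larger of the two directed distances between the boundary pixel sets
#' of `pred` and `gt`; lower is better, and it is sensitive to contour shape
#' where IoU is sensitive to region fill. Conventions for empty masks: both
#' empty gives 0 (the contours agree vacuously); exactly one empty gives
#' `NA` (the distance is undefined — there is no pixel to measure to), which
#' callers must flag rather than fold into means silently.
#'
#' @inheritParams confusion_counts
#' @return non-negative number, or `NA` if exactly one mask is empty.
#' @export
hausdorff <- function(pred, gt) {
  pred <- binary_mask(pred); gt <- binary_mask(gt)
  check_same_dim(pred, gt, "pred and gt")
  A <- boundary_pixels(pred); B <- boundary_pixels(gt)
  if (nrow(A) == 0L && nrow(B) == 0L) return(0)
  if (nrow(A) == 0L || nrow(B) == 0L) return(NA_real_)
  max(directed_hausdorff(A, B), directed_hausdorff(B, A))
}

#' Evaluate a predicted series against ground truth
#'
#' Computes per-slice IoU and Hausdorff distance, plus three aggregates:
#' `mean_iou` (unweighted mean of per-slice IoU), `pooled_iou` (IoU of the
#' confusion counts summed over all slices, weighting slices by area), and
#' `mean_hd` (mean over slices whose HD is defined). Slices where exactly
#' one of prediction and ground truth is empty have undefined HD; they are
#' excluded from `mean_hd` and counted in `n_undefined_hd`.
#'
#' @param preds,gts [mask_series()] of equal length and dimensions.
#' @return an object of class `eval_result`: list with `per_slice` (a
#'   data.frame with columns `slice_index`, `iou`, `hd`, `hd_defined`),
#'   `mean_iou`, `pooled_iou`, `mean_hd`, `n_undefined_hd`, `series_id`.
#' @export
evaluate_series <- function(preds, gts) {
  stopifnot(inherits(preds, "mask_series"), inherits(gts, "mask_series"))
  check_same_series(preds, gts, "preds and gts")
  n <- length(preds)
  iou_v <- numeric(n); hd_v <- numeric(n)
  tot <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_len(n)) {
    p <- preds$slices[[i]]; g <- gts$slices[[i]]
    cc <- confusion_counts(p, g)
    tot <- tot + cc
    denom <- cc[["tp"]] + cc[["fp"]] + cc[["fn"]]
    iou_v[i] <- if (denom == 0) 1.0 else cc[["tp"]] / denom
    hd_v[i] <- hausdorff(p, g)
  }
  defined <- !is.na(hd_v)
  pooled_denom <- tot[["tp"]] + tot[["fp"]] + tot[["fn"]]
  res <- list(
    per_slice = data.frame(
      slice_index = seq_len(n),
      iou = iou_v,
      hd = hd_v,
      hd_defined = defined
    ),
    mean_iou = mean(iou_v),
    pooled_iou = if (pooled_denom == 0) 1.0 else tot[["tp"]] / pooled_denom,
    mean_hd = if (any(defined)) mean(hd_v[defined]) else NA_real_,
    n_undefined_hd = sum(!defined),
    series_id = preds$series_id
  )
  class(res) <- "eval_result"
  res
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result '%s': %d slices, mean IoU %.4f, pooled IoU %.4f, mean HD %s (%d undefined)>\n",
    x$series_id, nrow(x$per_slice), x$mean_iou, x$pooled_iou,
    if (is.na(x$mean_hd)) "NA" else sprintf("%.3f", x$mean_hd),
    x$n_undefined_hd))
  invisible(x)
}

#' Write an evaluation report
#'
#' Writes the per-slice table as CSV (columns `series_id`, `slice_index`,
#' `iou`, `hd`, `hd_defined`) and the aggregates as a JSON summary.
#'
#' @param result an `eval_result` from [evaluate_series()].
#' @param csv_path,json_path output paths; either may be `NULL` to skip.
#' @return invisibly, a list of the paths written.
#' @export
write_eval_report <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "eval_result"))
  if (!is.null(csv_path)) {
    df <- cbind(series_id = result$series_id, result$per_slice)
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(series_id = result$series_id,
           mean_iou = result$mean_iou,
           pooled_iou = result$pooled_iou,
           mean_hd = result$mean_hd,
           n_undefined_hd = result$n_undefined_hd),
      json_path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  }
  invisible(list(csv = csv_path, json = json_path))
}
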