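#' Accumulate a model's error profile over a labelled series
#'
#' Sums per-slice false positives into `num_overseg` (pixels the model calls
#' brain that the ground truth calls background) and per-slice false
#' negatives into `num_miss` (ground-truth brain pixels the model misses).
#' These two totals drive the choice of fusion operation in
#' [select_strategy()].
#'
#' @param preds model output series, a [mask_series()].
#' @param gts matching ground-truth series.
#' @param model_id label for the model.
#' @return object of class `model_error_profile`: list with `model_id`,
#'   `num_overseg`, `num_miss`, `n_slices`.
#' @export
accumulate_profile <- function(preds, gts, model_id = preds$series_id) {
  stopifnot(inherits(preds, "mask_series"), inherits(gts, "mask_series"))
  check_same_series(preds, gts, "preds and gts")
  fp <- 0L; fn <- 0L
  for (i in seq_len(length(preds))) {
    cc <- confusion_counts(preds$slices[[i]], gts$slices[[i]])
    fp <- fp + cc[["fp"]]; fn <- fn + cc[["fn"]]
  }
  error_profile(model_id, fp, fn, length(preds))
}

#' Build an error profile from known counts
#'
#' Use this when the over-/under-segmentation totals were computed elsewhere
#' (e.g. a published table of model error counts).
#'
#' @param model_id label.
#' @param num_overseg,num_miss non-negative totals of over-segmented and
#'   missed pixels.
#' @param n_slices number of slices the counts were accumulated over, if known.
#' @return a `model_error_profile`.
#' @export
error_profile <- function(model_id, num_overseg, num_miss, n_slices = NA_integer_) {
  stopifnot(num_overseg >= 0, num_miss >= 0)
  structure(list(model_id = as.character(model_id),
                 num_overseg = as.numeric(num_overseg),
                 num_miss = as.numeric(num_miss),
                 n_slices = n_slices),
            class = "model_error_profile")
}

#' @export
print.model_error_profile <- function(x, ...) {
  cat(sprintf("<error profile '%s': num_overseg=%g, num_miss=%g (%s)>\n",
              x$model_id, x$num_overseg, x$num_miss, classify_profile(x)))
  invisible(x)
}

# OVER: over-segmentation dominates; UNDER: misses dominate; NEUTRAL: equal.
# Comparisons are strict; exact equality is classified NEUTRAL.
classify_profile <- function(p) {
  if (p$num_overseg > p$num_miss) "OVER"
  else if (p$num_miss > p$num_overseg) "UNDER"
  else "NEUTRAL"
}

#' Choose the fusion operation from model error profiles
#'
#' Each model is classified by its dominant error direction: `OVER` when
#' `num_overseg > num_miss`, `UNDER` when `num_miss > num_overseg`, `NEUTRAL`
#' on exact equality. When two or more models over-segment, their
#' intersection is taken (intersection can only remove false positives);
#' when two or more under-segment, their union is taken (union can only
#' recover missed pixels). With only two models of opposite direction the
#' rule alone cannot decide — a third model resolves the tie by providing an
#' agreeing pair. If no two models agree in direction the plan defaults to
#' intersection over all models, and the rationale flags the unresolved tie:
#' in practice segmentation networks of this family produce more false
#' positives than misses, so intersection is the safer default.
#'
#' @param profiles list of `model_error_profile` objects (at least 2).
#' @return object of class `fusion_plan`: list with `operation`
#'   (`"union"` or `"intersection"`), `model_ids` (the models fused),
#'   `classification` (named character vector over all input models), and
#'   `rationale` (human-readable decision trace).
#' @export
select_strategy <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 2L) {
    stop("select_strategy needs at least two model profiles", call. = FALSE)
  }
  ids <- vapply(profiles, function(p) p$model_id, character(1))
  if (anyDuplicated(ids)) stop("model ids must be distinct", call. = FALSE)
  cls <- vapply(profiles, classify_profile, character(1))
  names(cls) <- ids
  counts <- vapply(profiles, function(p)
    sprintf("%s: num_overseg=%g, num_miss=%g -> %s",
            p$model_id, p$num_overseg, p$num_miss, classify_profile(p)),
    character(1))
  over <- ids[cls == "OVER"]; under <- ids[cls == "UNDER"]
  if (length(over) >= 2L) {
    op <- "intersection"; sel <- over
    why <- sprintf("%d model(s) over-segment; intersecting them removes false positives",
                   length(over))
  } else if (length(under) >= 2L) {
    op <- "union"; sel <- under
    why <- sprintf("%d model(s) under-segment; their union recovers missed pixels",
                   length(under))
  } else {
    op <- "intersection"; sel <- ids
    why <- "tie-unresolved default: no two models agree in error direction; intersection over all models"
  }
  structure(list(operation = op,
                 model_ids = sel,
                 classification = cls,
                 rationale = paste(c(counts, why), collapse = "; ")),
            class = "fusion_plan")
}

#' @export
print.fusion_plan <- function(x, ...) {
  cat(sprintf("<fusion_plan: %s over {%s}>\n  %s\n",
              x$operation, paste(x$model_ids, collapse = ", "), x$rationale))
  invisible(x)
}

#' Fuse binary masks by pixel-wise union or intersection
#'
#' Union marks a pixel foreground when any input does; intersection keeps
#' only pixels every input marks foreground (the overlapped area). Both
#' operations are commutative and associative, so the order of `masks` is
#' irrelevant.
#'
#' @param masks list of at least two binary masks of identical dimensions.
#' @param operation `"union"` or `"intersection"`.
#' @return a [binary_mask()].
#' @export
fuse <- function(masks, operation = c("intersection", "union")) {
  operation <- match.arg(operation)
  if (!is.list(masks) || length(masks) < 2L) {
    stop("fuse needs at least two masks", call. = FALSE)
  }
  masks <- lapply(masks, binary_mask)
  for (i in seq_along(masks)[-1L]) {
    check_same_dim(masks[[1L]], masks[[i]], "masks")
  }
  acc <- Reduce(if (operation == "union") pmax else pmin, masks)
  binary_mask(acc)
}

#' Fuse mask series slice-by-slice according to a fusion plan
#'
#' Applies [fuse()] to corresponding slices of the series the plan selects;
#' series for models outside the plan are ignored.
#'
#' @param series_list named list of [mask_series()], one per model; names
#'   (or each series' `series_id`) must cover `plan$model_ids`.
#' @param plan a `fusion_plan` from [select_strategy()], or the result of
#'   [fusion_plan_manual()].
#' @param series_id label for the fused output series.
#' @return a [mask_series()].
#' @export
fuse_series <- function(series_list, plan, series_id = "fused") {
  stopifnot(inherits(plan, "fusion_plan"))
  if (is.null(names(series_list)) || any(names(series_list) == "")) {
    names(series_list) <- vapply(series_list, function(s) s$series_id, character(1))
  }
  missing <- setdiff(plan$model_ids, names(series_list))
  if (length(missing) > 0L) {
    stop(sprintf("fusion plan needs model series not supplied: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sel <- series_list[plan$model_ids]
  for (s in sel[-1L]) check_same_series(sel[[1L]], s, "model series")
  n <- length(sel[[1L]])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- fuse(lapply(sel, function(s) s$slices[[i]]), plan$operation)
  }
  mask_series(out, series_id)
}

#' Construct a fusion plan by hand
#'
#' Bypasses profiling: force a given operation over a given model subset
#' (used by the CLI's `--operation union|intersection` override).
#'
#' @param operation `"union"` or `"intersection"`.
#' @param model_ids at least two distinct model labels.
#' @return a `fusion_plan`.
#' @export
fusion_plan_manual <- function(operation = c("intersection", "union"), model_ids) {
  operation <- match.arg(operation)
  model_ids <- as.character(model_ids)
  if (length(model_ids) < 2L || anyDuplicated(model_ids)) {
    stop("need at least two distinct model ids", call. = FALSE)
  }
  structure(list(operation = operation, model_ids = model_ids,
                 classification = NULL,
                 rationale = "manual override"),
            class = "fusion_plan")
}

#' Write a model error-profile report
#'
#' One CSV row per model: `model_id`, `num_overseg`, `num_miss`,
#' `classification`, `filtered` (whether the profiled predictions had been
#' post-processed).
#'
#' @param profiles list of `model_error_profile`s.
#' @param path output CSV path.
#' @param filtered logical flag recorded in the report.
#' @return the data frame written, invisibly.
#' @export
write_profile_report <- function(profiles, path, filtered = FALSE) {
  df <- data.frame(
    model_id = vapply(profiles, function(p) p$model_id, character(1)),
    num_overseg = vapply(profiles, function(p) p$num_overseg, numeric(1)),
    num_miss = vapply(profiles, function(p) p$num_miss, numeric(1)),
    classification = vapply(profiles, classify_profile, character(1)),
    filtered = if (isTRUE(filtered)) "yes" else "no"
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Serialize a fusion plan as JSON
#'
#' @param plan a `fusion_plan`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fusion_plan <- function(plan, path) {
  stopifnot(inherits(plan, "fusion_plan"))
  jsonlite::write_json(
    list(operation = plan$operation,
         model_ids = plan$model_ids,
         classification = as.list(plan$classification),
         rationale = plan$rationale),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
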