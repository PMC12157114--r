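#' Configuration for a synthetic head-series phantom
#'
#' Describes a stack of axial slices whose brain cross-section is small at
#' the bottom of the head, largest in the middle, and small or absent at the
#' top, with non-brain distractor structures (eye/cheek-like blobs) on the
#' lowest slices. The defaults model a whole-head series of 31 slices — the
#' scale of a routine head scan — on an abstract 128x128 pixel grid.
#'
#' @param n_slices number of slices (bottom of head first).
#' @param height,width slice dimensions in pixels.
#' @param base_radius nominal brain radius in pixels at full area scale.
#' @param area_profile per-slice area scale factors in `[0, 1]`, length
#'   `n_slices`; defaults to [default_area_profile()].
#' @param distractor_rate probability that a slice in the lowest quartile
#'   carries distractor structures.
#' @param seed integer seed; the generator is a pure function of it.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(n_slices = 31L, height = 128L, width = 128L,
                           base_radius = round(0.3 * min(height, width)),
                           area_profile = default_area_profile(n_slices),
                           distractor_rate = 0.8, seed = 20210101L) {
  n_slices <- as.integer(n_slices)
  if (is.na(n_slices) || n_slices < 1L) {
    stop("n_slices must be a positive integer", call. = FALSE)
  }
  if (height < 8L || width < 8L) {
    stop("slices must be at least 8x8 pixels", call. = FALSE)
  }
  if (length(area_profile) != n_slices) {
    stop("area_profile must have one factor per slice", call. = FALSE)
  }
  if (any(area_profile < 0 | area_profile > 1)) {
    stop("area_profile factors must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_slices = n_slices, height = as.integer(height),
                 width = as.integer(width), base_radius = base_radius,
                 area_profile = as.numeric(area_profile),
                 distractor_rate = distractor_rate,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Default unimodal slice-area profile
#'
#' Rises from a small cross-section at the bottom of the head to a maximum
#' in the middle slices and falls again towards the top; the topmost slice
#' is empty (above the brain, ground truth all background).
#'
#' @param n_slices number of slices.
#' @return numeric vector of length `n_slices` in `[0, 1]`.
#' @export
default_area_profile <- function(n_slices) {
  t <- seq_len(n_slices) / (n_slices + 1)
  f <- sin(pi * t)^0.8
  f <- f / max(f)
  if (n_slices > 1L) f[n_slices] <- 0
  f
}

# Disc-shaped 0/1 stamp of given radius applied onto `mask` at (r0, c0),
# clipped to the image. Returns the updated matrix.
stamp_disc <- function(mask, r0, c0, radius) {
  h <- nrow(mask); w <- ncol(mask)
  rr <- max(1L, floor(r0 - radius)):min(h, ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(w, ceiling(c0 + radius))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  mask[rr, cc][d2 <= radius^2] <- 1L
  mask
}

# Removes a disc-shaped bite from `mask`.
bite_disc <- function(mask, r0, c0, radius) {
  h <- nrow(mask); w <- ncol(mask)
  rr <- max(1L, floor(r0 - radius)):min(h, ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(w, ceiling(c0 + radius))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  mask[rr, cc][d2 <= radius^2] <- 0L
  mask
}

#' Generate a phantom ground-truth series with distractor structures
#'
#' Each non-empty slice's brain region is a perturbed ellipse: an ellipse
#' whose radius is modulated by low-frequency radial harmonics, giving a
#' single dominant component with a smooth, slightly irregular boundary.
#' The harmonic amplitudes are fixed across slices while their phases drift
#' slowly, so slice area tracks `area_profile` closely and neighbouring
#' slices have similar but not identical shapes. Slices in the lowest
#' quartile may additionally carry distractor blobs (returned separately,
#' always disjoint from the brain region) standing in for periorbital and
#' skull-base structures that tempt segmenters into false alarms.
#'
#' The generator is deterministic: the same config (including its seed)
#' always yields bit-identical output.
#'
#' @param config a [phantom_config()].
#' @return list with elements `gt` and `distractors`, both [mask_series()]
#'   of `config$n_slices` slices.
#' @export
generate_phantom_series <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$height; w <- config$width; n <- config$n_slices
  nz <- config$area_profile > 0
  if (any(nz) && config$base_radius * sqrt(min(config$area_profile[nz])) < 1) {
    stop("degenerate geometry: brain radius below 1 pixel at a nonzero area factor",
         call. = FALSE)
  }
  with_rng_seed(config$seed, {
    cy0 <- h / 2 + stats::runif(1, -2, 2)
    cx0 <- w / 2 + stats::runif(1, -2, 2)
    amp <- stats::runif(3, 0.01, 0.06)        # harmonics k = 2, 3, 4
    ph0 <- stats::runif(3, 0, 2 * pi)
    drift <- stats::runif(3, -0.15, 0.15)     # phase drift per slice
    aspect <- stats::runif(1, 1.05, 1.2)
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    gt <- vector("list", n)
    dis <- vector("list", n)
    low <- ceiling(n / 4)
    for (i in seq_len(n)) {
      f <- config$area_profile[i]
      if (f == 0) {
        gt[[i]] <- matrix(0L, h, w)
      } else {
        a <- config$base_radius * sqrt(f) * aspect      # column semi-axis
        b <- config$base_radius * sqrt(f) / aspect      # row semi-axis
        dy <- (rows - cy0) / b
        dx <- (cols - cx0) / a
        rho <- sqrt(dx^2 + dy^2)
        theta <- atan2(dy, dx)
        lim <- 1
        for (k in 1:3) {
          lim <- lim + amp[k] * cos((k + 1) * theta + ph0[k] + drift[k] * i)
        }
        gt[[i]] <- (rho <= lim) + 0L
      }
      d <- matrix(0L, h, w)
      if (i <= low && stats::runif(1) < config$distractor_rate) {
        nblob <- sample(2:3, 1)
        for (j in seq_len(nblob)) {
          ang <- stats::runif(1, 0, 2 * pi)
          dist <- config$base_radius * stats::runif(1, 1.5, 1.9)
          r0 <- cy0 + dist * sin(ang)
          c0 <- cx0 + dist * cos(ang)
          r0 <- min(max(r0, 4), h - 3); c0 <- min(max(c0, 4), w - 3)
          d <- stamp_disc(d, r0, c0, config$base_radius * stats::runif(1, 0.2, 0.35))
        }
        d[gt[[i]] == 1L] <- 0L    # distractors never overlap brain
      }
      dis[[i]] <- d
    }
    list(gt = mask_series(gt, "gt"),
         distractors = mask_series(dis, "distractors"))
  })
}

#' Error profile of a simulated segmenter
#'
#' Encodes a segmentation model's characteristic mistakes. `dilate_px`
#' uniformly over-segments (the predicted region is grown), `erode_px`
#' under-segments; they are mutually exclusive. `blob_rate` is the expected
#' number of spurious foreground blobs per slice (false alarms outside the
#' brain, placed preferentially on distractor structures, mimicking
#' periorbital and skull-base misclassification). `dropout_rate` is the
#' per-slice probability of losing a bite of radius `dropout_radius` from
#' the region boundary. `jitter` is the per-pixel probability that a
#' boundary pixel flips (inner boundary dropped, outer boundary added).
#'
#' @param model_id label.
#' @param dilate_px,erode_px non-negative integers; at most one positive.
#' @param blob_rate expected spurious blobs per slice.
#' @param blob_radius blob radius in pixels.
#' @param dropout_rate per-slice dropout probability in `[0, 1]`.
#' @param dropout_radius bite radius in pixels.
#' @param jitter boundary flip probability in `[0, 1]`.
#' @param seed integer seed for this model's noise.
#' @return object of class `segmenter_profile`.
#' @export
segmenter_profile <- function(model_id, dilate_px = 0L, erode_px = 0L,
                              blob_rate = 0, blob_radius = 3,
                              dropout_rate = 0, dropout_radius = 4,
                              jitter = 0, seed = 1L) {
  if (dilate_px < 0L || erode_px < 0L) {
    stop("dilate_px and erode_px must be non-negative", call. = FALSE)
  }
  if (dilate_px > 0L && erode_px > 0L) {
    stop("a profile cannot both dilate and erode", call. = FALSE)
  }
  if (jitter < 0 || jitter > 1 || dropout_rate < 0 || dropout_rate > 1) {
    stop("jitter and dropout_rate must lie in [0, 1]", call. = FALSE)
  }
  structure(list(model_id = as.character(model_id),
                 dilate_px = as.integer(dilate_px),
                 erode_px = as.integer(erode_px),
                 blob_rate = blob_rate, blob_radius = blob_radius,
                 dropout_rate = dropout_rate, dropout_radius = dropout_radius,
                 jitter = jitter, seed = as.integer(seed)),
            class = "segmenter_profile")
}

#' Simulate a biased segmenter's output for a ground-truth series
#'
#' Applies, per slice and in this order: boundary jitter, dilation or
#' erosion, spurious blobs (sampled outside the ground-truth region,
#' preferentially on distractor structures), and dropout bites. With an
#' all-zero profile the output equals the ground truth exactly. Dilate-only
#' profiles produce supersets of the truth (no missed pixels); erode-only
#' profiles produce subsets (no over-segmented pixels). Deterministic given
#' `profile$seed`.
#'
#' @param gt ground-truth [mask_series()].
#' @param distractors matching distractor series (may be all-background).
#' @param profile a [segmenter_profile()].
#' @return a [mask_series()] labelled with `profile$model_id`.
#' @export
simulate_model_output <- function(gt, distractors, profile) {
  stopifnot(inherits(gt, "mask_series"), inherits(profile, "segmenter_profile"))
  check_same_series(gt, distractors, "gt and distractors")
  h <- nrow(gt$slices[[1L]]); w <- ncol(gt$slices[[1L]])
  with_rng_seed(profile$seed, {
    out <- vector("list", length(gt))
    for (i in seq_len(length(gt))) {
      g <- gt$slices[[i]]
      pred <- matrix(as.integer(g), h, w)
      if (profile$jitter > 0) {
        bp <- boundary_pixels(pred)
        if (nrow(bp) > 0L) {
          drop <- stats::runif(nrow(bp)) < profile$jitter
          pred[bp[drop, , drop = FALSE]] <- 0L
        }
        outer_bp <- boundary_pixels(1L - pred)
        if (nrow(outer_bp) > 0L) {
          add <- stats::runif(nrow(outer_bp)) < profile$jitter
          pred[outer_bp[add, , drop = FALSE]] <- 1L
        }
      }
      if (profile$dilate_px > 0L) {
        brush <- EBImage::makeBrush(2L * profile$dilate_px + 1L, "disc")
        pred <- matrix(as.integer(EBImage::dilate(pred, brush) > 0), h, w)
      } else if (profile$erode_px > 0L) {
        brush <- EBImage::makeBrush(2L * profile$erode_px + 1L, "disc")
        pred <- matrix(as.integer(EBImage::erode(pred, brush) > 0), h, w)
      }
      if (profile$blob_rate > 0) {
        nb <- stats::rpois(1L, profile$blob_rate)
        if (nb > 0L) {
          dslice <- distractors$slices[[i]]
          dpix <- which(dslice == 1L)
          bgpix <- which(g == 0L)
          for (j in seq_len(nb)) {
            pool <- if (length(dpix) > 0L && stats::runif(1) < 0.8) dpix else bgpix
            if (length(pool) == 0L) next
            ctr <- pool[[sample.int(length(pool), 1L)]]
            r0 <- ((ctr - 1L) %% h) + 1L
            c0 <- ((ctr - 1L) %/% h) + 1L
            blob <- stamp_disc(matrix(0L, h, w), r0, c0, profile$blob_radius)
            blob[g == 1L] <- 0L   # spurious blobs stay outside the true region
            pred[blob == 1L] <- 1L
          }
        }
      }
      if (profile$dropout_rate > 0 && stats::runif(1) < profile$dropout_rate) {
        bp <- boundary_pixels(pred)
        if (nrow(bp) > 0L) {
          k <- sample.int(nrow(bp), 1L)
          pred <- bite_disc(pred, bp[k, "row"], bp[k, "col"], profile$dropout_radius)
        }
      }
      out[[i]] <- pred
    }
    mask_series(out, profile$model_id)
  })
}

#' Default trio of simulated segmenters
#'
#' Three profiles emulating the error characters commonly seen in U-Net
#' family segmenters on head scans: a baseline model with moderate
#' over-segmentation and distractor-linked false alarms near the orbits
#' (`unet_like`); a model that heavily over-segments the skull base but
#' misses very little true tissue (`unet2p_like`); and a more accurate model
#' whose residual errors are boundary noise with occasional small false
#' alarms (`unet3p_like`). All three over-segment more than they miss, so
#' profiling them selects intersection fusion.
#'
#' @param seed base seed; each profile derives its own stream from it.
#' @return named list of three [segmenter_profile()]s.
#' @export
default_segmenter_profiles <- function(seed = 20210101L) {
  s <- as.integer(seed %% 2000000000L)
  list(
    unet_like = segmenter_profile(
      "unet_like", dilate_px = 1L, blob_rate = 0.6, blob_radius = 3,
      dropout_rate = 0.2, dropout_radius = 4, jitter = 0.1, seed = s + 1L),
    unet2p_like = segmenter_profile(
      "unet2p_like", dilate_px = 2L, blob_rate = 1.5, blob_radius = 4,
      dropout_rate = 0, jitter = 0.05, seed = s + 2L),
    unet3p_like = segmenter_profile(
      "unet3p_like", dilate_px = 1L, blob_rate = 0.25, blob_radius = 2,
      dropout_rate = 0.3, dropout_radius = 4, jitter = 0.12, seed = s + 3L)
  )
}

#' Write a complete synthetic benchmark bundle to disk
#'
#' Generates a phantom ground-truth series, simulates one output series per
#' segmenter profile, writes every series, and records a `manifest.json`
#' echoing the full configuration (seeds included) so the bundle can be
#' regenerated bit-identically.
#'
#' @param config a [phantom_config()].
#' @param profiles list of at least two [segmenter_profile()]s.
#' @param dir output directory.
#' @param format `"png"` (one subdirectory of slice PNGs per series) or
#'   `"nifti"` (one volume per series).
#' @return invisibly, the manifest as a list (also written to
#'   `file.path(dir, "manifest.json")`).
#' @export
benchmark_bundle <- function(config, profiles, dir, format = c("png", "nifti")) {
  format <- match.arg(format)
  stopifnot(inherits(config, "phantom_config"))
  if (length(profiles) < 2L) {
    stop("benchmark_bundle needs at least two segmenter profiles", call. = FALSE)
  }
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    stop(sprintf("cannot create output directory '%s'", dir), call. = FALSE)
  }
  phantom <- generate_phantom_series(config)
  series_paths <- list()
  write_one <- function(series, name) {
    sub <- file.path(dir, name)
    if (format == "png") {
      write_series(series, sub, "png")
      series_paths[[name]] <<- name
    } else {
      p <- write_series(series, dir, "nifti")
      series_paths[[name]] <<- basename(p)
    }
  }
  write_one(phantom$gt, "gt")
  for (p in profiles) {
    pred <- simulate_model_output(phantom$gt, phantom$distractors, p)
    write_one(pred, p$model_id)
  }
  manifest <- list(
    format = format,
    n_slices = config$n_slices,
    height = config$height, width = config$width,
    base_radius = config$base_radius,
    area_profile = config$area_profile,
    distractor_rate = config$distractor_rate,
    seed = config$seed,
    series = series_paths,
    profiles = lapply(profiles, function(p) unclass(p))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
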