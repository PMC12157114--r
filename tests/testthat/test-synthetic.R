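test_that("phantom generation respects the config and its seed", {
  cfg <- phantom_config(seed = 7L)
  ph <- generate_phantom_series(cfg)
  expect_equal(length(ph$gt), 31L)
  expect_equal(dim(ph$gt$slices[[1]]), c(128L, 128L))
  expect_equal(length(ph$distractors), 31L)

  # same seed -> bit-identical; different seed -> different series
  ph2 <- generate_phantom_series(cfg)
  expect_identical(lapply(ph$gt$slices, as.integer),
                   lapply(ph2$gt$slices, as.integer))
  ph3 <- generate_phantom_series(phantom_config(seed = 8L))
  expect_false(identical(lapply(ph$gt$slices, as.integer),
                         lapply(ph3$gt$slices, as.integer)))

  # zero factors at both ends force empty first and last slices
  prof <- default_area_profile(9); prof[1] <- 0
  cfg0 <- phantom_config(n_slices = 9L, height = 64L, width = 64L,
                         area_profile = prof, seed = 7L)
  ph0 <- generate_phantom_series(cfg0)
  expect_equal(sum(ph0$gt$slices[[1]]), 0L)
  expect_equal(sum(ph0$gt$slices[[9]]), 0L)
  expect_gt(sum(ph0$gt$slices[[5]]), 0L)
})

test_that("phantom geometry is validated", {
  expect_error(phantom_config(n_slices = 0L), "positive")
  expect_error(phantom_config(n_slices = 5L, area_profile = rep(0.5, 4)),
               "one factor per slice")
  expect_error(phantom_config(n_slices = 5L, area_profile = rep(2, 5)),
               "\\[0, 1\\]")
  # radius below one pixel at a nonzero factor is degenerate
  cfg <- phantom_config(n_slices = 3L, height = 64L, width = 64L,
                        base_radius = 1, area_profile = c(0.1, 1, 0.1))
  expect_error(generate_phantom_series(cfg), "degenerate")
})

test_that("phantom slice areas follow the unimodal head profile", {
  cfg <- phantom_config(seed = 123L)
  ph <- generate_phantom_series(cfg)
  areas <- vapply(ph$gt$slices, sum, integer(1))
  n <- length(areas)
  expect_gt(cor(areas, cfg$area_profile), 0.99)
  peak <- which.max(areas)
  expect_true(peak >= ceiling(n / 3) && peak <= floor(2 * n / 3))
  # rises towards the peak and falls after it (up to pixelation wobble)
  tol <- ceiling(0.02 * max(areas))
  expect_true(all(diff(areas[1:peak]) >= -tol))
  expect_true(all(diff(areas[peak:n]) <= tol))
  # bottom and top cross-sections are small relative to the middle
  expect_lt(areas[1], 0.4 * max(areas))
  expect_lt(areas[n], 0.4 * max(areas))
})

test_that("distractors sit on low slices and never touch the brain region", {
  cfg <- phantom_config(seed = 99L, distractor_rate = 1)
  ph <- generate_phantom_series(cfg)
  low <- ceiling(length(ph$gt) / 4)
  d_areas <- vapply(ph$distractors$slices, sum, integer(1))
  expect_true(all(d_areas[(low + 1):length(d_areas)] == 0L))
  expect_gt(sum(d_areas[1:low]), 0L)
  for (i in seq_len(low)) {
    expect_equal(sum(ph$gt$slices[[i]] & ph$distractors$slices[[i]]), 0L)
  }
})

test_that("simulated segmenters have the configured error direction", {
  cfg <- tiny_bundle_config(5L)
  ph <- generate_phantom_series(cfg)

  clean <- segmenter_profile("clean", seed = 5L)
  out <- simulate_model_output(ph$gt, ph$distractors, clean)
  expect_identical(lapply(out$slices, as.integer),
                   lapply(ph$gt$slices, as.integer))

  dil <- simulate_model_output(ph$gt, ph$distractors,
                               segmenter_profile("dil", dilate_px = 1L, seed = 5L))
  ero <- simulate_model_output(ph$gt, ph$distractors,
                               segmenter_profile("ero", erode_px = 1L, seed = 5L))
  for (i in seq_len(length(ph$gt))) {
    ccd <- confusion_counts(dil$slices[[i]], ph$gt$slices[[i]])
    cce <- confusion_counts(ero$slices[[i]], ph$gt$slices[[i]])
    expect_equal(ccd[["fn"]], 0L)               # dilation is a superset
    expect_equal(cce[["fp"]], 0L)               # erosion is a subset
    if (sum(ph$gt$slices[[i]]) > 0) {
      expect_gt(ccd[["fp"]], 0L)
      expect_gt(cce[["fn"]], 0L)
    }
  }

  expect_error(segmenter_profile("bad", dilate_px = 1L, erode_px = 1L),
               "cannot both")
})

test_that("simulation is a pure function of the profile seed", {
  cfg <- tiny_bundle_config(6L)
  ph <- generate_phantom_series(cfg)
  prof <- segmenter_profile("m", dilate_px = 1L, blob_rate = 1, jitter = 0.1,
                            dropout_rate = 0.3, seed = 77L)
  a <- simulate_model_output(ph$gt, ph$distractors, prof)
  b <- simulate_model_output(ph$gt, ph$distractors, prof)
  expect_identical(lapply(a$slices, as.integer), lapply(b$slices, as.integer))
  prof2 <- segmenter_profile("m", dilate_px = 1L, blob_rate = 1, jitter = 0.1,
                             dropout_rate = 0.3, seed = 78L)
  c2 <- simulate_model_output(ph$gt, ph$distractors, prof2)
  expect_false(identical(lapply(a$slices, as.integer),
                         lapply(c2$slices, as.integer)))
})

test_that("benchmark bundles round-trip and profile to intersection fusion", {
  dir <- withr::local_tempdir()
  cfg <- phantom_config(seed = 20210101L)
  profs <- default_segmenter_profiles(cfg$seed)
  man <- benchmark_bundle(cfg, profs, file.path(dir, "bundle"))
  expect_setequal(names(man$series),
                  c("gt", "unet_like", "unet2p_like", "unet3p_like"))
  expect_true(file.exists(file.path(dir, "bundle", "manifest.json")))

  # written series equal the in-memory generation
  ph <- generate_phantom_series(cfg)
  gt_disk <- read_series(sort(list.files(file.path(dir, "bundle", "gt"),
                                         full.names = TRUE)), "gt")
  expect_identical(lapply(gt_disk$slices, as.integer),
                   lapply(ph$gt$slices, as.integer))

  # profiling the default paper-like bundle yields all-OVER -> intersection
  preds <- lapply(names(profs), function(id)
    read_series(sort(list.files(file.path(dir, "bundle", id),
                                full.names = TRUE)), id))
  eps <- lapply(preds, function(p) accumulate_profile(p, gt_disk, p$series_id))
  for (ep in eps) expect_gt(ep$num_overseg, ep$num_miss)
  plan <- select_strategy(eps)
  expect_equal(plan$operation, "intersection")
  expect_setequal(plan$model_ids, names(profs))

  expect_error(benchmark_bundle(cfg, profs["unet_like"], file.path(dir, "b2")),
               "at least two")
})

test_that("a two-profile bundle lists three series in its manifest", {
  dir <- withr::local_tempdir()
  cfg <- tiny_bundle_config(3L)
  profs <- list(segmenter_profile("a", dilate_px = 1L, seed = 4L),
                segmenter_profile("b", erode_px = 1L, seed = 5L))
  man <- benchmark_bundle(cfg, profs, file.path(dir, "bundle"))
  expect_equal(length(man$series), 3L)
  expect_setequal(names(man$series), c("gt", "a", "b"))
})
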