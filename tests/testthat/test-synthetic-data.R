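test_that("kidney sizes reproduce the per-class clinical moments", {
  profs <- default_profiles()
  # degenerate SD pins the draw at the published mean
  for (p in profs) {
    p0 <- p; p0$size_sd_cm <- 0
    expect_equal(sample_kidney_size(p0, 3),
                 rep(p$size_mean_cm, 3))
  }
  # large-sample means converge to the published values (3 SE)
  set.seed(101)
  for (p in profs) {
    draws <- sample_kidney_size(p, 1e5)
    se <- p$size_sd_cm / sqrt(1e5)
    expect_lt(abs(mean(draws) - p$size_mean_cm), 3 * se + 1e-12)
    expect_true(all(draws >= 0.5))
  }
  # seeded determinism
  set.seed(7); a <- sample_kidney_size(profs$severe, 50)
  set.seed(7); b <- sample_kidney_size(profs$severe, 50)
  expect_identical(a, b)
})

test_that("region textures honor the speckle contract", {
  tp <- texture_params(120, 6, 2)
  # noiseless limit is a constant raster at the echo level
  flat <- generate_region_texture(texture_params(120, Inf, 2), c(20, 30))
  expect_true(all(flat == 120L))
  # determinism under a shared seed
  set.seed(5); a <- generate_region_texture(tp, c(40, 40))
  set.seed(5); b <- generate_region_texture(tp, c(40, 40))
  expect_identical(a, b)
  # mean within 10% of mean_echo at ROI scale, all class/region params
  set.seed(9)
  for (p in default_profiles()) for (reg in c("cortex", "boundary", "medulla")) {
    tx <- generate_region_texture(p[[reg]], c(50, 50))
    expect_lt(abs(mean(tx) - p[[reg]]$mean_echo) / p[[reg]]$mean_echo, 0.10)
  }
  # bright and dark textures never swap order (Monte-Carlo separation)
  bright <- texture_params(180, 6, 2); dark <- texture_params(60, 6, 2)
  for (rep in 1:25) {
    set.seed(1000 + rep); mb <- mean(generate_region_texture(bright, c(50, 50)))
    set.seed(1000 + rep); md <- mean(generate_region_texture(dark, c(50, 50)))
    expect_gt(mb, md)
  }
  expect_error(generate_region_texture(tp, c(1, 5)), class = "renotex_image_error")
})

test_that("kidney frames lay out three disjoint in-bounds ROIs", {
  spec <- cohort_spec(seed = 3)
  profs <- default_profiles()
  set.seed(3)
  frame <- generate_kidney_image(profs$normal, spec)
  expect_named(frame$rois, c("cortex", "boundary", "medulla"))
  for (r in frame$rois) {
    expect_equal(r$side, 50L)
    expect_lte(r$top_row + r$side, nrow(frame$image))
    expect_lte(r$left_col + r$side, ncol(frame$image))
  }
  rows <- vapply(frame$rois, function(r) r$top_row, 1L)
  expect_true(all(diff(sort(rows)) >= 50))  # vertically disjoint
  # too-small frame refuses the layout
  expect_error(generate_kidney_image(profs$normal,
                                     cohort_spec(image_dims = c(120, 160))),
               class = "renotex_layout_error")
})

test_that("cortical echogenicity and boundary crispness track severity", {
  spec <- cohort_spec(seed = 1)
  profs <- default_profiles()
  roi_mean <- function(frame, nm) mean(crop_roi(frame$image, frame$rois[[nm]]))
  grad_stat <- function(frame) {
    w <- crop_roi(frame$image, frame$rois$boundary)
    mean(abs(diff(w)))  # mean absolute vertical gradient
  }
  for (rep in 1:20) {
    means <- vapply(profs, function(p) {
      set.seed(3000 + rep)
      roi_mean(generate_kidney_image(p, spec), "cortex")
    }, 1)
    expect_true(means[["normal"]] < means[["mild_moderate"]] &&
                means[["mild_moderate"]] < means[["severe"]])
  }
  # blurring the corticomedullary edge lowers the boundary gradient
  sharp <- profs$normal
  blurred <- profs$normal
  blurred$boundary$boundary_sharpness <- 0
  for (rep in 1:10) {
    set.seed(4000 + rep); gs <- grad_stat(generate_kidney_image(sharp, spec))
    set.seed(4000 + rep); gb <- grad_stat(generate_kidney_image(blurred, spec))
    expect_lte(gb, gs)
  }
})

test_that("cohort generation is exact in counts and fully seeded", {
  spec <- tiny_cohort_spec(seed = 21, n = c(2, 0, 1))
  co <- generate_cohort(spec)
  expect_length(co, 3)
  expect_equal(vapply(co, `[[`, "", "label"),
               c("normal", "normal", "severe"))
  expect_false(anyDuplicated(vapply(co, `[[`, "", "id")) > 0)
  # byte-identical regeneration
  co2 <- generate_cohort(spec)
  expect_identical(co, co2)
  # empty cohort is a valid empty list
  expect_length(generate_cohort(tiny_cohort_spec(n = c(0, 0, 0))), 0)
})

test_that("cohort round-trips through PNG frames and the CSV manifest", {
  dir <- withr::local_tempdir()
  spec <- tiny_cohort_spec(seed = 8, n = c(2, 1, 1))
  co <- generate_cohort(spec)
  manifest <- write_cohort(co, dir, spec = spec)
  expect_equal(nrow(manifest), 4)
  expect_true(file.exists(file.path(dir, "spec.yaml")))
  img <- read_gray_image(file.path(dir, manifest$image_path[1]))
  expect_identical(img, co[[1]]$image)
  # features from disk match features from memory
  t_mem <- extract_cohort_features(co)
  t_disk <- extract_cohort_features(file.path(dir, "manifest.csv"))
  expect_equal(as.data.frame(t_mem)[feature_column_names()],
               as.data.frame(t_disk)[feature_column_names()],
               tolerance = 1e-12)
})
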