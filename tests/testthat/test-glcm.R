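test_that("quantization bins linearly into 1..N", {
  expect_true(all(quantize_image(matrix(77, 4, 4)) == 1L))
  v <- matrix(0:255, 16, 16)
  q <- quantize_image(v, feature_config(gray_limits = "full_range"))
  expect_equal(as.vector(q), as.integer(floor((0:255) / 32) + 1))
  # idempotent in level space: requantizing levels preserves them
  lv <- matrix(c(1, 8, 3, 5), 2, 2)
  q2 <- quantize_image(lv, feature_config())
  expect_equal(range(q2), c(1L, 8L))
  expect_identical(quantize_image(q2, feature_config()),
                   matrix(c(1L, 8L, 3L, 5L), 2, 2))
})

test_that("co-occurrence counting matches exhaustive pair enumeration", {
  img <- rbind(c(1, 1, 2, 2), c(1, 1, 2, 2), c(3, 3, 4, 4), c(3, 3, 4, 4))
  g <- build_glcm(img, 0, n_levels = 4, symmetric = FALSE)
  want <- matrix(0, 4, 4)
  want[1, 1] <- want[1, 2] <- want[2, 2] <- 1 / 6
  want[3, 3] <- want[3, 4] <- want[4, 4] <- 1 / 6
  expect_equal(g$p, want)
  # constant image: one cell holds all mass
  gc <- build_glcm(matrix(1L, 5, 5), 45, n_levels = 3, symmetric = FALSE)
  expect_equal(gc$p[1, 1], 1)
  # checkerboard at 0 degrees: all mass off-diagonal, split evenly
  cb <- outer(1:4, 1:4, function(r, c) ((r + c) %% 2) + 1)
  gb <- build_glcm(cb, 0, n_levels = 2, symmetric = FALSE)
  expect_equal(gb$p[1, 2], 0.5)
  expect_equal(gb$p[2, 1], 0.5)
  # symmetric mode equals its transpose; no-pairs input errors
  gs <- build_glcm(img, 90, n_levels = 4, symmetric = TRUE)
  expect_equal(gs$p, t(gs$p))
  expect_error(build_glcm(matrix(1L, 1, 1), 0, n_levels = 2),
               class = "renotex_no_pairs_error")
  # oracle agreement across all four angles on random rasters
  set.seed(31)
  for (rep in 1:10) {
    q <- random_levels(6, 6, 4)
    for (a in GLCM_ANGLES) {
      off <- glcm_offset(a)
      expect_equal(build_glcm(q, a, n_levels = 4, symmetric = TRUE)$p,
                   oracle_glcm(q, off$drow, off$dcol, 4, TRUE),
                   tolerance = 1e-14)
    }
  }
})

test_that("marginal quantities match hand summation on the worked example", {
  img <- rbind(c(1, 1, 2, 2), c(1, 1, 2, 2), c(3, 3, 4, 4), c(3, 3, 4, 4))
  g <- build_glcm(img, 0, n_levels = 4, symmetric = FALSE)
  m <- glcm_marginals(g)
  expect_equal(m$px, c(1/3, 1/6, 1/3, 1/6))
  expect_equal(m$py, c(1/6, 1/3, 1/6, 1/3))
  want_sum <- numeric(7)                    # k = 2..8
  want_sum[c(2, 3, 4, 6, 7, 8) - 1] <- 1 / 6
  expect_equal(m$p_sum, want_sum)
  expect_equal(m$p_dif, c(4/6, 2/6, 0, 0))
  expect_true(m$hxy1 >= m$hxy - 1e-12)
  # normalization of every marginal
  expect_equal(sum(m$px), 1); expect_equal(sum(m$py), 1)
  expect_equal(sum(m$p_sum), 1); expect_equal(sum(m$p_dif), 1)
  # uniform marginal attains maximum entropy
  gu <- build_glcm(matrix(rep(1:4, 4), 4, 4, byrow = TRUE), 90,
                   n_levels = 4, symmetric = FALSE)
  mu <- glcm_marginals(gu)
  expect_equal(mu$hx, log(4))
  # single-cell GLCM degenerates cleanly
  g1 <- build_glcm(matrix(2L, 3, 3), 0, n_levels = 3, symmetric = FALSE)
  m1 <- glcm_marginals(g1)
  expect_equal(m1$hxy, 0)
  expect_equal(m1$mu_x, 2); expect_equal(m1$mu_y, 2)
})

test_that("descriptors hit their closed-form values", {
  # all mass on one diagonal cell
  g1 <- build_glcm(matrix(1L, 50, 50), 0, n_levels = 8)
  f1 <- glcm_features(g1)
  expect_equal(unname(f1[c("energy", "entropy", "contrast", "dissimilarity",
                           "homogeneity", "maximum_probability",
                           "inverse_difference")]),
               c(1, 0, 0, 0, 1, 1, 1))
  expect_equal(unname(f1[c("correlation", "imc1", "imc2")]), c(0, 0, 0))
  # the worked 1/6 example
  img <- rbind(c(1, 1, 2, 2), c(1, 1, 2, 2), c(3, 3, 4, 4), c(3, 3, 4, 4))
  g <- build_glcm(img, 0, n_levels = 4, symmetric = FALSE)
  f <- glcm_features(g)
  expect_equal(unname(f["contrast"]), 1 / 3)
  expect_equal(unname(f["energy"]), 1 / 6)
  expect_equal(unname(f["entropy"]), log(6))
  expect_equal(unname(f["dissimilarity"]), 1 / 3)
  expect_equal(unname(f["homogeneity"]), 5 / 6)
  expect_equal(unname(f["sum_average"]), 5)
  expect_equal(unname(f["difference_entropy"]),
               -(2/3 * log(2/3) + 1/3 * log(1/3)))
  # checkerboard: perfect anticorrelation
  cb <- outer(1:4, 1:4, function(r, c) ((r + c) %% 2) + 1)
  fb <- glcm_features(build_glcm(cb, 0, n_levels = 2, symmetric = FALSE))
  expect_equal(unname(fb[c("correlation", "contrast", "energy")]),
               c(-1, 1, 0.5))
})

test_that("every descriptor agrees with the brute-force oracle", {
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(2:4, 1)
    q <- random_levels(sample(4:6, 1), sample(4:6, 1), n)
    sym <- rep %% 2 == 0
    dialect <- if (rep %% 3 == 0) "classical_haralick" else "as_printed"
    cfg <- feature_config(n_levels = n, symmetric = sym, dialect = dialect)
    a <- sample(GLCM_ANGLES, 1)
    g <- build_glcm(q, a, n_levels = n, symmetric = sym)
    off <- glcm_offset(a)
    p_or <- oracle_glcm(q, off$drow, off$dcol, n, sym)
    expect_equal(glcm_features(g, cfg = cfg),
                 oracle_features(p_or, dialect = dialect),
                 tolerance = 1e-10)
  }
})

test_that("descriptor invariants hold on random matrices", {
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(2:4, 1)
    q <- random_levels(6, 6, n)
    g <- build_glcm(q, sample(GLCM_ANGLES, 1), n_levels = n, symmetric = TRUE)
    m <- glcm_marginals(g)
    f <- glcm_features(g, m)
    expect_equal(sum(g$p), 1)
    # symmetric mode: marginals coincide
    expect_equal(m$px, m$py)
    expect_equal(m$hx, m$hy)
    # HXY1 - HXY is a KL divergence, so printed IMC1 is nonpositive
    expect_gte(m$hxy1, m$hxy - 1e-12)
    expect_lte(f[["imc1"]], 1e-12)
    expect_gte(f[["correlation"]], -1 - 1e-9)
    expect_lte(f[["correlation"]], 1 + 1e-9)
    expect_true(f[["energy"]] > 0 && f[["energy"]] <= 1)
    expect_gte(f[["entropy"]], 0)
    expect_true(f[["contrast"]] >= 0 && f[["dissimilarity"]] >= 0)
    expect_true(f[["homogeneity"]] > 0 && f[["homogeneity"]] <= 1)
    expect_true(f[["inverse_difference"]] > 0 &&
                f[["inverse_difference"]] <= 1)
  }
})

test_that("angle averaging is an element-wise mean with fixed arity", {
  set.seed(5)
  q <- random_levels(6, 6, 3)
  vecs <- lapply(GLCM_ANGLES, function(a)
    glcm_features(build_glcm(q, a, n_levels = 3)))
  avg <- average_over_angles(vecs)
  expect_equal(avg[["contrast"]],
               mean(vapply(vecs, `[[`, 1, "contrast")))
  expect_equal(average_over_angles(rep(list(vecs[[1]]), 4)), vecs[[1]])
  expect_error(average_over_angles(vecs[1:3]), class = "renotex_config_error")
})

test_that("rotating the raster 90 degrees permutes angles, fixing the average", {
  set.seed(77)
  for (rep in 1:5) {
    q <- random_levels(7, 7, 4)
    qr <- t(q)[, nrow(q):1, drop = FALSE]   # quarter-turn rotation
    feats <- function(x) lapply(GLCM_ANGLES, function(a)
      glcm_features(build_glcm(x, a, n_levels = 4, symmetric = TRUE)))
    f0 <- feats(q); f90 <- feats(qr)
    # 0 <-> 90 and 45 <-> 135 swap under rotation (symmetric matrices)
    expect_equal(f0[[1]], f90[[3]], tolerance = 1e-12)
    expect_equal(f0[[3]], f90[[1]], tolerance = 1e-12)
    expect_equal(f0[[2]], f90[[4]], tolerance = 1e-12)
    expect_equal(f0[[4]], f90[[2]], tolerance = 1e-12)
    expect_equal(average_over_angles(f0), average_over_angles(f90),
                 tolerance = 1e-12)
  }
})

test_that("ROI extraction composes crop, preprocess, GLCM and averaging", {
  img <- matrix(150L, 80, 80)
  roi <- roi_spec("cortex", 10, 10, 50)
  f <- extract_roi_features(img, roi,
                            preprocess_config(equalize = FALSE,
                                              range_filter = FALSE))
  expect_length(f, 19)
  expect_equal(unname(f[c("energy", "entropy", "homogeneity")]), c(1, 0, 1))
  expect_error(extract_roi_features(img, roi_spec("cortex", 40, 40, 50)),
               class = "renotex_roi_error")
  # deterministic regression on a seeded synthetic cortex window
  set.seed(99)
  tx <- generate_region_texture(texture_params(110, 5, 2.5), c(80, 80))
  f1 <- extract_roi_features(tx, roi)
  f2 <- extract_roi_features(tx, roi)
  expect_identical(f1, f2)
})
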