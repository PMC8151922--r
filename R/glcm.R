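#' Canonical names of the 19 co-occurrence descriptors
#'
#' Fixed serialization order used in feature vectors and CSV headers.
#' @export
GLCM_FEATURE_NAMES <- c(
  "autocorrelation", "contrast", "correlation", "cluster_prominence",
  "cluster_shade", "dissimilarity", "energy", "entropy", "homogeneity",
  "maximum_probability", "sum_of_squares_variance", "sum_average",
  "sum_variance", "sum_entropy", "difference_variance", "difference_entropy",
  "imc1", "imc2", "inverse_difference")

#' The four co-occurrence orientations
#' @export
GLCM_ANGLES <- c(0, 45, 90, 135)

#' Texture-feature configuration
#'
#' Houses every convention the co-occurrence computation needs fixed.
#'
#' @param n_levels Number of gray levels `N` after quantization (default 8).
#' @param symmetric Count each pixel pair in both directions (default `TRUE`).
#' @param log_base `"natural"` or `"log2"` for all entropies.
#' @param dialect `"as_printed"` (cluster prominence cubic, cluster shade
#'   quartic, IMC2 without the square root) or `"classical_haralick"`
#'   (quartic prominence, cubic shade, IMC2 with square root). Both
#'   dialects use the full inverse-difference sum and a positive
#'   homogeneity, as the descriptor ranges require.
#' @param gray_limits `"image_minmax"` (bin the observed range; a constant
#'   image maps to level 1) or `"full_range"` (bin `[0, 255]`, so with
#'   `N = 8` level is `floor(v / 32) + 1`).
#' @param distance Pixel displacement magnitude `d` (default 1).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(n_levels = 8, symmetric = TRUE,
                           log_base = c("natural", "log2"),
                           dialect = c("as_printed", "classical_haralick"),
                           gray_limits = c("image_minmax", "full_range"),
                           distance = 1) {
  if (n_levels < 2) stop_renotex("n_levels must be >= 2",
                                 class = "renotex_config_error")
  if (distance < 1) stop_renotex("distance must be >= 1",
                                 class = "renotex_config_error")
  structure(list(n_levels = as.integer(n_levels), symmetric = isTRUE(symmetric),
                 log_base = match.arg(log_base), dialect = match.arg(dialect),
                 gray_limits = match.arg(gray_limits),
                 distance = as.integer(distance)),
            class = "feature_config")
}

glcm_log <- function(cfg) if (cfg$log_base == "log2") log2 else log

xlogx_sum <- function(p, logf) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * logf(p))
}

#' Angle and distance to pixel displacement
#'
#' Image-processing convention: 0 deg -> `(0, d)`, 45 deg -> `(-d, d)`,
#' 90 deg -> `(-d, 0)`, 135 deg -> `(-d, -d)` as `(drow, dcol)` with row
#' index growing downward.
#'
#' @param angle_deg One of 0, 45, 90, 135.
#' @param distance Positive integer `d`.
#' @return List with `angle_deg`, `distance`, `drow`, `dcol`.
#' @export
glcm_offset <- function(angle_deg, distance = 1) {
  if (!angle_deg %in% GLCM_ANGLES)
    stop_renotex("angle must be one of 0, 45, 90, 135",
                 class = "renotex_config_error")
  d <- as.integer(distance)
  disp <- switch(as.character(angle_deg),
                 "0" = c(0L, d), "45" = c(-d, d),
                 "90" = c(-d, 0L), "135" = c(-d, -d))
  list(angle_deg = angle_deg, distance = d, drow = disp[1], dcol = disp[2])
}

#' Quantize an image to N gray levels
#'
#' Equal-width linear binning into levels `1..N`. Under `image_minmax` the
#' observed `[min, max]` is divided into `N` bins (constant image: all level
#' 1); under `full_range` the fixed 8-bit range is divided so that with
#' `N = 8` level equals `floor(v / 32) + 1`.
#'
#' @param img Numeric matrix of intensities.
#' @param cfg A [feature_config()].
#' @return Integer matrix of levels in `1..N`.
#' @export
quantize_image <- function(img, cfg = feature_config()) {
  if (!is.matrix(img) || length(img) == 0)
    stop_renotex("img must be a non-empty matrix", class = "renotex_image_error")
  n <- cfg$n_levels
  if (cfg$gray_limits == "full_range") {
    lo <- 0; width <- 256
  } else {
    lo <- min(img); width <- max(img) - lo
    if (width == 0)
      return(matrix(1L, nrow(img), ncol(img)))
  }
  lev <- pmin(n, floor((img - lo) / width * n) + 1)
  matrix(as.integer(pmax(lev, 1L)), nrow(img), ncol(img))
}

#' Build a gray-level co-occurrence matrix
#'
#' Counts every in-bounds ordered pixel pair `(p, p + displacement)`; in
#' symmetric mode the transposed counts are added before normalizing to
#' probabilities `p(i, j) = x(i, j) / sum(x)`.
#'
#' @param q Integer matrix of quantized levels in `1..N`.
#' @param offset A [glcm_offset()] (or an angle in degrees).
#' @param n_levels Number of gray levels `N`.
#' @param symmetric Add transposed counts before normalizing.
#' @return Object of class `glcm`: list with `counts`, `p` (both `N x N`,
#'   rows = level `i` of the reference pixel), `symmetric`, `offset`.
#' @export
build_glcm <- function(q, offset, n_levels = max(q), symmetric = TRUE) {
  if (is.numeric(offset) && length(offset) == 1)
    offset <- glcm_offset(offset)
  n <- as.integer(n_levels)
  nr <- nrow(q); nc <- ncol(q)
  dr <- offset$drow; dc <- offset$dcol
  r0 <- max(1L, 1L - dr):min(nr, nr - dr)
  c0 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (max(1L, 1L - dr) > min(nr, nr - dr) ||
      max(1L, 1L - dc) > min(nc, nc - dc))
    stop_renotex("image too small for offset (%d, %d): no pixel pairs",
                 dr, dc, class = "renotex_no_pairs_error")
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + dr, c0 + dc, drop = FALSE]
  counts <- matrix(tabulate((a - 1L) * n + b, n * n), n, n, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  structure(list(counts = counts, p = counts / sum(counts),
                 symmetric = symmetric, offset = offset, n_levels = n),
            class = "glcm")
}

#' Marginal quantities of a co-occurrence matrix
#'
#' Computes the full set of marginal distributions and entropies the
#' descriptor formulas draw on: row/column marginals `px`, `py` with means
#' and variances, the sum and difference marginals `px+y(k)` (`k` in
#' `2..2N`) and `px-y(k)` (`k` in `0..N-1`) with their means, and the
#' entropies `HX`, `HY`, `HXY`, `HXY1`, `HXY2` (convention `0 log 0 = 0`).
#'
#' @param g A [build_glcm()] result.
#' @param cfg A [feature_config()] (log base).
#' @return List of class `glcm_marginals`.
#' @export
glcm_marginals <- function(g, cfg = feature_config()) {
  stopifnot(inherits(g, "glcm"))
  p <- g$p
  n <- g$n_levels
  logf <- glcm_log(cfg)
  lev <- seq_len(n)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  var_x <- sum((lev - mu_x)^2 * px); var_y <- sum((lev - mu_y)^2 * py)
  isum <- row(p) + col(p); idif <- abs(row(p) - col(p))
  p_sum <- vapply(2:(2 * n), function(k) sum(p[isum == k]), numeric(1))
  p_dif <- vapply(0:(n - 1), function(k) sum(p[idif == k]), numeric(1))
  mu_sum <- sum((2:(2 * n)) * p_sum)
  mu_dif <- sum((0:(n - 1)) * p_dif)
  pxpy <- outer(px, py)
  hxy1 <- -sum(p[pxpy > 0] * logf(pxpy[pxpy > 0]))
  structure(list(
    px = px, py = py, mu_x = mu_x, mu_y = mu_y,
    var_x = var_x, var_y = var_y,
    p_sum = p_sum, p_dif = p_dif, mu_sum = mu_sum, mu_dif = mu_dif,
    hx = xlogx_sum(px, logf), hy = xlogx_sum(py, logf),
    hxy = xlogx_sum(p, logf), hxy1 = hxy1,
    hxy2 = xlogx_sum(pxpy, logf)),
    class = "glcm_marginals")
}

#' The 19 co-occurrence descriptors of one GLCM
#'
#' Evaluates each descriptor from the normalized matrix and its marginals
#' under the selected dialect (see [feature_config()]). The unsubscripted
#' mean in cluster prominence/shade and sum-of-squares variance is
#' `mu = mu_x` (equal to `mu_y` on symmetric matrices). Degenerate cases
#' follow fixed conventions: correlation is 0 when either marginal variance
#' vanishes, IMC1 is 0 when `max(HX, HY) = 0`, and IMC2's exponential
#' argument is floored at 0 before the (classical-dialect) square root.
#'
#' @param g A [build_glcm()] result.
#' @param m Its [glcm_marginals()] (computed if omitted).
#' @param cfg A [feature_config()].
#' @return Named numeric vector of length 19 in canonical order.
#' @export
glcm_features <- function(g, m = NULL, cfg = feature_config()) {
  stopifnot(inherits(g, "glcm"))
  if (is.null(m)) m <- glcm_marginals(g, cfg)
  p <- g$p
  n <- g$n_levels
  logf <- glcm_log(cfg)
  i <- row(p); j <- col(p)
  dif <- i - j
  dev <- i + j - 2 * m$mu_x
  ks <- 2:(2 * n); kd <- 0:(n - 1)
  printed <- cfg$dialect == "as_printed"

  corr <- if (m$var_x > 0 && m$var_y > 0)
    sum((i - m$mu_x) * (j - m$mu_y) * p) / sqrt(m$var_x * m$var_y) else 0

  inverse_difference <- sum(p / (1 + abs(dif)))

  hmax <- max(m$hx, m$hy)
  imc1 <- if (hmax > 0) (m$hxy - m$hxy1) / hmax else 0
  imc2_arg <- max(0, 1 - exp(-2 * (m$hxy2 - m$hxy)))
  imc2 <- if (printed) imc2_arg else sqrt(imc2_arg)

  c(autocorrelation = sum(i * j * p),
    contrast = sum(dif^2 * p),
    correlation = corr,
    cluster_prominence = sum(dev^(if (printed) 3 else 4) * p),
    cluster_shade = sum(dev^(if (printed) 4 else 3) * p),
    dissimilarity = sum(abs(dif) * p),
    energy = sum(p^2),
    entropy = m$hxy,
    homogeneity = sum(p / (1 + dif^2)),
    maximum_probability = max(p),
    sum_of_squares_variance = sum((i - m$mu_x)^2 * p),
    sum_average = m$mu_sum,
    sum_variance = sum((ks - m$mu_sum)^2 * m$p_sum),
    sum_entropy = xlogx_sum(m$p_sum, logf),
    difference_variance = sum((kd - m$mu_dif)^2 * m$p_dif),
    difference_entropy = xlogx_sum(m$p_dif, logf),
    imc1 = imc1,
    imc2 = imc2,
    inverse_difference = inverse_difference)
}

#' Average descriptor vectors over the four orientations
#'
#' @param vectors List of exactly four length-19 named vectors, one per
#'   orientation.
#' @return Element-wise arithmetic mean, canonical order.
#' @export
average_over_angles <- function(vectors) {
  if (length(vectors) != 4L)
    stop_renotex("expected exactly four per-angle vectors, got %d",
                 length(vectors), class = "renotex_config_error")
  mat <- do.call(rbind, lapply(vectors, function(v) v[GLCM_FEATURE_NAMES]))
  if (anyNA(mat))
    stop_renotex("per-angle vectors must carry the 19 canonical names",
                 class = "renotex_config_error")
  colMeans(mat)
}

#' Extract the angle-averaged descriptor vector of one ROI
#'
#' Crop -> preprocess -> quantize -> build the GLCM at the four orientations
#' -> descriptors per orientation -> arithmetic mean. Deterministic.
#'
#' @param img Full frame, integer matrix in `[0, 255]`.
#' @param roi A [roi_spec()] inside the frame.
#' @param pcfg A [preprocess_config()].
#' @param fcfg A [feature_config()].
#' @return Named numeric vector of length 19.
#' @export
extract_roi_features <- function(img, roi, pcfg = preprocess_config(),
                                 fcfg = feature_config()) {
  window <- crop_roi(img, roi)
  window <- preprocess_roi(window, pcfg)
  q <- quantize_image(window, fcfg)
  per_angle <- lapply(GLCM_ANGLES, function(a)
    glcm_features(build_glcm(q, glcm_offset(a, fcfg$distance),
                             n_levels = fcfg$n_levels,
                             symmetric = fcfg$symmetric),
                  cfg = fcfg))
  average_over_angles(per_angle)
}
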