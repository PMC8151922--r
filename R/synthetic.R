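#' Texture parameters for one renal region
#'
#' Bundles the knobs of the correlated multiplicative speckle model used by
#' the synthetic cohort generator. The marginal law of the speckle field is
#' Gamma(shape, rate = shape), i.e. unit mean, so `mean_echo` is the expected
#' intensity before 8-bit clipping.
#'
#' @param mean_echo Expected echo level, in intensity units on `[0, 255]`.
#' @param speckle_shape Gamma shape of the multiplicative speckle; larger
#'   values give smoother (lower-contrast) texture. `Inf` disables noise.
#' @param corr_length_px Spatial correlation scale of the latent field, in
#'   pixels (standard deviation of the Gaussian smoothing kernel).
#' @param boundary_sharpness In `[0, 1]`; 1 gives a crisp corticomedullary
#'   edge, 0 a fully blurred transition. Only the boundary-region parameters
#'   of a class profile consult this field.
#' @return An object of class `texture_params`.
#' @export
texture_params <- function(mean_echo, speckle_shape = 6, corr_length_px = 2,
                           boundary_sharpness = 1) {
  if (!is.numeric(mean_echo) || mean_echo < 0 || mean_echo > 255)
    stop_renotex("mean_echo must lie in [0, 255]", class = "renotex_profile_error")
  if (speckle_shape <= 0)
    stop_renotex("speckle_shape must be positive", class = "renotex_profile_error")
  if (corr_length_px <= 0)
    stop_renotex("corr_length_px must be positive", class = "renotex_profile_error")
  if (boundary_sharpness < 0 || boundary_sharpness > 1)
    stop_renotex("boundary_sharpness must lie in [0, 1]", class = "renotex_profile_error")
  structure(list(mean_echo = mean_echo, speckle_shape = speckle_shape,
                 corr_length_px = corr_length_px,
                 boundary_sharpness = boundary_sharpness),
            class = "texture_params")
}

#' Admissible disease classes
#'
#' Canonical class order used everywhere (confusion matrices, one-hot
#' coding, CSV serialization).
#' @export
CLASS_LEVELS <- c("normal", "mild_moderate", "severe")

#' Per-class generative profile
#'
#' @param label One of `"normal"`, `"mild_moderate"`, `"severe"`.
#' @param cortex,boundary,medulla [texture_params()] for each region.
#' @param size_mean_cm,size_sd_cm Kidney bipolar length distribution (cm).
#' @param egfr_mean,egfr_sd eGFR distribution (mL/min/1.73 m^2); cohort
#'   metadata only, never a classifier input.
#' @return An object of class `class_profile`.
#' @export
class_profile <- function(label, cortex, boundary, medulla,
                          size_mean_cm, size_sd_cm, egfr_mean, egfr_sd) {
  label <- match.arg(label, CLASS_LEVELS)
  stopifnot(inherits(cortex, "texture_params"),
            inherits(boundary, "texture_params"),
            inherits(medulla, "texture_params"))
  if (size_mean_cm <= 0 || size_sd_cm < 0)
    stop_renotex("size_mean_cm must be > 0 and size_sd_cm >= 0",
                 class = "renotex_profile_error")
  structure(list(label = label, cortex = cortex, boundary = boundary,
                 medulla = medulla, size_mean_cm = size_mean_cm,
                 size_sd_cm = size_sd_cm, egfr_mean = egfr_mean,
                 egfr_sd = egfr_sd),
            class = "class_profile")
}

#' Default class profiles
#'
#' Kidney-size and eGFR moments are the published per-class clinical values
#' (sizes 11.7 +/- 0.46, 9.14 +/- 2.00, 7.07 +/- 1.70 cm; eGFR 105 +/- 16.7,
#' 40 +/- 9.7, 4 +/- 4.2). Echo levels and speckle parameters are free
#' calibration choices encoding the qualitative sonographic picture: cortical
#' echogenicity rises with fibrosis (60 / 110 / 160), texture coarsens
#' (correlation length 1.5 / 2.5 / 3.5 px, speckle shape 10 / 5 / 3 in the
#' cortex), and corticomedullary differentiation fades (boundary sharpness
#' 1.0 / 0.5 / 0.2, medullary echo converging toward cortical).
#'
#' @return Named list of three [class_profile()] objects in canonical order.
#' @export
default_profiles <- function() {
  list(
    normal = class_profile(
      "normal",
      cortex   = texture_params(60, 10, 1.5),
      boundary = texture_params(115, 8, 2.0, boundary_sharpness = 1.0),
      medulla  = texture_params(170, 6, 2.0),
      size_mean_cm = 11.7, size_sd_cm = 0.46,
      egfr_mean = 105, egfr_sd = 16.7),
    mild_moderate = class_profile(
      "mild_moderate",
      cortex   = texture_params(110, 5, 2.5),
      boundary = texture_params(137, 5, 2.5, boundary_sharpness = 0.5),
      medulla  = texture_params(165, 5, 2.5),
      size_mean_cm = 9.14, size_sd_cm = 2.00,
      egfr_mean = 40, egfr_sd = 9.7),
    severe = class_profile(
      "severe",
      cortex   = texture_params(160, 3, 3.5),
      boundary = texture_params(157, 4, 3.0, boundary_sharpness = 0.2),
      medulla  = texture_params(160, 4, 3.0),
      size_mean_cm = 7.07, size_sd_cm = 1.70,
      egfr_mean = 4, egfr_sd = 4.2)
  )
}

#' Cohort specification
#'
#' @param counts Named integer vector over the three classes. Defaults to
#'   the published cohort composition (251 / 328 / 162, total 741).
#' @param image_dims `(rows, cols)` of each synthetic frame.
#' @param roi_side Side of the square ROI windows, pixels.
#' @param seed Integer seed; the whole cohort is a pure function of the spec.
#' @param profiles Named list of [class_profile()]s.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(counts = c(normal = 251, mild_moderate = 328, severe = 162),
                        image_dims = c(160, 160), roi_side = 50, seed = 1,
                        profiles = default_profiles()) {
  counts <- counts[CLASS_LEVELS]
  names(counts) <- CLASS_LEVELS
  counts[is.na(counts)] <- 0
  if (any(counts < 0)) stop_renotex("class counts must be nonnegative",
                                    class = "renotex_spec_error")
  if (roi_side < 2) stop_renotex("roi_side must be >= 2",
                                 class = "renotex_spec_error")
  structure(list(counts = counts, image_dims = as.integer(image_dims),
                 roi_side = as.integer(roi_side), seed = as.integer(seed),
                 profiles = profiles),
            class = "cohort_spec")
}

#' Draw kidney sizes for one class
#'
#' Sizes are normal with the profile's mean and SD, truncated below at
#' 0.5 cm (inverse-CDF truncation, so one draw consumes one uniform and the
#' stream stays aligned for any truncation point). With `size_sd_cm = 0`
#' the draw is degenerate at the mean.
#'
#' @param profile A [class_profile()].
#' @param n Number of draws.
#' @return Numeric vector of lengths in cm.
#' @export
sample_kidney_size <- function(profile, n = 1) {
  stopifnot(inherits(profile, "class_profile"))
  m <- profile$size_mean_cm; s <- profile$size_sd_cm
  if (s == 0) {
    if (m < 0.5)
      stop_renotex("degenerate size distribution below the 0.5 cm floor",
                   class = "renotex_profile_error")
    return(rep(m, n))
  }
  plo <- stats::pnorm(0.5, m, s)
  if (plo >= 1)
    stop_renotex("size truncation at 0.5 cm leaves no probability mass",
                 class = "renotex_profile_error")
  stats::qnorm(stats::runif(n, plo, 1), m, s)
}

#' Generate one region's speckle texture
#'
#' Multiplicative-speckle surrogate: a white Gaussian field is smoothed to
#' correlation scale `corr_length_px`, standardized, and mapped through the
#' Gaussian copula to a unit-mean Gamma(shape, rate = shape) marginal; the
#' result scales `mean_echo`, is clipped to `[0, 255]` and rounded to 8 bits.
#' Draws come from the current RNG stream, so seeding the session seeds the
#' texture.
#'
#' @param params A [texture_params()].
#' @param dims `(rows, cols)`, both at least 2.
#' @return Integer matrix in `[0, 255]`.
#' @export
generate_region_texture <- function(params, dims) {
  stopifnot(inherits(params, "texture_params"))
  if (length(dims) != 2L || any(dims < 2))
    stop_renotex("dims must give at least a 2x2 image",
                 class = "renotex_image_error")
  field <- generate_speckle_field(params, dims)
  img <- clip01(params$mean_echo * field, 0, 255)
  storage.mode(img) <- "double"
  matrix(as.integer(round_half_up(img)), dims[1], dims[2])
}

# Latent unit-mean speckle field (double matrix). Split out so image
# composition can blend fields before quantizing to 8 bits.
generate_speckle_field <- function(params, dims) {
  if (!is.finite(params$speckle_shape))
    return(matrix(1, dims[1], dims[2]))
  z <- matrix(stats::rnorm(prod(dims)), dims[1], dims[2])
  z <- gauss_smooth(z, params$corr_length_px)
  z <- (z - mean(z)) / stats::sd(z)
  u <- clip01(stats::pnorm(z), 1e-12, 1 - 1e-12)
  matrix(stats::qgamma(u, shape = params$speckle_shape,
                       rate = params$speckle_shape),
         dims[1], dims[2])
}

# Vertical layout: three roi_side windows stacked and centered; the
# corticomedullary transitions sit at 20% and 80% of the boundary window so
# both edges fall inside it. Rows above the first transition are cortex,
# below the second medulla.
kidney_layout <- function(image_dims, roi_side) {
  rows <- image_dims[1]; cols <- image_dims[2]
  if (rows < 3 * roi_side || cols < roi_side)
    stop_renotex("image_dims %dx%d cannot hold three disjoint %dx%d ROIs",
                 rows, cols, roi_side, roi_side, class = "renotex_layout_error")
  top0 <- (rows - 3 * roi_side) %/% 2L
  left0 <- (cols - roi_side) %/% 2L
  rois <- list(
    cortex   = roi_spec("cortex",   top0,                left0, roi_side),
    boundary = roi_spec("boundary", top0 + roi_side,     left0, roi_side),
    medulla  = roi_spec("medulla",  top0 + 2L * roi_side, left0, roi_side))
  b1 <- top0 + roi_side + 0.2 * roi_side   # 0-based row of upper transition
  b2 <- top0 + roi_side + 0.8 * roi_side
  list(rois = rois, transitions = c(b1, b2))
}

#' Generate one synthetic kidney frame with its three ROIs
#'
#' Composites cortex, boundary and medulla speckle fields in a vertical-band
#' layout. Transition width between bands follows the boundary region's
#' `boundary_sharpness`: logistic blending with half-width
#' `1 + 12 * (1 - sharpness)` pixels, so sharpness 1 gives a crisp edge and
#' sharpness 0 a diffuse one.
#'
#' @param profile A [class_profile()].
#' @param spec A [cohort_spec()] (supplies image dims and ROI side).
#' @return List with `image` (integer matrix) and `rois` (named list of
#'   three [roi_spec()]s: cortex, boundary, medulla).
#' @export
generate_kidney_image <- function(profile, spec) {
  stopifnot(inherits(profile, "class_profile"), inherits(spec, "cohort_spec"))
  dims <- spec$image_dims
  lay <- kidney_layout(dims, spec$roi_side)
  fc <- generate_speckle_field(profile$cortex, dims)
  fb <- generate_speckle_field(profile$boundary, dims)
  fm <- generate_speckle_field(profile$medulla, dims)
  h <- 1 + 12 * (1 - profile$boundary$boundary_sharpness)
  r <- seq_len(dims[1]) - 0.5                     # 0-based row centers
  wc <- stats::plogis((lay$transitions[1] - r) / h)
  wm <- stats::plogis((r - lay$transitions[2]) / h)
  wb <- pmax(1 - wc - wm, 0)
  tot <- wc + wb + wm
  mix <- (wc * profile$cortex$mean_echo * fc +
          wb * profile$boundary$mean_echo * fb +
          wm * profile$medulla$mean_echo * fm) / tot
  img <- matrix(as.integer(round_half_up(clip01(mix, 0, 255))),
                dims[1], dims[2])
  list(image = img, rois = lay$rois)
}

#' Generate a full seeded cohort
#'
#' Materializes one record per requested kidney: frame, ROI triple, size and
#' eGFR, in canonical class order. The result is a pure function of the
#' spec (including its seed); the session RNG state is left untouched.
#'
#' @param spec A [cohort_spec()].
#' @return List of records, each with `id`, `label`, `image`, `rois`,
#'   `size_cm`, `egfr`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    records <- vector("list", sum(spec$counts))
    k <- 0L
    for (cls in CLASS_LEVELS) {
      n <- spec$counts[[cls]]
      if (n == 0L) next
      profile <- spec$profiles[[cls]]
      sizes <- sample_kidney_size(profile, n)
      egfrs <- pmax(stats::rnorm(n, profile$egfr_mean, profile$egfr_sd), 0)
      for (i in seq_len(n)) {
        frame <- generate_kidney_image(profile, spec)
        k <- k + 1L
        records[[k]] <- list(
          id = sprintf("%s_%03d", cls, i), label = cls,
          image = frame$image, rois = frame$rois,
          size_cm = sizes[i], egfr = egfrs[i])
      }
    }
    records
  })
}

#' Write a cohort to disk (PNG frames + CSV manifest + YAML spec)
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param spec The [cohort_spec()] used, recorded as `spec.yaml`.
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(rec) {
    path <- file.path("images", paste0(rec$id, ".png"))
    write_gray_image(rec$image, file.path(dir, path))
    cbind(data.frame(id = rec$id, label = rec$label, image_path = path,
                     stringsAsFactors = FALSE),
          manifest_roi_cols(rec$rois),
          data.frame(size_cm = rec$size_cm, egfr = rec$egfr))
  })
  manifest <- do.call(rbind, rows)
  if (is.null(manifest))
    manifest <- empty_manifest()
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(spec))
    yaml::write_yaml(cohort_spec_to_list(spec), file.path(dir, "spec.yaml"))
  invisible(manifest)
}

manifest_roi_cols <- function(rois) {
  out <- list()
  for (nm in c("cortex", "boundary", "medulla")) {
    r <- rois[[nm]]
    out[[paste0("roi_", nm, "_row")]] <- r$top_row
    out[[paste0("roi_", nm, "_col")]] <- r$left_col
    out[[paste0("roi_", nm, "_side")]] <- r$side
  }
  as.data.frame(out)
}

empty_manifest <- function() {
  cols <- c("id", "label", "image_path",
            as.vector(t(outer(c("roi_cortex_", "roi_boundary_", "roi_medulla_"),
                              c("row", "col", "side"), paste0))),
            "size_cm", "egfr")
  df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  df
}

cohort_spec_to_list <- function(spec) {
  list(counts = as.list(spec$counts),
       image_dims = spec$image_dims, roi_side = spec$roi_side,
       seed = spec$seed,
       profiles = lapply(spec$profiles, function(p) {
         list(label = p$label,
              cortex = unclass(p$cortex), boundary = unclass(p$boundary),
              medulla = unclass(p$medulla),
              size_mean_cm = p$size_mean_cm, size_sd_cm = p$size_sd_cm,
              egfr_mean = p$egfr_mean, egfr_sd = p$egfr_sd)
       }))
}
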