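#' Preprocessing configuration
#'
#' The two ROI-level preprocessing operators, applied in a fixed order:
#' histogram equalization first, then the local range filter.
#'
#' @param equalize Apply histogram equalization (default `TRUE`).
#' @param range_filter Apply the local range filter (default `TRUE`).
#' @param levels Output gray levels of equalization (default 256).
#' @param window Odd neighborhood side for the range filter (default 3).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(equalize = TRUE, range_filter = TRUE,
                              levels = 256, window = 3) {
  if (levels < 2)
    stop_renotex("levels must be >= 2", class = "renotex_config_error")
  if (window < 3 || window %% 2 == 0)
    stop_renotex("window must be an odd integer >= 3",
                 class = "renotex_config_error")
  structure(list(equalize = isTRUE(equalize),
                 range_filter = isTRUE(range_filter),
                 levels = as.integer(levels), window = as.integer(window)),
            class = "preprocess_config")
}

#' Histogram equalization
#'
#' Classical CDF remapping: `out(v) = round((cdf(v) - cdf_min) /
#' (1 - cdf_min) * (levels - 1))`, where `cdf` is the empirical cumulative
#' histogram of the input and `cdf_min` its smallest nonzero value. The map
#' is monotone in input intensity; a constant image maps to all zeros.
#'
#' @param img Integer matrix in `[0, 255]`.
#' @param levels Number of output gray levels.
#' @return Integer matrix in `[0, levels - 1]`.
#' @export
equalize_histogram <- function(img, levels = 256) {
  assert_gray_image(img)
  v <- as.integer(img)
  cdf <- cumsum(tabulate(v + 1L, 256L)) / length(v)
  cdf_min <- min(cdf[cdf > 0])
  lut <- if (cdf_min >= 1) rep(0L, 256L) else
    as.integer(round_half_up((cdf - cdf_min) / (1 - cdf_min) * (levels - 1)))
  matrix(lut[v + 1L], nrow(img), ncol(img))
}

#' Local range filter
#'
#' `out(r, c) = max - min` over the `window x window` neighborhood centered
#' at `(r, c)`, with replicate padding at the borders so ROI edges do not
#' produce artificial responses.
#'
#' @param img Integer matrix in `[0, 255]`.
#' @param window Odd neighborhood side, at least 3.
#' @return Integer matrix of local ranges (nonnegative).
#' @export
range_filter <- function(img, window = 3) {
  assert_gray_image(img)
  if (window < 3 || window %% 2 == 0)
    stop_renotex("window must be an odd integer >= 3",
                 class = "renotex_config_error")
  w2 <- window %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ridx <- clip01(seq(1 - w2, nr + w2), 1, nr)
  cidx <- clip01(seq(1 - w2, nc + w2), 1, nc)
  pad <- img[ridx, cidx, drop = FALSE]
  mx <- matrix(-Inf, nr, nc); mn <- matrix(Inf, nr, nc)
  for (dr in 0:(window - 1L)) for (dc in 0:(window - 1L)) {
    blk <- pad[dr + seq_len(nr), dc + seq_len(nc), drop = FALSE]
    mx <- pmax(mx, blk); mn <- pmin(mn, blk)
  }
  matrix(as.integer(mx - mn), nr, nc)
}

#' Preprocess one ROI window
#'
#' Applies the enabled stages in fixed order (equalize, then range filter);
#' with both disabled the input is returned unchanged.
#'
#' @param img ROI window, integer matrix in `[0, 255]`.
#' @param cfg A [preprocess_config()].
#' @return Integer matrix.
#' @export
preprocess_roi <- function(img, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  assert_gray_image(img)
  out <- img
  if (cfg$equalize) out <- equalize_histogram(out, cfg$levels)
  if (cfg$range_filter) out <- range_filter(out, cfg$window)
  out
}
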