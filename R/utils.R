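# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_renotex <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "renotex_error")))
}

assert_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop_renotex("`%s` must be a non-empty numeric matrix", arg,
                 class = "renotex_image_error")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop_renotex("`%s` must hold intensities in [0, 255]", arg,
                 class = "renotex_image_error")
  invisible(img)
}

clip01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Separable Gaussian smoothing of a matrix, realized as two banded-matrix
# products. Rows of each band matrix are renormalized so borders keep unit
# weight (equivalent to renormalized truncation, no padding artifacts).
gauss_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  band <- function(n) {
    idx <- seq_len(n)
    w <- outer(idx, idx, function(i, j) exp(-((i - j)^2) / (2 * sigma^2)))
    w[abs(row(w) - col(w)) > ceiling(3 * sigma)] <- 0
    w / rowSums(w)
  }
  band(nrow(mat)) %*% mat %*% t(band(ncol(mat)))
}

round_half_up <- function(x) floor(x + 0.5)
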