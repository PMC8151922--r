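# 8-bit grayscale image I/O. Internal representation everywhere is a plain
# integer matrix in [0, 255], row = image row.

#' Read an 8-bit grayscale image (PNG or TIFF)
#'
#' Color inputs are converted to luma by channel averaging.
#'
#' @param path File path; format chosen by extension.
#' @return Integer matrix in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_renotex("unsupported image format: .%s", ext,
                 class = "renotex_io_error"))
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , seq_len(min(3, dim(arr)[3])),
                                               drop = FALSE], c(1, 2), mean)
  matrix(as.integer(round_half_up(arr * 255)), nrow(arr), ncol(arr))
}

#' Write an 8-bit grayscale image (PNG or TIFF)
#'
#' @param img Integer matrix in `[0, 255]`.
#' @param path Destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  assert_gray_image(img)
  ext <- tolower(tools::file_ext(path))
  x <- img / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop_renotex("unsupported image format: .%s", ext,
                 class = "renotex_io_error"))
  invisible(path)
}
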