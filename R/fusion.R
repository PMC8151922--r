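#' Region-of-interest window
#'
#' 0-based, half-open square window `[top_row, top_row + side) x
#' [left_col, left_col + side)`.
#'
#' @param name One of `"cortex"`, `"boundary"`, `"medulla"`.
#' @param top_row,left_col 0-based corner.
#' @param side Window side in pixels (default 50).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, top_row, left_col, side = 50) {
  name <- match.arg(name, c("cortex", "boundary", "medulla"))
  if (side < 2) stop_renotex("roi side must be >= 2",
                             class = "renotex_roi_error")
  if (top_row < 0 || left_col < 0)
    stop_renotex("roi corner must be nonnegative", class = "renotex_roi_error")
  structure(list(name = name, top_row = as.integer(top_row),
                 left_col = as.integer(left_col), side = as.integer(side)),
            class = "roi_spec")
}

#' Crop an ROI window out of a frame
#'
#' @param img Integer matrix.
#' @param roi A [roi_spec()]; must lie fully inside `img`.
#' @return `side x side` integer matrix.
#' @export
crop_roi <- function(img, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  if (roi$top_row + roi$side > nrow(img) || roi$left_col + roi$side > ncol(img))
    stop_renotex("ROI '%s' (%d, %d, side %d) exceeds %d x %d frame",
                 roi$name, roi$top_row, roi$left_col, roi$side,
                 nrow(img), ncol(img), class = "renotex_roi_error")
  img[roi$top_row + seq_len(roi$side), roi$left_col + seq_len(roi$side),
      drop = FALSE]
}

ROI_NAMES <- c("cortex", "boundary", "medulla")

#' Column names of the fused 58-vector
#'
#' Three 19-descriptor blocks suffixed by ROI (`cortex.contrast`, ...)
#' followed by `size_cm`.
#' @export
feature_column_names <- function() {
  c(as.vector(vapply(ROI_NAMES, function(r)
      paste(r, GLCM_FEATURE_NAMES, sep = "."), character(19))),
    "size_cm")
}

#' Fuse per-ROI descriptor blocks and kidney size into one sample
#'
#' Concatenation order is fixed by ROI name (cortex, boundary, medulla),
#' not by arrival order; the 58th element is the kidney size.
#'
#' @param blocks Named list of exactly three length-19 vectors, names
#'   `cortex`, `boundary`, `medulla`.
#' @param size_cm Kidney size, cm, positive.
#' @param id Sample identifier.
#' @param label Class label.
#' @return List of class `sample_record` with `id`, `label`, `blocks`,
#'   `size_cm` and the ordered 58-element `vector`.
#' @export
assemble_sample <- function(blocks, size_cm, id, label) {
  if (!setequal(names(blocks), ROI_NAMES) || length(blocks) != 3L)
    stop_renotex("blocks must be named exactly cortex, boundary, medulla",
                 class = "renotex_schema_error")
  if (!is.numeric(size_cm) || length(size_cm) != 1L || size_cm <= 0)
    stop_renotex("size_cm must be a positive scalar",
                 class = "renotex_schema_error")
  label <- match.arg(label, CLASS_LEVELS)
  blocks <- blocks[ROI_NAMES]
  for (b in blocks)
    if (length(b) != 19L || anyNA(b[GLCM_FEATURE_NAMES]))
      stop_renotex("each ROI block must carry the 19 canonical descriptors",
                   class = "renotex_schema_error")
  vec <- c(unlist(lapply(blocks, function(b) unname(b[GLCM_FEATURE_NAMES]))),
           size_cm)
  names(vec) <- feature_column_names()
  structure(list(id = id, label = label, blocks = blocks,
                 size_cm = size_cm, vector = vec),
            class = "sample_record")
}

#' Extract the fused feature table of a whole cohort
#'
#' Runs crop -> preprocess -> GLCM -> angle-average over the three ROIs of
#' every record and fuses with kidney size. Accepts either an in-memory
#' cohort (output of [generate_cohort()]) or a manifest CSV path whose
#' `image_path` entries resolve relative to the manifest directory. Any
#' failing record aborts the run with all failures listed (silent row loss
#' would corrupt class balance).
#'
#' @param cohort Cohort list or manifest CSV path.
#' @param pcfg A [preprocess_config()].
#' @param fcfg A [feature_config()].
#' @param seed Optional provenance seed recorded in the table.
#' @return A `feature_table`: data frame with `id`, `label`, the 58 feature
#'   columns, and a `provenance` attribute.
#' @export
extract_cohort_features <- function(cohort, pcfg = preprocess_config(),
                                    fcfg = feature_config(), seed = NA) {
  if (is.character(cohort)) cohort <- load_manifest_records(cohort)
  errors <- character(0)
  rows <- vector("list", length(cohort))
  for (k in seq_along(cohort)) {
    rec <- cohort[[k]]
    rows[[k]] <- tryCatch({
      if (inherits(rec$image, "missing_image"))
        stop_renotex("image file not found: %s", rec$image$path,
                     class = "renotex_io_error")
      blocks <- lapply(rec$rois, function(roi)
        extract_roi_features(rec$image, roi, pcfg, fcfg))
      names(blocks) <- vapply(rec$rois, `[[`, "", "name")
      assemble_sample(blocks, rec$size_cm, rec$id, rec$label)$vector
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<- sprintf("%s: %s", rec$id,
                                                conditionMessage(e))
      NULL
    })
  }
  if (length(errors) > 0)
    stop_renotex("feature extraction failed for %d record(s):\n%s",
                 length(errors), paste(errors, collapse = "\n"),
                 class = "renotex_extract_error")
  tab <- as.data.frame(do.call(rbind, rows))
  if (length(cohort) == 0)
    tab <- as.data.frame(matrix(numeric(0), 0, 58,
                                dimnames = list(NULL, feature_column_names())))
  tab <- cbind(data.frame(id = vapply(cohort, `[[`, "", "id"),
                          label = vapply(cohort, `[[`, "", "label"),
                          stringsAsFactors = FALSE),
               tab)
  attr(tab, "provenance") <- list(
    equalize = pcfg$equalize, range_filter = pcfg$range_filter,
    levels = pcfg$levels, window = pcfg$window,
    n_levels = fcfg$n_levels, symmetric = fcfg$symmetric,
    log_base = fcfg$log_base, dialect = fcfg$dialect,
    gray_limits = fcfg$gray_limits, distance = fcfg$distance, seed = seed)
  class(tab) <- c("feature_table", "data.frame")
  tab
}

load_manifest_records <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(k) {
    row <- man[k, ]
    path <- file.path(base, row$image_path)
    if (!file.exists(path))
      return(list(id = row$id, label = row$label,
                  image = structure(list(path = path), class = "missing_image"),
                  rois = list(), size_cm = row$size_cm, egfr = row$egfr))
    rois <- lapply(ROI_NAMES, function(nm)
      roi_spec(nm, row[[paste0("roi_", nm, "_row")]],
               row[[paste0("roi_", nm, "_col")]],
               row[[paste0("roi_", nm, "_side")]]))
    names(rois) <- ROI_NAMES
    list(id = row$id, label = row$label, image = read_gray_image(path),
         rois = rois, size_cm = row$size_cm, egfr = row$egfr)
  })
}

#' Write / read a feature table as CSV with a provenance header
#'
#' Values are serialized to 15 significant digits; provenance (preprocess
#' and feature configuration plus seed) travels in `# provenance:` comment
#' lines and is restored on read.
#'
#' @param tab A `feature_table`.
#' @param path CSV destination.
#' @return `path` invisibly (write); the restored `feature_table` (read).
#' @export
write_feature_table <- function(tab, path) {
  stopifnot(inherits(tab, "feature_table"))
  prov <- attr(tab, "provenance")
  hdr <- vapply(names(prov), function(k)
    sprintf("# provenance: %s=%s", k, as.character(prov[[k]])), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(tab)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# provenance: ", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE)
  tab <- utils::read.csv(text = paste(lines[body], collapse = "\n"),
                         stringsAsFactors = FALSE)
  expected <- c("id", "label", feature_column_names())
  missing <- setdiff(expected, names(tab))
  if (length(missing) > 0)
    stop_renotex("feature table at '%s' lacks column(s): %s", path,
                 paste(missing, collapse = ", "),
                 class = "renotex_schema_error")
  prov <- list()
  for (h in hdr) {
    kv <- sub("^# provenance: ", "", h)
    key <- sub("=.*$", "", kv)
    prov[[key]] <- utils::type.convert(sub("^[^=]*=", "", kv), as.is = TRUE)
  }
  attr(tab, "provenance") <- prov
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Feature matrix and labels of a table
#'
#' @param tab A `feature_table`.
#' @return List with `x` (numeric matrix, n x 58) and `y` (factor over the
#'   canonical class levels).
#' @export
feature_matrix <- function(tab) {
  x <- as.matrix(as.data.frame(tab)[, feature_column_names(), drop = FALSE])
  storage.mode(x) <- "double"
  list(x = x, y = factor(tab$label, levels = CLASS_LEVELS))
}
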