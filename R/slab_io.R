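#' OCTA slab container
#'
#' An `octa_slab` bundles one en-face angiography image with its plexus label
#' (superficial or deep capillary plexus) and the eye it belongs to. Pixels
#' are stored as an integer matrix of 8-bit intensities, row-major with the
#' origin at the top-left corner.
#'
#' @param pixels integer matrix, values in `[0, 255]`, both dimensions >= 32.
#' @param eye_id opaque string identifying the eye.
#' @param plexus `"SCP"` or `"DCP"`.
#' @param scan_width_mm,scan_height_mm nominal scan field, default 3 x 3 mm.
#' @return an object of class `octa_slab`.
#' @export
octa_slab <- function(pixels, eye_id, plexus = c("SCP", "DCP"),
                      scan_width_mm = 3, scan_height_mm = 3) {
  plexus <- match.arg(plexus)
  if (!is.matrix(pixels)) abort_validation("`pixels` must be a matrix")
  if (nrow(pixels) < 32 || ncol(pixels) < 32)
    abort_validation(sprintf("slab must be at least 32x32 pixels, got %dx%d",
                             nrow(pixels), ncol(pixels)))
  px <- as.vector(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255)
    abort_validation("pixel intensities must lie in [0, 255]")
  if (scan_width_mm <= 0 || scan_height_mm <= 0)
    abort_validation("scan dimensions must be positive")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, eye_id = as.character(eye_id), plexus = plexus,
         scan_width_mm = scan_width_mm, scan_height_mm = scan_height_mm),
    class = "octa_slab")
}

#' @export
print.octa_slab <- function(x, ...) {
  cat(sprintf("<octa_slab> eye %s, %s, %dx%d px, %.1fx%.1f mm\n",
              x$eye_id, x$plexus, nrow(x$pixels), ncol(x$pixels),
              x$scan_width_mm, x$scan_height_mm))
  invisible(x)
}

# Collapse an array returned by png/tiff readers to a grayscale matrix in
# [0, 1]. Multi-channel images are converted by the Rec. 709 luma weights;
# an alpha channel is ignored.
collapse_gray <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    if (nc == 2) return(arr[, , 1])                      # gray + alpha
    if (nc >= 3)
      return(0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3])
    return(arr[, , 1])
  }
  abort_io("unsupported image layout")
}

#' Read an en-face OCTA slab image
#'
#' Reads a PNG or TIFF slab (single-channel or collapsible to gray). 8-bit
#' images are taken as-is; deeper images are linearly rescaled by the image
#' maximum to the 8-bit range, preserving the histogram shape that Otsu
#' thresholding relies on.
#'
#' @param path image file (`.png`, `.tif`/`.tiff`).
#' @param plexus plexus label, `"SCP"` or `"DCP"`.
#' @param eye_id eye identifier attached to the slab.
#' @return an [octa_slab].
#' @export
read_slab <- function(path, plexus = c("SCP", "DCP"), eye_id = "unknown") {
  plexus <- match.arg(plexus)
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- tryCatch(png::readPNG(path),
                    error = function(e) abort_io(sprintf("cannot decode PNG %s: %s",
                                                         path, conditionMessage(e))))
    g <- collapse_gray(arr)            # values in [0, 1], scaled by 2^depth - 1
    # bit depth is judged on the raw channels, before any luma combination
    raw255 <- arr * 255
    if (max(abs(raw255 - round(raw255))) < 1e-6) {
      px <- round(g * 255)             # true 8-bit content
    } else {
      mx <- max(g)
      px <- if (mx > 0) round(255 * g / mx) else round(g)
    }
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                    error = function(e) abort_io(sprintf("cannot decode TIFF %s: %s",
                                                         path, conditionMessage(e))))
    g <- collapse_gray(arr)
    mx <- max(g)
    px <- if (mx <= 255) g else round(255 * g / mx)
  } else {
    abort_io(sprintf("unsupported image extension '%s'", ext))
  }
  px <- matrix(as.integer(px), nrow = nrow(g), ncol = ncol(g))
  octa_slab(px, eye_id = eye_id, plexus = plexus)
}

#' Write a binary mask as an 8-bit PNG
#'
#' True pixels are written as 255, false as 0.
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (!is.logical(mask) || !is.matrix(mask))
    abort_validation("`mask` must be a logical matrix")
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask written by [write_mask_png()]
#' @param path PNG file with values {0, 255}.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  collapse_gray(png::readPNG(path)) >= 0.5
}

eye_table_columns <- c("eye_id", "npa_quadrants", "bcva_letters", "cmt_um",
                       "age_years", "sex", "diabetes_type")

#' Read the per-eye clinical metadata table
#'
#' The table carries, per eye, the fluorescein-angiography-derived count of
#' peripheral quadrants showing non-perfusion areas (0-4) together with the
#' clinical covariates. The perfusion group is derived: an eye is `NPA` iff
#' at least one quadrant is affected, otherwise `WELL_PERFUSED`.
#'
#' @param path CSV file with columns `eye_id`, `npa_quadrants`,
#'   `bcva_letters`, `cmt_um`, `age_years`, `sex`, `diabetes_type`.
#' @return a data.frame with one row per eye, row order preserved, plus the
#'   derived `group` column.
#' @export
read_eye_table <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(eye_table_columns, names(df))
  if (length(missing))
    abort_schema(sprintf("eye table is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  validate_eye_table(df)
}

#' Validate an in-memory eye table and derive the perfusion group
#' @param df data.frame with the eye-table columns.
#' @return the validated data.frame with a `group` column.
#' @export
validate_eye_table <- function(df) {
  bad <- which(!(df$npa_quadrants %in% 0:4))
  if (length(bad))
    abort_validation(sprintf("npa_quadrants outside 0-4 at row(s): %s",
                             paste(bad, collapse = ", ")))
  if (anyDuplicated(df$eye_id))
    abort_validation("duplicate eye_id values in eye table")
  if (any(df$cmt_um <= 0)) abort_validation("cmt_um must be positive")
  if (!all(df$sex %in% c("M", "F"))) abort_validation("sex must be 'M' or 'F'")
  if (!all(df$diabetes_type %in% c("T1", "T2")))
    abort_validation("diabetes_type must be 'T1' or 'T2'")
  df$group <- ifelse(df$npa_quadrants >= 1, "NPA", "WELL_PERFUSED")
  df
}

#' Write the per-eye fractal feature table
#'
#' Rows are ordered by `eye_id` and, within an eye, SCP before DCP, so that
#' the written bytes depend only on the content and never on filesystem
#' enumeration order.
#'
#' @param features data.frame with columns `eye_id`, `plexus`, `fd`, `lac`,
#'   `fit_r2`, `n_box_sizes`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  cols <- c("eye_id", "plexus", "fd", "lac", "fit_r2", "n_box_sizes")
  missing <- setdiff(cols, names(features))
  if (length(missing))
    abort_schema(sprintf("feature table missing column(s): %s",
                         paste(missing, collapse = ", ")))
  features <- features[, cols, drop = FALSE]
  if (nrow(features)) {
    ord <- order(features$eye_id, match(features$plexus, c("SCP", "DCP")))
    features <- features[ord, , drop = FALSE]
  }
  # 15 significant digits: round-trips doubles well beyond the 12-digit contract
  for (col in c("fd", "lac", "fit_r2"))
    features[[col]] <- formatC(features[[col]], digits = 15, format = "g")
  write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame with numeric `fd`, `lac`, `fit_r2`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a cohort to the on-disk layout
#'
#' The layout is one folder per eye holding `<eye_id>_SCP.png` and
#' `<eye_id>_DCP.png`, with a single `eyes.csv` metadata table at the root.
#'
#' @param eyes eye table (see [read_eye_table()] for columns).
#' @param slabs named list: `slabs[[eye_id]]` is a list with elements `SCP`
#'   and `DCP`, each an [octa_slab].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(eyes, slabs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- eyes[, setdiff(names(eyes), "group"), drop = FALSE]
  write.csv(out, file.path(dir, "eyes.csv"), row.names = FALSE, quote = FALSE)
  for (id in eyes$eye_id) {
    edir <- file.path(dir, id)
    dir.create(edir, showWarnings = FALSE)
    for (plx in c("SCP", "DCP")) {
      slab <- slabs[[id]][[plx]]
      if (is.null(slab)) abort_validation(sprintf("missing %s slab for eye %s", plx, id))
      png::writePNG(slab$pixels / 255, file.path(edir, sprintf("%s_%s.png", id, plx)))
    }
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `eyes.csv` and one folder per eye.
#' @param plexuses which plexus slabs to load.
#' @return list with `eyes` (data.frame) and `slabs` (named list keyed by
#'   eye_id, each holding the requested plexus slabs).
#' @export
read_cohort <- function(dir, plexuses = c("SCP", "DCP")) {
  eyes <- read_eye_table(file.path(dir, "eyes.csv"))
  slabs <- list()
  missing <- character()
  for (id in eyes$eye_id) {
    slabs[[id]] <- list()
    for (plx in plexuses) {
      p <- file.path(dir, id, sprintf("%s_%s.png", id, plx))
      if (!file.exists(p)) { missing <- c(missing, sprintf("%s (%s)", id, plx)); next }
      slabs[[id]][[plx]] <- read_slab(p, plexus = plx, eye_id = id)
    }
  }
  if (length(missing))
    abort_io(sprintf("missing slab image(s) for: %s", paste(missing, collapse = ", ")))
  list(eyes = eyes, slabs = slabs)
}
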