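#' Otsu's threshold over the 256-bin intensity histogram
#'
#' Returns the threshold `t` that maximises the between-class variance of the
#' foreground/background split at `t` (background: intensity <= t). Ties are
#' broken towards the smallest `t` so the result is fully deterministic.
#'
#' @param pixels integer matrix of 8-bit intensities.
#' @return integer threshold in `[0, 254]`.
#' @export
otsu_threshold <- function(pixels) {
  v <- as.integer(pixels)
  if (anyNA(v) || min(v) < 0 || max(v) > 255)
    abort_validation("intensities must be integers in [0, 255]")
  if (min(v) == max(v))
    abort_degenerate("constant image: Otsu threshold undefined")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                 # P(class <= t), t = 0..255
  mu <- cumsum(p * (0:255))          # first moment up to t
  mu_t <- mu[256]
  # between-class variance for t = 0..254 (a split at 255 has no foreground)
  w0 <- omega[1:255]
  m0 <- mu[1:255]
  sigma_b <- (mu_t * w0 - m0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  as.integer(which.max(sigma_b) - 1L)
}

#' Disk-neighbourhood median filter
#'
#' Replaces each pixel by the median over the disk of the given radius
#' (offsets with `dx^2 + dy^2 <= radius^2`; 13 pixels for radius 2, the
#' speckle-suppression setting used before thresholding). Borders are handled
#' by edge replication so the local histogram is not diluted with zeros.
#'
#' @param pixels numeric or integer matrix.
#' @param radius_px neighbourhood radius in pixels, >= 1.
#' @return matrix of the same shape and integer mode if the input was integer.
#' @export
median_filter <- function(pixels, radius_px = 2) {
  if (radius_px < 1) abort_validation("radius_px must be >= 1")
  out <- .cpp_disk_median(matrix(as.numeric(pixels), nrow(pixels), ncol(pixels)),
                          as.integer(radius_px))
  if (is.integer(pixels)) {
    out <- matrix(as.integer(round(out)), nrow(out), ncol(out))
  }
  out
}

#' Binarize a slab into a vessel mask
#'
#' Applies the radius-2 disk median filter, computes Otsu's threshold `t` on
#' the filtered image and takes strictly-above-threshold pixels as vessel
#' (`filtered >= t + 1`). With `filter_order = "post"` the threshold is
#' computed on the raw image and the median filter is applied to the binary
#' mask instead.
#'
#' @param slab an [octa_slab].
#' @param filter_order `"pre"` (filter, then threshold; default) or `"post"`.
#' @param radius_px median-filter radius, default 2.
#' @return a `binary_map`: list with `mask` (logical matrix),
#'   `otsu_threshold`, `source_eye`, `plexus`.
#' @export
binarize <- function(slab, filter_order = c("pre", "post"), radius_px = 2) {
  filter_order <- match.arg(filter_order)
  if (!inherits(slab, "octa_slab")) abort_validation("`slab` must be an octa_slab")
  if (filter_order == "pre") {
    filtered <- median_filter(slab$pixels, radius_px)
    t <- otsu_threshold(filtered)
    mask <- filtered >= t + 1L
  } else {
    t <- otsu_threshold(slab$pixels)
    mask0 <- slab$pixels >= t + 1L
    filt <- median_filter(matrix(as.integer(mask0), nrow(mask0), ncol(mask0)), radius_px)
    mask <- filt >= 1L
  }
  if (!any(mask))
    abort_empty_mask("binarization produced an empty vessel mask")
  structure(list(mask = mask, otsu_threshold = t,
                 source_eye = slab$eye_id, plexus = slab$plexus),
            class = "binary_map")
}

#' Thin a vessel mask to a one-pixel-wide skeleton
#'
#' Iterative Zhang-Suen morphological thinning with 8-connected foreground.
#' Thinning only removes pixels, so the skeleton is always contained in the
#' input mask; iteration runs to a fixed point, which makes the operation
#' idempotent. If thinning annihilates a blob entirely (possible for small
#' compact components), the first foreground pixel of the input is retained
#' so a non-empty mask always yields a non-empty skeleton.
#'
#' @param binary a `binary_map` from [binarize()], or a logical matrix.
#' @return a `skeleton_map`: list with `skeleton` (logical matrix) and
#'   `n_pixels`.
#' @export
skeletonize <- function(binary) {
  mask <- if (inherits(binary, "binary_map")) binary$mask else binary
  if (!is.logical(mask) || !is.matrix(mask))
    abort_validation("input must be a binary_map or logical matrix")
  if (!any(mask)) abort_empty_mask("cannot skeletonize an empty mask")
  skel <- .cpp_thin(mask)
  if (!any(skel)) {
    idx <- which(mask)[1]
    skel[idx] <- TRUE
  }
  structure(list(skeleton = skel, n_pixels = sum(skel)), class = "skeleton_map")
}

#' @export
print.skeleton_map <- function(x, ...) {
  cat(sprintf("<skeleton_map> %dx%d, %d skeleton pixels\n",
              nrow(x$skeleton), ncol(x$skeleton), x$n_pixels))
  invisible(x)
}
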