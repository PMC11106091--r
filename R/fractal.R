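#' Default dyadic box-size ladder
#'
#' Powers of 2 from 2 up to `floor(min(H, W) / 4)`, giving at least four
#' points for the log-log fit on images of 256 px and larger.
#'
#' @param dims image dimensions `c(H, W)`.
#' @return integer vector of box sizes.
#' @export
default_box_sizes <- function(dims) {
  top <- floor(min(dims) / 4)
  if (top < 2) abort_validation("image too small for the default box-size ladder")
  2^(1:floor(log2(top)))
}

# Deterministic grid offsets for one box size: the first n points, in
# row-major order, of a k x k lattice over [0, eps)^2 with k = ceiling
# (sqrt(n)). Always includes (0, 0). For n = 4 these are the corners of a
# 2 x 2 lattice: (0,0), (0,floor(eps/2)), (floor(eps/2),0), (floor(eps/2),
# floor(eps/2)).
box_origins <- function(eps, n_origins) {
  k <- ceiling(sqrt(n_origins))
  steps <- floor((0:(k - 1)) * eps / k)
  grid <- expand.grid(ox = steps, oy = steps)[, c("oy", "ox")]
  as.matrix(grid[seq_len(n_origins), , drop = FALSE])
}

#' Multi-origin box counting
#'
#' For each box size `eps`, the image is divided into an `eps x eps` grid
#' whose origin is shifted to each of `n_origins` deterministic offsets in
#' `[0, eps)^2` (offset `(0,0)` always included); the number of boxes
#' containing at least one skeleton pixel is counted for each offset, partial
#' boxes at the image edges included, and the mean count across origins is
#' retained.
#'
#' @param skeleton a `skeleton_map` from [skeletonize()] or a logical matrix.
#' @param box_sizes integer box sizes; default dyadic ladder.
#' @param n_origins number of grid origins per size, default 4.
#' @return a `box_count_curve`: data.frame with `box_size`, `mean_count`,
#'   plus attributes `per_origin` (matrix of counts) and `n_origins`.
#' @export
box_count <- function(skeleton, box_sizes = NULL, n_origins = 4) {
  skel <- if (inherits(skeleton, "skeleton_map")) skeleton$skeleton else skeleton
  if (!is.logical(skel) || !is.matrix(skel))
    abort_validation("`skeleton` must be a skeleton_map or logical matrix")
  if (!any(skel)) abort_empty_mask("cannot box-count an empty skeleton")
  if (n_origins < 1) abort_validation("n_origins must be >= 1")
  if (is.null(box_sizes)) box_sizes <- default_box_sizes(dim(skel))
  box_sizes <- as.integer(box_sizes)
  if (any(box_sizes < 1)) abort_validation("box sizes must be positive")
  if (is.unsorted(box_sizes, strictly = TRUE))
    abort_validation("box sizes must be strictly increasing")
  if (max(box_sizes) > min(dim(skel)))
    abort_validation("box size exceeds image dimensions")
  per_origin <- matrix(NA_real_, length(box_sizes), n_origins)
  for (s in seq_along(box_sizes)) {
    eps <- box_sizes[s]
    orig <- box_origins(eps, n_origins)
    for (o in seq_len(n_origins)) {
      per_origin[s, o] <- .cpp_box_count_one(skel, eps, orig[o, 1], orig[o, 2])
    }
  }
  curve <- data.frame(box_size = box_sizes, mean_count = rowMeans(per_origin))
  structure(curve, per_origin = per_origin, n_origins = n_origins,
            class = c("box_count_curve", "data.frame"))
}

#' Fit the fractal dimension from a box-count curve
#'
#' Ordinary least-squares fit of `log N(eps)` against `log(1 / eps)`; the
#' slope is the box-counting fractal dimension, bounded by 2 for a planar
#' image. The slope is clamped to `[0, 2]`; the raw pre-clamp value and the
#' coefficient of determination of the fit are returned alongside.
#'
#' @param curve a `box_count_curve` (or data.frame with `box_size`,
#'   `mean_count`) of at least 3 sizes.
#' @return list with `fd`, `fd_raw`, `fit_r2`.
#' @export
fit_fd <- function(curve) {
  if (nrow(curve) < 3) abort_validation("need at least 3 box sizes to fit FD")
  if (any(curve$mean_count <= 0)) abort_validation("box counts must be positive")
  x <- log(1 / curve$box_size)
  y <- log(curve$mean_count)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(fd = min(max(slope, 0), 2), fd_raw = slope, fit_r2 = r2)
}

#' Gliding-box lacunarity curve
#'
#' For each window size `r`, an `r x r` window glides with step 1 over all
#' fully contained positions; with `M` the skeleton-pixel mass per window,
#' the lacunarity is the normalised second moment
#' `Lambda(r) = <M^2> / <M>^2 = 1 + CV^2`. Sizes whose windows hold no mass
#' at all are skipped (`Lambda` undefined there).
#'
#' @param skeleton a `skeleton_map` or logical matrix.
#' @param box_sizes window sizes; default dyadic ladder.
#' @return data.frame with `box_size`, `lambda`, `mean_mass`, `n_windows`.
#' @export
gliding_box_lacunarity <- function(skeleton, box_sizes = NULL) {
  skel <- if (inherits(skeleton, "skeleton_map")) skeleton$skeleton else skeleton
  if (!is.logical(skel) || !is.matrix(skel))
    abort_validation("`skeleton` must be a skeleton_map or logical matrix")
  if (!any(skel)) abort_empty_mask("cannot compute lacunarity of an empty skeleton")
  if (is.null(box_sizes)) box_sizes <- default_box_sizes(dim(skel))
  box_sizes <- as.integer(box_sizes)
  if (any(box_sizes < 1) || max(box_sizes) > min(dim(skel)))
    abort_validation("window sizes must be positive and fit inside the image")
  m <- .cpp_gliding_box(skel, box_sizes)
  keep <- m[, 2] > 0 & m[, 3] > 0            # windows exist and carry mass
  if (!any(keep)) abort_degenerate("no window size carries any skeleton mass")
  data.frame(box_size = m[keep, 1],
             lambda = m[keep, 4] / m[keep, 3]^2,
             mean_mass = m[keep, 3],
             n_windows = m[keep, 2])
}

#' Summarise a lacunarity curve into a single scalar
#'
#' The per-size values are mapped to `1 - 1 / Lambda(r)` (0 for a perfectly
#' homogeneous texture, approaching 1 for extreme gappiness) and averaged
#' over sizes, giving a scale-aggregated lacunarity in `[0, 1)`.
#'
#' @param lac_curve data.frame from [gliding_box_lacunarity()].
#' @param normalization `"normalized"` (default), `"raw"` (mean Lambda), or
#'   `"cv2"` (mean Lambda - 1).
#' @return scalar lacunarity summary.
#' @export
summarize_lac <- function(lac_curve, normalization = c("normalized", "raw", "cv2")) {
  normalization <- match.arg(normalization)
  if (!nrow(lac_curve)) abort_validation("empty lacunarity curve")
  switch(normalization,
         normalized = mean(1 - 1 / lac_curve$lambda),
         raw = mean(lac_curve$lambda),
         cv2 = mean(lac_curve$lambda - 1))
}

#' Full fractal analysis of one slab
#'
#' Composes the pipeline: median filter + Otsu binarization, Zhang-Suen
#' skeletonization, multi-origin box counting with a log-log fit for the
#' fractal dimension, and gliding-box lacunarity on the same skeleton. Any
#' stage error is re-signalled with the failing stage named.
#'
#' @param slab an [octa_slab].
#' @param config a [run_config()] list controlling filter order, radius, box
#'   sizes, origins and lacunarity normalization.
#' @return a `fractal_result`: list with `fd`, `fd_raw`, `lac`, `fit_r2`,
#'   `curve`, `lac_curve`, `otsu_threshold`, `n_skeleton_px`, `eye_id`,
#'   `plexus`.
#' @export
analyze_slab <- function(slab, config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, octa_error = function(e) {
      octa_abort(sprintf("[stage %s] %s", name, conditionMessage(e)),
                 class(e)[1])
    })
  }
  bm <- stage("binarize", binarize(slab, filter_order = config$filter_order,
                                   radius_px = config$median_radius_px))
  sk <- stage("skeletonize", skeletonize(bm))
  sizes <- if (identical(config$box_sizes, "auto"))
    default_box_sizes(dim(sk$skeleton)) else as.integer(config$box_sizes)
  curve <- stage("box_count", box_count(sk, sizes, config$n_origins))
  fit <- stage("fit_fd", fit_fd(curve))
  lacc <- stage("lacunarity", gliding_box_lacunarity(sk, sizes))
  lac <- summarize_lac(lacc, config$lac_normalization)
  structure(list(fd = fit$fd, fd_raw = fit$fd_raw, fit_r2 = fit$fit_r2,
                 lac = lac, curve = curve, lac_curve = lacc,
                 otsu_threshold = bm$otsu_threshold,
                 n_skeleton_px = sk$n_pixels,
                 eye_id = slab$eye_id, plexus = slab$plexus),
            class = "fractal_result")
}

#' @export
print.fractal_result <- function(x, ...) {
  cat(sprintf("<fractal_result> eye %s %s: FD = %.4f (R2 = %.4f), LAC = %.4f\n",
              x$eye_id, x$plexus, x$fd, x$fit_r2, x$lac))
  invisible(x)
}
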