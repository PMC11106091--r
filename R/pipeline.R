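#' Pipeline configuration
#'
#' One object holding every switch the pipeline exposes; it serialises to a
#' single JSON document and unknown keys are rejected on the way back in.
#'
#' @param filter_order median filter before (`"pre"`, default) or after
#'   (`"post"`) Otsu thresholding.
#' @param median_radius_px disk radius of the median filter.
#' @param box_sizes `"auto"` (dyadic ladder) or an integer vector.
#' @param n_origins grid origins per box size.
#' @param lac_normalization `"normalized"`, `"raw"` or `"cv2"`.
#' @param ttest `"welch"` or `"student"`.
#' @param extent_coding `"quadrants"` or `"binary"`.
#' @param seed integer seed for any synthesis step.
#' @param log_level `"info"` or `"quiet"`.
#' @return a `run_config` list.
#' @export
run_config <- function(filter_order = "pre", median_radius_px = 2,
                       box_sizes = "auto", n_origins = 4,
                       lac_normalization = "normalized", ttest = "welch",
                       extent_coding = "quadrants", seed = 1,
                       log_level = "info") {
  cfg <- list(filter_order = filter_order, median_radius_px = median_radius_px,
              box_sizes = box_sizes, n_origins = n_origins,
              lac_normalization = lac_normalization, ttest = ttest,
              extent_coding = extent_coding, seed = seed, log_level = log_level)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  allowed <- names(formals(run_config))
  extra <- setdiff(names(cfg), allowed)
  if (length(extra))
    abort_validation(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  missing <- setdiff(allowed, names(cfg))
  if (length(missing))
    abort_validation(sprintf("missing config key(s): %s", paste(missing, collapse = ", ")))
  if (!cfg$filter_order %in% c("pre", "post")) abort_validation("bad filter_order")
  if (!cfg$lac_normalization %in% c("normalized", "raw", "cv2"))
    abort_validation("bad lac_normalization")
  if (!cfg$ttest %in% c("welch", "student")) abort_validation("bad ttest")
  if (!cfg$extent_coding %in% c("quadrants", "binary")) abort_validation("bad extent_coding")
  if (!identical(cfg$box_sizes, "auto") && any(cfg$box_sizes < 1))
    abort_validation("bad box_sizes")
  if (cfg$median_radius_px < 1 || cfg$n_origins < 1)
    abort_validation("median_radius_px and n_origins must be >= 1")
  structure(cfg, class = "run_config")
}

#' Write a config to JSON / read it back
#' @param cfg a [run_config()].
#' @param path JSON file path.
#' @return `path` invisibly / the validated `run_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

# Stable 64-bit-ish FNV-1a hash of a string, reported as hex; used to
# fingerprint the config in the run manifest.
fnv1a_hex <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

pipe_log <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(fmt, ...))
}

#' Compute fractal features for every slab of a cohort
#'
#' @param cohort list with `eyes` and `slabs` as returned by
#'   [generate_cohort()] or [read_cohort()].
#' @param config a [run_config()].
#' @param plexuses which plexuses to analyze.
#' @return data.frame with one row per eye and plexus: `eye_id`, `plexus`,
#'   `fd`, `lac`, `fit_r2`, `n_box_sizes`.
#' @export
cohort_features <- function(cohort, config = run_config(),
                            plexuses = c("SCP", "DCP")) {
  rows <- list()
  for (id in cohort$eyes$eye_id) {
    for (plx in plexuses) {
      slab <- cohort$slabs[[id]][[plx]]
      if (is.null(slab))
        abort_validation(sprintf("missing %s slab for eye %s", plx, id))
      res <- analyze_slab(slab, config)
      rows[[length(rows) + 1]] <- data.frame(
        eye_id = id, plexus = plx, fd = res$fd, lac = res$lac,
        fit_r2 = res$fit_r2, n_box_sizes = nrow(res$curve),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full pipeline over a cohort directory
#'
#' Reads the on-disk cohort layout, computes fractal features for every slab,
#' runs the cohort statistics and writes `features.csv`, `summary.csv`,
#' `correlations.csv`, `report.json` and a run manifest (`manifest.json`,
#' holding the config, its hash, package version and per-stage timings) under
#' `out_dir`. Outputs are deterministic for a fixed config and input.
#'
#' @param config a [run_config()].
#' @param in_dir cohort directory in the layout of [write_cohort()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the result paths and the `cohort_summary`.
#' @export
run_pipeline <- function(config = run_config(), in_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  cohort <- read_cohort(in_dir)
  timings["read"] <- tic() - t0
  pipe_log(config, "read %d eyes from %s", nrow(cohort$eyes), in_dir)

  t0 <- tic()
  features <- cohort_features(cohort, config)
  timings["fractal"] <- tic() - t0
  fpath <- file.path(out_dir, "features.csv")
  write_feature_table(features, fpath)
  pipe_log(config, "fractal features for %d slabs", nrow(features))

  t0 <- tic()
  summ <- run_cohort_analysis(cohort$eyes, features,
                              ttest = config$ttest,
                              extent_coding = config$extent_coding)
  timings["stats"] <- tic() - t0
  spath <- file.path(out_dir, "summary.csv")
  write.csv(summ$summary, spath, row.names = FALSE)
  cpath <- file.path(out_dir, "correlations.csv")
  write.csv(summ$correlations, cpath, row.names = FALSE)
  rpath <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(n_eyes = summ$n_eyes, n_npa = summ$n_npa,
                            n_well_perfused = summ$n_well_perfused,
                            summary = summ$summary,
                            correlations = summ$correlations),
                       rpath, auto_unbox = TRUE, digits = NA, dataframe = "rows")

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  manifest <- list(config = unclass(config),
                   config_hash = fnv1a_hex(as.character(cfg_json)),
                   package_version = as.character(packageVersion("octafractal")),
                   in_dir = in_dir,
                   stage_seconds = as.list(round(timings, 3)))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(list(features = fpath, summary = spath, correlations = cpath,
                 report = rpath, manifest = mpath, cohort_summary = summ))
}
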