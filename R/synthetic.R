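# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Single draw per element from a normal truncated to [lo, hi] via the
# inverse-CDF transform (deterministic in the number of uniforms consumed).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Analytic binary fixtures with known fractal dimension
#'
#' Deterministic bitmaps used to validate the box-counting and lacunarity
#' estimators against closed forms: a filled square (FD 2), a one-pixel line
#' (FD 1), a single pixel (FD 0), the Sierpinski carpet (FD log 8 / log 3)
#' and seeded random dust.
#'
#' @param kind one of `"FILLED"`, `"LINE"`, `"SINGLE_PIXEL"`,
#'   `"SIERPINSKI_CARPET"`, `"RANDOM_DUST"`.
#' @param size_px image side in pixels; for the carpet this must equal
#'   `3^level` (and defaults to it).
#' @param level carpet recursion depth (center ninth removed at each level).
#' @param density foreground fraction for `RANDOM_DUST`.
#' @param seed RNG seed for `RANDOM_DUST`.
#' @return logical matrix `size_px x size_px`.
#' @export
make_fixture <- function(kind = c("FILLED", "LINE", "SINGLE_PIXEL",
                                  "SIERPINSKI_CARPET", "RANDOM_DUST"),
                         size_px = NULL, level = NULL, density = 0.1, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "SIERPINSKI_CARPET") {
    if (is.null(level)) abort_validation("carpet fixture needs `level`")
    if (is.null(size_px)) size_px <- 3^level
    if (size_px != 3^level)
      abort_validation(sprintf("carpet size must be 3^level = %d, got %d",
                               3^level, size_px))
  }
  if (is.null(size_px) || size_px < 1) abort_validation("`size_px` must be positive")
  switch(kind,
    FILLED = matrix(TRUE, size_px, size_px),
    SINGLE_PIXEL = {
      m <- matrix(FALSE, size_px, size_px)
      m[ceiling(size_px / 2), ceiling(size_px / 2)] <- TRUE
      m
    },
    LINE = {
      m <- matrix(FALSE, size_px, size_px)
      m[ceiling(size_px / 2), ] <- TRUE
      m
    },
    SIERPINSKI_CARPET = {
      idx <- 0:(size_px - 1)
      bad <- matrix(FALSE, size_px, size_px)
      for (k in 0:(level - 1)) {
        mid <- (idx %/% 3^k) %% 3 == 1
        bad <- bad | outer(mid, mid, "&")
      }
      !bad
    },
    RANDOM_DUST = with_local_seed(seed, {
      matrix(runif(size_px^2) < density, size_px, size_px)
    }))
}

#' Committed generator calibration
#'
#' Fixed constants controlling the synthetic plexus texture and the
#' dropout-vs-quadrant mapping, together with the clinical covariate
#' distributions of the emulated cohort (group means and SDs for age, BCVA
#' and CMT). The texture and dropout constants were derived once by a grid
#' search against this package's own fractal pipeline so that default
#' cohorts land on the target group statistics (superficial plexus FD near
#' 1.92 in well-perfused eyes and near 1.21 in eyes with peripheral
#' non-perfusion, with lacunarity near 0.31 and 0.39); they are versioned
#' numbers, not knobs re-fit at run time.
#'
#' @return named list of calibration constants.
#' @export
octa_calibration <- function() {
  list(
    # capillary lattice: carrier period (px) and vessel-area fraction
    scp = list(density = 0.58, wavelength_px = 5),
    dcp = list(density = 0.60, wavelength_px = 5),
    # seeded band-limited displacement that bends the lattice: harmonic
    # periods and amplitudes, in pixels (the capillary scale is set by the
    # device sampling, not by the crop size)
    warp_periods_px = c(37, 13, 7),
    warp_amps_px = c(6, 4, 2),
    # ischemia model: dropout fraction per affected peripheral quadrant
    dropout_per_quadrant = 0.22,
    dropout_jitter_sd = 0.05,
    dropout_min = 0.02,
    dropout_max = 0.95,
    # dropout patch semi-axes as fractions of the image side
    patch_frac = c(1 / 32, 1 / 14),
    faz_radius_frac = 0.10,      # foveal avascular zone, fraction of image side
    render = list(fg = 180, bg = 40, noise_sd = 10, salt_frac = 0.001),
    covariates = list(
      NPA = list(age = c(63.80, 10.51), bcva = c(61.83, 12.23), cmt = c(442.13, 115.75)),
      WELL_PERFUSED = list(age = c(70.40, 9.84), bcva = c(64.70, 12.64), cmt = c(420.28, 106.02))),
    males = list(NPA = 16, WELL_PERFUSED = 11),
    t1_fraction = 0.48
  )
}

#' Generate one synthetic capillary-plexus slab
#'
#' Emulates an en-face OCTA slab. The healthy texture is a dense
#' capillary-like lattice: a stripe carrier of period `wavelength_px` whose
#' phase is modulated row-wise by a seeded band-limited displacement (a sum
#' of harmonics with random phases), bending the vessels into wavy,
#' quasi-parallel capillaries with uniform coverage. The vessel-area
#' fraction is set by `density` (the carrier duty cycle). A central disk is
#' cleared as the foveal avascular zone; `dropout` then clears randomly
#' placed elliptical patches (ischemic capillary loss) until that fraction
#' of the vessel area is removed. The binary pattern is rendered to 8-bit
#' grayscale with additive Gaussian noise and sparse bright speckle.
#'
#' @param density target vessel-area fraction in `(0, 1]`.
#' @param dropout fraction of vessel area removed by ischemic patches, `[0, 1)`.
#' @param faz_radius_frac radius of the cleared central disk as a fraction of
#'   the image side.
#' @param size_px image side in pixels.
#' @param seed integer seed; the full pixel array is reproducible from it.
#' @param wavelength_px lattice carrier period in pixels.
#' @param calib calibration constants, see [octa_calibration()].
#' @param eye_id,plexus labels attached to the returned slab.
#' @return an [octa_slab].
#' @export
generate_plexus <- function(density = octa_calibration()$scp$density,
                            dropout = 0,
                            faz_radius_frac = octa_calibration()$faz_radius_frac,
                            size_px = 256, seed = 1,
                            wavelength_px = octa_calibration()$scp$wavelength_px,
                            calib = octa_calibration(),
                            eye_id = "synthetic", plexus = "SCP") {
  if (density <= 0 || density > 1) abort_validation("density must be in (0, 1]")
  if (dropout < 0 || dropout >= 1) abort_validation("dropout must be in [0, 1)")
  if (faz_radius_frac < 0 || faz_radius_frac > 0.45)
    abort_validation("faz_radius_frac must be in [0, 0.45]")
  if (size_px < 32) abort_validation("size_px must be >= 32")
  n <- as.integer(size_px)
  with_local_seed(derive_seed(seed, 101L), {
    # phase-modulated lattice: displacement is a function of the row index
    y <- seq_len(n)
    periods <- calib$warp_periods_px
    amps <- calib$warp_amps_px
    phases <- runif(length(periods), 0, 2 * pi)
    D <- rep(0, n)
    for (h in seq_along(periods))
      D <- D + amps[h] * sin(2 * pi * y / periods[h] + phases[h])
    xg <- matrix(rep(seq_len(n), each = n), n, n)  # column index
    mask <- ((xg + matrix(rep(D, n), n, n)) %% wavelength_px) <
      wavelength_px * density
    # foveal avascular zone
    ctr <- (n + 1) / 2
    d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
    mask[d2 <= (faz_radius_frac * n)^2] <- FALSE
    # ischemic dropout: elliptical patches cleared until the target vessel
    # fraction is removed
    if (dropout > 0) {
      initial <- sum(mask)
      target <- dropout * initial
      cleared <- 0
      it <- 0
      while (cleared < target && it < 2000) {
        it <- it + 1
        cy <- runif(1, 1, n); cx <- runif(1, 1, n)
        a <- runif(1, n * calib$patch_frac[1], n * calib$patch_frac[2])
        b <- runif(1, n * calib$patch_frac[1], n * calib$patch_frac[2])
        th <- runif(1, 0, pi)
        # work only inside the patch bounding box
        rmax <- max(a, b)
        ri <- max(1, floor(cy - rmax)):min(n, ceiling(cy + rmax))
        ci <- max(1, floor(cx - rmax)):min(n, ceiling(cx + rmax))
        cc <- matrix(rep(ci, each = length(ri)), length(ri))
        rr <- matrix(rep(ri, length(ci)), length(ri))
        u <- (cc - cx) * cos(th) + (rr - cy) * sin(th)
        v <- -(cc - cx) * sin(th) + (rr - cy) * cos(th)
        ell <- (u / a)^2 + (v / b)^2 <= 1
        sub <- mask[ri, ci, drop = FALSE]
        hit <- sub & ell
        cleared <- cleared + sum(hit)
        sub[hit] <- FALSE
        mask[ri, ci] <- sub
      }
    }
    # render to 8-bit grayscale with mild speckle
    r <- calib$render
    img <- ifelse(mask, r$fg, r$bg) + rnorm(n * n, 0, r$noise_sd)
    salt <- runif(n * n) < r$salt_frac
    img[salt] <- 255
    px <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), n, n)
    octa_slab(px, eye_id = eye_id, plexus = plexus)
  })
}

#' Cohort specification
#'
#' Defaults encode the emulated study composition: 50 eyes, 60% with
#' peripheral non-perfusion areas, and among those 6/4/9/11 eyes with
#' 1/2/3/4 affected quadrants.
#'
#' @param n_eyes cohort size.
#' @param npa_fraction fraction of eyes with at least one affected quadrant.
#' @param quadrant_distribution counts of NPA eyes with 1, 2, 3, 4 affected
#'   quadrants; must sum to `round(n_eyes * npa_fraction)`.
#' @param image_size_px slab side length in pixels.
#' @param seed cohort seed; every image and covariate derives from it.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_eyes = 50, npa_fraction = 0.60,
                        quadrant_distribution = c(6, 4, 9, 11),
                        image_size_px = 256, seed = 1) {
  n_npa <- round(n_eyes * npa_fraction)
  if (length(quadrant_distribution) != 4 || any(quadrant_distribution < 0))
    abort_validation("quadrant_distribution must be 4 non-negative counts")
  if (sum(quadrant_distribution) != n_npa)
    abort_validation(sprintf(
      "quadrant_distribution sums to %d but n_eyes x npa_fraction = %d",
      sum(quadrant_distribution), n_npa))
  if (n_npa > n_eyes) abort_validation("npa_fraction out of range")
  structure(list(n_eyes = n_eyes, npa_fraction = npa_fraction,
                 quadrant_distribution = quadrant_distribution,
                 image_size_px = image_size_px, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic DME cohort
#'
#' Emits `n_eyes` eye records with the specified non-perfusion composition
#' plus one SCP and one DCP slab per eye. Per-eye ischemic dropout is
#' `dropout_per_quadrant x npa_quadrants` plus seeded jitter (well-perfused
#' eyes have none), so fractal dimension falls and lacunarity rises with
#' non-perfusion extent by construction. Clinical covariates are drawn from
#' group-specific truncated normals (BCVA 0-100 letters, CMT 150-900 um,
#' age 30-95 y). All randomness derives from `spec$seed` via
#' [derive_seed()].
#'
#' @param spec a [cohort_spec()].
#' @param calib calibration constants, see [octa_calibration()].
#' @param dir optional directory; if given, the cohort is written in the
#'   on-disk layout (`eyes.csv` plus one folder per eye).
#' @return list with `eyes` (data.frame incl. derived `group`) and `slabs`
#'   (named list: `slabs[[eye_id]]$SCP` / `$DCP`).
#' @export
generate_cohort <- function(spec = cohort_spec(), calib = octa_calibration(),
                            dir = NULL) {
  if (!inherits(spec, "cohort_spec")) abort_validation("`spec` must be a cohort_spec")
  qd <- spec$quadrant_distribution
  n_npa <- sum(qd)
  n_wp <- spec$n_eyes - n_npa
  quadrants <- c(rep(0L, n_wp), rep(1L:4L, times = qd))
  ids <- sprintf("eye_%03d", seq_len(spec$n_eyes))
  group <- ifelse(quadrants >= 1, "NPA", "WELL_PERFUSED")

  # deterministic sex assignment reproducing the group compositions
  sex <- character(spec$n_eyes)
  for (g in c("NPA", "WELL_PERFUSED")) {
    idx <- which(group == g)
    nm <- calib$males[[g]]
    if (nm > length(idx)) nm <- length(idx)
    sex[idx] <- c(rep("M", nm), rep("F", length(idx) - nm))
  }

  eyes <- with_local_seed(derive_seed(spec$seed, 7L), {
    age <- bcva <- cmt <- numeric(spec$n_eyes)
    for (g in c("NPA", "WELL_PERFUSED")) {
      idx <- which(group == g)
      cv <- calib$covariates[[g]]
      age[idx] <- rtrunc_norm(length(idx), cv$age[1], cv$age[2], 30, 95)
      bcva[idx] <- rtrunc_norm(length(idx), cv$bcva[1], cv$bcva[2], 0, 100)
      cmt[idx] <- rtrunc_norm(length(idx), cv$cmt[1], cv$cmt[2], 150, 900)
    }
    dtype <- ifelse(runif(spec$n_eyes) < calib$t1_fraction, "T1", "T2")
    data.frame(eye_id = ids, npa_quadrants = quadrants,
               bcva_letters = round(bcva, 2), cmt_um = round(cmt, 2),
               age_years = round(age, 1), sex = sex, diabetes_type = dtype,
               stringsAsFactors = FALSE)
  })
  eyes <- validate_eye_table(eyes)

  slabs <- vector("list", spec$n_eyes)
  names(slabs) <- ids
  for (i in seq_len(spec$n_eyes)) {
    q <- quadrants[i]
    dropout <- if (q == 0) 0 else with_local_seed(derive_seed(spec$seed, i, 9L), {
      min(max(q * calib$dropout_per_quadrant + rnorm(1, 0, calib$dropout_jitter_sd),
              calib$dropout_min), calib$dropout_max)
    })
    slabs[[i]] <- list(
      SCP = generate_plexus(density = calib$scp$density, dropout = dropout,
                            faz_radius_frac = calib$faz_radius_frac,
                            size_px = spec$image_size_px,
                            seed = derive_seed(spec$seed, i, 1L),
                            wavelength_px = calib$scp$wavelength_px,
                            calib = calib, eye_id = ids[i], plexus = "SCP"),
      DCP = generate_plexus(density = calib$dcp$density, dropout = dropout,
                            faz_radius_frac = calib$faz_radius_frac,
                            size_px = spec$image_size_px,
                            seed = derive_seed(spec$seed, i, 2L),
                            wavelength_px = calib$dcp$wavelength_px,
                            calib = calib, eye_id = ids[i], plexus = "DCP"))
  }
  if (!is.null(dir)) write_cohort(eyes, slabs, dir)
  list(eyes = eyes, slabs = slabs)
}
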