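test_that("8-bit PNG slabs round-trip exactly and multi-channel input collapses", {
  set.seed(11)
  px <- matrix(sample(0:255, 64 * 48, replace = TRUE), 64, 48)
  slab <- octa_slab(px, "eyeA", "SCP")
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(slab$pixels / 255, f)
  back <- read_slab(f, "SCP", "eyeA")
  expect_identical(back$pixels, slab$pixels)
  expect_equal(dim(back$pixels), c(64, 48))

  # RGB image collapses by fixed luma weights
  arr <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  frgb <- withr::local_tempfile(fileext = ".png")
  png::writePNG(arr, frgb)
  g <- read_slab(frgb, "DCP", "eyeB")
  expect_equal(dim(g$pixels), c(32, 32))
  arr8 <- round(arr * 255) / 255
  lum <- 0.2126 * arr8[, , 1] + 0.7152 * arr8[, , 2] + 0.0722 * arr8[, , 3]
  expect_true(max(abs(g$pixels - lum * 255)) <= 1)
})

test_that("deep TIFF input is rescaled to 8 bits by the image maximum", {
  set.seed(12)
  v16 <- matrix(sample(0:60000, 40 * 40, replace = TRUE), 40, 40)
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(v16 / 65535, f, bits.per.sample = 16)
  slab <- read_slab(f, "SCP", "x")
  expect_equal(slab$pixels, matrix(as.integer(round(255 * v16 / max(v16))), 40, 40))
  expect_true(max(slab$pixels) == 255)
})

test_that("undersized and unreadable images are rejected", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 10, 10), f)
  expect_error(read_slab(f, "SCP"), class = "octa_validation_error")
  expect_error(read_slab(file.path(tempdir(), "nope.png"), "SCP"),
               class = "octa_io_error")
  expect_error(octa_slab(matrix(300L, 64, 64), "e", "SCP"),
               class = "octa_validation_error")
})

test_that("masks round-trip exactly through 8-bit PNG", {
  set.seed(13)
  mask <- matrix(runif(50 * 50) < 0.3, 50, 50)
  f <- withr::local_tempfile(fileext = ".png")
  write_mask_png(mask, f)
  expect_identical(read_mask_png(f), mask)
})

test_that("eye table reading derives the perfusion group and validates", {
  df <- data.frame(eye_id = c("a", "b", "c"), npa_quadrants = c(0, 3, 1),
                   bcva_letters = c(70, 60, 55), cmt_um = c(400, 450, 500),
                   age_years = c(60, 65, 70), sex = c("M", "F", "M"),
                   diabetes_type = c("T1", "T2", "T2"))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  eyes <- read_eye_table(f)
  expect_equal(eyes$group, c("WELL_PERFUSED", "NPA", "NPA"))
  expect_equal(eyes$eye_id, df$eye_id)  # row order preserved

  # missing column named in the error
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, -2], f2, row.names = FALSE)
  expect_error(read_eye_table(f2), "npa_quadrants", class = "octa_schema_error")

  # out-of-range quadrant count flagged with its row
  df$npa_quadrants[2] <- 5
  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f3, row.names = FALSE)
  expect_error(read_eye_table(f3), "2", class = "octa_validation_error")
})

test_that("feature table writing is ordered, deterministic and round-trips", {
  feats <- data.frame(
    eye_id = c("b", "a", "b", "a"), plexus = c("DCP", "DCP", "SCP", "SCP"),
    fd = c(1.23456789012345, 1.9, 1.5, 1.7), lac = c(0.31, 0.39, 0.2, 0.1),
    fit_r2 = c(0.99, 0.98, 0.97, 0.96), n_box_sizes = c(6L, 6L, 6L, 6L))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(feats, f1)
  write_feature_table(feats[c(3, 1, 4, 2), ], f2)  # shuffled input
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_feature_table(f1)
  expect_equal(back$eye_id, c("a", "a", "b", "b"))
  expect_equal(back$plexus, c("SCP", "DCP", "SCP", "DCP"))
  expect_equal(back$fd[back$eye_id == "b" & back$plexus == "DCP"],
               1.23456789012345, tolerance = 1e-12)

  # empty input gives a header-only file
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(feats[0, ], f3)
  expect_equal(length(readLines(f3)), 1L)
})

test_that("cohort directory layout round-trips and reports missing slabs", {
  spec <- cohort_spec(n_eyes = 4, npa_fraction = 0.5,
                      quadrant_distribution = c(1, 1, 0, 0),
                      image_size_px = 48, seed = 5)
  dir <- withr::local_tempdir()
  coh <- generate_cohort(spec, dir = dir)
  expect_true(file.exists(file.path(dir, "eyes.csv")))
  back <- read_cohort(dir)
  expect_equal(back$eyes$eye_id, coh$eyes$eye_id)
  expect_identical(back$slabs[["eye_001"]]$SCP$pixels,
                   coh$slabs[["eye_001"]]$SCP$pixels)

  unlink(file.path(dir, "eye_002", "eye_002_DCP.png"))
  expect_error(read_cohort(dir), "eye_002", class = "octa_io_error")
})
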