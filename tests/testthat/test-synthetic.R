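test_that("analytic fixtures have their constructed pixel counts", {
  expect_identical(make_fixture("FILLED", 64), matrix(TRUE, 64, 64))
  expect_equal(sum(make_fixture("SIERPINSKI_CARPET", level = 3)), 8^3)
  expect_equal(dim(make_fixture("SIERPINSKI_CARPET", level = 3)), c(27, 27))
  expect_equal(sum(make_fixture("LINE", 50)), 50)
  expect_equal(sum(make_fixture("SINGLE_PIXEL", 33)), 1)
  expect_error(make_fixture("SIERPINSKI_CARPET", size_px = 30, level = 3),
               class = "octa_validation_error")
  d1 <- make_fixture("RANDOM_DUST", 40, density = 0.2, seed = 4)
  expect_identical(d1, make_fixture("RANDOM_DUST", 40, density = 0.2, seed = 4))
})

test_that("plexus generation is reproducible and respects its contracts", {
  s1 <- generate_plexus(size_px = 96, seed = 7)
  s2 <- generate_plexus(size_px = 96, seed = 7)
  expect_identical(s1$pixels, s2$pixels)
  s3 <- generate_plexus(size_px = 96, seed = 8)
  expect_false(identical(s1$pixels, s3$pixels))

  expect_error(generate_plexus(density = 0), class = "octa_validation_error")
  expect_error(generate_plexus(dropout = 1), class = "octa_validation_error")
})

test_that("a healthy plexus yields a quadrant-spanning skeleton with high FD", {
  slab <- generate_plexus(size_px = 128, seed = 3, dropout = 0)
  sk <- skeletonize(binarize(slab))$skeleton
  h <- nrow(sk) %/% 2; w <- ncol(sk) %/% 2
  expect_true(any(sk[1:h, 1:w]) && any(sk[1:h, (w + 1):ncol(sk)]) &&
              any(sk[(h + 1):nrow(sk), 1:w]) &&
              any(sk[(h + 1):nrow(sk), (w + 1):ncol(sk)]))
  r <- analyze_slab(slab)
  expect_true(r$fd > 1.5 && r$fd <= 2)
})

test_that("dropout removes skeleton mass monotonically at a fixed seed", {
  s0 <- generate_plexus(size_px = 128, seed = 5, dropout = 0)
  s9 <- generate_plexus(size_px = 128, seed = 5, dropout = 0.9)
  n0 <- skeletonize(binarize(s0))$n_pixels
  n9 <- skeletonize(binarize(s9))$n_pixels
  expect_lt(n9, n0)
})

test_that("increasing dropout degrades FD and raises lacunarity", {
  levels <- seq(0, 0.9, length.out = 10)
  n_seeds <- 20
  fd_rho <- lac_rho <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    fd <- lac <- numeric(length(levels))
    for (k in seq_along(levels)) {
      r <- analyze_slab(generate_plexus(size_px = 128, seed = s,
                                        dropout = levels[k]))
      fd[k] <- r$fd; lac[k] <- r$lac
    }
    fd_rho[s] <- cor(levels, fd, method = "spearman")
    lac_rho[s] <- cor(levels, lac, method = "spearman")
  }
  # sign test across seeds: the trend direction must be systematic
  expect_lt(binom.test(sum(fd_rho < 0), n_seeds, 0.5)$p.value, 0.01)
  expect_lt(binom.test(sum(lac_rho > 0), n_seeds, 0.5)$p.value, 0.01)
  expect_gt(sum(fd_rho < 0), n_seeds * 0.75)
  expect_gt(sum(lac_rho > 0), n_seeds * 0.75)
})

test_that("default cohorts reproduce the study composition exactly", {
  coh <- generate_cohort(cohort_spec(seed = 1, image_size_px = 64))
  expect_equal(nrow(coh$eyes), 50)
  expect_equal(sum(coh$eyes$group == "NPA"), 30)
  expect_equal(sum(coh$eyes$group == "WELL_PERFUSED"), 20)
  expect_equal(as.vector(table(coh$eyes$npa_quadrants[coh$eyes$npa_quadrants > 0])),
               c(6, 4, 9, 11))
  expect_equal(sum(coh$eyes$sex == "M" & coh$eyes$group == "NPA"), 16)
  expect_equal(sum(coh$eyes$sex == "M" & coh$eyes$group == "WELL_PERFUSED"), 11)
  # covariates inside their clinical truncation ranges
  expect_true(all(coh$eyes$bcva_letters >= 0 & coh$eyes$bcva_letters <= 100))
  expect_true(all(coh$eyes$cmt_um >= 150 & coh$eyes$cmt_um <= 900))
})

test_that("an invalid quadrant distribution is rejected", {
  expect_error(cohort_spec(quadrant_distribution = c(1, 1, 1, 1)),
               class = "octa_validation_error")
})

test_that("cohort generation is byte-reproducible from its seed", {
  spec <- cohort_spec(n_eyes = 4, npa_fraction = 0.5,
                      quadrant_distribution = c(1, 1, 0, 0),
                      image_size_px = 48, seed = 17)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(spec, dir = d1)
  generate_cohort(spec, dir = d2)
  for (rel in c("eyes.csv", file.path("eye_003", "eye_003_SCP.png"),
                file.path("eye_002", "eye_002_DCP.png"))) {
    expect_identical(readBin(file.path(d1, rel), "raw", file.size(file.path(d1, rel))),
                     readBin(file.path(d2, rel), "raw", file.size(file.path(d2, rel))))
  }
})

test_that("fractal metrics separate the groups in the expected direction", {
  for (seed in 1:2) {
    m <- cached_cohort_features(seed)
    for (plx in c("SCP", "DCP")) {
      sub <- m[m$plexus == plx, ]
      expect_lt(mean(sub$fd[sub$group == "NPA"]),
                mean(sub$fd[sub$group == "WELL_PERFUSED"]))
      expect_gt(mean(sub$lac[sub$group == "NPA"]),
                mean(sub$lac[sub$group == "WELL_PERFUSED"]))
    }
  }
})
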