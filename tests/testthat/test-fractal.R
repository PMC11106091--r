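test_that("box counts take closed-form values on filled and single-pixel images", {
  filled <- make_fixture("FILLED", 256)
  cv <- box_count(filled, box_sizes = c(2, 4, 8, 16, 32, 64), n_origins = 1)
  expect_equal(cv$mean_count, (256 / cv$box_size)^2)

  single <- make_fixture("SINGLE_PIXEL", 64)
  cv1 <- box_count(single, box_sizes = c(2, 3, 8, 16), n_origins = 4)
  expect_true(all(attr(cv1, "per_origin") == 1))
})

test_that("multi-origin box counts match the nested-loop oracle exactly", {
  set.seed(31)
  for (i in 1:12) {
    n <- sample(33:64, 1)
    skel <- matrix(runif(n * n) < runif(1, 0.02, 0.4), n, n)
    if (!any(skel)) skel[1, 1] <- TRUE
    sizes <- sort(sample(2:min(16, n), 4))
    cv <- box_count(skel, box_sizes = sizes, n_origins = 4)
    per <- attr(cv, "per_origin")
    for (s in seq_along(sizes)) {
      eps <- sizes[s]
      offs <- rbind(c(0, 0), c(0, floor(eps / 2)),
                    c(floor(eps / 2), 0), c(floor(eps / 2), floor(eps / 2)))
      for (o in 1:4) {
        expect_equal(per[s, o], bf_box_count(skel, eps, offs[o, 1], offs[o, 2]))
      }
    }
  }
})

test_that("mean occupied-box count never increases with box size", {
  set.seed(32)
  for (i in 1:8) {
    skel <- matrix(runif(64 * 64) < 0.15, 64, 64)
    skel[5, 5] <- TRUE
    cv <- box_count(skel, box_sizes = c(2, 4, 8, 16, 32), n_origins = 4)
    expect_true(all(diff(cv$mean_count) <= 1e-9))
  }
})

test_that("log-log fit recovers exact power laws and degenerate slopes", {
  curve <- data.frame(box_size = c(2, 4, 8, 16, 32, 64),
                      mean_count = (256 / c(2, 4, 8, 16, 32, 64))^2)
  fit <- fit_fd(curve)
  expect_equal(fit$fd, 2, tolerance = 1e-12)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-12)

  flat <- data.frame(box_size = c(2, 4, 8), mean_count = c(1, 1, 1))
  expect_equal(fit_fd(flat)$fd, 0, tolerance = 1e-12)

  expect_error(fit_fd(flat[1:2, ]), class = "octa_validation_error")
})

test_that("the Sierpinski carpet yields its similarity dimension", {
  carpet <- make_fixture("SIERPINSKI_CARPET", level = 5)
  expect_equal(dim(carpet), c(243, 243))
  cv <- box_count(carpet, box_sizes = c(1, 3, 9, 27, 81), n_origins = 1)
  # self-similar construction: N(3^k) = 8^(5-k) at origin (0,0)
  expect_equal(cv$mean_count, 8^(5:1))
  fit <- fit_fd(cv)
  expect_equal(fit$fd, log(8) / log(3), tolerance = 0.05)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-9)
})

test_that("a one-pixel line has dimension near 1 under default settings", {
  line <- make_fixture("LINE", 256)
  fit <- fit_fd(box_count(line))
  expect_equal(fit$fd, 1, tolerance = 0.05)
})

test_that("gliding-box lacunarity matches brute force and closed forms", {
  # homogeneous limit
  full <- make_fixture("FILLED", 32)
  lc <- gliding_box_lacunarity(full, box_sizes = c(2, 4, 8))
  expect_equal(lc$lambda, rep(1, 3), tolerance = 1e-12)
  expect_equal(summarize_lac(lc), 0, tolerance = 1e-12)

  # single pixel at r = 1: Lambda = number of window positions
  single <- make_fixture("SINGLE_PIXEL", 24)
  lc1 <- gliding_box_lacunarity(single, box_sizes = 1)
  expect_equal(lc1$lambda, 24 * 24, tolerance = 1e-9)

  # 16x16 with one 4x4 block, r in {2,4}: direct enumeration
  blk <- matrix(FALSE, 16, 16); blk[5:8, 9:12] <- TRUE
  lc2 <- gliding_box_lacunarity(blk, box_sizes = c(2, 4))
  expect_equal(lc2$lambda, c(bf_gliding_box(blk, 2), bf_gliding_box(blk, 4)),
               tolerance = 1e-12)

  set.seed(33)
  for (i in 1:10) {
    n <- sample(20:64, 1)
    skel <- matrix(runif(n * n) < runif(1, 0.05, 0.5), n, n)
    if (!any(skel)) skel[2, 3] <- TRUE
    for (r in c(2, 5, 8)) {
      got <- gliding_box_lacunarity(skel, box_sizes = r)
      expect_equal(got$lambda, bf_gliding_box(skel, r), tolerance = 1e-12)
    }
  }
})

test_that("lacunarity summary is the mean of 1 - 1/Lambda and is monotone", {
  lc <- data.frame(box_size = c(2, 4), lambda = c(2, 2))
  expect_equal(summarize_lac(lc), 0.5)
  expect_equal(summarize_lac(lc, "raw"), 2)
  expect_equal(summarize_lac(lc, "cv2"), 1)

  set.seed(34)
  for (i in 1:20) {
    lam <- runif(5, 1, 6)
    base <- summarize_lac(data.frame(box_size = 1:5, lambda = lam))
    j <- sample(5, 1)
    lam2 <- lam; lam2[j] <- lam2[j] + runif(1, 0.1, 2)
    expect_gt(summarize_lac(data.frame(box_size = 1:5, lambda = lam2)), base)
  }
})

test_that("analyze_slab composes the stages deterministically", {
  slab <- generate_plexus(size_px = 96, seed = 41)
  r1 <- analyze_slab(slab)
  r2 <- analyze_slab(slab)
  expect_identical(r1, r2)
  expect_true(r1$fd > 0 && r1$fd <= 2)
  expect_true(r1$lac >= 0 && r1$lac < 1)
  expect_equal(r1$n_skeleton_px, sum(skeletonize(binarize(slab))$skeleton))

  err <- tryCatch(analyze_slab(octa_slab(matrix(0L, 64, 64), "z", "SCP")),
                  error = function(e) e)
  expect_s3_class(err, "octa_degenerate_error")
  expect_match(conditionMessage(err), "binarize")
})

test_that("fitted dimension stays in [0, 2] across degraded inputs", {
  for (seed in 1:5) {
    slab <- generate_plexus(size_px = 64, seed = seed,
                            dropout = c(0, 0.45, 0.9, 0.7, 0.2)[seed])
    r <- analyze_slab(slab)
    expect_true(r$fd >= 0 && r$fd <= 2)
    expect_true(r$fit_r2 >= 0 && r$fit_r2 <= 1)
  }
})
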