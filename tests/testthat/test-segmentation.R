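test_that("low-pass filter: fixed points, identity, mass conservation", {
  u <- matrix(120, 20, 30)
  expect_equal(lowpass_filter(u, 2), u)
  spike <- matrix(0, 21, 21); spike[11, 11] <- 255
  sm <- lowpass_filter(spike, 1.5)
  expect_lt(max(sm), 255)
  expect_equal(sum(sm), sum(spike), tolerance = 1e-8)
  f <- frame_record(matrix(7, 4, 4))
  expect_identical(lowpass_filter(f, 0), f)
  expect_error(lowpass_filter(f, -1), "sigma")
})

test_that("low-pass filter matches a direct-convolution oracle", {
  set.seed(21)
  img <- matrix(runif(8 * 9, 0, 255), 8, 9)
  for (sigma in c(0.7, 1.3)) {
    expect_equal(lowpass_filter(img, sigma), ref_gauss_blur(img, sigma),
                 tolerance = 1e-10)
  }
})

test_that("Otsu threshold agrees with the EBImage reference", {
  # On a well-separated bimodal image the Otsu criterion is flat across the
  # empty intensity gap, so implementations may return different levels in
  # the gap; what must agree is the induced segmentation.
  set.seed(22)
  x <- matrix(c(rnorm(600, 60, 10), rnorm(400, 200, 12)), 25, 40)
  x <- pmin(pmax(x, 0), 255)
  mine <- otsu_threshold(x)
  ref <- EBImage::otsu(EBImage::Image(t(x) / 255), range = c(0, 1),
                       levels = 256) * 255
  # compare the induced segmentation on the binned scale both optimise
  expect_identical(floor(x) > mine, floor(x) > ref)
  expect_gt(mine, 80); expect_lt(mine, 180)
  # overlapping classes: no gap, thresholds must nearly coincide
  set.seed(25)
  y <- pmin(pmax(matrix(c(rnorm(600, 90, 30), rnorm(400, 170, 30)),
                        25, 40), 0), 255)
  mine_y <- otsu_threshold(y)
  ref_y <- EBImage::otsu(EBImage::Image(t(y) / 255), range = c(0, 1),
                         levels = 256) * 255
  expect_lt(abs(mine_y - ref_y), 2)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "degenerate histogram")
})

test_that("background estimation: medians of constant and near-constant stacks", {
  f <- function(m, i) frame_record(m, index = i, timestamp_s = i)
  base <- matrix(200, 10, 12)
  fs <- frame_sequence(list(f(base, 0L), f(base, 1L), f(base, 2L)), 1)
  expect_equal(estimate_background(fs), base)
  odd <- base; odd[4, 5] <- 30
  fs2 <- frame_sequence(list(f(base, 0L), f(odd, 1L), f(base, 2L)), 1)
  expect_equal(estimate_background(fs2), base)  # majority of 3 wins
  expect_equal(estimate_background(fs2, "fixed_image", fixed_image = odd), odd)
  expect_error(estimate_background(fs2, "fixed_image"), "fixed_image")
})

test_that("background estimation recovers litter under a moving blob", {
  # blob sweeps across so each pixel sees litter in > 50% of frames
  set.seed(23)
  frames <- lapply(0:9, function(t) {
    m <- matrix(200 + rnorm(30 * 60, 0, 0.5), 30, 60)
    m[, pmin(1:8 + 6 * t, 60)] <- 60
    frame_record(pmin(pmax(m, 0), 255), index = t, timestamp_s = t)
  })
  bg <- estimate_background(frame_sequence(frames, 1))
  visits <- Reduce(`+`, lapply(frames, function(f) f$pixels < 100))
  expect_true(all(abs(bg[visits < 5] - 200) <= 2))
})

test_that("foreground segmentation: difference and polarity semantics", {
  bg <- matrix(200, 40, 50)
  frame <- bg; disk <- disk_mask(40, 50, 20, 25, 8)
  frame[disk] <- 30
  p_fix <- segmentation_params(background_method = "fixed_image",
                               threshold_method = "fixed",
                               fixed_threshold = 100, fixed_background = bg)
  expect_identical(segment_foreground(frame, bg, p_fix), disk)
  expect_false(any(segment_foreground(bg, bg, p_fix)))
  # global threshold with inverted polarity segments the inverted fixture
  p_dark <- segmentation_params(background_method = "global_threshold",
                                threshold_method = "fixed",
                                fixed_threshold = 100, polarity = "dark")
  p_light <- segmentation_params(background_method = "global_threshold",
                                 threshold_method = "fixed",
                                 fixed_threshold = 155, polarity = "light")
  expect_identical(segment_foreground(255 - frame, NULL, p_light),
                   segment_foreground(frame, NULL, p_dark))
  expect_error(segment_foreground(frame, matrix(200, 2, 2), p_fix),
               "dimensions differ")
})

test_that("mask clean-up fills holes, filters specks, and is idempotent", {
  p <- segmentation_params(min_blob_area_px = 50)
  ring <- disk_mask(40, 40, 20, 20, 10) & !disk_mask(40, 40, 20, 20, 5)
  expect_identical(clean_mask(ring, p), disk_mask(40, 40, 20, 20, 10))
  specks <- matrix(FALSE, 50, 80)
  set.seed(24)
  specks[cbind(sample(50, 10), sample(80, 10))] <- TRUE
  blob <- square_mask(50, 80, 21:40, 41:50)  # 200 px
  cleaned <- clean_mask(specks | blob, p)
  expect_identical(cleaned, blob)
  empty <- matrix(FALSE, 10, 10)
  expect_identical(clean_mask(empty, p), empty)
  for (s in 1:10) {
    set.seed(s)
    m <- random_mask(30, 40, 0.35)
    once <- clean_mask(m, p)
    expect_identical(clean_mask(once, p), once)
  }
})

test_that("shape extraction reproduces hand-computed descriptors", {
  m <- square_mask(60, 100, 16:25, 16:25) | square_mask(60, 100, 16:25, 76:85)
  ss <- extract_shapes(m, 8, 7L)
  expect_equal(ss$n_clusters, 2L)
  expect_equal(ss$mean_area, 100)
  expect_equal(ss$mean_pair_distance, 60)
  expect_equal(ss$shapes$centroid_row, c(20.5, 20.5))
  expect_equal(ss$shapes$centroid_col, c(20.5, 80.5))
  expect_equal(ss$shapes$perimeter_px, c(36, 36))  # 4 x 9 orthogonal steps
  expect_true(ss$valid)
  expect_equal(ss$frame_index, 7L)

  single <- extract_shapes(square_mask(20, 20, 5:8, 5:8))
  expect_equal(single$n_clusters, 1L)
  expect_true(is.na(single$mean_pair_distance))
  expect_false(single$valid)

  m3 <- matrix(FALSE, 5, 30)
  m3[2, c(3, 13, 23)] <- TRUE
  tri <- extract_shapes(m3)
  expect_equal(tri$mean_pair_distance, (10 + 10 + 20) / 3)
})

test_that("shape extraction respects connectivity and transposition", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal touch
  expect_equal(extract_shapes(m, 8)$n_clusters, 1L)
  expect_equal(extract_shapes(m, 4)$n_clusters, 2L)
  for (s in 1:5) {
    set.seed(s)
    m <- random_mask(25, 35, 0.3)
    a <- extract_shapes(m, 8)
    b <- extract_shapes(t(m), 8)
    expect_equal(a$n_clusters, b$n_clusters)
    expect_equal(sort(a$shapes$area_px2), sort(b$shapes$area_px2))
    expect_equal(sort(a$shapes$perimeter_px), sort(b$shapes$perimeter_px))
  }
})

test_that("foreground pixel count equals the sum of shape areas", {
  for (s in 1:8) {
    set.seed(100 + s)
    m <- random_mask(30, 45, runif(1, 0.1, 0.5))
    ss <- extract_shapes(m, sample(c(4L, 8L), 1))
    expect_equal(sum(ss$shapes$area_px2), sum(m))
  }
})

test_that("shape tables export to CSV with the documented columns", {
  ss <- extract_shapes(square_mask(20, 20, 3:6, 3:6), frame_index = 4L)
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- write_shape_csv(ss, path)
  back <- read.csv(path)
  expect_identical(names(back),
                   c("frame_index", "shape_id", "area_px2", "perimeter_px",
                     "centroid_row", "centroid_col"))
  expect_equal(back$area_px2, 16L)
})

test_that("segmentation parameters validate their invariants", {
  expect_error(segmentation_params(lowpass_sigma = -1), "lowpass_sigma")
  expect_error(segmentation_params(connectivity = 6), "connectivity")
  expect_error(segmentation_params(threshold_method = "fixed"),
               "fixed_threshold")
  expect_error(segmentation_params(fixed_threshold = 10), "fixed_threshold")
})
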