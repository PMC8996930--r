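test_that("calibration factor reproduces its closed form and is linear in H", {
  expect_equal(calibration_factor(camera_geometry(10, 90, 20)), 1)
  expect_equal(calibration_factor(camera_geometry(300, 60, 976)),
               2 * 300 * tan(pi / 6) / 976)
  k1 <- calibration_factor(camera_geometry(150, 48, 640))
  k2 <- calibration_factor(camera_geometry(300, 48, 640))
  expect_equal(k2, 2 * k1)
  expect_error(camera_geometry(0, 60, 976), "mount_height_cm")
  expect_error(camera_geometry(300, 180, 976), "lens_angle_deg")
  expect_error(camera_geometry(300, -5, 976), "lens_angle_deg")
})

test_that("directed and symmetric Hausdorff match hand-computed cases", {
  A <- rbind(c(0, 0), c(0, 3)); B <- rbind(c(0, 1))
  expect_equal(directed_hausdorff(A, B), 2)
  expect_equal(directed_hausdorff(B, A), 1)
  expect_equal(symmetric_hausdorff(A, B), 2)
  expect_equal(symmetric_hausdorff(B, A), 2)
  P <- rbind(c(0, 0)); Q <- rbind(c(3, 4))
  expect_equal(directed_hausdorff(P, Q), 5)
  expect_equal(directed_hausdorff(Q, P), 5)
  set.seed(31)
  S <- matrix(runif(20, 0, 50), ncol = 2)
  expect_equal(symmetric_hausdorff(S, S), 0)
  expect_error(directed_hausdorff(S, matrix(numeric(), 0, 2)), "empty")
})

test_that("point-set Hausdorff equals the exhaustive oracle", {
  for (s in 1:40) {
    set.seed(s)
    A <- matrix(runif(2 * sample(1:50, 1), 0, 100), ncol = 2)
    B <- matrix(runif(2 * sample(1:50, 1), 0, 100), ncol = 2)
    expect_identical(directed_hausdorff(A, B), brute_directed_hausdorff(A, B))
    expect_identical(symmetric_hausdorff(A, B), brute_symmetric_hausdorff(A, B))
  }
})

test_that("mask Hausdorff via distance transform equals brute force exactly", {
  for (s in 1:20) {
    set.seed(200 + s)
    m1 <- random_mask(30, 45, 0.1)
    m2 <- random_mask(30, 45, 0.1)
    if (!any(m1) || !any(m2)) next
    fast <- unrest_index(m1, m2, k = 1)
    brute <- brute_symmetric_hausdorff(mask_point_set(m1), mask_point_set(m2))
    expect_identical(fast, brute)
  }
})

test_that("unrest index measures rigid translations in cm", {
  m1 <- disk_mask(60, 60, 20, 20, 8)
  m2 <- disk_mask(60, 60, 23, 24, 8)  # translated by (3,4): length 5
  expect_equal(unrest_index(m2, m1, k = 2), 10, tolerance = 1.5 / 10)
  expect_true(abs(unrest_index(m2, m1, k = 2) - 10) <= 0.75 * 2)
  expect_equal(unrest_index(m1, m1, k = 2), 0)
  expect_equal(unrest_index(m2, m1, k = 0), 0)
  empty <- matrix(FALSE, 60, 60)
  expect_true(is.na(unrest_index(m1, empty, k = 2)))
  expect_true(is.na(unrest_index(empty, m1, k = 2)))
  expect_error(unrest_index(m1, matrix(FALSE, 2, 2), 1), "dimensions")
})

test_that("unrest of any translated convex blob equals k * translation length", {
  base <- ellipse_mask(80, 120, 35, 45, 10, 6, theta = 0.4)
  k <- 0.7
  set.seed(32)
  for (i in 1:12) {
    v <- sample(-12:12, 2, replace = TRUE)
    if (all(v == 0)) next
    moved <- ellipse_mask(80, 120, 35 + v[1], 45 + v[2], 10, 6, theta = 0.4)
    u <- unrest_index(moved, base, k)
    expect_true(abs(u - k * sqrt(sum(v^2))) <= 0.75 * k)
  }
})

test_that("centroid point mode agrees with the point-set Hausdorff", {
  m1 <- square_mask(40, 60, 5:10, 5:10) | square_mask(40, 60, 25:30, 45:50)
  m2 <- square_mask(40, 60, 8:13, 7:12) | square_mask(40, 60, 22:27, 40:45)
  u <- unrest_index(m1, m2, k = 1, point_mode = "centroids")
  c1 <- rbind(c(7.5, 7.5), c(27.5, 47.5))
  c2 <- rbind(c(10.5, 9.5), c(24.5, 42.5))
  expect_equal(u, brute_symmetric_hausdorff(c1, c2))
})

test_that("cluster index reproduces hand-computed values and variants", {
  ss <- make_shape_set(2, 100, 40, 60, 100, 100)
  expected <- 2 * 100 * sqrt(100^2 + 100^2) / (40 * 60 * 1)
  expect_equal(cluster_index(ss), expected)
  expect_equal(cluster_index(ss), 11.785, tolerance = 1e-4)
  # doubling the mean pair distance exactly halves the index
  ss2 <- make_shape_set(2, 100, 40, 120, 100, 100)
  expect_equal(cluster_index(ss2), expected / 2)
  # with n_A = 2 the nA_inverse variant halves the default variant
  expect_equal(cluster_index(ss, variant = "nA_inverse"), expected / 2)
  # frame-diagonal flag
  expect_equal(cluster_index(ss, use_diagonal = FALSE),
               2 * 100 * (100^2 + 100^2) / (40 * 60 * 1))
  # frames with < 2 blobs are flagged invalid, both variants
  ss1 <- make_shape_set(1, 100, 40, NA_real_, 100, 100)
  expect_true(is.na(cluster_index(ss1)))
  expect_true(is.na(cluster_index(ss1, variant = "nA_inverse")))
})

test_that("cluster index scales linearly under consistent spatial rescaling", {
  base <- make_shape_set(3, 80, 36, 50, 120, 160)
  for (s in c(0.5, 2, 3)) {
    scaled <- make_shape_set(3, 80 * s^2, 36 * s, 50 * s, 120 * s, 160 * s)
    expect_equal(cluster_index(scaled), s * cluster_index(base))
  }
})

test_that("moving fixed-shape blobs apart strictly decreases the cluster index", {
  vals <- vapply(c(30, 45, 60, 75), function(sep) {
    m <- square_mask(100, 120, 41:50, 21:30) |
      square_mask(100, 120, 41:50, 21:30 + sep)
    cluster_index(extract_shapes(m))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("index series on a static two-blob scene is flat and complete", {
  frames <- frame_sequence(list(two_blob_frame(0), two_blob_frame(1),
                                two_blob_frame(2)), 1)
  p <- segmentation_params(lowpass_sigma = 0,
                           background_method = "global_threshold",
                           threshold_method = "fixed", fixed_threshold = 100,
                           min_blob_area_px = 10)
  g <- camera_geometry(10, 90, 20)  # k = 1
  s <- compute_index_series(frames, p, g)
  expect_equal(nrow(s$cluster), 3L)
  expect_equal(nrow(s$unrest), 2L)
  expect_true(all(s$unrest$unrest_cm == 0))
  expect_true(all(s$cluster$valid))
  expect_equal(length(unique(s$cluster$cluster_index)), 1L)
  # and a moved pair of frames measures the translation
  frames2 <- frame_sequence(list(two_blob_frame(0),
                                 two_blob_frame(1, shift = c(3, 4))), 1)
  s2 <- compute_index_series(frames2, p, g)
  expect_true(abs(s2$unrest$unrest_cm - 5) <= 0.75)
})

test_that("index series flags invalid frames instead of dropping them", {
  blank <- frame_record(matrix(200, 30, 40), 1L, 1)
  frames <- frame_sequence(list(two_blob_frame(0, 30, 40), blank,
                                two_blob_frame(2, 30, 40)), 1)
  p <- segmentation_params(lowpass_sigma = 0,
                           background_method = "global_threshold",
                           threshold_method = "fixed", fixed_threshold = 100,
                           min_blob_area_px = 10)
  s <- compute_index_series(frames, p, camera_geometry(10, 90, 20))
  expect_equal(s$cluster$valid, c(TRUE, FALSE, TRUE))
  expect_equal(s$unrest$valid, c(FALSE, FALSE))
  expect_true(all(is.na(s$unrest$unrest_cm)))
  # all-blank input cannot produce a series
  blanks <- frame_sequence(list(frame_record(matrix(200, 30, 40), 0L, 0),
                                blank), 1)
  expect_error(compute_index_series(blanks, p, camera_geometry(10, 90, 20)),
               "all frames invalid")
})

test_that("parameter fingerprints ignore construction order", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.yaml"); f2 <- file.path(dir, "b.yaml")
  writeLines(c("geometry:", "  mount_height_cm: 300", "  lens_angle_deg: 60",
               "  sensor_length_px: 976", "segmentation:",
               "  lowpass_sigma: 1", "  min_blob_area_px: 25"), f1)
  writeLines(c("segmentation:", "  min_blob_area_px: 25",
               "  lowpass_sigma: 1", "geometry:", "  sensor_length_px: 976",
               "  lens_angle_deg: 60", "  mount_height_cm: 300"), f2)
  c1 <- read_pipeline_config(f1); c2 <- read_pipeline_config(f2)
  frames <- frame_sequence(list(two_blob_frame(0), two_blob_frame(1)), 1)
  p <- function(cfg) {
    sp <- cfg$segmentation
    sp$background_method <- "global_threshold"
    sp$threshold_method <- "fixed"
    sp$fixed_threshold <- 100
    compute_index_series(frames, sp, cfg$geometry)
  }
  s1 <- p(c1); s2 <- p(c2)
  expect_identical(s1$params_fingerprint, s2$params_fingerprint)
  expect_identical(s1$cluster, s2$cluster)
})

test_that("index series export includes flags and timestamps", {
  frames <- frame_sequence(list(two_blob_frame(0), two_blob_frame(1)), 1)
  p <- segmentation_params(lowpass_sigma = 0,
                           background_method = "global_threshold",
                           threshold_method = "fixed", fixed_threshold = 100,
                           min_blob_area_px = 10)
  s <- compute_index_series(frames, p, camera_geometry(10, 90, 20))
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- write_index_csv(s, path)
  back <- read.csv(path)
  expect_identical(names(back),
                   c("frame_index", "timestamp_s", "cluster_index",
                     "cluster_valid", "unrest_cm", "unrest_valid"))
  expect_true(is.na(back$unrest_cm[1]))
})
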