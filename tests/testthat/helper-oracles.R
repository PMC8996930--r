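# Independent oracles and fixture builders shared by the tests.

# exhaustive double-loop directed Hausdorff (the reference the fast paths
# must match exactly)
brute_directed_hausdorff <- function(A, B) {
  max(apply(A, 1, function(a) {
    sqrt(min((a[1] - B[, 1])^2 + (a[2] - B[, 2])^2))
  }))
}

brute_symmetric_hausdorff <- function(A, B) {
  max(brute_directed_hausdorff(A, B), brute_directed_hausdorff(B, A))
}

mask_point_set <- function(mask) {
  which(mask, arr.ind = TRUE)
}

# dense direct-convolution Gaussian blur oracle (mirror boundary), R loops
ref_gauss_blur <- function(img, sigma) {
  rad <- ceiling(3 * sigma)
  w <- exp(-(-rad:rad)^2 / (2 * sigma^2))
  w <- w / sum(w)
  reflect <- function(i, n) {
    while (any(bad <- i < 1 | i > n)) {
      i[i < 1] <- 1 - i[i < 1] + 0  # mirror about 0.5: -0 -> 1, -1 -> 2
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (kr in -rad:rad) for (kc in -rad:rad) {
      acc <- acc + w[kr + rad + 1] * w[kc + rad + 1] *
        img[reflect(r + kr, nr), reflect(c + kc, nc)]
    }
    out[r, c] <- acc
  }
  out
}

disk_mask <- function(h, w, r0, c0, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - r0)^2 + (cc - c0)^2 <= radius^2
}

square_mask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

ellipse_mask <- function(h, w, r0, c0, a1, a2, theta = 0) {
  rr <- matrix(seq_len(h), h, w) - r0
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - c0
  u <- rr * cos(theta) + cc * sin(theta)
  v <- -rr * sin(theta) + cc * cos(theta)
  (u / a1)^2 + (v / a2)^2 <= 1
}

# hand-assembled shape summary for the tabulated cluster-index fixtures
make_shape_set <- function(n_clusters, mean_area, mean_perimeter,
                           mean_pair_distance, h, w) {
  structure(list(frame_index = 0L, shapes = NULL, n_clusters = n_clusters,
                 mean_area = mean_area, mean_perimeter = mean_perimeter,
                 mean_pair_distance = mean_pair_distance,
                 frame_height_px = h, frame_width_px = w,
                 valid = n_clusters >= 2, mask = NULL),
            class = "frame_shape_set")
}

# two-blob frame for small end-to-end pipeline fixtures
two_blob_frame <- function(index, h = 60, w = 100, shift = c(0, 0)) {
  m <- matrix(200, h, w)
  m[(6:13) + shift[1], (6:13) + shift[2]] <- 50
  m[(h - 13):(h - 6) + shift[1], (w - 13):(w - 6) + shift[2]] <- 50
  frame_record(m, index = index, timestamp_s = index)
}

random_mask <- function(h, w, p = 0.2) {
  matrix(runif(h * w) < p, h, w)
}

# hand-built index_series (bypasses segmentation) for aggregation tests
fake_index_series <- function(cluster_values, unrest_values = NULL,
                              cluster_valid = NULL, unrest_valid = NULL) {
  n <- length(cluster_values)
  if (is.null(unrest_values)) unrest_values <- rep(1, n - 1L)
  if (is.null(cluster_valid)) cluster_valid <- !is.na(cluster_values)
  if (is.null(unrest_valid)) unrest_valid <- !is.na(unrest_values)
  structure(list(
    cluster = data.frame(frame_index = seq_len(n) - 1L,
                         timestamp_s = seq_len(n) - 1,
                         cluster_index = cluster_values,
                         valid = cluster_valid),
    unrest = data.frame(frame_index = seq_len(n)[-1L] - 1L,
                        timestamp_s = seq_len(n)[-1L] - 1,
                        unrest_cm = unrest_values, valid = unrest_valid),
    params_fingerprint = "fixture", sample_rate_fps = 1),
    class = "index_series")
}

# split-plot block table with known effects, for the ANOVA simulations
synth_blocks <- function(n_blocks = 14, temp_effect = 0, enrich_effect = 0,
                         block_sd = 1, noise_sd = 1) {
  block_eff <- rnorm(n_blocks, 0, block_sd)
  grid <- expand.grid(block_id = seq_len(n_blocks),
                      temperature = c("comfort", "heat_stress"),
                      enrichment = c("enriched", "nonenriched"),
                      stringsAsFactors = FALSE)
  y <- 50 + block_eff[grid$block_id] +
    ifelse(grid$temperature == "comfort", temp_effect / 2, -temp_effect / 2) +
    ifelse(grid$enrichment == "enriched", enrich_effect / 2,
           -enrich_effect / 2) +
    rnorm(nrow(grid), 0, noise_sd)
  data.frame(grid, mean_cluster = y, mean_unrest = y,
             n_valid_frames = 100L, n_valid_pairs = 99L)
}

# the scaled study conditions used by the regime-recovery suites:
# 14 blocks of 30 s per condition at half camera resolution
scaled_design <- function() {
  experiment_design(block_duration_min = 0.5, session_hours = 14 * 0.5 / 60)
}

scaled_arena <- c(248, 488)

# memoised 20-replicate pipeline run shared between the synthetic-module
# invariant tests and the acceptance suite
.recovery_cache <- new.env(parent = emptyenv())

regime_recovery_runs <- function(n_seeds = 20) {
  key <- paste0("runs_", n_seeds)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  runs <- lapply(seq_len(n_seeds), function(s) {
    simulate_experiment(seed = s, design = scaled_design(),
                        arena_px = scaled_arena)
  })
  .recovery_cache[[key]] <- runs
  runs
}

regime_mean <- function(run, regime, what) {
  cm <- run$condition_means
  cm[[what]][cm$regime == regime]
}
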