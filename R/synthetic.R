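#' Synthetic flock-scene configuration
#'
#' Parameters of the ground-truthed scene generator: an arena of litter at
#' `litter_intensity` with `n_birds` dark ellipses, speck noise, attractor
#' points (drinker, feeder, enrichment objects) that pull movement with
#' weight `crowding_strength`, and per-second displacement magnitudes drawn
#' around `step_cm_per_s`. All randomness flows from `seed` (one stream for
#' the walk, `seed + 1` for rendering noise), so identical configurations
#' reproduce identical scenes.
#'
#' @param arena_px `c(height, width)` of the frame, default `c(496, 976)`.
#' @param n_birds number of birds, default 10.
#' @param bird_axes_px ellipse semi-axes in pixels, default `c(21, 13)`
#'   (a 21-day broiler of roughly 15 x 9 cm seen at 0.355 cm/px).
#' @param bird_intensity,litter_intensity grayscale levels in \[0, 255\];
#'   must differ (default dark birds 60 on light litter 200).
#' @param attractors numeric matrix with columns `row`, `col`, `weight`:
#'   pull points such as the drinker, feeder and enrichment objects.
#' @param crowding_strength mixing weight in \[0, 1\] of the
#'   attractor-directed movement component (0 = pure random walk).
#' @param step_cm_per_s mean per-second displacement of a moving bird, cm.
#' @param step_dispersion coefficient of variation of step magnitudes.
#' @param sit_probability probability a bird does not move in a given
#'   second, in \[0, 1\].
#' @param noise_speck_density expected fraction of pixels per frame covered
#'   by single-pixel litter specks (feathers, shavings).
#' @param geometry a [camera_geometry] providing the cm/px factor used to
#'   convert `step_cm_per_s` to pixels; default is a 3-m ceiling camera
#'   with a 60-degree lens over the arena width (k of about 0.355 cm/px at
#'   full resolution).
#' @param seed integer seed.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(arena_px = c(496, 976), n_birds = 10,
                         bird_axes_px = c(21, 13), bird_intensity = 60,
                         litter_intensity = 200, attractors = NULL,
                         crowding_strength = 0.15, step_cm_per_s = 10,
                         step_dispersion = 0.35, sit_probability = 0.1,
                         noise_speck_density = 1e-4, geometry = NULL,
                         seed = 1L) {
  if (n_birds < 1L) stop_input("n_birds must be >= 1")
  if (crowding_strength < 0 || crowding_strength > 1)
    stop_input("crowding_strength must lie in [0, 1]")
  if (sit_probability < 0 || sit_probability > 1)
    stop_input("sit_probability must lie in [0, 1]")
  if (bird_intensity == litter_intensity)
    stop_input("bird and litter intensities must be distinct")
  if (is.null(geometry))
    geometry <- camera_geometry(300, 60, arena_px[2])
  if (is.null(attractors))
    attractors <- default_attractors(arena_px, enriched = FALSE)
  colnames(attractors) <- c("row", "col", "weight")
  margin <- max(bird_axes_px) + 1
  if (arena_px[1] <= 2 * margin || arena_px[2] <= 2 * margin)
    stop_input("arena too small for the configured bird size")
  need <- n_birds * pi * prod(bird_axes_px) * 4
  if (need > prod(arena_px))
    stop_input("arena too small for non-overlapping placement of ",
               n_birds, " birds")
  structure(list(arena_px = as.integer(arena_px), n_birds = as.integer(n_birds),
                 bird_axes_px = bird_axes_px, bird_intensity = bird_intensity,
                 litter_intensity = litter_intensity, attractors = attractors,
                 crowding_strength = crowding_strength,
                 step_cm_per_s = step_cm_per_s,
                 step_dispersion = step_dispersion,
                 sit_probability = sit_probability,
                 noise_speck_density = noise_speck_density,
                 geometry = geometry, seed = as.integer(seed)),
            class = "scene_config")
}

default_attractors <- function(arena_px, enriched) {
  h <- arena_px[1]; w <- arena_px[2]
  base <- rbind(c(0.30 * h, 0.22 * w, 1),  # drinker
                c(0.72 * h, 0.20 * w, 1))  # feeder
  if (enriched)
    base <- rbind(base,
                  c(0.35 * h, 0.70 * w, 1),  # hanging rings
                  c(0.68 * h, 0.75 * w, 1),  # sand box
                  c(0.50 * h, 0.55 * w, 1))  # perch
  colnames(base) <- c("row", "col", "weight")
  base
}

# Preset movement/crowding parameters per regime. Chosen once to encode the
# qualitative regime orderings (comfort moves more than heat stress within
# each enrichment level; enriched moves more than plain within each
# temperature; heat stress crowds at least as strongly as comfort), not any
# absolute index value.
regime_table <- list(
  comfort_enriched = list(step = 12.0, sit = 0.10, crowd = 0.15,
                          enriched = TRUE),
  comfort_plain    = list(step = 9.0,  sit = 0.15, crowd = 0.15,
                          enriched = FALSE),
  stress_enriched  = list(step = 5.0,  sit = 0.45, crowd = 0.55,
                          enriched = TRUE),
  stress_plain     = list(step = 3.5,  sit = 0.55, crowd = 0.60,
                          enriched = FALSE))

#' Scene presets for the four temperature x enrichment regimes
#'
#' Returns a ready [scene_config] for one of `comfort_enriched`,
#' `comfort_plain`, `stress_enriched`, `stress_plain`. All four share the
#' arena, 10 birds and bird geometry; they differ in mean step length
#' (comfort > stress within enrichment level, enriched > plain within
#' temperature), sit probability (highest for `stress_plain`), crowding
#' strength (stress >= comfort) and attractor layout (enriched presets add
#' the rings, sand box and perch to the drinker and feeder).
#'
#' Bird ellipse axes scale with the arena so that the physical bird size
#' (semi-axes 7.5 x 4.5 cm) is constant under the camera model
#' (H = 300 cm, alpha = 60 degrees, sensor = arena width).
#'
#' @param name regime name.
#' @param arena_px `c(height, width)`; default full camera resolution.
#' @param seed integer seed.
#' @return A [scene_config].
#' @export
regime_preset <- function(name = c("comfort_enriched", "comfort_plain",
                                   "stress_enriched", "stress_plain"),
                          arena_px = c(496, 976), seed = 1L) {
  name <- match.arg(name)
  p <- regime_table[[name]]
  geometry <- camera_geometry(300, 60, arena_px[2])
  k <- calibration_factor(geometry)
  axes <- pmax(round(c(7.5, 4.5) / k), 2)
  cfg <- scene_config(
    arena_px = arena_px, n_birds = 10, bird_axes_px = axes,
    attractors = default_attractors(arena_px, p$enriched),
    crowding_strength = p$crowd, step_cm_per_s = p$step,
    step_dispersion = 0.35, sit_probability = p$sit,
    geometry = geometry, seed = seed)
  cfg$regime <- name
  cfg
}

#' Simulate ground-truth bird tracks
#'
#' Bounded random walk with attractor blending: each second every bird
#' moves with probability `1 - sit_probability`, taking a step whose
#' magnitude is drawn from a truncated normal with mean
#' `step_cm_per_s / k` pixels and coefficient of variation
#' `step_dispersion`, in a direction blending a uniform random unit vector
#' with the unit vector toward its nearest attractor (weight
#' `crowding_strength`). Positions are clipped to the arena (one bird
#' semi-major axis of margin). Initial placement is non-overlapping;
#' overlap during motion is allowed -- merged blobs are the crowding
#' signal. Fully reproducible from `config$seed`.
#'
#' @param config a [scene_config].
#' @param duration_s number of simulated seconds (>= 1).
#' @return An object of class `flock_track`: numeric array
#'   `(duration_s + 1) x n_birds x 2` of (row, col) centres, with the
#'   regime label (if any) and `config` as attributes.
#' @export
simulate_flock <- function(config, duration_s) {
  stopifnot(inherits(config, "scene_config"))
  if (duration_s < 1L) stop_input("duration_s must be >= 1")
  k <- calibration_factor(config$geometry)
  mu_px <- config$step_cm_per_s / k
  n <- config$n_birds
  margin <- max(config$bird_axes_px) + 1
  lo <- c(margin, margin)
  hi <- c(config$arena_px[1] - margin, config$arena_px[2] - margin)
  att <- config$attractors
  withr::with_seed(config$seed, {
    # non-overlapping initial placement (rejection sampling)
    sep <- 2 * max(config$bird_axes_px)
    pos <- matrix(NA_real_, n, 2)
    placed <- 0L
    tries <- 0L
    while (placed < n) {
      cand <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
      ok <- placed == 0L ||
        min(sqrt(rowSums(sweep(pos[seq_len(placed), , drop = FALSE], 2,
                               cand)^2))) >= sep
      if (ok) {
        placed <- placed + 1L
        pos[placed, ] <- cand
      }
      tries <- tries + 1L
      if (tries > 10000L * n)
        stop_input("arena too small for non-overlapping placement")
    }
    track <- array(NA_real_, c(duration_s + 1L, n, 2L))
    track[1, , ] <- pos
    for (t in seq_len(duration_s)) {
      moving <- runif(n) >= config$sit_probability
      mag <- pmax(rnorm(n, mu_px, config$step_dispersion * mu_px), 0)
      ang <- runif(n, 0, 2 * pi)
      rand_dir <- cbind(sin(ang), cos(ang))
      # unit vector toward each bird's nearest attractor
      att_dir <- t(vapply(seq_len(n), function(b) {
        d2 <- (att[, "row"] - pos[b, 1])^2 + (att[, "col"] - pos[b, 2])^2
        a <- att[which.min(d2 / att[, "weight"]), c("row", "col")]
        v <- a - pos[b, ]
        nv <- sqrt(sum(v^2))
        if (nv < 1e-9) c(0, 0) else v / nv
      }, numeric(2)))
      dir <- (1 - config$crowding_strength) * rand_dir +
        config$crowding_strength * att_dir
      nrm <- sqrt(rowSums(dir^2))
      zero <- nrm < 1e-9
      dir[zero, ] <- rand_dir[zero, ]
      nrm[zero] <- 1
      dir <- dir / nrm
      pos <- pos + (moving * mag) * dir
      pos[, 1] <- pmin(pmax(pos[, 1], lo[1]), hi[1])
      pos[, 2] <- pmin(pmax(pos[, 2], lo[2]), hi[2])
      track[t + 1L, , ] <- pos
    }
    structure(track, regime = config$regime, config = config,
              class = c("flock_track", "array"))
  })
}

#' Render ground-truth tracks into a grayscale frame sequence
#'
#' One frame per track time point: litter background, single-pixel speck
#' noise (binomially many specks at `noise_speck_density`, at the bird
#' intensity -- feathers on the bedding), then one filled ellipse per bird
#' at the bird intensity. Ellipse orientations are fixed per bird
#' (deterministic, evenly spread). Noise is reproducible from
#' `config$seed + 1`.
#'
#' @param track a [simulate_flock()] result.
#' @param config the same [scene_config] used for the simulation.
#' @return A [frame_sequence] at 1 frame per second.
#' @export
render_frames <- function(track, config) {
  stopifnot(inherits(track, "flock_track"), inherits(config, "scene_config"))
  h <- config$arena_px[1]; w <- config$arena_px[2]
  n <- config$n_birds
  a1 <- config$bird_axes_px[1]; a2 <- config$bird_axes_px[2]
  rad <- ceiling(max(a1, a2))
  theta <- (seq_len(n) - 1) * pi / n
  ct <- cos(theta); st <- sin(theta)
  nt <- dim(track)[1]
  withr::with_seed(config$seed + 1L, {
    frames <- vector("list", nt)
    for (t in seq_len(nt)) {
      m <- matrix(config$litter_intensity, h, w)
      nspeck <- rbinom(1, h * w, config$noise_speck_density)
      if (nspeck > 0)
        m[sample.int(h * w, nspeck)] <- config$bird_intensity
      for (b in seq_len(n)) {
        r0 <- track[t, b, 1]; c0 <- track[t, b, 2]
        rr <- max(1, floor(r0 - rad)):min(h, ceiling(r0 + rad))
        cc <- max(1, floor(c0 - rad)):min(w, ceiling(c0 + rad))
        dr <- outer(rr - r0, rep(1, length(cc)))
        dc <- outer(rep(1, length(rr)), cc - c0)
        u <- dr * ct[b] + dc * st[b]
        v <- -dr * st[b] + dc * ct[b]
        inside <- (u / a1)^2 + (v / a2)^2 <= 1
        m[rr, cc][inside] <- config$bird_intensity
      }
      frames[[t]] <- frame_record(m, index = t - 1L, timestamp_s = t - 1)
    }
    frame_sequence(frames, sample_rate_fps = 1)
  })
}

#' Write a ground-truth track as CSV
#'
#' Columns `t`, `bird_id`, `row`, `col` (pixels).
#'
#' @param track a [simulate_flock()] result.
#' @param path output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_track_csv <- function(track, path) {
  nt <- dim(track)[1]; n <- dim(track)[2]
  tab <- data.frame(t = rep(seq_len(nt) - 1L, each = n),
                    bird_id = rep(seq_len(n), nt),
                    row = as.vector(t(track[, , 1])),
                    col = as.vector(t(track[, , 2])))
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Simulate, render and analyse a full four-regime experiment
#'
#' For each regime preset: simulate tracks for one session of the given
#' design, render frames, run the full index pipeline, and average into
#' blocks. The default segmentation for synthetic scenes thresholds the
#' raw frame globally with Otsu (the scenes are bimodal by construction).
#' Per-regime seeds are derived as `seed * 4 + regime position`.
#'
#' @param seed integer base seed.
#' @param design an [experiment_design]; scale `session_hours` /
#'   `block_duration_min` down for quick studies.
#' @param arena_px frame size passed to [regime_preset()].
#' @param seg_params segmentation parameters; default global Otsu, dark
#'   polarity, blobs under 25 px removed.
#' @param point_mode unrest point sets, see [unrest_index()].
#' @param variant cluster-index variant, see [cluster_index()].
#' @return List: `blocks` (row-bound [block_averages()] for all four
#'   conditions), `condition_means` (per regime: mean cluster and unrest),
#'   `regimes` (the preset names).
#' @export
simulate_experiment <- function(seed = 1L, design = experiment_design(),
                                arena_px = c(496, 976),
                                seg_params = NULL,
                                point_mode = "foreground_pixels",
                                variant = "nA_minus_1") {
  if (is.null(seg_params))
    seg_params <- segmentation_params(
      lowpass_sigma = 1, background_method = "global_threshold",
      threshold_method = "otsu", min_blob_area_px = 25,
      fill_holes = TRUE, connectivity = 8, polarity = "dark")
  regimes <- names(regime_table)
  labels <- list(comfort_enriched = c("comfort", "enriched"),
                 comfort_plain = c("comfort", "nonenriched"),
                 stress_enriched = c("heat_stress", "enriched"),
                 stress_plain = c("heat_stress", "nonenriched"))
  nframes <- frames_per_session(design)
  blocks <- list()
  means <- list()
  for (i in seq_along(regimes)) {
    rg <- regimes[i]
    cfg <- regime_preset(rg, arena_px = arena_px,
                         seed = (seed * 4L + i) %% 214748329L)
    track <- simulate_flock(cfg, nframes - 1L)
    frames <- render_frames(track, cfg)
    series <- compute_index_series(frames, seg_params, cfg$geometry,
                                   variant = variant,
                                   point_mode = point_mode)
    bl <- block_averages(series, design, temperature = labels[[rg]][1],
                         enrichment = labels[[rg]][2])
    blocks[[rg]] <- bl
    means[[rg]] <- data.frame(
      regime = rg, temperature = labels[[rg]][1],
      enrichment = labels[[rg]][2],
      mean_cluster = mean(bl$mean_cluster, na.rm = TRUE),
      mean_unrest = mean(bl$mean_unrest, na.rm = TRUE))
  }
  list(blocks = do.call(rbind, c(blocks, make.row.names = FALSE)),
       condition_means = do.call(rbind, c(means, make.row.names = FALSE)),
       regimes = regimes)
}
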