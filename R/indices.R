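#' Camera geometry and the cm-per-pixel proportionality factor
#'
#' Converts pixel displacements to centimetres from the camera mounting:
#' `k = 2 * H * tan(alpha/2) / w`, where `H` is the camera height above the
#' floor (cm), `alpha` the lens opening angle (degrees), and `w` the sensor
#' length in pixels along the longest frame dimension.
#'
#' @param mount_height_cm camera height above the floor, cm (> 0).
#' @param lens_angle_deg lens opening angle in degrees, in (0, 180).
#' @param sensor_length_px sensor length in pixels (> 0), the longest frame
#'   dimension.
#' @return An object of class `camera_geometry` with the inputs plus the
#'   derived `k_cm_per_px`.
#' @export
camera_geometry <- function(mount_height_cm, lens_angle_deg,
                            sensor_length_px) {
  if (mount_height_cm <= 0) stop_input("mount_height_cm must be positive")
  if (lens_angle_deg <= 0 || lens_angle_deg >= 180)
    stop_input("lens_angle_deg must lie strictly between 0 and 180 degrees")
  if (sensor_length_px <= 0) stop_input("sensor_length_px must be positive")
  g <- list(mount_height_cm = mount_height_cm,
            lens_angle_deg = lens_angle_deg,
            sensor_length_px = sensor_length_px)
  g$k_cm_per_px <- 2 * mount_height_cm *
    tan(lens_angle_deg * pi / 360) / sensor_length_px
  structure(g, class = "camera_geometry")
}

#' @export
print.camera_geometry <- function(x, ...) {
  cat(sprintf("camera_geometry: H = %g cm, alpha = %g deg, w = %g px -> k = %.5f cm/px\n",
              x$mount_height_cm, x$lens_angle_deg, x$sensor_length_px,
              x$k_cm_per_px))
  invisible(x)
}

#' Proportionality factor of a camera geometry
#'
#' @param geometry a [camera_geometry] object.
#' @return `k` in cm per pixel.
#' @export
calibration_factor <- function(geometry) {
  stopifnot(inherits(geometry, "camera_geometry"))
  geometry$k_cm_per_px
}

as_point_matrix <- function(x, arg) {
  if (is.logical(x) || (is.matrix(x) && ncol(x) != 2L))
    stop_input("`", arg, "` must be an n x 2 matrix of (row, col) points")
  x <- as.matrix(x)
  if (!is.numeric(x) || ncol(x) != 2L)
    stop_input("`", arg, "` must be an n x 2 matrix of (row, col) points")
  if (nrow(x) == 0L)
    stop_input("Hausdorff distance is undefined for an empty point set (`",
               arg, "`); flag the frame pair instead")
  x
}

#' Directed Hausdorff distance between point sets
#'
#' `max` over points of `A` of the distance to the nearest point of `B`
#' (Euclidean).
#'
#' @param A,B numeric `n x 2` matrices of (row, col) points; non-empty.
#' @return Distance in pixels.
#' @export
directed_hausdorff <- function(A, B) {
  cpp_directed_hausdorff(as_point_matrix(A, "A"), as_point_matrix(B, "B"))
}

#' Symmetric Hausdorff distance between point sets
#'
#' `max` of the two directed distances; symmetric in its arguments.
#'
#' @inheritParams directed_hausdorff
#' @return Distance in pixels.
#' @export
symmetric_hausdorff <- function(A, B) {
  A <- as_point_matrix(A, "A")
  B <- as_point_matrix(B, "B")
  max(cpp_directed_hausdorff(A, B), cpp_directed_hausdorff(B, A))
}

mask_centroids <- function(mask, connectivity = 8L) {
  lab <- cpp_label(mask, connectivity)
  nlab <- attr(lab, "n_labels")
  if (nlab == 0L) return(matrix(numeric(), 0L, 2L))
  st <- cpp_component_stats(lab, nlab)
  cbind(st$centroid_row, st$centroid_col)
}

#' Unrest index between two consecutive frames
#'
#' The movement of the flock between two frames one sampling interval
#' apart, in cm: `k` times the symmetric Hausdorff distance between the
#' bird point sets of the two binary masks. With
#' `point_mode = "foreground_pixels"` (default, the literal reading) the
#' point sets are all foreground pixels and the distance is computed
#' through an exact Euclidean distance transform; `"centroids"` uses one
#' point per blob and is much faster.
#'
#' @param mask_curr,mask_prev logical masks of identical size.
#' @param k proportionality factor in cm/pixel (see
#'   [calibration_factor()]).
#' @param point_mode `"foreground_pixels"` or `"centroids"`.
#' @return Unrest in cm, or `NA` (flagged missing, never zero) when either
#'   mask has no foreground.
#' @export
unrest_index <- function(mask_curr, mask_prev, k,
                         point_mode = c("foreground_pixels", "centroids")) {
  point_mode <- match.arg(point_mode)
  if (!all(dim(mask_curr) == dim(mask_prev)))
    stop_input("masks must share dimensions")
  if (!is.logical(mask_curr)) storage.mode(mask_curr) <- "logical"
  if (!is.logical(mask_prev)) storage.mode(mask_prev) <- "logical"
  if (point_mode == "foreground_pixels") {
    d <- cpp_hausdorff_masks(mask_curr, mask_prev)
    return(if (is.na(d)) NA_real_ else k * d)
  }
  a <- mask_centroids(mask_curr)
  b <- mask_centroids(mask_prev)
  if (nrow(a) == 0L || nrow(b) == 0L) return(NA_real_)
  k * symmetric_hausdorff(a, b)
}

#' Cluster index of a segmented frame
#'
#' Per-frame crowding statistic
#' `2 * A * sqrt(h^2 + w^2) / (P * D * (n_A - 1))`, where `A`, `P` are the
#' mean blob area and perimeter (pixels), `D` the mean inter-centroid
#' distance, `n_A` the number of blobs, and `h`, `w` the frame dimensions.
#' Fewer, larger, closer blobs give higher values. The denominator term is
#' `n_A - 1` by default; `variant = "nA_inverse"` uses `n_A`. Frames with
#' fewer than two blobs have no defined inter-centroid distance and return
#' `NA` (flagged invalid) under both variants. `use_diagonal = FALSE`
#' replaces the frame diagonal `sqrt(h^2 + w^2)` by `h^2 + w^2`.
#'
#' @param shape_set a [extract_shapes()] result.
#' @param variant `"nA_minus_1"` (default) or `"nA_inverse"`.
#' @param use_diagonal logical; default `TRUE` (dimensionally consistent:
#'   the index scales linearly under spatial rescaling).
#' @return Dimensionless index, or `NA` for invalid frames.
#' @export
cluster_index <- function(shape_set,
                          variant = c("nA_minus_1", "nA_inverse"),
                          use_diagonal = TRUE) {
  variant <- match.arg(variant)
  stopifnot(inherits(shape_set, "frame_shape_set"))
  n <- shape_set$n_clusters
  if (n < 2L) return(NA_real_)
  if (shape_set$mean_perimeter <= 0 || shape_set$mean_pair_distance <= 0)
    stop_input("invalid shapes: non-positive mean perimeter or distance")
  sq <- shape_set$frame_height_px^2 + shape_set$frame_width_px^2
  num <- 2 * shape_set$mean_area * (if (use_diagonal) sqrt(sq) else sq)
  den <- shape_set$mean_perimeter * shape_set$mean_pair_distance *
    (if (variant == "nA_minus_1") n - 1 else n)
  num / den
}

#' Compute cluster and unrest index series for a frame sequence
#'
#' Runs the full per-frame pipeline: low-pass filter, background estimate
#' (per `seg_params$background_method`), foreground segmentation, mask
#' clean-up, shape extraction, then the cluster index per frame and the
#' unrest index per consecutive frame pair. Invalid frames (fewer than two
#' blobs for the cluster index; empty foreground for the unrest index) are
#' flagged, never silently dropped. Pure: identical inputs and parameters
#' give bit-identical output, fingerprinted in `params_fingerprint`.
#'
#' @param frames a [frame_sequence] with at least two frames.
#' @param seg_params a [segmentation_params] object.
#' @param geometry a [camera_geometry] object.
#' @param variant cluster-index variant, see [cluster_index()].
#' @param point_mode unrest point sets, see [unrest_index()].
#' @param use_diagonal see [cluster_index()].
#' @return An object of class `index_series`: `cluster` (data frame
#'   `frame_index`, `timestamp_s`, `cluster_index`, `valid`), `unrest`
#'   (data frame `frame_index`, `timestamp_s`, `unrest_cm`, `valid`, one
#'   row per consecutive frame pair, indexed by the later frame),
#'   `params_fingerprint`, `sample_rate_fps`.
#' @export
compute_index_series <- function(frames, seg_params = segmentation_params(),
                                 geometry,
                                 variant = c("nA_minus_1", "nA_inverse"),
                                 point_mode = c("foreground_pixels",
                                                "centroids"),
                                 use_diagonal = TRUE) {
  variant <- match.arg(variant)
  point_mode <- match.arg(point_mode)
  stopifnot(inherits(frames, "frame_sequence"),
            inherits(geometry, "camera_geometry"))
  n <- length(frames$frames)
  if (n < 2L) stop_input("need at least two frames")
  k <- calibration_factor(geometry)

  filtered <- lapply(frames$frames, lowpass_filter,
                     sigma = seg_params$lowpass_sigma)
  background <- switch(seg_params$background_method,
    median_of_sequence = estimate_background(
      frame_sequence(filtered, frames$sample_rate_fps)),
    fixed_image = seg_params$fixed_background,
    global_threshold = NULL)

  idx <- vapply(frames$frames, function(f) f$index, integer(1))
  ts <- vapply(frames$frames, function(f) f$timestamp_s, numeric(1))
  cluster_vals <- numeric(n)
  cluster_ok <- logical(n)
  unrest_vals <- rep(NA_real_, n - 1L)
  unrest_ok <- logical(n - 1L)
  prev_mask <- NULL
  for (i in seq_len(n)) {
    mask <- clean_mask(
      segment_foreground(filtered[[i]], background, seg_params), seg_params)
    ss <- extract_shapes(mask, seg_params$connectivity, idx[i])
    ci <- cluster_index(ss, variant, use_diagonal)
    cluster_vals[i] <- ci
    cluster_ok[i] <- !is.na(ci)
    if (i > 1L) {
      u <- unrest_index(mask, prev_mask, k, point_mode)
      unrest_vals[i - 1L] <- u
      unrest_ok[i - 1L] <- !is.na(u)
    }
    prev_mask <- mask
  }
  if (!any(cluster_ok) && !any(unrest_ok))
    stop_input("all frames invalid: no index values could be computed")
  fp <- params_fingerprint(
    seg = unclass(seg_params)[setdiff(names(seg_params), "fixed_background")],
    geometry = unclass(geometry), variant = variant,
    point_mode = point_mode, use_diagonal = use_diagonal,
    sample_rate_fps = frames$sample_rate_fps)
  structure(list(
    cluster = data.frame(frame_index = idx, timestamp_s = ts,
                         cluster_index = cluster_vals, valid = cluster_ok),
    unrest = data.frame(frame_index = idx[-1L], timestamp_s = ts[-1L],
                        unrest_cm = unrest_vals, valid = unrest_ok),
    params_fingerprint = fp,
    sample_rate_fps = frames$sample_rate_fps), class = "index_series")
}

#' @export
print.index_series <- function(x, ...) {
  cat(sprintf(paste0("index_series: %d cluster values (%d valid), ",
                     "%d unrest values (%d valid)\n"),
              nrow(x$cluster), sum(x$cluster$valid),
              nrow(x$unrest), sum(x$unrest$valid)))
  invisible(x)
}

#' Export an index series as CSV
#'
#' One row per frame: `frame_index`, `timestamp_s`, `cluster_index`,
#' `cluster_valid`, `unrest_cm`, `unrest_valid` (unrest columns are `NA`
#' for the first frame, which has no predecessor).
#'
#' @param series an [compute_index_series()] result.
#' @param path output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_index_csv <- function(series, path) {
  tab <- merge(
    setNames(series$cluster,
             c("frame_index", "timestamp_s", "cluster_index", "cluster_valid")),
    setNames(series$unrest[, c("frame_index", "unrest_cm", "valid")],
             c("frame_index", "unrest_cm", "unrest_valid")),
    by = "frame_index", all.x = TRUE)
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Read pipeline configuration from a YAML file
#'
#' A single key-value file with two top-level sections: `geometry`
#' (`mount_height_cm`, `lens_angle_deg`, `sensor_length_px`) and
#' `segmentation` (any arguments of [segmentation_params()]).
#'
#' @param path YAML file path.
#' @return List with `$geometry` ([camera_geometry]) and `$segmentation`
#'   ([segmentation_params]).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$geometry))
    stop_input("config file must contain a `geometry` section")
  geom <- do.call(camera_geometry, cfg$geometry)
  seg <- do.call(segmentation_params, cfg$segmentation %||% list())
  list(geometry = geom, segmentation = seg)
}
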