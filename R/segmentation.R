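#' Segmentation parameters
#'
#' Bundles every knob of the bird-segmentation stage. The defaults are the
#' package's reference configuration: light Gaussian low-pass smoothing
#' (litter specks, feathers), temporal-median background subtraction with an
#' Otsu threshold on the absolute difference, hole filling, removal of blobs
#' under 25 px, and 8-connected foreground (birds touching diagonally merge
#' into one cluster, which is exactly the crowding signal).
#'
#' @param lowpass_sigma Gaussian smoothing scale in pixels (>= 0; 0 disables).
#' @param background_method one of `"median_of_sequence"` (pixel-wise
#'   temporal median), `"fixed_image"` (user-supplied background in
#'   `fixed_background`), or `"global_threshold"` (threshold the raw frame
#'   directly; appropriate when birds and litter are well separated in
#'   intensity).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold intensity in \[0, 255\]; required iff
#'   `threshold_method = "fixed"`.
#' @param min_blob_area_px connected components smaller than this are
#'   removed as noise (default 25).
#' @param fill_holes fill enclosed background holes before area filtering.
#' @param connectivity foreground connectivity, 4 or 8 (default 8); the
#'   hole-filling complement always uses 4.
#' @param polarity `"dark"` if birds are darker than litter (default) or
#'   `"light"`; only consulted by `"global_threshold"` segmentation, since
#'   background subtraction works on absolute differences.
#' @param fixed_background optional background intensity matrix used when
#'   `background_method = "fixed_image"`.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(lowpass_sigma = 1,
                                background_method = c("median_of_sequence",
                                                      "fixed_image",
                                                      "global_threshold"),
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_blob_area_px = 25L,
                                fill_holes = TRUE,
                                connectivity = 8L,
                                polarity = c("dark", "light"),
                                fixed_background = NULL) {
  background_method <- match.arg(background_method)
  threshold_method <- match.arg(threshold_method)
  polarity <- match.arg(polarity)
  if (lowpass_sigma < 0) stop_input("lowpass_sigma must be >= 0")
  if (min_blob_area_px < 0) stop_input("min_blob_area_px must be >= 0")
  if (!connectivity %in% c(4L, 8L)) stop_input("connectivity must be 4 or 8")
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop_input("fixed_threshold is required when threshold_method = 'fixed'")
  if (threshold_method != "fixed" && !is.null(fixed_threshold))
    stop_input("fixed_threshold must be NULL unless threshold_method = 'fixed'")
  structure(list(lowpass_sigma = lowpass_sigma,
                 background_method = background_method,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_blob_area_px = as.integer(min_blob_area_px),
                 fill_holes = isTRUE(fill_holes),
                 connectivity = as.integer(connectivity),
                 polarity = polarity,
                 fixed_background = fixed_background),
            class = "segmentation_params")
}

#' Gaussian low-pass filter
#'
#' Separable Gaussian smoothing (kernel radius `ceil(3*sigma)`, mirror
#' boundary) used to suppress litter-speck noise before thresholding.
#' `sigma = 0` returns the input unchanged, bit for bit.
#'
#' @param frame a [frame_record] or a plain intensity matrix.
#' @param sigma smoothing scale in pixels (>= 0).
#' @return Same type as the input.
#' @export
lowpass_filter <- function(frame, sigma) {
  if (sigma < 0) stop_input("sigma must be >= 0")
  if (inherits(frame, "frame_record")) {
    if (sigma == 0) return(frame)
    out <- frame
    out$pixels <- cpp_gauss_blur(frame$pixels, sigma)
    return(out)
  }
  if (sigma == 0) return(frame)
  cpp_gauss_blur(frame, sigma)
}

#' Estimate the static background of a frame sequence
#'
#' Pixel-wise temporal median over (a subsample of) the sequence, or the
#' user-supplied image. The median is robust wherever each pixel shows
#' litter in more than half of the sampled frames.
#'
#' @param sequence a [frame_sequence] (>= 3 frames recommended for the
#'   median).
#' @param method `"median_of_sequence"` or `"fixed_image"`.
#' @param fixed_image background matrix, required for `"fixed_image"`.
#' @param max_frames at most this many evenly spaced frames enter the
#'   median (default 25), keeping the estimate O(pixels).
#' @return Background intensity matrix.
#' @export
estimate_background <- function(sequence,
                                method = c("median_of_sequence",
                                           "fixed_image"),
                                fixed_image = NULL, max_frames = 25L) {
  method <- match.arg(method)
  if (method == "fixed_image") {
    if (is.null(fixed_image)) stop_input("fixed_image is required")
    return(fixed_image)
  }
  n <- length(sequence$frames)
  if (n == 0L) stop_input("cannot estimate a background from an empty sequence")
  pick <- unique(round(seq(1L, n, length.out = min(n, max_frames))))
  f1 <- sequence$frames[[1]]
  stack <- vapply(pick, function(i) as.vector(sequence$frames[[i]]$pixels),
                  numeric(f1$height_px * f1$width_px))
  if (is.null(dim(stack))) stack <- matrix(stack, ncol = 1L)
  matrix(cpp_median_stack(stack), nrow = f1$height_px, ncol = f1$width_px)
}

#' Otsu threshold of an intensity image
#'
#' Maximises between-class variance over a 256-bin histogram of \[0, 255\]
#' intensities; returns the bin value `t` such that `> t` separates the
#' upper class.
#'
#' @param x numeric matrix or vector of intensities in \[0, 255\].
#' @return Threshold on the \[0, 255\] scale.
#' @export
otsu_threshold <- function(x) {
  b <- pmin(pmax(floor(as.numeric(x)), 0), 255)
  counts <- tabulate(b + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    stop_input("degenerate histogram: image is constant, Otsu thresholding ",
               "is undefined. Use threshold_method = 'fixed' or check that ",
               "the frame differs from the background.")
  p <- counts / sum(counts)
  lev <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[256]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  lev[which.max(sb2)]
}

#' Segment bird foreground from a frame
#'
#' For background-subtraction methods the absolute difference
#' `|frame - background|` is thresholded (Otsu or fixed); for
#' `"global_threshold"` the raw frame is thresholded directly with the
#' configured polarity (dark birds below, light birds above the threshold).
#'
#' @param frame a [frame_record] or intensity matrix.
#' @param background background matrix (ignored for `"global_threshold"`).
#' @param params a [segmentation_params] object.
#' @return Logical matrix: `TRUE` for bird pixels.
#' @export
segment_foreground <- function(frame, background = NULL,
                               params = segmentation_params()) {
  px <- if (inherits(frame, "frame_record")) frame$pixels else frame
  if (params$background_method == "global_threshold") {
    thr <- if (params$threshold_method == "fixed") params$fixed_threshold
           else otsu_threshold(px)
    return(if (params$polarity == "dark") px < thr else px > thr)
  }
  if (is.null(background)) background <- params$fixed_background
  if (is.null(background))
    stop_input("a background image is required for background subtraction")
  if (!all(dim(px) == dim(background)))
    stop_input("frame (", nrow(px), "x", ncol(px), ") and background (",
               nrow(background), "x", ncol(background),
               ") dimensions differ")
  d <- abs(px - background)
  thr <- if (params$threshold_method == "fixed") params$fixed_threshold
         else otsu_threshold(d)
  d > thr
}

#' Morphological clean-up of a binary mask
#'
#' Fills enclosed holes (background components, 4-connected, not touching
#' the border) when `params$fill_holes`, then removes foreground components
#' (under `params$connectivity`) smaller than `params$min_blob_area_px`.
#' Idempotent.
#'
#' @param mask logical matrix.
#' @param params a [segmentation_params] object.
#' @return Cleaned logical matrix.
#' @export
clean_mask <- function(mask, params = segmentation_params()) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (params$fill_holes) mask <- cpp_fill_holes(mask)
  if (params$min_blob_area_px > 0L) {
    lab <- cpp_label(mask, params$connectivity)
    nlab <- attr(lab, "n_labels")
    if (nlab > 0L) {
      st <- cpp_component_stats(lab, nlab)
      keep <- which(st$area >= params$min_blob_area_px)
      mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
    }
  }
  mask
}

#' Extract per-blob shape descriptors from a binary mask
#'
#' Labels connected components and reports for each blob its pixel area,
#' perimeter (Moore contour traversal: orthogonal steps 1, diagonal steps
#' sqrt(2); isolated pixels get perimeter 1 by convention), and centre of
#' mass (1-based row/col). Summary fields feed the cluster index: the number
#' of clusters `n_clusters`, mean area, mean perimeter, and the mean
#' Euclidean distance over all unordered centroid pairs
#' (`mean_pair_distance`, `NA` and `valid = FALSE` when fewer than two
#' blobs are present).
#'
#' @param mask cleaned logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param frame_index index of the originating frame, carried through.
#' @return An object of class `frame_shape_set` with fields `frame_index`,
#'   `shapes` (data frame: `shape_id`, `area_px2`, `perimeter_px`,
#'   `centroid_row`, `centroid_col`), `n_clusters`, `mean_area`,
#'   `mean_perimeter`, `mean_pair_distance`, `frame_height_px`,
#'   `frame_width_px`, `valid`, `mask`.
#' @export
extract_shapes <- function(mask, connectivity = 8L, frame_index = 0L) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  lab <- cpp_label(mask, as.integer(connectivity))
  nlab <- attr(lab, "n_labels")
  if (nlab == 0L) {
    shapes <- data.frame(shape_id = integer(), area_px2 = integer(),
                         perimeter_px = numeric(), centroid_row = numeric(),
                         centroid_col = numeric())
  } else {
    st <- cpp_component_stats(lab, nlab)
    shapes <- data.frame(shape_id = seq_len(nlab), area_px2 = st$area,
                         perimeter_px = st$perimeter,
                         centroid_row = st$centroid_row,
                         centroid_col = st$centroid_col)
  }
  dbar <- if (nlab >= 2L)
    mean(dist(cbind(shapes$centroid_row, shapes$centroid_col)))
  else NA_real_
  structure(list(
    frame_index = as.integer(frame_index),
    shapes = shapes,
    n_clusters = nlab,
    mean_area = if (nlab > 0L) mean(shapes$area_px2) else NA_real_,
    mean_perimeter = if (nlab > 0L) mean(shapes$perimeter_px) else NA_real_,
    mean_pair_distance = dbar,
    frame_height_px = nrow(mask),
    frame_width_px = ncol(mask),
    valid = nlab >= 2L,
    mask = mask), class = "frame_shape_set")
}

#' @export
print.frame_shape_set <- function(x, ...) {
  cat(sprintf(paste0("frame_shape_set (frame %d): n_A = %d, ",
                     "A = %.2f px^2, P = %.2f px, D = %.2f px%s\n"),
              x$frame_index, x$n_clusters, x$mean_area, x$mean_perimeter,
              x$mean_pair_distance,
              if (!x$valid) " [invalid: < 2 blobs]" else ""))
  invisible(x)
}

#' Write shape descriptors for one or more frames to CSV
#'
#' @param shape_sets a `frame_shape_set` or list of them.
#' @param path output CSV path.
#' @return Invisibly, the combined data frame written.
#' @export
write_shape_csv <- function(shape_sets, path) {
  if (inherits(shape_sets, "frame_shape_set")) shape_sets <- list(shape_sets)
  tab <- do.call(rbind, lapply(shape_sets, function(s) {
    if (nrow(s$shapes) == 0L) return(NULL)
    cbind(frame_index = s$frame_index, s$shapes)
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
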