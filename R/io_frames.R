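#' Single sampled video frame
#'
#' A `frame_record` holds one grayscale frame of the down-sampled sequence:
#' its 0-based position `index` in the sampled sequence, its timestamp in
#' seconds from session start (derived from index and sampling rate, never
#' from container metadata), and a `height x width` matrix of intensities in
#' \[0, 255\].
#'
#' @param pixels numeric matrix of grayscale intensities in \[0, 255\];
#'   rows are image rows (top to bottom), columns are image columns.
#' @param index integer >= 0, position in the sampled sequence.
#' @param timestamp_s seconds from session start.
#' @return An object of class `frame_record` with fields `index`,
#'   `timestamp_s`, `pixels`, `height_px`, `width_px`.
#' @export
frame_record <- function(pixels, index = 0L, timestamp_s = 0) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_input("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_input("frame must have positive dimensions")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255)
    stop_input("pixel intensities must lie in [0, 255]")
  structure(
    list(index = as.integer(index), timestamp_s = as.numeric(timestamp_s),
         pixels = pixels, height_px = nrow(pixels), width_px = ncol(pixels)),
    class = "frame_record")
}

#' Ordered sequence of sampled frames
#'
#' @param frames list of [frame_record] objects sharing identical
#'   dimensions, sorted by index.
#' @param sample_rate_fps frames per second after down-sampling (> 0).
#' @param crop_region optional length-4 integer vector
#'   `c(row0, col0, row1, col1)`, 1-based and inclusive, recording the crop
#'   applied when the frames were read.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, sample_rate_fps = 1, crop_region = NULL) {
  if (length(frames) == 0L) stop_input("empty frame sequence")
  if (sample_rate_fps <= 0) stop_input("sample_rate_fps must be positive")
  dims <- vapply(frames, function(f) c(f$height_px, f$width_px), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_input("all frames in a sequence must share identical dimensions")
  idx <- vapply(frames, function(f) f$index, integer(1))
  frames <- frames[order(idx)]
  structure(list(frames = frames, sample_rate_fps = sample_rate_fps,
                 crop_region = crop_region),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  f1 <- x$frames[[1]]
  cat(sprintf("frame_sequence: %d frames, %d x %d px, %.3g fps\n",
              length(x$frames), f1$height_px, f1$width_px,
              x$sample_rate_fps))
  invisible(x)
}

#' Convert a colour frame to grayscale luminance
#'
#' Uses the Rec. 709 luma weights (0.2126 R + 0.7152 G + 0.0722 B),
#' applied identically to every input source so that video-derived and
#' image-directory frames are comparable.
#'
#' @param color_frame numeric array `height x width x 3` with channel
#'   values in \[0, 255\].
#' @return numeric matrix `height x width` in \[0, 255\].
#' @export
to_grayscale <- function(color_frame) {
  if (is.matrix(color_frame)) return(color_frame)
  d <- dim(color_frame)
  if (length(d) != 3L || d[3] != 3L)
    stop_input("colour frames must have exactly 3 channels")
  if (min(color_frame) < 0 || max(color_frame) > 255)
    stop_input("channel values must lie in [0, 255]")
  0.2126 * color_frame[, , 1] + 0.7152 * color_frame[, , 2] +
    0.0722 * color_frame[, , 3]
}

read_one_image <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img) * 255
  # EBImage stores (x = column, y = row); transpose to row-major matrices
  if (length(dim(dat)) == 2L) {
    t(dat)
  } else {
    dat <- aperm(dat, c(2, 1, 3))
    to_grayscale(dat[, , 1:3, drop = FALSE])
  }
}

video_exts <- c("avi", "mp4", "mkv", "mov", "wmv", "h264", "dav")
image_exts <- c("png", "jpg", "jpeg", "tif", "tiff")

#' Read a 1-fps grayscale frame sequence from a directory of frame images
#'
#' Reads sequentially numbered frame images (PNG/JPEG/TIFF; filenames must
#' sort into temporal order), converts them to grayscale, decimates from the
#' native frame rate to `sample_rate_fps` by frame skipping (every
#' `floor(native_fps / sample_rate_fps)`-th frame, no temporal averaging),
#' optionally crops, and renumbers indices `0..N-1`. Timestamps are
#' `index / sample_rate_fps`. Video containers are not decoded: extract
#' frames to images first (e.g. with ffmpeg) and point this function at the
#' resulting directory.
#'
#' @param source path to a directory of frame images.
#' @param sample_rate_fps target sampling rate, default 1 frame/s.
#' @param native_fps native frame rate the images were captured at
#'   (default 30, typical of NVR surveillance recorders); must be >=
#'   `sample_rate_fps`.
#' @param crop_region optional `c(row0, col0, row1, col1)`, 1-based
#'   inclusive, applied to every frame.
#' @return A [frame_sequence].
#' @export
read_frame_sequence <- function(source, sample_rate_fps = 1,
                                native_fps = 30, crop_region = NULL) {
  if (!file.exists(source))
    stop_input("cannot read source: '", source, "' does not exist")
  ext <- tolower(tools::file_ext(source))
  if (ext %in% video_exts)
    stop_input("'", source, "' is a video container; no video decoder is ",
               "bundled. Extract frames to an image directory (e.g. ",
               "`ffmpeg -i video.avi -vf fps=1 frames/%06d.png`) and read ",
               "that directory instead.")
  if (!dir.exists(source))
    stop_input("cannot read source: '", source,
               "' is neither a directory nor a supported input")
  files <- list.files(source,
                      pattern = "\\.(png|jpe?g|tiff?)$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- sort(files)
  if (length(files) == 0L)
    stop_input("no decodable frames found in '", source, "'")
  if (sample_rate_fps > native_fps)
    stop_input("sample_rate_fps must not exceed the native rate")
  step <- floor(native_fps / sample_rate_fps)
  files <- files[seq(1L, length(files), by = step)]
  mats <- lapply(files, read_one_image)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_input("frame size mismatch within '", source, "': found ",
               paste(unique(apply(dims, 2, paste, collapse = "x")),
                     collapse = ", "))
  if (!is.null(crop_region)) mats <- lapply(mats, apply_crop, crop_region)
  frames <- lapply(seq_along(mats), function(i)
    frame_record(mats[[i]], index = i - 1L,
                 timestamp_s = (i - 1L) / sample_rate_fps))
  frame_sequence(frames, sample_rate_fps, crop_region)
}

apply_crop <- function(mat, crop_region) {
  cr <- as.integer(crop_region)
  if (length(cr) != 4L) stop_input("crop_region must be c(row0, col0, row1, col1)")
  if (cr[1] < 1L || cr[2] < 1L || cr[3] > nrow(mat) || cr[4] > ncol(mat) ||
      cr[1] > cr[3] || cr[2] > cr[4])
    stop_input("crop_region out of bounds for ", nrow(mat), "x", ncol(mat),
               " frame")
  mat[cr[1]:cr[3], cr[2]:cr[4], drop = FALSE]
}

#' Write a frame sequence as numbered PNG images
#'
#' Audit dump readable back by [read_frame_sequence()] (use
#' `native_fps = sample_rate_fps` so no further decimation occurs).
#'
#' @param sequence a [frame_sequence].
#' @param dir output directory, created if missing.
#' @return Invisibly, the written file paths.
#' @export
write_frame_sequence <- function(sequence, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(sequence$frames, function(f) {
    path <- file.path(dir, sprintf("frame_%06d.png", f$index))
    EBImage::writeImage(EBImage::Image(t(f$pixels) / 255), path)
    path
  }, character(1))
  invisible(paths)
}
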