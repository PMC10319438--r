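#' Create a calibrated image stack
#'
#' An `spt_movie` is a numeric array with dimensions `c(ny, nx, n_frames)`
#' carrying the physical calibration every downstream analysis needs: the
#' frame interval in seconds and the pixel size in micrometers. The
#' coordinate convention is fixed package-wide: the origin sits at the center
#' of the top-left pixel, x runs rightward along columns, y downward along
#' rows, and all physical distances are in micrometers.
#'
#' @param data Numeric array `c(ny, nx, n_frames)`, or a matrix for a
#'   single-frame movie.
#' @param frame_interval_s Time between consecutive frames, seconds.
#' @param pixel_size_um Pixel edge length, micrometers.
#' @return An `spt_movie` object.
#' @examples
#' mv <- spt_movie(array(0, c(8, 8, 5)), frame_interval_s = 1 / 138,
#'                 pixel_size_um = 0.16)
#' frame_rate(mv)
#' @export
spt_movie <- function(data, frame_interval_s, pixel_size_um) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L || !is.numeric(data)) {
    stop_spt("`data` must be a numeric ny x nx x n_frames array.",
             class = "sptkinetics_bad_argument")
  }
  check_number(frame_interval_s, "frame_interval_s", min = 1e-12)
  check_number(pixel_size_um, "pixel_size_um", min = 1e-12)
  structure(data,
            frame_interval_s = frame_interval_s,
            pixel_size_um = pixel_size_um,
            class = "spt_movie")
}

#' @export
print.spt_movie <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<spt_movie> %d x %d px, %d frames, dt = %.5g s (%.4g fps), pixel %.3g um\n",
    d[1], d[2], d[3], frame_interval(x), frame_rate(x), pixel_size(x)))
  invisible(x)
}

#' Movie calibration accessors
#'
#' @param movie An [spt_movie()].
#' @return `frame_interval()` the frame interval in seconds, `frame_rate()`
#'   its reciprocal in frames per second, `pixel_size()` the pixel size in
#'   micrometers, `n_frames()` the number of frames, and `movie_duration()`
#'   the total acquisition span `n_frames * frame_interval` in seconds.
#' @export
frame_interval <- function(movie) attr(movie, "frame_interval_s")

#' @rdname frame_interval
#' @export
frame_rate <- function(movie) 1 / attr(movie, "frame_interval_s")

#' @rdname frame_interval
#' @export
pixel_size <- function(movie) attr(movie, "pixel_size_um")

#' @rdname frame_interval
#' @export
n_frames <- function(movie) dim(movie)[3]

#' @rdname frame_interval
#' @export
movie_duration <- function(movie) dim(movie)[3] * attr(movie, "frame_interval_s")

#' Block-average movie frames
#'
#' Replaces non-overlapping blocks of `window` consecutive frames by their
#' per-pixel mean. Averaging amplifies the signal of static molecules while
#' blurring out mobile ones, which is the basis of residence-time tracking of
#' chromatin-bound particles. The output frame interval is the input interval
#' times `window` (e.g. a 138 fps acquisition averaged with `window = 10`
#' becomes an effective 13.8 fps movie). A trailing partial block is dropped.
#'
#' @param movie An [spt_movie()].
#' @param window Number of frames per block (>= 1, <= number of frames).
#' @return An [spt_movie()] with `floor(n_frames / window)` frames.
#' @export
average_frames <- function(movie, window) {
  window <- check_count(window, "window", min = 1L)
  d <- dim(movie)
  if (window > d[3]) {
    stop_spt("`window` is larger than the number of frames in the movie.",
             class = "sptkinetics_bad_argument")
  }
  n_blocks <- d[3] %/% window
  flat <- matrix(unclass(movie)[, , seq_len(n_blocks * window), drop = FALSE],
                 nrow = d[1] * d[2])
  out <- vapply(seq_len(n_blocks), function(b) {
    cols <- ((b - 1L) * window + 1L):(b * window)
    rowMeans(flat[, cols, drop = FALSE])
  }, numeric(d[1] * d[2]))
  spt_movie(array(out, c(d[1], d[2], n_blocks)),
            frame_interval_s = frame_interval(movie) * window,
            pixel_size_um = pixel_size(movie))
}

#' Read and write calibrated movies as multi-page TIFF
#'
#' Movies are written as 16-bit multi-page TIFF files plus a plain-text
#' `key=value` metadata sidecar (`<path>.meta.txt`) recording the frame
#' interval, pixel size, and the linear intensity scale used to map the data
#' into the TIFF range. `read_movie()` inverts the scaling, so a round trip
#' reproduces intensities up to 16-bit quantization.
#'
#' @param movie An [spt_movie()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `write_movie()` returns `path` invisibly; `read_movie()` returns an
#'   [spt_movie()].
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "spt_movie"))
  lo <- min(movie)
  hi <- max(movie)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(n_frames(movie)), function(k) {
    (unclass(movie)[, , k] - lo) / scale
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  meta <- c(sprintf("frame_interval_s=%.17g", frame_interval(movie)),
            sprintf("pixel_size_um=%.17g", pixel_size(movie)),
            sprintf("intensity_offset=%.17g", lo),
            sprintf("intensity_scale=%.17g", scale))
  writeLines(meta, paste0(path, ".meta.txt"))
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) {
    stop_spt(sprintf("Movie file not found: %s", path),
             class = "sptkinetics_missing_input")
  }
  meta_path <- paste0(path, ".meta.txt")
  if (!file.exists(meta_path)) {
    stop_spt(sprintf("Metadata sidecar not found: %s", meta_path),
             class = "sptkinetics_missing_input")
  }
  kv <- strsplit(readLines(meta_path), "=", fixed = TRUE)
  meta <- setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                   vapply(kv, `[[`, character(1), 1))
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(unlist(frames), c(dim(frames[[1]]), length(frames)))
  arr <- arr * meta[["intensity_scale"]] + meta[["intensity_offset"]]
  spt_movie(arr,
            frame_interval_s = meta[["frame_interval_s"]],
            pixel_size_um = meta[["pixel_size_um"]])
}
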