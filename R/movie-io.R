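#' Movie stack container
#'
#' A time-lapse image stack with its physical metadata: an `H x W x T` array
#' of intensities, the pixel size (um) and the frame interval (s).
#'
#' @param frames Numeric array `H x W x T` (a matrix is promoted to T = 1).
#' @param pixel_size Pixel size, um (> 0).
#' @param frame_interval Frame interval, s (> 0).
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(frames, pixel_size, frame_interval) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1))
  if (length(dim(frames)) != 3 || dim(frames)[3] < 1) {
    stop("`frames` must be an H x W x T array with T >= 1")
  }
  if (pixel_size <= 0 || frame_interval <= 0) {
    stop("`pixel_size` and `frame_interval` must be > 0")
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Movie stack: %d x %d px, %d frames (%.3g um/px, %.4g s/frame)\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

n_frames <- function(movie) dim(movie$frames)[3]

#' Write and read movies as multi-page 16-bit TIFF with a JSON sidecar
#'
#' Intensities are linearly scaled into the 16-bit range; the scale factor and
#' physical metadata (`pixel_size_um`, `frame_interval_s`, plus any extra
#' fields) go to `<path>.json` so the round trip preserves calibrated values.
#'
#' @param movie A [movie_stack()].
#' @param path Output TIFF path.
#' @param metadata Named list of extra sidecar fields (e.g. seed, parameters).
#' @return `write_movie_tiff()` returns `path` invisibly; `read_movie_tiff()`
#'   returns a [movie_stack()].
#' @export
write_movie_tiff <- function(movie, path, metadata = list()) {
  stopifnot(inherits(movie, "movie_stack"))
  lo <- min(movie$frames); hi <- max(movie$frames)
  scale <- if (hi > lo) 65535 / (hi - lo) else 1
  pages <- lapply(seq_len(n_frames(movie)), function(t) {
    (movie$frames[, , t] - lo) * scale / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- c(list(pixel_size_um = movie$pixel_size,
                 frame_interval_s = movie$frame_interval,
                 intensity_offset = lo, intensity_scale = scale),
            metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) {
    frames[, , t] <- pages[[t]] * 65535 / side$intensity_scale +
      side$intensity_offset
  }
  movie_stack(frames, side$pixel_size_um, side$frame_interval_s)
}

#' Write and read trajectory tables as CSV
#'
#' Schema: `track_id`, `frame` (0-based), `t_s`, `x_um`, `y_um`, `intensity`
#' and, when present, `true_label`.
#'
#' @param trajectories Long trajectory data frame.
#' @param path CSV path.
#' @return `write_trajectories()` returns `path` invisibly;
#'   `read_trajectories()` returns the data frame.
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(trajectories, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# split a long trajectory table into per-track data frames (frame-ordered)
split_tracks <- function(trajectories) {
  out <- split(trajectories, trajectories$track_id)
  lapply(out, function(d) d[order(d$frame), ])
}
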