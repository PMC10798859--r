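#' Simulate an ensemble of photobleaching intensity traces
#'
#' Each molecule carries `fluorophores_per_molecule` fluorophores that bleach
#' in single steps with exponential lifetimes at `bleach_rate`; the trace is
#' `photon_scale` times the number of surviving fluorophores plus camera
#' noise. The ensemble mean decays as exp(-bleach_rate * t).
#'
#' @param imaging An [imaging_params()] object.
#' @param n_traces Number of traces (>= 1).
#' @param trace_length Trace duration, s.
#' @param seed Optional integer seed.
#' @return A list with `time_s`, `traces` (matrix `n_traces x n_time`) and
#'   `mean_trace`.
#' @export
simulate_bleach_trace_ensemble <- function(imaging, n_traces, trace_length,
                                           seed = NULL) {
  stopifnot(inherits(imaging, "imaging_params"))
  n_traces <- as.integer(n_traces)
  if (n_traces < 1) stop("`n_traces` must be >= 1")
  with_seed(seed, {
    tt <- seq(0, trace_length, by = imaging$frame_interval)
    nf <- imaging$fluorophores_per_molecule
    traces <- matrix(0, n_traces, length(tt))
    for (i in seq_len(n_traces)) {
      bl <- if (imaging$bleach_rate > 0) {
        rexp(nf, imaging$bleach_rate)
      } else rep(Inf, nf)
      surv <- vapply(tt, function(t) sum(bl > t), numeric(1))
      traces[i, ] <- imaging$photon_scale * surv +
        rnorm(length(tt), 0, imaging$camera_noise_sd)
    }
    list(time_s = tt, traces = traces, mean_trace = colMeans(traces))
  })
}

# add one Gaussian spot (amplitude at peak) to an H x W frame, clipped
add_gaussian_spot <- function(frame, row, col, amplitude, sigma) {
  H <- nrow(frame); W <- ncol(frame)
  r <- ceiling(4 * sigma)
  r0 <- max(1L, floor(row - r)); r1 <- min(H, ceiling(row + r))
  c0 <- max(1L, floor(col - r)); c1 <- min(W, ceiling(col + r))
  if (r0 > r1 || c0 > c1) return(frame)
  rr <- r0:r1; cc <- c0:c1
  gy <- exp(-((rr - row)^2) / (2 * sigma^2))
  gx <- exp(-((cc - col)^2) / (2 * sigma^2))
  frame[rr, cc] <- frame[rr, cc] + amplitude * outer(gy, gx)
  frame
}

#' Render trajectories into a synthetic movie
#'
#' Each molecule is drawn as an isotropic 2D Gaussian of sigma `psf_sigma`
#' whose amplitude is `photon_scale` times its surviving fluorophores
#' (per-fluorophore single-step bleaching clocks start at the molecule's
#' first frame). Poisson shot noise is applied to signal plus background and
#' Gaussian camera noise added on top. Positions outside the field of view
#' are clipped with a warning.
#'
#' @param trajectories Long trajectory data frame (`track_id`, `frame`,
#'   `x_um`, `y_um`).
#' @param imaging An [imaging_params()] object.
#' @param seed Optional integer seed.
#' @param n_frames Number of frames; default spans the trajectories.
#' @return A list with `movie` (a [movie_stack()]) and `truth` (data frame:
#'   `track_id`, `bleach_time_1..k` relative to first appearance).
#' @export
render_movie <- function(trajectories, imaging = imaging_params(),
                         seed = NULL, n_frames = NULL) {
  stopifnot(inherits(imaging, "imaging_params"))
  H <- imaging$image_shape[1]; W <- imaging$image_shape[2]
  empty <- is.null(trajectories) || nrow(trajectories) == 0
  if (is.null(n_frames)) {
    n_frames <- if (empty) 1L else max(trajectories$frame) + 1L
  }
  with_seed(seed, {
    ids <- if (empty) integer(0) else unique(trajectories$track_id)
    nf <- imaging$fluorophores_per_molecule
    bleach <- matrix(Inf, length(ids), nf)
    first_t <- numeric(length(ids))
    if (imaging$bleach_rate > 0 && length(ids)) {
      bleach <- matrix(rexp(length(ids) * nf, imaging$bleach_rate),
                       length(ids), nf)
    }
    frames <- array(0, dim = c(H, W, n_frames))
    clipped <- FALSE
    if (!empty) {
      trajectories <- trajectories[order(trajectories$track_id,
                                         trajectories$frame), ]
      for (j in seq_along(ids)) {
        tr <- trajectories[trajectories$track_id == ids[j], ]
        first_t[j] <- min(tr$frame) * imaging$frame_interval
        for (k in seq_len(nrow(tr))) {
          fr <- tr$frame[k] + 1L
          if (fr > n_frames) next
          col <- tr$x_um[k] / imaging$pixel_size + 1
          row <- tr$y_um[k] / imaging$pixel_size + 1
          if (col < 1 || col > W || row < 1 || row > H) clipped <- TRUE
          t_rel <- tr$frame[k] * imaging$frame_interval - first_t[j]
          amp <- imaging$photon_scale * sum(bleach[j, ] > t_rel)
          if (amp > 0) {
            frames[, , fr] <- add_gaussian_spot(frames[, , fr], row, col,
                                                amp, imaging$psf_sigma)
          }
        }
      }
    }
    if (clipped) warning("trajectory positions outside the field of view were clipped")
    for (fr in seq_len(n_frames)) {
      lam <- frames[, , fr] + imaging$background_level
      frames[, , fr] <- rpois(H * W, lam) +
        rnorm(H * W, 0, imaging$camera_noise_sd)
    }
    truth <- data.frame(track_id = ids)
    if (length(ids)) {
      for (k in seq_len(nf)) truth[[paste0("bleach_time_", k)]] <- bleach[, k]
    }
    list(movie = movie_stack(frames, imaging$pixel_size,
                             imaging$frame_interval),
         truth = truth)
  })
}

#' Simulate a two-channel spot field with controlled co-occurrence
#'
#' Reference spots (channel A) are placed at least `min_separation` pixels
#' apart; each is co-occupied in channel B with probability `p_overlap`. The
#' remaining B spots are placed at least `min_separation` from every A spot
#' (and from each other), so the generated co-occurrence fraction is exactly
#' the Bernoulli rate. Calibration input for the object-based colocalization
#' procedure.
#'
#' @param n_ref_spots Number of reference (A) spots; B receives the same
#'   total number.
#' @param p_overlap Probability a reference spot is co-occupied in B.
#' @param image_shape `c(H, W)` pixels.
#' @param psf_sigma Spot Gaussian sigma, pixels.
#' @param min_separation Minimum centre separation, pixels.
#' @param seed Optional integer seed.
#' @param amplitude Spot peak amplitude, counts.
#' @param background Constant background, counts.
#' @param noise_sd Gaussian noise SD, counts.
#' @return A list with `image_a`, `image_b` (matrices) and `truth` (data
#'   frame: spot centres in pixels and the `co_occupied` flag).
#' @export
simulate_spot_channels <- function(n_ref_spots, p_overlap,
                                   image_shape = c(256, 256),
                                   psf_sigma = 1.3, min_separation = 8,
                                   seed = NULL, amplitude = 300,
                                   background = 10, noise_sd = 2) {
  if (p_overlap < 0 || p_overlap > 1) stop("`p_overlap` must be in [0, 1]")
  H <- image_shape[1]; W <- image_shape[2]
  margin <- ceiling(4 * psf_sigma) + 1
  with_seed(seed, {
    place <- function(n, avoid_r, avoid_c) {
      rs <- numeric(0); cs <- numeric(0)
      attempts <- 0L
      while (length(rs) < n) {
        attempts <- attempts + 1L
        if (attempts > 200L * n + 1000L) {
          stop("cannot place spots at the requested minimum separation")
        }
        r <- runif(1, margin, H - margin); c <- runif(1, margin, W - margin)
        d2 <- c((r - rs)^2 + (c - cs)^2, (r - avoid_r)^2 + (c - avoid_c)^2)
        if (all(d2 >= min_separation^2)) {
          rs <- c(rs, r); cs <- c(cs, c)
        }
      }
      cbind(rs, cs)
    }
    a_pos <- place(n_ref_spots, numeric(0), numeric(0))
    co <- runif(n_ref_spots) < p_overlap
    n_extra <- sum(!co)
    b_extra <- place(n_extra, a_pos[, 1], a_pos[, 2])
    img_a <- matrix(background, H, W)
    img_b <- matrix(background, H, W)
    for (i in seq_len(n_ref_spots)) {
      img_a <- add_gaussian_spot(img_a, a_pos[i, 1], a_pos[i, 2],
                                 amplitude, psf_sigma)
      if (co[i]) {
        img_b <- add_gaussian_spot(img_b, a_pos[i, 1], a_pos[i, 2],
                                   amplitude, psf_sigma)
      }
    }
    for (i in seq_len(n_extra)) {
      img_b <- add_gaussian_spot(img_b, b_extra[i, 1], b_extra[i, 2],
                                 amplitude, psf_sigma)
    }
    img_a <- img_a + matrix(rnorm(H * W, 0, noise_sd), H, W)
    img_b <- img_b + matrix(rnorm(H * W, 0, noise_sd), H, W)
    truth <- data.frame(row_px = a_pos[, 1], col_px = a_pos[, 2],
                        co_occupied = co)
    list(image_a = img_a, image_b = img_b, truth = truth)
  })
}
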