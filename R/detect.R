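#' Temporal sliding average of a movie
#'
#' Centred boxcar average along time, truncated at the stack boundaries, as
#' used to raise the signal-to-noise ratio of 50-fps single-molecule movies
#' before tracking (five-frame window in the reference protocol).
#'
#' @param movie A [movie_stack()].
#' @param window Window length in frames (1 <= window <= T). `window = 1` is
#'   the identity. Even windows take one extra frame on the trailing side.
#' @return A [movie_stack()] of the same dimensions.
#' @export
sliding_average <- function(movie, window = 5) {
  stopifnot(inherits(movie, "movie_stack"))
  T <- n_frames(movie)
  window <- as.integer(window)
  if (window < 1 || window > T) stop("`window` must be in [1, T]")
  if (window == 1) return(movie)
  lo_off <- (window - 1L) %/% 2L
  hi_off <- window - 1L - lo_off
  d <- dim(movie$frames)
  flat <- matrix(movie$frames, d[1] * d[2], d[3])
  cs <- cbind(0, t(apply(flat, 1, cumsum)))
  out <- matrix(0, d[1] * d[2], d[3])
  for (t in seq_len(T)) {
    lo <- max(1L, t - lo_off); hi <- min(T, t + hi_off)
    out[, t] <- (cs[, hi + 1L] - cs[, lo]) / (hi - lo + 1L)
  }
  movie_stack(array(out, d), movie$pixel_size, movie$frame_interval)
}

# indices of strict-threshold local maxima of a matrix (8-neighbourhood;
# plateau points count as maxima so ties are resolved downstream)
local_maxima <- function(m, threshold) {
  H <- nrow(m); W <- ncol(m)
  ok <- m > threshold
  if (H > 2 && W > 2) {
    core <- function(dr, dc) {
      sh <- matrix(-Inf, H, W)
      sh[(1 + max(0, dr)):(H + min(0, dr)), (1 + max(0, dc)):(W + min(0, dc))] <-
        m[(1 - min(0, dr)):(H - max(0, dr)), (1 - min(0, dc)):(W - max(0, dc))]
      sh
    }
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      ok <- ok & (m >= core(dr, dc))
    }
  }
  which(ok, arr.ind = TRUE)
}

# median background in an annulus around an integer pixel position
annulus_background <- function(frame, row, col, r_in, r_out) {
  H <- nrow(frame); W <- ncol(frame)
  r0 <- max(1L, row - r_out); r1 <- min(H, row + r_out)
  c0 <- max(1L, col - r_out); c1 <- min(W, col + r_out)
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  vals <- frame[rr, cc][d2 >= r_in^2 & d2 <= r_out^2]
  if (!length(vals)) return(stats::median(frame))
  stats::median(vals)
}

#' Detect diffraction-limited spots in one frame
#'
#' Band-pass (difference-of-Gaussians) response, thresholded at
#' `threshold_factor` times the robust (MAD) noise of the response; local
#' maxima closer than `2 * max_sigma` pixels are merged (brightest kept).
#' Sub-pixel centroids come from an intensity-weighted mean over a square
#' fitting window after subtracting a local annulus-median background.
#'
#' @param frame Numeric matrix.
#' @param min_sigma,max_sigma Band-pass sigmas, pixels.
#' @param threshold_factor Detection threshold in robust-noise units.
#' @param fit_radius Half-width of the centroid window, pixels.
#' @param annulus `c(r_in, r_out)` of the background annulus, pixels.
#' @return A data frame with `row_px`, `col_px` (sub-pixel, 1-based),
#'   `raw_intensity` (aperture sum), `intensity` (background-subtracted
#'   aperture sum), `background`, `quality` (peak response / noise) and
#'   `clipped` (fitting window touched the border).
#' @export
detect_spots <- function(frame, min_sigma = 1, max_sigma = 2,
                         threshold_factor = 5, fit_radius = 3,
                         annulus = c(4, 6)) {
  if (!is.matrix(frame) || !length(frame)) stop("`frame` must be a non-empty matrix")
  resp <- EBImage::gblur(frame, sigma = min_sigma) -
    EBImage::gblur(frame, sigma = max_sigma)
  noise <- stats::mad(resp)
  if (noise == 0) noise <- stats::sd(resp)
  empty <- data.frame(row_px = numeric(0), col_px = numeric(0),
                      raw_intensity = numeric(0), intensity = numeric(0),
                      background = numeric(0), quality = numeric(0),
                      clipped = logical(0))
  if (!is.finite(noise) || noise == 0) return(empty)
  cand <- local_maxima(resp, threshold_factor * noise)
  if (!nrow(cand)) return(empty)
  vals <- resp[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]; vals <- vals[ord]
  # non-maximum suppression: merge detections closer than 2 * max_sigma
  keep <- logical(nrow(cand))
  min_d2 <- (2 * max_sigma)^2
  for (i in seq_len(nrow(cand))) {
    ki <- which(keep)
    if (!length(ki) ||
        all((cand[ki, 1] - cand[i, 1])^2 + (cand[ki, 2] - cand[i, 2])^2 >= min_d2)) {
      keep[i] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]; vals <- vals[keep]
  H <- nrow(frame); W <- ncol(frame)
  out <- lapply(seq_len(nrow(cand)), function(i) {
    pr <- cand[i, 1]; pc <- cand[i, 2]
    bg <- annulus_background(frame, pr, pc, annulus[1], annulus[2])
    r0 <- pr - fit_radius; r1 <- pr + fit_radius
    c0 <- pc - fit_radius; c1 <- pc + fit_radius
    clipped <- r0 < 1 || c0 < 1 || r1 > H || c1 > W
    rr <- max(1L, r0):min(H, r1); cc <- max(1L, c0):min(W, c1)
    w <- pmax(frame[rr, cc, drop = FALSE] - bg, 0)
    tot <- sum(w)
    if (tot > 0) {
      row_c <- sum(outer(rr, rep(1, length(cc))) * w) / tot
      col_c <- sum(outer(rep(1, length(rr)), cc) * w) / tot
    } else {
      row_c <- pr; col_c <- pc
    }
    raw <- sum(frame[rr, cc])
    data.frame(row_px = row_c, col_px = col_c, raw_intensity = raw,
               intensity = raw - length(rr) * length(cc) * bg,
               background = bg, quality = vals[i] / noise, clipped = clipped)
  })
  do.call(rbind, out)
}

#' Detect spots in every frame of a movie
#'
#' Applies [detect_spots()] per frame and converts centroids to physical
#' units.
#'
#' @param movie A [movie_stack()].
#' @inheritParams detect_spots
#' @return A data frame with `frame` (0-based), `x_um`, `y_um` and the
#'   per-spot columns of [detect_spots()].
#' @export
detect_spots_movie <- function(movie, min_sigma = 1, max_sigma = 2,
                               threshold_factor = 5, fit_radius = 3,
                               annulus = c(4, 6)) {
  stopifnot(inherits(movie, "movie_stack"))
  out <- lapply(seq_len(n_frames(movie)), function(t) {
    s <- detect_spots(movie$frames[, , t], min_sigma, max_sigma,
                      threshold_factor, fit_radius, annulus)
    if (!nrow(s)) return(NULL)
    cbind(frame = t - 1L,
          x_um = (s$col_px - 1) * movie$pixel_size,
          y_um = (s$row_px - 1) * movie$pixel_size, s)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
                      row_px = numeric(0), col_px = numeric(0),
                      raw_intensity = numeric(0), intensity = numeric(0),
                      background = numeric(0), quality = numeric(0),
                      clipped = logical(0))
  }
  out
}

#' Link per-frame spots into trajectories
#'
#' Frame-to-frame greedy nearest-neighbour assignment, resolved globally per
#' frame pair by ascending distance; candidate links longer than `max_step`
#' per elapsed frame are rejected and disappearances up to `max_gap` frames
#' are bridged. Spots are put into a canonical (x, then y) order within each
#' frame before matching, so the result is invariant to input ordering; ties
#' break on the lower canonical index.
#'
#' @param spots Data frame with `frame` (0-based), `x_um`, `y_um` and
#'   optionally `intensity`.
#' @param max_step Maximum link length per elapsed frame, um.
#' @param max_gap Maximum number of bridged missing frames.
#' @param frame_interval Frame interval used to fill `t_s`, s.
#' @return A long trajectory data frame (`track_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`, `intensity`); track ids are ordered by first frame then x.
#' @export
link_tracks <- function(spots, max_step, max_gap = 1,
                        frame_interval = 0.02) {
  need <- c("frame", "x_um", "y_um")
  if (!all(need %in% names(spots))) stop("spots need frame, x_um, y_um")
  if (!nrow(spots)) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      t_s = numeric(0), x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  }
  spots <- spots[order(spots$frame, spots$x_um, spots$y_um), ]
  if (is.null(spots$intensity)) spots$intensity <- NA_real_
  frames <- sort(unique(spots$frame))
  # active tracks: parallel vectors for last position/frame; rows collected
  last_x <- numeric(0); last_y <- numeric(0); last_f <- integer(0)
  rows <- list()   # per track: data frame rows
  open <- integer(0)  # indices into rows of open tracks
  result_rows <- list()
  for (f in frames) {
    sp <- spots[spots$frame == f, , drop = FALSE]
    alive <- open[last_f[open] >= f - 1L - max_gap]
    assigned_spot <- rep(FALSE, nrow(sp))
    if (length(alive) && nrow(sp)) {
      dg <- expand.grid(ti = seq_along(alive), si = seq_len(nrow(sp)))
      tr_idx <- alive[dg$ti]
      gapn <- f - last_f[tr_idx]
      d <- sqrt((last_x[tr_idx] - sp$x_um[dg$si])^2 +
                (last_y[tr_idx] - sp$y_um[dg$si])^2)
      okl <- d <= max_step * gapn
      dg <- dg[okl, , drop = FALSE]; d <- d[okl]
      ordl <- order(d, dg$ti, dg$si)
      used_t <- logical(length(alive))
      for (k in ordl) {
        ti <- dg$ti[k]; si <- dg$si[k]
        if (used_t[ti] || assigned_spot[si]) next
        used_t[ti] <- TRUE; assigned_spot[si] <- TRUE
        tr <- alive[ti]
        rows[[tr]] <- rbind(rows[[tr]], sp[si, c("frame", "x_um", "y_um", "intensity")])
        last_x[tr] <- sp$x_um[si]; last_y[tr] <- sp$y_um[si]; last_f[tr] <- f
      }
    }
    for (si in which(!assigned_spot)) {
      rows[[length(rows) + 1L]] <- sp[si, c("frame", "x_um", "y_um", "intensity")]
      last_x[length(rows)] <- sp$x_um[si]
      last_y[length(rows)] <- sp$y_um[si]
      last_f[length(rows)] <- f
      open <- c(open, length(rows))
    }
    open <- open[last_f[open] >= f - max_gap]
  }
  first_frame <- vapply(rows, function(r) min(r$frame), numeric(1))
  first_x <- vapply(rows, function(r) r$x_um[which.min(r$frame)], numeric(1))
  ord <- order(first_frame, first_x)
  out <- do.call(rbind, lapply(seq_along(ord), function(i) {
    r <- rows[[ord[i]]]
    data.frame(track_id = i, frame = as.integer(r$frame),
               t_s = r$frame * frame_interval,
               x_um = r$x_um, y_um = r$y_um, intensity = r$intensity)
  }))
  rownames(out) <- NULL
  out
}

#' Measure background-subtracted spot intensity along a trajectory
#'
#' Per-frame circular-aperture sum around the tracked centroid minus the
#' aperture area times a local annulus-median background. Apertures clipped
#' by the image border yield `NA` and are flagged.
#'
#' @param movie A [movie_stack()].
#' @param trajectory Single-track data frame (`frame`, `x_um`, `y_um`).
#' @param aperture_radius Aperture radius, pixels.
#' @param annulus `c(r_in, r_out)` background annulus, pixels.
#' @return Numeric vector (length = trajectory length) with attribute
#'   `clipped` (logical vector).
#' @export
measure_intensity <- function(movie, trajectory, aperture_radius = 3,
                              annulus = c(4, 6)) {
  stopifnot(inherits(movie, "movie_stack"))
  H <- dim(movie$frames)[1]; W <- dim(movie$frames)[2]
  n <- nrow(trajectory)
  out <- numeric(n); clipped <- logical(n)
  for (i in seq_len(n)) {
    fr <- trajectory$frame[i] + 1L
    if (fr < 1 || fr > n_frames(movie)) { out[i] <- NA; clipped[i] <- TRUE; next }
    col <- round(trajectory$x_um[i] / movie$pixel_size + 1)
    row <- round(trajectory$y_um[i] / movie$pixel_size + 1)
    if (row - aperture_radius < 1 || row + aperture_radius > H ||
        col - aperture_radius < 1 || col + aperture_radius > W) {
      out[i] <- NA; clipped[i] <- TRUE; next
    }
    rr <- (row - aperture_radius):(row + aperture_radius)
    cc <- (col - aperture_radius):(col + aperture_radius)
    d2 <- outer((rr - row)^2, (cc - col)^2, "+")
    mask <- d2 <= aperture_radius^2
    frame <- movie$frames[, , fr]
    bg <- annulus_background(frame, row, col, annulus[1], annulus[2])
    out[i] <- sum(frame[rr, cc][mask]) - sum(mask) * bg
  }
  attr(out, "clipped") <- clipped
  out
}

#' Build a kymograph along a line segment
#'
#' Positions are sampled along the segment at one-pixel spacing and, for each
#' frame, the maximum intensity across a perpendicular band of `width` pixels
#' is taken -- the standard maximum-intensity "reslice" used to display
#' motion along a cell's long axis.
#'
#' @param movie A [movie_stack()].
#' @param p0,p1 Segment end points `c(x, y)`, um.
#' @param width Band width, pixels (odd recommended).
#' @return A `T x P` matrix of class `kymograph` with attributes
#'   `position_um` and `time_s`.
#' @export
make_kymograph <- function(movie, p0, p1, width = 5) {
  stopifnot(inherits(movie, "movie_stack"))
  L <- sqrt(sum((p1 - p0)^2))
  if (L <= 0) stop("kymograph axis has zero length")
  ps <- movie$pixel_size
  n_pos <- max(2L, as.integer(floor(L / ps)) + 1L)
  tvec <- seq(0, L, length.out = n_pos)
  u <- (p1 - p0) / L
  v <- c(-u[2], u[1])  # unit normal
  offs <- (seq_len(width) - (width + 1) / 2) * ps
  H <- dim(movie$frames)[1]; W <- dim(movie$frames)[2]
  T <- n_frames(movie)
  ky <- matrix(NA_real_, T, n_pos)
  for (j in seq_len(n_pos)) {
    base <- p0 + tvec[j] * u
    cols <- round((base[1] + offs * v[1]) / ps + 1)
    rows <- round((base[2] + offs * v[2]) / ps + 1)
    okp <- cols >= 1 & cols <= W & rows >= 1 & rows <= H
    if (!any(okp)) next
    idx2 <- cbind(rows[okp], cols[okp])
    for (t in seq_len(T)) {
      ky[t, j] <- max(movie$frames[, , t][idx2])
    }
  }
  structure(ky, position_um = tvec,
            time_s = (seq_len(T) - 1) * movie$frame_interval,
            class = c("kymograph", "matrix"))
}
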