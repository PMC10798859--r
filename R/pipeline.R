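#' Simulate a single-molecule imaging experiment as rendered movies
#'
#' Generates `n_tracks` binding events with [simulate_dynein_tracks()],
#' scatters them over one or more rendered movies (random positions away
#' from the border, random staggered start frames) and returns the movies
#' together with the ground-truth trajectories. The nucleus reference is
#' placed far to the left of the field so the minus-end direction is
#' approximately -x everywhere, as in an elongated cell imaged with the
#' nucleus outside the field of view.
#'
#' @param n_tracks Total number of binding events.
#' @param params A [motor_params()].
#' @param imaging An [imaging_params()].
#' @param seed Optional integer seed.
#' @param tracks_per_movie Events per rendered movie.
#' @param movie_frames Frames per movie.
#' @param margin_px Border margin for starting positions, pixels.
#' @param min_separation_px Minimum separation between starting positions in
#'   one movie, pixels; keeps concurrent molecules resolvable.
#' @param enforce_class_consistency Passed to [simulate_dynein_tracks()].
#' @return A list: `movies` (list of [movie_stack()]), `trajectories`
#'   (ground-truth long data frame with `movie` column), `truth` (per-track
#'   table with `movie`), `nucleus` (the reference used).
#' @export
simulate_tracking_experiment <- function(n_tracks, params = motor_params(),
                                         imaging = imaging_params(),
                                         seed = NULL, tracks_per_movie = 10,
                                         movie_frames = 250,
                                         margin_px = 10,
                                         min_separation_px = 16,
                                         enforce_class_consistency = TRUE) {
  H <- imaging$image_shape[1]; W <- imaging$image_shape[2]
  ps <- imaging$pixel_size
  nucleus <- nucleus_ref(-1000, (H - 1) / 2 * ps)
  # binding events must be able to run to completion before the movie ends,
  # otherwise apparent residences are right-censored; reserve enough frames
  # that an event outlasting them is vanishingly rare (P < e^-6)
  reserve <- min(movie_frames - 1L,
                 ceiling(6 / (params$off_rate * imaging$frame_interval)))
  n_movies <- ceiling(n_tracks / tracks_per_movie)
  movies <- vector("list", n_movies)
  all_traj <- list(); all_truth <- list()
  offset <- 0L
  for (m in seq_len(n_movies)) {
    n_here <- min(tracks_per_movie, n_tracks - offset)
    sseed <- if (is.null(seed)) NULL else derive_seed(seed, 100000 + m)
    placements <- with_seed(sseed, {
      xs <- numeric(0); ys <- numeric(0); tries <- 0L
      while (length(xs) < n_here) {
        tries <- tries + 1L
        if (tries > 500L * n_here) stop("cannot place tracks at the requested separation")
        x <- runif(1, margin_px, W - margin_px)
        y <- runif(1, margin_px, H - margin_px)
        if (all((x - xs)^2 + (y - ys)^2 >= min_separation_px^2)) {
          xs <- c(xs, x); ys <- c(ys, y)
        }
      }
      list(x = xs * ps, y = ys * ps,
           f = sample.int(max(1L, movie_frames - reserve), n_here,
                          replace = TRUE) - 1L)
    })
    sim <- simulate_dynein_tracks(
      n_here, params, imaging,
      seed = if (is.null(seed)) NULL else derive_seed(seed, 200000 + m),
      nucleus = nucleus,
      start_xy_fun = function(i) c(placements$x[i], placements$y[i]),
      start_frame_fun = function(i) placements$f[i],
      enforce_class_consistency = enforce_class_consistency
    )
    sim$trajectories$track_id <- sim$trajectories$track_id + offset
    sim$truth$track_id <- sim$truth$track_id + offset
    rend <- render_movie(sim$trajectories, imaging,
                         seed = if (is.null(seed)) NULL else derive_seed(seed, 300000 + m),
                         n_frames = movie_frames)
    movies[[m]] <- rend$movie
    sim$trajectories$movie <- m
    sim$truth$movie <- m
    all_traj[[m]] <- sim$trajectories
    all_truth[[m]] <- sim$truth
    offset <- offset + n_here
  }
  list(movies = movies, trajectories = do.call(rbind, all_traj),
       truth = do.call(rbind, all_truth), nucleus = nucleus)
}

#' Detect and link spots in a movie
#'
#' Convenience wrapper: optional temporal sliding average, per-frame spot
#' detection and nearest-neighbour linking. Note that temporal averaging
#' smears binding/unbinding edges and lengthens apparent residences, so the
#' default here is no averaging; use `window = 5` for low-SNR data.
#'
#' @param movie A [movie_stack()].
#' @param window Sliding-average window, frames.
#' @param max_step Maximum link step, um; default adapts to 3 pixels.
#' @param max_gap Maximum bridged gap, frames.
#' @inheritParams detect_spots
#' @return A long trajectory data frame (see [link_tracks()]).
#' @export
track_movie <- function(movie, window = 1, min_sigma = 1, max_sigma = 2,
                        threshold_factor = 5, max_step = NULL, max_gap = 1) {
  if (window > 1) movie <- sliding_average(movie, window)
  spots <- detect_spots_movie(movie, min_sigma, max_sigma, threshold_factor)
  link_tracks(spots, max_step = max_step %||% (3 * movie$pixel_size),
              max_gap = max_gap, frame_interval = movie$frame_interval)
}

#' Match recovered trajectories to ground truth
#'
#' For every ground-truth track, finds the recovered track sharing the most
#' frames at matching positions (within `tol_um`) and scores the overlap by
#' the Jaccard index of the two frame sets.
#'
#' @param truth_traj Ground-truth long trajectory data frame.
#' @param rec_traj Recovered long trajectory data frame.
#' @param tol_um Position tolerance for a frame to count as matched, um.
#' @return Data frame per truth track: `track_id`, `best_match` (recovered
#'   id or `NA`), `jaccard`, `n_true`, `n_matched`.
#' @export
match_tracks <- function(truth_traj, rec_traj, tol_um = 0.3) {
  tt <- split_tracks(truth_traj)
  rr <- split_tracks(rec_traj)
  rec_frames <- lapply(rr, `[[`, "frame")
  out <- lapply(names(tt), function(id) {
    tr <- tt[[id]]
    best <- NA_character_; best_j <- 0; best_m <- 0L
    for (rid in names(rr)) {
      rv <- rr[[rid]]
      common <- intersect(tr$frame, rv$frame)
      if (length(common) <= best_m && length(common) == 0) next
      i1 <- match(common, tr$frame); i2 <- match(common, rv$frame)
      okp <- sqrt((tr$x_um[i1] - rv$x_um[i2])^2 +
                  (tr$y_um[i1] - rv$y_um[i2])^2) <= tol_um
      nm <- sum(okp)
      uni <- length(union(tr$frame, rv$frame))
      j <- nm / uni
      if (j > best_j) { best_j <- j; best <- rid; best_m <- nm }
    }
    data.frame(track_id = id, best_match = best, jaccard = best_j,
               n_true = nrow(tr), n_matched = best_m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run the full synthetic tracking experiment and analyse it
#'
#' End-to-end driver: simulate binding events, render movies, detect, link,
#' classify the recovered tracks against the nucleus reference and fit the
#' residence-time distribution of the recovered track durations. Tracking is
#' performed per movie; track ids are made globally unique.
#'
#' @inheritParams simulate_tracking_experiment
#' @param class_params A [classification_params()].
#' @param ... Passed to [track_movie()].
#' @return A list: `truth`, `nucleus`, `recovered` (long data frame),
#'   `matches` (from [match_tracks()]), `recovery_fraction` (Jaccard >= 0.8),
#'   `classes` (per recovered track), `proportions`, `residence_fit`.
#' @export
run_tracking_experiment <- function(n_tracks, params = motor_params(),
                                    imaging = imaging_params(), seed = NULL,
                                    tracks_per_movie = 8, movie_frames = 200,
                                    enforce_class_consistency = TRUE,
                                    class_params = classification_params(),
                                    ...) {
  sim <- simulate_tracking_experiment(
    n_tracks, params, imaging, seed, tracks_per_movie, movie_frames,
    enforce_class_consistency = enforce_class_consistency
  )
  rec_list <- list()
  offset <- 0L
  for (m in seq_along(sim$movies)) {
    rec <- track_movie(sim$movies[[m]], ...)
    if (nrow(rec)) {
      rec$track_id <- rec$track_id + offset
      offset <- max(rec$track_id)
      rec$movie <- m
      rec_list[[m]] <- rec
    }
  }
  recovered <- do.call(rbind, rec_list)
  matches <- do.call(rbind, lapply(seq_along(sim$movies), function(m) {
    mt <- match_tracks(sim$trajectories[sim$trajectories$movie == m, ],
                       recovered[recovered$movie == m, ])
    mt
  }))
  classes <- classify_tracks(recovered, sim$nucleus, class_params)
  # Residence estimation from linked tracks: a molecule seen in m frames
  # resided between (m-1) and m frame intervals, so T-hat = (m - 0.5) dt.
  # Tracks need >= 2 frames to be trusted; by memorylessness of the
  # exponential the off-rate is then 1 / (mean(T-hat) - dt).
  dt <- imaging$frame_interval
  m_frames <- vapply(split_tracks(recovered), nrow, numeric(1))
  t_hat <- (m_frames[m_frames >= 2] - 0.5) * dt
  off_rate_est <- 1 / (mean(t_hat) - dt)
  fit <- fit_residence_survival(pmax(t_hat - dt, dt / 2), method = "mle")
  list(truth = sim$truth, nucleus = sim$nucleus, recovered = recovered,
       matches = matches,
       recovery_fraction = mean(matches$jaccard >= 0.8),
       classes = classes,
       proportions = class_proportions(classes),
       durations_est = t_hat,
       off_rate_est = off_rate_est,
       residence_fit = fit)
}
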