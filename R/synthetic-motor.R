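# truncated-at-zero normal draw, one value per call site vector
rtnorm_pos <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  if (sd == 0) {
    if (mean <= 0) stop("degenerate velocity distribution at <= 0")
    return(rep(mean, n))
  }
  out <- rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Sample microtubule binding events
#'
#' Draws independent binding events: exponentially distributed residence
#' durations with the motor off-rate, and behavioural class labels from the
#' class mixture. These are the per-event quantities underlying the residence
#' survival fit and the class-proportion tables.
#'
#' @param params A [motor_params()] object.
#' @param n Number of events (>= 0).
#' @param seed Optional integer seed; a fixed seed makes the draw reproducible.
#' @return A data frame with columns `duration_s` and `class`
#'   (`"stationary"`, `"minus"`, `"plus"`).
#' @examples
#' ev <- sample_binding_events(motor_params(), 1000, seed = 1)
#' mean(ev$duration_s)  # close to 1/1.7 = 0.59 s
#' @export
sample_binding_events <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "motor_params"))
  n <- as.integer(n)
  if (n < 0) stop("`n` must be >= 0")
  with_seed(seed, {
    data.frame(
      duration_s = rexp(n, params$off_rate),
      class = if (n) {
        sample(names(params$class_probs), n, replace = TRUE,
               prob = params$class_probs)
      } else character(0),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate one single-motor binding event as a trajectory
#'
#' One binding event: a residence duration is drawn from the exponential
#' off-rate, a class from the mixture, and the molecule's position advances at
#' the class velocity (minus class toward the nucleus reference, plus class
#' away, stationary with zero drift), plus per-frame localization noise.
#'
#' With `enforce_class_consistency = TRUE` (default), moving events are
#' redrawn (duration and speed jointly) until their noise-free net axial
#' displacement exceeds `consistency_threshold`, so that with zero noise the
#' classification rule recovers the generating label exactly. Set it to
#' `FALSE` for unconditioned exponential residence kinetics (at the cost of
#' short moving events falling below the classification threshold).
#'
#' @param params A [motor_params()] object.
#' @param imaging An [imaging_params()] object (frame timing).
#' @param seed Optional integer seed.
#' @param class Optional forced class label.
#' @param duration Optional forced residence duration, s.
#' @param speed Optional forced run speed, um/s.
#' @param start_xy Starting position `c(x, y)` um; default 10 um from the
#'   nucleus reference along x.
#' @param nucleus A [nucleus_ref()]; default origin.
#' @param start_frame First (0-based) frame index.
#' @param track_id Track identifier for the output table.
#' @param enforce_class_consistency Logical; see Details.
#' @param consistency_threshold Net-displacement threshold used when
#'   enforcing consistency, um (default the 0.32 um classification threshold).
#' @return A list with `trajectory` (data frame: `track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`, `intensity`, `true_label`) and `truth` (list with
#'   `class`, `duration_s`, `speed_um_s`, `n_frames`, `rng_seed`).
#' @export
simulate_dynein_track <- function(params, imaging = imaging_params(),
                                  seed = NULL, class = NULL, duration = NULL,
                                  speed = NULL,
                                  start_xy = c(10, 0),
                                  nucleus = nucleus_ref(0, 0),
                                  start_frame = 0L, track_id = 1L,
                                  enforce_class_consistency = TRUE,
                                  consistency_threshold = 0.32) {
  stopifnot(inherits(params, "motor_params"), inherits(imaging, "imaging_params"))
  with_seed(seed, {
    dt <- imaging$frame_interval
    cls <- class %||% sample(names(params$class_probs), 1,
                             prob = params$class_probs)
    draw_pair <- function() {
      dur <- duration %||% rexp(1, params$off_rate)
      v <- if (cls == "stationary") 0 else {
        speed %||% if (cls == "minus") {
          rtnorm_pos(1, params$v_minus_mean, params$v_minus_sd)
        } else {
          rtnorm_pos(1, params$v_plus_mean, params$v_plus_sd)
        }
      }
      list(dur = dur, v = v)
    }
    p <- draw_pair()
    if (enforce_class_consistency && cls != "stationary" &&
        is.null(duration) && is.null(speed)) {
      # moving events must clear the classification threshold (noise-free);
      # displacement spans (n_frames - 1) frame intervals
      repeat {
        nf <- max(1L, ceiling(p$dur / dt))
        if (p$v * (nf - 1L) * dt > consistency_threshold) break
        p <- draw_pair()
      }
    }
    n_frames <- max(1L, as.integer(ceiling(p$dur / dt)))
    tt <- (seq_len(n_frames) - 1L) * dt
    # axial unit vector toward the nucleus reference
    d0 <- c(start_xy[1] - nucleus[1], start_xy[2] - nucleus[2])
    nrm <- sqrt(sum(d0^2))
    u <- if (nrm > 0) d0 / nrm else c(1, 0)
    drift <- switch(cls, stationary = 0, minus = -p$v, plus = p$v)
    x <- start_xy[1] + drift * u[1] * tt
    y <- start_xy[2] + drift * u[2] * tt
    if (params$localization_noise_sd > 0) {
      x <- x + rnorm(n_frames, 0, params$localization_noise_sd)
      y <- y + rnorm(n_frames, 0, params$localization_noise_sd)
    }
    traj <- data.frame(
      track_id = track_id,
      frame = start_frame + seq_len(n_frames) - 1L,
      t_s = (start_frame + seq_len(n_frames) - 1L) * dt,
      x_um = x, y_um = y,
      intensity = imaging$photon_scale * imaging$fluorophores_per_molecule,
      true_label = cls,
      stringsAsFactors = FALSE
    )
    list(trajectory = traj,
         truth = list(class = cls, duration_s = p$dur, speed_um_s = p$v,
                      n_frames = n_frames, rng_seed = seed))
  })
}

#' Simulate a population of single-motor binding events
#'
#' Repeatedly applies [simulate_dynein_track()] with deterministically split
#' sub-seeds. Starting positions are scattered so tracks do not overlap in a
#' rendered field of view.
#'
#' @inheritParams simulate_dynein_track
#' @param n Number of tracks.
#' @param start_xy_fun Function of the track index returning a starting
#'   position `c(x, y)` um; default places tracks at 10 um from the nucleus.
#' @param start_frame_fun Function of the track index returning the first
#'   0-based frame.
#' @return A list with `trajectories` (one long data frame) and `truth`
#'   (data frame: `track_id`, `class`, `duration_s`, `speed_um_s`,
#'   `n_frames`).
#' @export
simulate_dynein_tracks <- function(n, params, imaging = imaging_params(),
                                   seed = NULL,
                                   nucleus = nucleus_ref(0, 0),
                                   start_xy_fun = function(i) c(10, 0),
                                   start_frame_fun = function(i) 0L,
                                   enforce_class_consistency = TRUE,
                                   consistency_threshold = 0.32) {
  n <- as.integer(n)
  if (n < 0) stop("`n` must be >= 0")
  sims <- lapply(seq_len(n), function(i) {
    simulate_dynein_track(
      params, imaging,
      seed = if (is.null(seed)) NULL else derive_seed(seed, i),
      start_xy = start_xy_fun(i), nucleus = nucleus,
      start_frame = as.integer(start_frame_fun(i)), track_id = i,
      enforce_class_consistency = enforce_class_consistency,
      consistency_threshold = consistency_threshold
    )
  })
  truth <- do.call(rbind, lapply(seq_along(sims), function(i) {
    tr <- sims[[i]]$truth
    data.frame(track_id = i, class = tr$class, duration_s = tr$duration_s,
               speed_um_s = tr$speed_um_s, n_frames = tr$n_frames,
               stringsAsFactors = FALSE)
  }))
  list(
    trajectories = do.call(rbind, lapply(sims, `[[`, "trajectory")),
    truth = truth %||% data.frame(track_id = integer(0), class = character(0),
                                  duration_s = numeric(0),
                                  speed_um_s = numeric(0),
                                  n_frames = integer(0))
  )
}

#' Censor residence durations by photobleaching
#'
#' A molecule disappears from the movie either when it unbinds or when its
#' last fluorophore bleaches; the observed residence is the minimum of the
#' true residence and the maximum of the per-fluorophore bleach lifetimes.
#' Used to quantify how far bleaching (time constant 5.9 s) biases the
#' residence fit (mean 0.59 s) -- about an order of magnitude of separation.
#'
#' @param durations True residence durations, s.
#' @param bleach_rate Per-fluorophore bleach rate, s^-1.
#' @param n_fluorophores Fluorophores per molecule.
#' @param seed Optional integer seed.
#' @return Observed (possibly censored) durations, same length.
#' @export
apply_bleach_censoring <- function(durations, bleach_rate = 0.17,
                                   n_fluorophores = 2, seed = NULL) {
  if (bleach_rate < 0) stop("`bleach_rate` must be >= 0")
  if (bleach_rate == 0) return(durations)
  with_seed(seed, {
    n <- length(durations)
    dark <- apply(matrix(rexp(n * n_fluorophores, bleach_rate),
                         nrow = n), 1, max)
    pmin(durations, dark)
  })
}
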