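#' Simulate a run-and-pause cargo trajectory
#'
#' Semi-Markov alternation pause -> run -> pause: pauses are the waiting
#' times for a motor to arrive, runs terminate when the motor unbinds. Run
#' direction is minus-ward with probability `minus_bias`; speed is drawn once
#' per run from a normal truncated at zero. A fraction of vesicles
#' (`immobile_fraction`) never runs and only diffuses passively at
#' `passive_diffusion` (the microtubule-depolymerized condition); paused
#' mobile vesicles are held stationary, reflecting their tethering near the
#' microtubule.
#'
#' @param params A [cargo_params()] object.
#' @param duration Total trace duration, s (>= `frame_interval`).
#' @param frame_interval Sampling interval, s.
#' @param seed Optional integer seed.
#' @param start_xy Starting position `c(x, y)` um.
#' @param nucleus A [nucleus_ref()] giving the minus-end direction.
#' @param localization_noise_sd Optional per-frame localization noise SD, um.
#' @param track_id Track identifier.
#' @return A list with `trajectory` (data frame as in
#'   [simulate_dynein_track()]) and `truth` (list with `immobile`, `schedule`
#'   -- a data frame of contiguous segments `state`, `t_start`, `t_end`,
#'   `velocity_um_s` (signed, minus-ward positive) -- and `rng_seed`).
#' @export
simulate_cargo_trajectory <- function(params, duration, frame_interval,
                                      seed = NULL, start_xy = c(10, 0),
                                      nucleus = nucleus_ref(0, 0),
                                      localization_noise_sd = 0,
                                      track_id = 1L) {
  stopifnot(inherits(params, "cargo_params"))
  if (duration < frame_interval) stop("`duration` must be >= `frame_interval`")
  with_seed(seed, {
    n_frames <- as.integer(floor(duration / frame_interval)) + 1L
    tt <- (seq_len(n_frames) - 1L) * frame_interval
    immobile <- runif(1) < params$immobile_fraction
    d0 <- c(start_xy[1] - nucleus[1], start_xy[2] - nucleus[2])
    nrm <- sqrt(sum(d0^2))
    u <- if (nrm > 0) d0 / nrm else c(1, 0)

    if (immobile) {
      step_sd <- sqrt(2 * params$passive_diffusion * frame_interval)
      x <- start_xy[1] + cumsum(c(0, rnorm(n_frames - 1L, 0, step_sd)))
      y <- start_xy[2] + cumsum(c(0, rnorm(n_frames - 1L, 0, step_sd)))
      schedule <- data.frame(state = "pause", t_start = 0,
                             t_end = duration, velocity_um_s = 0,
                             stringsAsFactors = FALSE)
    } else {
      draw_dwell <- function(mean) {
        if (params$dwell_mode == "fixed") mean else rexp(1, 1 / mean)
      }
      segs <- list(); t <- 0; in_run <- FALSE
      while (t < duration) {
        if (!in_run) {
          d <- draw_dwell(params$pause_mean)
          segs[[length(segs) + 1L]] <-
            c(t, min(t + d, duration), 0)
        } else {
          d <- draw_dwell(params$run_mean)
          v <- rtnorm_pos(1, params$run_speed_mean, params$run_speed_sd)
          dir <- if (runif(1) < params$minus_bias) 1 else -1  # minus-ward positive
          segs[[length(segs) + 1L]] <-
            c(t, min(t + d, duration), dir * v)
        }
        t <- t + d
        in_run <- !in_run
      }
      m <- do.call(rbind, segs)
      schedule <- data.frame(
        state = ifelse(m[, 3] == 0, "pause",
                       ifelse(m[, 3] > 0, "run_minus", "run_plus")),
        t_start = m[, 1], t_end = m[, 2], velocity_um_s = m[, 3],
        stringsAsFactors = FALSE
      )
      # axial position: piecewise-linear integral of the signed velocity
      # (minus-ward positive means motion toward the nucleus, i.e. -u)
      axial_at <- function(times) {
        s <- numeric(length(times))
        acc <- 0
        for (k in seq_len(nrow(schedule))) {
          t0 <- schedule$t_start[k]; t1 <- schedule$t_end[k]
          v <- schedule$velocity_um_s[k]
          inside <- times > t0 & times <= t1
          s[inside] <- acc + v * (times[inside] - t0)
          acc <- acc + v * (t1 - t0)
        }
        s[times <= 0] <- 0
        s
      }
      s <- axial_at(tt)
      x <- start_xy[1] - s * u[1]
      y <- start_xy[2] - s * u[2]
    }
    if (localization_noise_sd > 0) {
      x <- x + rnorm(n_frames, 0, localization_noise_sd)
      y <- y + rnorm(n_frames, 0, localization_noise_sd)
    }
    traj <- data.frame(track_id = track_id, frame = seq_len(n_frames) - 1L,
                       t_s = tt, x_um = x, y_um = y, intensity = NA_real_,
                       true_label = if (immobile) "pause" else NA_character_,
                       stringsAsFactors = FALSE)
    # per-frame truth label from the schedule
    if (!immobile) {
      idx <- findInterval(pmax(tt, 1e-12), schedule$t_start,
                          rightmost.closed = FALSE)
      idx[idx < 1] <- 1L
      traj$true_label <- schedule$state[pmin(idx, nrow(schedule))]
    }
    list(trajectory = traj,
         truth = list(immobile = immobile, schedule = schedule,
                      rng_seed = seed))
  })
}

#' Simulate a population of cargo trajectories
#'
#' @inheritParams simulate_cargo_trajectory
#' @param n Number of vesicles.
#' @return A list with `trajectories` (long data frame) and `truth` (list of
#'   per-track truth lists, named by track id).
#' @export
simulate_cargo_trajectories <- function(n, params, duration, frame_interval,
                                        seed = NULL, start_xy = c(10, 0),
                                        nucleus = nucleus_ref(0, 0),
                                        localization_noise_sd = 0) {
  n <- as.integer(n)
  sims <- lapply(seq_len(n), function(i) {
    simulate_cargo_trajectory(
      params, duration, frame_interval,
      seed = if (is.null(seed)) NULL else derive_seed(seed, i),
      start_xy = start_xy, nucleus = nucleus,
      localization_noise_sd = localization_noise_sd, track_id = i
    )
  })
  list(trajectories = do.call(rbind, lapply(sims, `[[`, "trajectory")),
       truth = setNames(lapply(sims, `[[`, "truth"), seq_len(n)))
}

#' Calibrate the immobile fraction against a target net speed
#'
#' The printed run/pause statistics do not pin down population net transport:
#' most vesicles are effectively immobile over minutes, and the net speed is
#' set by how few vesicles undergo run-and-pause bouts. Given run/pause
#' kinetics, this computes by Monte Carlo over run sums the expected absolute
#' net axial displacement per minute of a *mobile* vesicle, and returns the
#' immobile fraction that yields the requested population mean net speed.
#'
#' @param target_net_speed Target population mean net speed, um/min.
#' @param params A [cargo_params()] object (mobile kinetics).
#' @param window Averaging window, s (default 60).
#' @param n_sim Monte Carlo replicates.
#' @param seed Optional integer seed.
#' @return The calibrated `cargo_params` object with `immobile_fraction` set;
#'   the mobile-vesicle expected |net| speed is attached as attribute
#'   `mobile_net_speed_um_min`.
#' @export
calibrate_immobile_fraction <- function(target_net_speed, params,
                                        window = 60, n_sim = 2000,
                                        seed = NULL) {
  stopifnot(inherits(params, "cargo_params"))
  if (target_net_speed < 0) stop("`target_net_speed` must be >= 0")
  mobile <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      t <- 0; x <- 0; in_run <- FALSE
      while (t < window) {
        if (!in_run) {
          d <- if (params$dwell_mode == "fixed") params$pause_mean else
            rexp(1, 1 / params$pause_mean)
        } else {
          d <- if (params$dwell_mode == "fixed") params$run_mean else
            rexp(1, 1 / params$run_mean)
          d_eff <- min(d, window - t)
          v <- rtnorm_pos(1, params$run_speed_mean, params$run_speed_sd)
          dir <- if (runif(1) < params$minus_bias) 1 else -1
          x <- x + dir * v * d_eff
        }
        t <- t + d
        in_run <- !in_run
      }
      abs(x)
    }, numeric(1))
  })
  e_net <- mean(mobile) * 60 / window
  if (e_net <= target_net_speed) {
    f <- 0
    warning("mobile net speed below target; immobile fraction set to 0")
  } else {
    f <- 1 - target_net_speed / e_net
  }
  out <- params
  out$immobile_fraction <- f
  attr(out, "mobile_net_speed_um_min") <- e_net
  out
}
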