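#' Signed axial displacement with respect to the nucleus reference
#'
#' The axial coordinate of a tracked particle is its change in distance to
#' the minus-end (nucleus) reference: `s(t) = d(t0) - d(t)`, so motion toward
#' the nucleus (minus-end directed) is positive.
#'
#' @param trajectory Single-track data frame (`x_um`, `y_um`), length >= 2.
#' @param nucleus A [nucleus_ref()].
#' @return Numeric vector of length `nrow(trajectory)` (first element 0), um.
#' @export
axial_displacement <- function(trajectory, nucleus) {
  if (nrow(trajectory) < 2) stop("trajectory must have >= 2 points")
  d <- sqrt((trajectory$x_um - nucleus[1])^2 +
            (trajectory$y_um - nucleus[2])^2)
  d[1] - d
}

#' Track classification parameters
#'
#' The net-displacement threshold separating directed from stationary tracks
#' derives from the tracking error: 80 nm per frame times four frames gives
#' the default 0.32 um, discounting apparent displacements attributable to
#' localization error.
#'
#' @param net_displacement_threshold Threshold, um; defaults to
#'   `tracking_error * error_frames`.
#' @param tracking_error Per-frame tracking error, um.
#' @param error_frames Number of frames used to derive the threshold.
#' @return An object of class `classification_params`.
#' @export
classification_params <- function(net_displacement_threshold = NULL,
                                  tracking_error = 0.08, error_frames = 4) {
  thr <- net_displacement_threshold %||% (tracking_error * error_frames)
  if (thr <= 0) stop("threshold must be > 0")
  structure(list(net_displacement_threshold = thr,
                 tracking_error = tracking_error,
                 error_frames = error_frames),
            class = "classification_params")
}

#' Classify a whole track as stationary, minus or plus
#'
#' Uses the net start-to-end axial displacement over the full tracked
#' duration with strict inequalities: net minus-ward displacement greater
#' than the threshold is `"minus"`, net displacement away from the nucleus
#' greater than the threshold is `"plus"`, everything else (including exact
#' ties) is `"stationary"`.
#'
#' @param trajectory Single-track data frame (length >= 2 for a decision).
#' @param nucleus A [nucleus_ref()].
#' @param params A [classification_params()].
#' @return A list of class `track_class`: `label` (`"stationary"`,
#'   `"minus"`, `"plus"`, or `NA` with a `reason` for rejected tracks) and
#'   `net_axial_um` (signed, minus-ward positive).
#' @export
classify_track <- function(trajectory, nucleus,
                           params = classification_params()) {
  if (nrow(trajectory) < 2) {
    return(structure(list(label = NA_character_, net_axial_um = NA_real_,
                          n_frames = nrow(trajectory),
                          reason = "track shorter than 2 frames"),
                     class = "track_class"))
  }
  s <- axial_displacement(trajectory, nucleus)
  net <- s[length(s)]
  thr <- params$net_displacement_threshold
  label <- if (net > thr) "minus" else if (net < -thr) "plus" else "stationary"
  structure(list(label = label, net_axial_um = net,
                 n_frames = nrow(trajectory), reason = NULL),
            class = "track_class")
}

#' Classify every track in a long trajectory table
#'
#' @param trajectories Long trajectory data frame.
#' @inheritParams classify_track
#' @return Data frame with `track_id`, `label`, `net_axial_um`, `n_frames`.
#' @export
classify_tracks <- function(trajectories, nucleus,
                            params = classification_params()) {
  tracks <- split_tracks(trajectories)
  out <- do.call(rbind, lapply(names(tracks), function(id) {
    cl <- classify_track(tracks[[id]], nucleus, params)
    data.frame(track_id = id, label = cl$label,
               net_axial_um = cl$net_axial_um, n_frames = cl$n_frames,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Class proportions table
#'
#' Counts and percentages of stationary / minus / plus labels. Unclassified
#' (`NA`) labels are dropped with a note in the `n_rejected` attribute.
#'
#' @param labels Character vector of labels (or a data frame with a `label`
#'   column).
#' @return A data frame of class `proportions_table`: `label`, `n`,
#'   `percent`, with attributes `total` and `n_rejected`.
#' @export
class_proportions <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  n_rej <- sum(is.na(labels))
  labels <- labels[!is.na(labels)]
  if (!length(labels)) stop("no classified tracks")
  lev <- c("stationary", "minus", "plus")
  counts <- table(factor(labels, levels = union(lev, unique(labels))))
  out <- data.frame(label = names(counts), n = as.integer(counts),
                    percent = 100 * as.integer(counts) / length(labels),
                    stringsAsFactors = FALSE)
  structure(out, total = length(labels), n_rejected = n_rej,
            class = c("proportions_table", "data.frame"))
}

#' @export
print.proportions_table <- function(x, ...) {
  cat(sprintf("Track classes (n = %d):\n", attr(x, "total")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-10s %5d  (%d%%)\n", x$label[i], x$n[i],
                round(x$percent[i])))
  }
  if (attr(x, "n_rejected") > 0) {
    cat(sprintf("  (%d tracks too short to classify)\n", attr(x, "n_rejected")))
  }
  invisible(x)
}

#' Run/pause segmentation parameters
#'
#' Per-step displacements smaller than `zero_step_threshold` (20 nm, the
#' tracking accuracy of the reference tracking tool) count as zero; at least
#' `min_run_steps` consecutive same-direction steps make a run and at least
#' `min_pause_steps` consecutive zero steps make a pause.
#'
#' @param zero_step_threshold Zero-step threshold, um.
#' @param min_run_steps Minimum consecutive directed steps for a run.
#' @param min_pause_steps Minimum consecutive zero steps for a pause.
#' @param step_mode `"axial"` applies the zero test to the nucleus-projected
#'   step (consistent with the directional run definition); `"2d"` applies
#'   it to the 2D step magnitude.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(zero_step_threshold = 0.020,
                                min_run_steps = 4, min_pause_steps = 2,
                                step_mode = c("axial", "2d")) {
  step_mode <- match.arg(step_mode)
  if (zero_step_threshold <= 0 || min_run_steps < 1 || min_pause_steps < 1) {
    stop("segmentation parameters must be positive")
  }
  structure(list(zero_step_threshold = zero_step_threshold,
                 min_run_steps = as.integer(min_run_steps),
                 min_pause_steps = as.integer(min_pause_steps),
                 step_mode = step_mode),
            class = "segmentation_params")
}

# step symbols to segments: maximal same-symbol stretches labelled by length
segments_from_symbols <- function(symbols, params) {
  r <- rle(symbols)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  kind <- character(length(r$values))
  for (i in seq_along(r$values)) {
    kind[i] <- if (r$values[i] == "0") {
      if (r$lengths[i] >= params$min_pause_steps) "pause" else "undetermined"
    } else if (r$lengths[i] >= params$min_run_steps) {
      if (r$values[i] == "+") "run_minus" else "run_plus"
    } else "undetermined"
  }
  data.frame(kind = kind, start_step = starts, end_step = ends,
             n_steps = r$lengths, stringsAsFactors = FALSE)
}

#' Segment a cargo trajectory into runs, pauses and undetermined stretches
#'
#' Each between-frame step is symbolized as zero (axial magnitude below the
#' zero-step threshold), minus-ward or plus-ward. Maximal same-symbol
#' stretches of at least `min_run_steps` directed steps become runs, maximal
#' zero stretches of at least `min_pause_steps` become pauses; shorter
#' stretches are `undetermined` and excluded from run/pause statistics. Any
#' zero or opposite-signed step terminates a run. Segments tile the step
#' sequence without overlap.
#'
#' @param trajectory Single-track data frame with `t_s`, `x_um`, `y_um`
#'   (length >= 3, i.e. >= 2 steps).
#' @param nucleus A [nucleus_ref()].
#' @param params A [segmentation_params()].
#' @return A data frame of `motion_segment`s: `kind`, `start_step`,
#'   `end_step` (1-based step indices; step i joins frames i-1 and i),
#'   `start_frame`, `end_frame` (0-based), `duration_s`,
#'   `axial_disp_um` (minus-ward positive) and `velocity_um_s` (0 for
#'   pauses).
#' @export
segment_motion <- function(trajectory, nucleus,
                           params = segmentation_params()) {
  if (nrow(trajectory) < 3) {
    stop("trajectory must have >= 3 frames (>= 2 steps) for segmentation")
  }
  s <- axial_displacement(trajectory, nucleus)
  step_ax <- diff(s)
  zero <- if (params$step_mode == "axial") {
    abs(step_ax) < params$zero_step_threshold
  } else {
    sqrt(diff(trajectory$x_um)^2 + diff(trajectory$y_um)^2) <
      params$zero_step_threshold
  }
  symbols <- ifelse(zero, "0", ifelse(step_ax > 0, "+", "-"))
  seg <- segments_from_symbols(symbols, params)
  dt <- diff(trajectory$t_s)
  t0 <- trajectory$t_s
  seg$start_frame <- trajectory$frame[seg$start_step]
  seg$end_frame <- trajectory$frame[seg$end_step + 1L]
  seg$duration_s <- t0[seg$end_step + 1L] - t0[seg$start_step]
  seg$axial_disp_um <- s[seg$end_step + 1L] - s[seg$start_step]
  seg$velocity_um_s <- ifelse(seg$kind %in% c("run_minus", "run_plus"),
                              seg$axial_disp_um / seg$duration_s, 0)
  seg
}

#' Segment every track in a long trajectory table
#'
#' @param trajectories Long trajectory data frame.
#' @inheritParams segment_motion
#' @param min_frames Tracks shorter than this are skipped.
#' @return Combined segment data frame with a `track_id` column.
#' @export
segment_tracks <- function(trajectories, nucleus,
                           params = segmentation_params(), min_frames = 3) {
  tracks <- split_tracks(trajectories)
  out <- lapply(names(tracks), function(id) {
    tr <- tracks[[id]]
    if (nrow(tr) < min_frames) return(NULL)
    cbind(track_id = id, segment_motion(tr, nucleus, params))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- cbind(track_id = character(0),
                 segments_from_symbols(character(0), params))
  }
  rownames(out) <- NULL
  out
}

#' Velocity statistics per segment kind
#'
#' Mean +/- SD of per-run velocities (axial displacement over duration) for
#' each run kind. Pauses have zero velocity by definition and are excluded.
#'
#' @param segments Segment data frame from [segment_motion()] or
#'   [segment_tracks()].
#' @return Data frame: `kind`, `n`, `mean_velocity_um_s`, `sd_velocity_um_s`,
#'   `mean_duration_s`, `sd_duration_s`. Empty (zero-row) if there are no
#'   runs.
#' @export
segment_velocities <- function(segments) {
  runs <- segments[segments$kind %in% c("run_minus", "run_plus"), ]
  if (!nrow(runs)) {
    return(data.frame(kind = character(0), n = integer(0),
                      mean_velocity_um_s = numeric(0),
                      sd_velocity_um_s = numeric(0),
                      mean_duration_s = numeric(0),
                      sd_duration_s = numeric(0)))
  }
  out <- do.call(rbind, lapply(split(runs, runs$kind), function(d) {
    data.frame(kind = d$kind[1], n = nrow(d),
               mean_velocity_um_s = mean(abs(d$velocity_um_s)),
               sd_velocity_um_s = if (nrow(d) > 1) sd(abs(d$velocity_um_s)) else 0,
               mean_duration_s = mean(d$duration_s),
               sd_duration_s = if (nrow(d) > 1) sd(d$duration_s) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
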