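#' Motor kinetic parameters
#'
#' Bundles the kinetic description of single motor molecules binding a
#' microtubule: the unbinding (off-) rate, the mixture of behavioural classes
#' observed on binding, and the class velocities. Defaults are the values
#' measured for single dynein molecules in HeLa cells: off-rate 1.7 s^-1
#' (mean residence 0.59 s), a 50/30/20 stationary/minus/plus mixture, and
#' minus/plus velocities of 1.2 +/- 0.7 and 1.1 +/- 0.7 um/s.
#'
#' @param off_rate Unbinding rate from the microtubule, per second (> 0).
#' @param class_probs Probabilities for the (stationary, minus, plus)
#'   behavioural classes; non-negative, summing to 1.
#' @param v_minus_mean,v_minus_sd Minus-end run velocity mean and SD, um/s.
#' @param v_plus_mean,v_plus_sd Plus-end run velocity mean and SD, um/s.
#' @param localization_noise_sd Per-frame localization error SD, um. The
#'   default 0.08 um is the tracking error from which the 0.32 um
#'   classification threshold derives (4 frames x 80 nm).
#' @return An object of class `motor_params`.
#' @export
motor_params <- function(off_rate = 1.7,
                         class_probs = c(stationary = 0.5, minus = 0.3, plus = 0.2),
                         v_minus_mean = 1.2, v_minus_sd = 0.7,
                         v_plus_mean = 1.1, v_plus_sd = 0.7,
                         localization_noise_sd = 0.08) {
  if (!is.numeric(off_rate) || length(off_rate) != 1 || !is.finite(off_rate) ||
      off_rate <= 0) {
    stop("`off_rate` must be a single positive number")
  }
  if (length(class_probs) != 3 || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-8) {
    stop("`class_probs` must be 3 non-negative probabilities summing to 1")
  }
  names(class_probs) <- c("stationary", "minus", "plus")
  if (any(c(v_minus_sd, v_plus_sd, localization_noise_sd) < 0)) {
    stop("sd parameters must be >= 0")
  }
  structure(list(off_rate = off_rate, class_probs = class_probs,
                 v_minus_mean = v_minus_mean, v_minus_sd = v_minus_sd,
                 v_plus_mean = v_plus_mean, v_plus_sd = v_plus_sd,
                 localization_noise_sd = localization_noise_sd),
            class = "motor_params")
}

#' Cargo kinetic parameters
#'
#' Describes run-and-pause motion of endosomal cargo driven by transient
#' motor binding. A run starts when a motor arrives (the pause is the waiting
#' time) and ends when it unbinds, so the default run mean is 1/1.7 ~ 0.59 s,
#' mirroring the motor off-rate. Pause means of 0.6 s (dextran-like) and
#' 0.4 s (EGF-like) reproduce the measured cargo dwell statistics.
#'
#' @param pause_mean Mean pause duration, s.
#' @param run_mean Mean run duration, s; defaults to the reciprocal of the
#'   motor off-rate (1/1.7 s).
#' @param minus_bias Probability that a run is minus-end (nucleus) directed.
#' @param run_speed_mean,run_speed_sd Run speed mean and SD, um/s (speed is
#'   drawn once per run from a normal truncated at 0).
#' @param immobile_fraction Probability that a vesicle never runs and only
#'   diffuses passively.
#' @param passive_diffusion Diffusion coefficient of immobile vesicles,
#'   um^2/s. Default 0.003 um^2/s, the value measured for dextran vesicles
#'   after microtubule depolymerization.
#' @param dwell_mode `"exponential"` (stochastic dwells) or `"fixed"`
#'   (deterministic dwell durations equal to the means).
#' @return An object of class `cargo_params`.
#' @seealso [dextran_cargo_params()], [egf_cargo_params()],
#'   [calibrate_immobile_fraction()]
#' @export
cargo_params <- function(pause_mean = 0.6, run_mean = 1 / 1.7,
                         minus_bias = 0.55,
                         run_speed_mean = 1.2, run_speed_sd = 0.7,
                         immobile_fraction = 0, passive_diffusion = 0.003,
                         dwell_mode = c("exponential", "fixed")) {
  dwell_mode <- match.arg(dwell_mode)
  if (pause_mean <= 0 || run_mean <= 0) stop("durations must be > 0")
  if (minus_bias < 0 || minus_bias > 1) stop("`minus_bias` must be in [0, 1]")
  if (immobile_fraction < 0 || immobile_fraction > 1) {
    stop("`immobile_fraction` must be in [0, 1]")
  }
  if (passive_diffusion < 0) stop("`passive_diffusion` must be >= 0")
  if (run_speed_sd < 0) stop("`run_speed_sd` must be >= 0")
  structure(list(pause_mean = pause_mean, run_mean = run_mean,
                 minus_bias = minus_bias, run_speed_mean = run_speed_mean,
                 run_speed_sd = run_speed_sd,
                 immobile_fraction = immobile_fraction,
                 passive_diffusion = passive_diffusion,
                 dwell_mode = dwell_mode),
            class = "cargo_params")
}

#' Dextran-like and EGF-like cargo presets
#'
#' Convenience presets for the two endosomal cargo conditions: both share
#' ~0.6 s runs, but EGF-like vesicles pause ~30% shorter (0.4 s vs 0.6 s)
#' and carry a slightly stronger minus-end bias, consistent with their faster
#' net delivery toward the perinuclear region.
#'
#' @param ... Overrides passed on to [cargo_params()].
#' @return An object of class `cargo_params`.
#' @export
dextran_cargo_params <- function(...) {
  do.call(cargo_params,
          utils::modifyList(list(pause_mean = 0.6, minus_bias = 0.55), list(...)))
}

#' @rdname dextran_cargo_params
#' @export
egf_cargo_params <- function(...) {
  do.call(cargo_params,
          utils::modifyList(list(pause_mean = 0.4, minus_bias = 0.60), list(...)))
}

#' Imaging and camera parameters
#'
#' Acquisition settings for synthetic movie rendering: HILO-style 50 fps
#' imaging with 20 ms exposure, per-fluorophore single-step photobleaching at
#' rate 0.17 s^-1 (time constant 5.9 s), and two fluorophores per molecule
#' (a GFP on each heavy chain of the dimer). Pixel size (0.16 um) and PSF
#' sigma (1.3 px) are package defaults chosen for a typical EMCCD/100x setup;
#' they are not measured values.
#'
#' @param frame_interval Time between frames, s (>= exposure).
#' @param exposure Exposure time per frame, s (> 0).
#' @param pixel_size Pixel size, um.
#' @param image_shape Image dimensions `c(H, W)` in pixels.
#' @param psf_sigma Gaussian PSF sigma, pixels.
#' @param background_level Mean background, counts.
#' @param photon_scale Peak amplitude contributed by one fluorophore, counts.
#' @param bleach_rate Per-fluorophore bleaching rate, s^-1 (>= 0).
#' @param fluorophores_per_molecule Integer >= 1.
#' @param camera_noise_sd Gaussian read-noise SD, counts.
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(frame_interval = 0.02, exposure = 0.02,
                           pixel_size = 0.16, image_shape = c(96, 96),
                           psf_sigma = 1.3, background_level = 100,
                           photon_scale = 150, bleach_rate = 0.17,
                           fluorophores_per_molecule = 2,
                           camera_noise_sd = 3) {
  if (exposure <= 0 || frame_interval < exposure) {
    stop("need `frame_interval` >= `exposure` > 0")
  }
  if (pixel_size <= 0) stop("`pixel_size` must be > 0")
  if (psf_sigma <= 0) stop("`psf_sigma` must be > 0")
  if (bleach_rate < 0) stop("`bleach_rate` must be >= 0")
  fluorophores_per_molecule <- as.integer(fluorophores_per_molecule)
  if (fluorophores_per_molecule < 1) {
    stop("`fluorophores_per_molecule` must be >= 1")
  }
  if (length(image_shape) != 2 || any(image_shape < 1)) {
    stop("`image_shape` must be c(H, W)")
  }
  structure(list(frame_interval = frame_interval, exposure = exposure,
                 pixel_size = pixel_size,
                 image_shape = as.integer(image_shape),
                 psf_sigma = psf_sigma, background_level = background_level,
                 photon_scale = photon_scale, bleach_rate = bleach_rate,
                 fluorophores_per_molecule = fluorophores_per_molecule,
                 camera_noise_sd = camera_noise_sd),
            class = "imaging_params")
}

#' Nucleus (minus-end) reference point
#'
#' Minus ends of microtubules cluster near the nucleus in the elongated cells
#' this package models, so a point close to the nucleus serves as the
#' minus-end reference for all directional analyses.
#'
#' @param x,y Coordinates of the reference point, um.
#' @return A numeric vector `c(x, y)` of class `nucleus_ref`.
#' @export
nucleus_ref <- function(x = 0, y = 0) {
  if (!all(is.finite(c(x, y)))) stop("nucleus reference must be finite")
  structure(c(x = x, y = y), class = "nucleus_ref")
}

#' @export
print.motor_params <- function(x, ...) {
  cat("Motor kinetic parameters\n")
  cat(sprintf("  off-rate: %.3g /s (mean residence %.3g s)\n",
              x$off_rate, 1 / x$off_rate))
  cat(sprintf("  class mixture (stat/minus/plus): %.2f/%.2f/%.2f\n",
              x$class_probs[1], x$class_probs[2], x$class_probs[3]))
  cat(sprintf("  v minus: %.2g +/- %.2g um/s, v plus: %.2g +/- %.2g um/s\n",
              x$v_minus_mean, x$v_minus_sd, x$v_plus_mean, x$v_plus_sd))
  cat(sprintf("  localization noise: %.3g um\n", x$localization_noise_sd))
  invisible(x)
}

#' @export
print.cargo_params <- function(x, ...) {
  cat("Cargo run-pause parameters\n")
  cat(sprintf("  run %.3g s / pause %.3g s (%s dwells), minus bias %.2f\n",
              x$run_mean, x$pause_mean, x$dwell_mode, x$minus_bias))
  cat(sprintf("  run speed %.2g +/- %.2g um/s; immobile fraction %.3g; D %.3g um^2/s\n",
              x$run_speed_mean, x$run_speed_sd, x$immobile_fraction,
              x$passive_diffusion))
  invisible(x)
}
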