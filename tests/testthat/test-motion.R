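test_that("axial displacement follows nucleus geometry", {
  nuc <- nucleus_ref(0, 0)
  # static track: all zeros
  st <- data.frame(x_um = rep(5, 4), y_um = rep(2, 4))
  expect_equal(axial_displacement(st, nuc), rep(0, 4))
  # straight toward the reference by 1 um: final value +1
  tw <- data.frame(x_um = c(5, 4.5, 4), y_um = 0)
  expect_equal(axial_displacement(tw, nuc)[3], 1)
  # perpendicular motion at large distance: final value ~ 0
  pp <- data.frame(x_um = 1000, y_um = c(0, 0.5, 1))
  expect_lt(abs(axial_displacement(pp, nuc)[3]), 1e-3)
  expect_error(axial_displacement(st[1, ], nuc), ">= 2")
})

test_that("whole-track classification applies strict thresholds", {
  nuc <- nucleus_ref(0, 0)
  mk <- function(net) data.frame(track_id = 1, frame = 0:1, t_s = c(0, 1),
                                 x_um = c(5, 5 - net), y_um = 0)
  expect_equal(classify_track(mk(0.5), nuc)$label, "minus")
  expect_equal(classify_track(mk(-0.5), nuc)$label, "plus")
  # boundary: a net displacement exactly at the threshold is stationary
  # (strict inequality); 0.25 is exactly representable so the arithmetic
  # carries no rounding
  cp <- classification_params(0.25)
  expect_equal(classify_track(mk(0.25), nuc, cp)$label, "stationary")
  expect_equal(classify_track(mk(0.2500001), nuc, cp)$label, "minus")
  expect_equal(classify_track(mk(0.33), nuc)$label, "minus")
  short <- classify_track(mk(1)[1, ], nuc)
  expect_true(is.na(short$label))
  expect_match(short$reason, "shorter")
})

test_that("noise-free simulated tracks classify to their generating labels", {
  p0 <- motor_params(localization_noise_sd = 0)
  sims <- simulate_dynein_tracks(400, p0, seed = 13)
  cls <- classify_tracks(sims$trajectories, nucleus_ref(0, 0))
  keep <- !is.na(cls$label)
  truth <- sims$truth$class[match(cls$track_id[keep], sims$truth$track_id)]
  expect_equal(mean(cls$label[keep] == truth), 1)
})

test_that("classification is invariant to rotation about the nucleus", {
  nuc <- nucleus_ref(0, 0)
  sims <- simulate_dynein_tracks(50, motor_params(), seed = 17)
  traj <- sims$trajectories
  th <- 0.7
  rot <- transform(traj,
                   x_um = cos(th) * x_um - sin(th) * y_um,
                   y_um = sin(th) * x_um + cos(th) * y_um)
  expect_equal(classify_tracks(traj, nuc)$label,
               classify_tracks(rot, nuc)$label)
})

test_that("class proportions reproduce printed count arithmetic", {
  labels <- rep(c("stationary", "minus", "plus"), c(177, 95, 57))
  pt <- class_proportions(labels)
  expect_equal(attr(pt, "total"), 329)
  expect_equal(pt$percent[pt$label == "stationary"], 100 * 177 / 329)
  expect_equal(round(pt$percent), c(54, 29, 17)[match(pt$label,
               c("stationary", "minus", "plus"))])
  all_st <- class_proportions(rep("stationary", 10))
  expect_equal(all_st$percent, c(100, 0, 0))
  expect_error(class_proportions(character(0)), "no classified")

  # multinomial simulation stays within the 95% acceptance region
  set.seed(3)
  draw <- sample(c("stationary", "minus", "plus"), 1e4, replace = TRUE,
                 prob = c(0.5, 0.3, 0.2))
  counts <- table(factor(draw, c("stationary", "minus", "plus")))
  expect_gt(stats::chisq.test(counts, p = c(0.5, 0.3, 0.2))$p.value, 0.05)
})

test_that("segmentation reproduces the hand-worked step example", {
  # axial steps (nm): four +30 (toward nucleus), two 5, three -30
  symbols <- c(rep("+", 4), rep("0", 2), rep("-", 3))
  set.seed(1)
  traj <- trajectory_from_symbols(symbols, directed_step = 0.03,
                                  zero_step = 0.005)
  seg <- segment_motion(traj, nucleus_ref(0, 0))
  expect_equal(seg$kind, c("run_minus", "pause", "undetermined"))
  expect_equal(seg$n_steps, c(4, 2, 3))
  # segments tile the steps without overlap
  expect_equal(sum(seg$n_steps), length(symbols))

  # constant trajectory: one pause covering all steps
  const <- data.frame(track_id = 1, frame = 0:10, t_s = (0:10) * 0.125,
                      x_um = 5, y_um = 1)
  segc <- segment_motion(const, nucleus_ref(0, 0))
  expect_equal(segc$kind, "pause")
  expect_equal(segc$n_steps, 10)
  expect_error(segment_motion(const[1:2, ], nucleus_ref(0, 0)), ">= 3")
})

test_that("segmentation equals the brute-force oracle on random sequences", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(2:50, 1)
    symbols <- sample(c("+", "-", "0"), n, replace = TRUE,
                      prob = c(0.35, 0.25, 0.4))
    traj <- trajectory_from_symbols(symbols)
    seg <- segment_motion(traj, nucleus_ref(0, 0))
    ora <- oracle_segment_symbols(symbols)
    expect_identical(seg$kind, ora$kind)
    expect_identical(seg$start_step, ora$start_step)
    expect_identical(seg$end_step, ora$end_step)
  }
})

test_that("fixed-dwell cargo re-segmentation recovers the schedule", {
  # runs 0.5 s at 1 um/s, pauses 0.5 s, frame 0.125 s: every dwell covers
  # exactly 4 frames so the segmentation recovers the schedule counts
  p <- cargo_params(pause_mean = 0.5, run_mean = 0.5, minus_bias = 1,
                    run_speed_mean = 1, run_speed_sd = 0,
                    dwell_mode = "fixed")
  sim <- simulate_cargo_trajectory(p, 20, 0.125, seed = 5)
  seg <- segment_motion(sim$trajectory, nucleus_ref(0, 0),
                        segmentation_params(min_run_steps = 4,
                                            min_pause_steps = 2))
  sched <- sim$truth$schedule
  expect_equal(sum(seg$kind == "run_minus"),
               sum(sched$state == "run_minus" & sched$t_end <= 20))
  expect_equal(sum(seg$kind == "pause"), sum(sched$state == "pause"))
})

test_that("segment velocities are displacement over duration", {
  traj <- data.frame(track_id = 1, frame = 0:5, t_s = (0:5) * 0.125,
                     x_um = 10 - 0.15 * (0:5), y_um = 0)
  seg <- segment_motion(traj, nucleus_ref(0, 0))
  sv <- segment_velocities(seg)
  expect_equal(sv$kind, "run_minus")
  expect_equal(sv$mean_velocity_um_s, 1.2, tolerance = 1e-10)
  # single run of 0.6 um in 0.5 s is 1.2 um/s
  expect_equal(0.6 / 0.5, 1.2)
  expect_equal(nrow(segment_velocities(seg[seg$kind == "pause", ])), 0)
})

test_that("run velocities recovered from simulated runs match generation", {
  # 1,000 single-run constant-velocity tracks at N(1.2, 0.7) truncated:
  # each track is one run, so the recovered per-run velocity is exact up to
  # the step arithmetic and the mean matches the drawn speeds within 5%
  set.seed(23)
  vs <- numeric(0)
  segs <- list()
  for (i in 1:1000) {
    v <- -1; while (v <= 0) v <- rnorm(1, 1.2, 0.7)
    vs[i] <- v
    tr <- data.frame(track_id = i, frame = 0:8, t_s = (0:8) * 0.125,
                     x_um = 10 - v * (0:8) * 0.125, y_um = 0)
    segs[[i]] <- segment_motion(tr, nucleus_ref(0, 0))
  }
  seg <- do.call(rbind, segs)
  sv <- segment_velocities(seg[seg$kind == "run_minus", ])
  expect_equal(sv$mean_velocity_um_s, mean(vs[vs * 0.125 >= 0.02]),
               tolerance = 0.05)

  # with exponential dwells the rules censor from below (>= 4-step minimum)
  # and merge same-direction runs across sub-frame pauses, so detected runs
  # can only be longer on average than the generating mean, and detected
  # run counts can only fall short of the schedule
  p <- cargo_params(pause_mean = 0.4, run_mean = 0.8, minus_bias = 1,
                    run_speed_mean = 1.2, run_speed_sd = 0.7)
  sim <- simulate_cargo_trajectories(60, p, 60, 0.125, seed = 23)
  segc <- segment_tracks(sim$trajectories, nucleus_ref(0, 0))
  sched <- do.call(rbind, lapply(sim$truth, `[[`, "schedule"))
  expect_gt(mean(segc$duration_s[segc$kind == "run_minus"]), 0.8)
  expect_lt(sum(segc$kind == "run_minus"), sum(sched$state == "run_minus"))
})
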