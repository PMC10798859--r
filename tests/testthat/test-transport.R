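test_that("run/pause statistics summarize segment durations", {
  seg <- data.frame(kind = c("run_minus", "pause", "run_minus", "pause"),
                    duration_s = c(0.5, 0.6, 0.7, 0.4))
  rp <- run_pause_stats(seg)
  expect_equal(rp$summary$mean_s[rp$summary$kind == "run_minus"], 0.6)
  expect_equal(rp$summary$mean_s[rp$summary$kind == "pause"], 0.5)
  # singleton run: mean itself, SD 0
  seg1 <- data.frame(kind = c("run_minus", "pause"), duration_s = c(0.5, 0.2))
  rp1 <- run_pause_stats(seg1)
  expect_equal(rp1$summary$sd_s, c(0, 0))
  expect_error(run_pause_stats(seg[seg$kind == "pause", ]), "at least one")
})

test_that("motile fractions reproduce printed counts", {
  dex <- fraction_over_displacement(counts = c(65, 196))
  expect_equal(dex$percent_rounded, 33)
  egf <- fraction_over_displacement(counts = c(92, 214))
  expect_equal(egf$percent_rounded, 43)

  # all-static population: 0%
  st <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(track_id = i, frame = 0:10, t_s = 0:10, x_um = i, y_um = 0)
  }))
  f0 <- fraction_over_displacement(st, nucleus_ref(0, 0), threshold = 1)
  expect_equal(f0$fraction, 0)
})

test_that("motile fraction is monotone non-increasing in the threshold", {
  p <- dextran_cargo_params()
  sim <- simulate_cargo_trajectories(40, p, 100, 0.125, seed = 31)
  fr <- vapply(c(0.5, 1, 2, 4),
               function(th) fraction_over_displacement(sim$trajectories,
                 nucleus_ref(0, 0), threshold = th)$fraction, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("net speed converts windowed displacement to um/min", {
  mover <- data.frame(track_id = 1, frame = 0:60, t_s = 0:60,
                      x_um = 100 - (0:60), y_um = 0)
  ns <- net_speed(mover, nucleus_ref(0, 0), window = 60)
  expect_equal(ns$per_track$net_speed_um_min, 60)

  immobile <- data.frame(track_id = 1, frame = 0:60, t_s = 0:60,
                         x_um = 10, y_um = 0)
  expect_equal(net_speed(immobile, nucleus_ref(0, 0))$mean, 0)

  short <- data.frame(track_id = 2, frame = 0:10, t_s = 0:10, x_um = 5,
                      y_um = 0)
  ns2 <- net_speed(rbind(mover, short), nucleus_ref(0, 0), window = 60)
  expect_equal(ns2$n_excluded, 1)
})

test_that("delivery time arithmetic matches the worked examples", {
  expect_equal(time_to_target(0.2, 10), 50)
  expect_equal(time_to_target(0.5, 10), 20)
  expect_equal(time_to_target(10, 10), 1)
  expect_warning(t0 <- time_to_target(0, 10), "infinite")
  expect_equal(t0, Inf)
})

test_that("halving all velocities doubles the delivery time", {
  # tracks start far from the reference so the axial reading stays linear
  p <- dextran_cargo_params(immobile_fraction = 0.5)
  sim <- simulate_cargo_trajectories(60, p, 70, 0.25, seed = 32,
                                     start_xy = c(50, 0))
  ns1 <- net_speed(sim$trajectories, nucleus_ref(0, 0), window = 60)$mean
  half <- sim$trajectories
  half$x_um <- 50 + (half$x_um - 50) / 2
  half$y_um <- half$y_um / 2
  ns2 <- net_speed(half, nucleus_ref(0, 0), window = 60)$mean
  expect_equal(time_to_target(ns2), 2 * time_to_target(ns1), tolerance = 0.02)
})

test_that("fisher exact matches enumeration and handles degenerate margins", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2, 2))$p_value, 1)
  t2 <- matrix(c(1, 9, 9, 1), 2, 2)
  expect_equal(fisher_exact(t2)$p_value, oracle_fisher_p(t2))
  # the dynein-association table is significant, as reported
  t3 <- matrix(c(12, 11, 32, 103), 2, 2)
  r3 <- fisher_exact(t3)
  expect_lt(r3$p_value, 0.05)
  expect_equal(r3$p_value, oracle_fisher_p(t3), tolerance = 1e-12)
  expect_equal(r3$odds_ratio, (12 * 103) / (32 * 11))
  z <- fisher_exact(matrix(c(0, 0, 3, 4), 2, 2))
  expect_equal(z$p_value, 1)
  expect_true(z$flagged_zero_margin)
  expect_error(fisher_exact(matrix(c(1, 2, -1, 3), 2, 2)), "non-negative")
  # larger tables go through the Freeman-Halton wrapper
  expect_error(fisher_exact(matrix(1, 2, 3)), "2x2")
  expect_lt(freeman_halton(matrix(c(50, 20, 30, 40, 20, 40), 2, 3))$p_value, 1)
})

test_that("fisher exact agrees with the standard routine on random tables", {
  set.seed(33)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("pipeline report consolidates stages and writes a bundle", {
  ev <- sample_binding_events(motor_params(), 500, seed = 34)
  fit <- fit_residence_survival(ev$duration_s)
  set.seed(35)
  mix <- fit_intensity_mixture(c(rnorm(500, 20, 5), rnorm(500, 40, 5)))
  props <- class_proportions(rep(c("stationary", "minus", "plus"),
                                 c(50, 30, 20)))
  rep1 <- pipeline_report(list(residence_fit = fit, intensity_fit = mix,
                               proportions = props,
                               residence_durations = ev$duration_s))
  expect_equal(rep1$residence$off_rate_per_s, fit$rate)
  expect_equal(rep1$intensity$mean_ratio, mix$mu2 / mix$mu1)
  expect_true(any(grepl("missing stage", rep1$notes)))

  out <- file.path(tempdir(), "report-test")
  pipeline_report(list(residence_fit = fit, intensity_fit = mix,
                       proportions = props,
                       residence_durations = ev$duration_s),
                  output_dir = out)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "class_proportions.csv")))
  expect_true(file.exists(file.path(out, "intensity_histogram.png")))

  # empty input: an empty report with notes, no error
  rep0 <- pipeline_report(list())
  expect_true(length(rep0$notes) >= 8)
})
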