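test_that("residence survival fits recover the exponential rate", {
  # degenerate: all durations equal d gives MLE lambda = 1/d exactly
  same <- rep(0.5, 20)
  expect_equal(fit_residence_survival(same, method = "mle")$rate, 2)

  # simulated exponentials at lambda = 2
  set.seed(4)
  x <- rexp(1e4, 2)
  f <- fit_residence_survival(x, method = "survival_lsq")
  expect_gt(f$rate, 1.9); expect_lt(f$rate, 2.1)
  # sample with mean ~0.59 s gives lambda ~1.7 /s
  z <- rexp(2000, 1 / 0.59)
  f3 <- fit_residence_survival(z, method = "survival_lsq")
  expect_equal(f3$rate, 1.7, tolerance = 0.08)

  expect_error(fit_residence_survival(c(1, -1)), "positive")
  expect_warning(fit_residence_survival(rexp(5, 1)), "fewer than 10")
})

test_that("MLE, survival-LSQ and density-LSQ agree within 10% on large samples", {
  set.seed(6)
  x <- rexp(1e3, 1.7)
  a <- fit_residence_survival(x, method = "mle")$rate
  b <- fit_residence_survival(x, method = "survival_lsq")$rate
  d <- fit_residence_survival(x, method = "density_lsq")$rate
  expect_lt(abs(a - b) / a, 0.1)
  expect_lt(abs(a - d) / a, 0.1)
})

test_that("bootstrap CI for the off-rate has near-nominal coverage", {
  set.seed(7)
  hits <- vapply(1:200, function(i) {
    x <- rexp(1000, 2)
    f <- fit_residence_survival(x, method = "mle", n_bootstrap = 300,
                                seed = 1000 + i)
    f$rate_ci[1] <= 2 && 2 <= f$rate_ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 1.00)
})

test_that("off-rate from mean residence is the reciprocal", {
  expect_equal(off_rate_from_mean(0.59), 1 / 0.59)
  expect_equal(round(off_rate_from_mean(0.59), 1), 1.7)
  expect_equal(off_rate_from_mean(1), 1)
  expect_equal(off_rate_from_mean(0.25), 4)
  expect_error(off_rate_from_mean(0), "> 0")
})

test_that("constrained two-Gaussian mixture recovers its parameters", {
  set.seed(8)
  x <- c(rnorm(2500, 20, 5), rnorm(2500, 40, 5))
  f <- fit_intensity_mixture(x)
  expect_equal(f$mu1, 20, tolerance = 0.05 * 20 / 20)
  expect_equal(f$mu2, 40, tolerance = 0.05)
  expect_equal(f$sigma, 5, tolerance = 0.08)
  expect_equal(f$weight, 0.5, tolerance = 0.05)
  expect_equal(f$mu2 / f$mu1, 2, tolerance = 0.05)
  expect_false(f$single_gaussian_fallback)

  # pure single Gaussian at 20: second weight collapses, fallback flagged
  set.seed(9)
  g <- rnorm(3000, 20, 4)
  fg <- fit_intensity_mixture(g)
  expect_true(fg$single_gaussian_fallback)

  expect_error(fit_intensity_mixture(rep(1, 200)), "identical")
  expect_error(fit_intensity_mixture(rnorm(50)), ">= 100")
})

test_that("mixture fit is shuffle-invariant and scale-equivariant", {
  set.seed(10)
  x <- c(rnorm(1500, 20, 5), rnorm(1500, 40, 5))
  f1 <- fit_intensity_mixture(x)
  f2 <- fit_intensity_mixture(sample(x))
  expect_equal(f1$mu1, f2$mu1)
  expect_equal(f1$mu2, f2$mu2)
  k <- 3
  fk <- fit_intensity_mixture(k * x, bounds1 = k * c(15, 30),
                              bounds2 = k * c(35, 50))
  expect_equal(fk$mu1, k * f1$mu1, tolerance = 0.02)
  expect_equal(fk$mu2, k * f1$mu2, tolerance = 0.02)
})

test_that("molecules per vesicle is a median intensity ratio", {
  set.seed(11)
  s <- rnorm(200, 30, 3)
  expect_equal(estimate_molecules_per_vesicle(s, s, n_bootstrap = 0)$copies, 1)
  expect_equal(estimate_molecules_per_vesicle(3 * s, s, n_bootstrap = 0)$copies,
               3, tolerance = 1e-10)
  r <- estimate_molecules_per_vesicle(1.5 * s, s, n_bootstrap = 200, seed = 1)
  expect_true(r$ci[1] <= 1.5 && 1.5 <= r$ci[2])
  expect_error(estimate_molecules_per_vesicle(s, rep(0, 10)), "zero")
})

test_that("MSD fit recovers diffusion and localization offset", {
  # stationary tracks: D = 0 and intercept = 0
  st <- do.call(rbind, lapply(1:12, function(i) {
    data.frame(track_id = i, frame = 0:29, t_s = (0:29) * 0.1,
               x_um = i, y_um = 2 * i)
  }))
  f0 <- fit_msd(st)
  expect_equal(f0$D, 0)
  expect_equal(f0$intercept, 0)

  # Brownian motion at the measured nocodazole D
  p <- cargo_params(immobile_fraction = 1, passive_diffusion = 0.003)
  sim <- simulate_cargo_trajectories(300, p, 10, 0.1, seed = 12)
  f <- fit_msd(sim$trajectories)
  expect_equal(f$D, 0.003, tolerance = 0.1)

  # localization noise appears as a 4 sigma^2 intercept
  sim2 <- simulate_cargo_trajectories(300, p, 10, 0.1, seed = 13,
                                      localization_noise_sd = 0.05)
  f2 <- fit_msd(sim2$trajectories)
  expect_equal(f2$intercept, 4 * 0.05^2, tolerance = 0.25)
  expect_error(fit_msd(st[st$track_id < 5, ]), ">= 10")
})

test_that("bleach decay fit flags constant traces and recovers rates", {
  flat <- matrix(100, 20, 50)
  f <- fit_bleach_decay(flat, time_s = seq(0, 4.9, by = 0.1))
  expect_true(f$flagged_no_decay || f$time_constant > 1e3)

  img <- imaging_params(bleach_rate = 0.17, frame_interval = 0.1)
  ens <- simulate_bleach_trace_ensemble(img, 119, 20, seed = 14)
  fb <- fit_bleach_decay(ens)
  expect_equal(fb$time_constant, 1 / 0.17, tolerance = 0.1)
})

test_that("expression fraction is the normalized intensity difference", {
  expect_equal(gfp_expression_fraction(0.64, 0.84), 0.2)
  expect_equal(gfp_expression_fraction(0.7, 0.7), 0)
  expect_equal(gfp_expression_fraction(0.5, 1.0), 0.5)
  expect_warning(gfp_expression_fraction(0.9, 0.8), "below detection")
  expect_error(gfp_expression_fraction(-0.1, 0.5), "0, 1.5")
})

test_that("bleaching an order of magnitude slower than unbinding leaves the
           residence fit nearly unbiased", {
  ev <- sample_binding_events(motor_params(off_rate = 1 / 0.59), 5000,
                              seed = 15)
  obs <- apply_bleach_censoring(ev$duration_s, bleach_rate = 1 / 5.9,
                                n_fluorophores = 2, seed = 16)
  lam_true <- fit_residence_survival(ev$duration_s, method = "mle")$rate
  lam_obs <- fit_residence_survival(obs, method = "mle")$rate
  expect_lt(abs(lam_obs - lam_true) / lam_true, 0.1)
})
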