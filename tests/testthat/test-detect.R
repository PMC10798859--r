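make_stack <- function(arr) movie_stack(arr, pixel_size = 0.16,
                                        frame_interval = 0.02)

test_that("sliding average is the centred boundary-truncated mean", {
  arr <- array(rnorm(8 * 8 * 10), c(8, 8, 10))
  mv <- make_stack(arr)
  expect_equal(sliding_average(mv, 1)$frames, arr)
  expect_error(sliding_average(mv, 11), "window")

  # impulse stack: one frame of value 5, window 5 spreads value 1 over the
  # five covering frames (truncated near the ends)
  imp <- array(0, c(4, 4, 12)); imp[, , 6] <- 5
  sm <- sliding_average(make_stack(imp), 5)
  expect_equal(sm$frames[1, 1, 4:8], rep(1, 5))
  expect_equal(sm$frames[1, 1, c(1:3, 9:12)], rep(0, 7))

  # interior frames are exact 5-frame means; boundary frames truncate
  sm2 <- sliding_average(mv, 5)
  expect_equal(sm2$frames[3, 3, 6], mean(arr[3, 3, 4:8]))
  expect_equal(sm2$frames[3, 3, 1], mean(arr[3, 3, 1:3]))
  expect_equal(sm2$frames[3, 3, 10], mean(arr[3, 3, 8:10]))
})

test_that("spot detection finds isolated spots to sub-pixel accuracy", {
  # blank frame: nothing
  set.seed(1)
  blank <- matrix(rnorm(64 * 64, 100, 3), 64, 64)
  expect_equal(nrow(detect_spots(blank)), 0)

  # 10 well-separated bright spots recovered within 1 pixel
  img <- imaging_params(image_shape = c(96, 96), bleach_rate = 0)
  pos <- expand.grid(r = c(20, 45, 70), c = c(20, 45, 70))[1:10 - 1, ]
  pos <- rbind(pos, data.frame(r = 80, c = 80))
  traj <- do.call(rbind, lapply(seq_len(nrow(pos)), function(i) {
    data.frame(track_id = i, frame = 0, t_s = 0,
               x_um = (pos$c[i] - 1) * 0.16, y_um = (pos$r[i] - 1) * 0.16)
  }))
  rend <- render_movie(traj, img, seed = 2, n_frames = 1)
  sp <- detect_spots(rend$movie$frames[, , 1])
  expect_equal(nrow(sp), 10)
  dmin <- vapply(seq_len(nrow(pos)), function(i) {
    min(sqrt((sp$row_px - pos$r[i])^2 + (sp$col_px - pos$c[i])^2))
  }, numeric(1))
  expect_lt(max(dmin), 1)

  # two spots closer than 2 * max_sigma merge into one detection
  two <- matrix(0, 48, 48)
  two <- runpause:::add_gaussian_spot(two, 24, 24, 300, 1.3)
  two <- runpause:::add_gaussian_spot(two, 24, 27, 300, 1.3)
  set.seed(3)
  two <- two + matrix(rnorm(48 * 48, 100, 3), 48, 48)
  expect_equal(nrow(detect_spots(two, max_sigma = 2)), 1)
})

test_that("linking follows spots, bridges gaps and splits long gaps", {
  # one persistent spot: one trajectory spanning every frame
  sp <- data.frame(frame = 0:19, x_um = 5 + 0.01 * (0:19), y_um = 3)
  tr <- link_tracks(sp, max_step = 0.5, max_gap = 1)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 20)

  # two parallel movers separated by more than twice the per-frame step
  sp2 <- rbind(
    data.frame(frame = 0:19, x_um = 1 + 0.05 * (0:19), y_um = 1),
    data.frame(frame = 0:19, x_um = 1 + 0.05 * (0:19), y_um = 3)
  )
  tr2 <- link_tracks(sp2, max_step = 0.5, max_gap = 1)
  expect_equal(length(unique(tr2$track_id)), 2)
  for (id in unique(tr2$track_id)) {
    expect_equal(length(unique(tr2$y_um[tr2$track_id == id])), 1)
  }

  # a disappearance of max_gap + 1 frames breaks the track in two
  sp3 <- data.frame(frame = c(0:4, 7:10), x_um = 2, y_um = 2)
  tr3 <- link_tracks(sp3, max_step = 0.5, max_gap = 1)
  expect_equal(length(unique(tr3$track_id)), 2)
  # but a gap of max_gap frames is bridged
  sp4 <- data.frame(frame = c(0:4, 6:10), x_um = 2, y_um = 2)
  tr4 <- link_tracks(sp4, max_step = 0.5, max_gap = 1)
  expect_equal(length(unique(tr4$track_id)), 1)
})

test_that("linking is invariant to spot input order", {
  set.seed(8)
  sp <- do.call(rbind, lapply(0:14, function(f) {
    data.frame(frame = f,
               x_um = c(1 + 0.04 * f, 4 - 0.04 * f, 2.5),
               y_um = c(1, 2, 4 + 0.02 * f))
  }))
  shuffled <- sp[sample(nrow(sp)), ]
  expect_equal(link_tracks(sp, 0.5, 1), link_tracks(shuffled, 0.5, 1))
})

test_that("intensity measurement recovers aperture sums", {
  # uniform disc of known sum on a zero background
  fr <- matrix(0, 32, 32)
  rr <- 14:18; cc <- 14:18
  d2 <- outer((rr - 16)^2, (cc - 16)^2, "+")
  fr[rr, cc][d2 <= 4] <- 7
  mv <- make_stack(array(fr, c(32, 32, 1)))
  traj <- data.frame(frame = 0, x_um = 15 * 0.16, y_um = 15 * 0.16)
  val <- measure_intensity(mv, traj, aperture_radius = 3)
  expect_equal(as.numeric(val), sum(fr))

  # Gaussian spot: aperture sum matches the analytic enclosed fraction
  g <- matrix(0, 64, 64)
  g <- runpause:::add_gaussian_spot(g, 32, 32, 200, 1.5)
  mvg <- make_stack(array(g, c(64, 64, 1)))
  trajg <- data.frame(frame = 0, x_um = 31 * 0.16, y_um = 31 * 0.16)
  got <- as.numeric(measure_intensity(mvg, trajg, aperture_radius = 4))
  total <- 200 * 2 * pi * 1.5^2
  enclosed <- total * (1 - exp(-4^2 / (2 * 1.5^2)))
  expect_equal(got, enclosed, tolerance = 0.03)

  # border aperture flagged
  trajb <- data.frame(frame = 0, x_um = 0, y_um = 0)
  vb <- measure_intensity(mvg, trajb, aperture_radius = 4)
  expect_true(is.na(vb[1]))
  expect_true(attr(vb, "clipped")[1])
})

test_that("kymographs turn motion into slope", {
  img <- imaging_params(image_shape = c(32, 128), bleach_rate = 0,
                        background_level = 20)
  # static spot -> vertical line
  st <- data.frame(track_id = 1, frame = 0:49, t_s = (0:49) * 0.02,
                   x_um = 60 * 0.16, y_um = 15 * 0.16)
  mv <- render_movie(st, img, seed = 5, n_frames = 50)$movie
  ky <- make_kymograph(mv, p0 = c(0, 15 * 0.16), p1 = c(127 * 0.16, 15 * 0.16))
  peaks <- apply(ky, 1, which.max)
  expect_lt(diff(range(attr(ky, "position_um")[peaks])), 0.2)

  # constant-velocity spot -> line of slope v
  v <- 2.0
  mvx <- data.frame(track_id = 1, frame = 0:49, t_s = (0:49) * 0.02,
                    x_um = 3 + v * (0:49) * 0.02, y_um = 15 * 0.16)
  mv2 <- render_movie(mvx, img, seed = 6, n_frames = 50)$movie
  ky2 <- make_kymograph(mv2, p0 = c(0, 15 * 0.16),
                        p1 = c(127 * 0.16, 15 * 0.16))
  pos <- attr(ky2, "position_um")[apply(ky2, 1, which.max)]
  slope <- unname(coef(lm(pos ~ attr(ky2, "time_s")))[2])
  expect_equal(slope, v, tolerance = 0.1)
  expect_error(make_kymograph(mv2, c(1, 1), c(1, 1)), "zero length")
})
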