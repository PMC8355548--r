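test_that("background removal zeroes static scenes and absorbs offsets", {
  sim <- make_movie(n_beads = 2, amplitude = 0, noise_sd = 0, duration = 0.5,
                    frame_shape = c(48, 48), seed = 1)
  res <- remove_background(sim$movie)
  expect_equal(max(abs(res$frames)), 0)
  # a constant offset changes nothing: the median absorbs it
  moving <- make_movie(n_beads = 2, duration = 0.5, frame_shape = c(64, 64),
                       seed = 2)
  r1 <- remove_background(moving$movie)
  r2 <- remove_background(cq_movie(moving$movie$frames + 50, fps = 120))
  expect_equal(r1$frames, r2$frames, tolerance = 1e-12)
  short <- cq_movie(array(0, c(8, 8, 5)), fps = 10)
  expect_error(remove_background(short), "at least 10 frames")
})

test_that("residual support is confined to the moving bead's path", {
  sim <- make_movie(n_beads = 1, noise_sd = 0, duration = 0.5,
                    frame_shape = c(64, 64), seed = 3)
  res <- remove_background(sim$movie)
  gt <- sim$ground_truth
  d <- dim(res$frames)
  yy <- matrix(seq_len(d[1]), d[1], d[2])
  xx <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  far <- sqrt((xx - gt$x0)^2 + (yy - gt$y0)^2) > 16  # amplitude + render-window diagonal
  for (t in seq_len(d[3]))
    expect_equal(max(abs(res$frames[, , t][far])), 0, tolerance = 1e-10)
})

test_that("noise-free detection finds each well-separated bead every frame", {
  # layout frozen after checking rest separations exceed the oscillation
  # envelopes, so lobes can never merge
  sim <- make_movie(n_beads = 5, f_true = 15, noise_sd = 0, duration = 1,
                    frame_shape = c(160, 160), seed = 1)
  expect_gt(min(dist(cbind(sim$ground_truth$x0, sim$ground_truth$y0))), 24)
  det <- detect_beads(remove_background(sim$movie), polarity = "dark")
  expect_equal(as.integer(range(table(det$frame))), c(5L, 5L))
  expect_true(all(det$peak_contrast < 0))
})

test_that("empty and pure-noise residual stacks give (almost) no detections", {
  zero <- cq_movie(array(0, c(32, 32, 12)), fps = 10)
  expect_equal(nrow(detect_beads(zero)), 0)
  set.seed(7)
  noise <- cq_movie(array(rnorm(128 * 128 * 60, 0, 3), c(128, 128, 60)), fps = 60)
  det <- detect_beads(noise, threshold_sd = 5)
  expect_lt(nrow(det) / 60, 0.1)
})

test_that("static well-separated detections link into full-span trajectories", {
  det <- tidyr::expand_grid(frame = 1:50,
                            tibble::tibble(x = c(10, 40, 70), y = c(10, 40, 70)))
  det$area <- 5L; det$peak_contrast <- -10
  trj <- link_trajectories(det, n_total_frames = 50)
  expect_equal(dplyr::n_distinct(trj$bead_id), 3)
  expect_equal(as.integer(table(trj$bead_id)), rep(50L, 3))
  expect_true(all(trj$observed))
})

test_that("gaps up to two frames are bridged by linear interpolation", {
  det <- tibble::tibble(frame = c(1:10, 13:20), x = c(1:10, 13:20), y = 5,
                        area = 5L, peak_contrast = -10)
  trj <- link_trajectories(det, n_total_frames = 20)
  expect_equal(dplyr::n_distinct(trj$bead_id), 1)
  expect_equal(nrow(trj), 20)
  expect_equal(trj$x, as.numeric(1:20))  # interpolation fills 11, 12
  expect_false(all(trj$observed))
  # a three-frame gap breaks the track
  det2 <- tibble::tibble(frame = c(1:10, 14:20), x = 1, y = 5,
                         area = 5L, peak_contrast = -10)
  trj2 <- link_trajectories(det2, n_total_frames = 20, min_coverage = 0.1)
  expect_equal(dplyr::n_distinct(trj2$bead_id), 2)
})

test_that("oscillating beads are tracked identity-preservingly", {
  sim <- make_movie(n_beads = 5, f_true = 15, noise_sd = 0, duration = 1,
                    frame_shape = c(160, 160), seed = 1)
  det <- detect_beads(remove_background(sim$movie), polarity = "dark")
  trj <- link_trajectories(det, n_total_frames = 120)
  expect_equal(dplyr::n_distinct(trj$bead_id), 5)
  gt <- sim$ground_truth
  hits <- integer(0)
  for (id in unique(trj$bead_id)) {
    tr <- trj[trj$bead_id == id, ]
    j <- which.min((gt$x0 - mean(tr$x))^2 + (gt$y0 - mean(tr$y))^2)
    hits <- c(hits, j)
    s <- 3 * sin(2 * pi * 15 * (tr$frame - 1) / 120 + gt$phase[j])
    err <- sqrt((tr$x - (gt$x0[j] + s * cos(gt$direction[j])))^2 +
                (tr$y - (gt$y0[j] + s * sin(gt$direction[j])))^2)
    # residual-lobe localization carries a small outward bias; identity
    # and phase, which the FFT consumes, are what must survive
    expect_lt(max(err), 2.5)
  }
  expect_setequal(hits, 1:5)  # one track per bead, no identity swaps
})

test_that("crossing paths are resolved by ascending distance and flagged", {
  frames <- 1:21
  det <- dplyr::bind_rows(
    tibble::tibble(frame = frames, x = 10 + 0.5 * (frames - 1), y = 20),
    tibble::tibble(frame = frames, x = 20 - 0.5 * (frames - 1), y = 20.6)
  )
  det$area <- 5L; det$peak_contrast <- -10
  expect_message(trj <- link_trajectories(det, n_total_frames = 21),
                 "ambiguous")
  expect_equal(dplyr::n_distinct(trj$bead_id), 2)
  expect_equal(nrow(trj), 42)
})

test_that("FFT estimation recovers a pure sinusoid and picks the stronger axis", {
  tr <- analytic_trajectory(f = 5, fps = 120, duration = 20)
  est <- estimate_cbf(tr, fps = 120)
  expect_equal(est$f_beat, 5, tolerance = 0.05 / 5)
  expect_equal(est$f_x, est$f_beat)
  expect_gt(est$quality, 5)
  # both axes periodic at different frequencies: larger amplitude wins
  tt <- seq_len(2400) - 1
  tr2 <- tibble::tibble(bead_id = 1L, frame = tt + 1L,
                        x = 50 + 3 * sin(2 * pi * 5 * tt / 120),
                        y = 50 + 1 * sin(2 * pi * 11 * tt / 120))
  est2 <- estimate_cbf(tr2, fps = 120)
  expect_equal(est2$f_beat, est2$f_x)
  expect_equal(est2$f_x, 5, tolerance = 0.01)
  expect_equal(est2$f_y, 11, tolerance = 0.01)
})

test_that("estimation guards Nyquist, short input and flat trajectories", {
  short <- analytic_trajectory(f = 5, fps = 120, duration = 1)
  expect_error(estimate_cbf(short, fps = 120), "too short")
  set.seed(1)
  noise <- tibble::tibble(bead_id = 1L, frame = 1:2400,
                          x = rnorm(2400), y = rnorm(2400))
  est <- estimate_cbf(noise, fps = 120)
  expect_lt(est$f_beat, 60)
  flat <- tibble::tibble(bead_id = 1L, frame = 1:2400, x = 1, y = 2)
  est0 <- estimate_cbf(flat, fps = 120)
  expect_true(is.na(est0$f_beat))
  expect_equal(est0$quality, 0)
})

test_that("linear drift within the detrending budget shifts nothing", {
  tr <- analytic_trajectory(f = 8, fps = 120, duration = 10,
                            drift = c(0.2, 0.1))
  est <- estimate_cbf(tr, fps = 120)
  bin <- 120 / (4 * nrow(tr))
  expect_equal(est$f_beat, 8, tolerance = bin / 8)
})

test_that("movie summary filters on quality and tolerates full exclusion", {
  res <- tibble::tibble(bead_id = 1:10,
                        f_x = 15, f_y = 15, power_x = 1, power_y = 1,
                        f_beat = 15, quality = c(0, rep(100, 9)),
                        n_samples = 2400)
  s <- summarize_movie(res)
  expect_equal(s$n_beads_used, 9)
  expect_equal(s$median_f_beat, 15)
  expect_equal(s$iqr_f_beat, 0)
  all_bad <- dplyr::mutate(res, quality = 0)
  s2 <- summarize_movie(all_bad)
  expect_equal(s2$n_beads_used, 0)
  expect_true(is.na(s2$median_f_beat))
  expect_error(summarize_movie(res[0, ]), "at least one")
})

test_that("the pipeline is invariant to intensity offset and rescale", {
  sim <- make_movie(n_beads = 3, f_true = 7, duration = 5,
                    frame_shape = c(96, 96), seed = 6)
  f0 <- suppressMessages(cbf_pipeline(sim$movie))$summary$median_f_beat
  f_off <- suppressMessages(
    cbf_pipeline(cq_movie(sim$movie$frames + 50, fps = 120)))$summary$median_f_beat
  f_scl <- suppressMessages(
    cbf_pipeline(cq_movie(sim$movie$frames * 1.7, fps = 120)))$summary$median_f_beat
  expect_equal(f_off, f0)
  expect_equal(f_scl, f0)
  expect_equal(f0, 7, tolerance = 0.05 / 7)
})

test_that("pipeline and analytic-series FFT agree on a noise-free single bead", {
  sim <- make_movie(n_beads = 1, f_true = 11, noise_sd = 0, duration = 5,
                    frame_shape = c(64, 64), seed = 4)
  pipe <- suppressMessages(cbf_pipeline(sim$movie))
  gt <- sim$ground_truth
  oracle <- estimate_cbf(
    analytic_trajectory(f = 11, fps = 120, duration = 5,
                        direction = gt$direction, phase = gt$phase,
                        x0 = gt$x0, y0 = gt$y0),
    fps = 120)
  bin <- 120 / (4 * 600)
  expect_equal(pipe$summary$median_f_beat, oracle$f_beat, tolerance = bin)
})

test_that("beat frequency is recovered across the physiological band", {
  # study conditions: amplitude 3 px, SNR 10, 120 fps; shorter 10-s movies
  # keep the property suite fast while leaving the 0.1 Hz resolution ample
  for (f in c(2, 15, 29)) {
    for (seed in c(3, 11)) {
      sim <- make_movie(n_beads = 3, f_true = f, duration = 10, seed = seed)
      s <- suppressMessages(cbf_pipeline(sim$movie))$summary
      expect_gte(s$n_beads_used, 2)
      expect_lt(abs(s$median_f_beat - f), 0.05)
      expect_lt(s$median_f_beat, 60)  # Nyquist guard
    }
  }
})
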