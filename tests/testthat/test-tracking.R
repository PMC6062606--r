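test_that("a single moving spot yields one full-length track", {
  spots <- lapply(1:100, function(f) make_spots(10 + f, 20, frame_index = f))
  trk <- link_tracks(spots, tracking_config())
  expect_equal(length(unique(trk$track_id)), 1L)
  expect_equal(nrow(trk), 100L)
  expect_equal(trk$frame, 1:100)
})

test_that("well-separated spots never swap identities", {
  set.seed(1)
  xa <- cumsum(c(10, rnorm(99, 0, 1))); ya <- cumsum(c(10, rnorm(99, 0, 1)))
  xb <- xa + 70; yb <- ya + 70
  spots <- lapply(1:100, function(f)
    make_spots(c(xa[f], xb[f]), c(ya[f], yb[f]), frame_index = f))
  trk <- link_tracks(spots, tracking_config())
  expect_equal(length(unique(trk$track_id)), 2L)
  t1 <- subset(as.data.frame(trk), track_id == 1)
  expect_equal(t1$x, xa, tolerance = 1e-9)      # stayed on the same spot
})

test_that("linking closes short gaps but respects max_gap", {
  spots <- lapply(1:30, function(f) {
    if (f %in% c(10, 11)) make_spots(numeric(0), numeric(0), frame_index = f)
    else make_spots(15, 15, frame_index = f)
  })
  trk <- link_tracks(spots, tracking_config(max_gap = 2, min_track_len = 20))
  expect_equal(length(unique(trk$track_id)), 1L)
  trk2 <- link_tracks(spots, tracking_config(max_gap = 1, min_track_len = 5))
  expect_equal(length(unique(trk2$track_id)), 2L)
})

test_that("linking is invariant to spot order within a frame", {
  set.seed(2)
  spots_fwd <- lapply(1:40, function(f)
    make_spots(c(10, 40, 70) + rnorm(3, 0, 0.5), c(10, 40, 70) + rnorm(3, 0, 0.5),
               frame_index = f))
  spots_rev <- lapply(spots_fwd, function(s) {
    r <- s[3:1, ]
    attr(r, "pixel_size_nm") <- attr(s, "pixel_size_nm")
    attr(r, "frame_index") <- attr(s, "frame_index")
    class(r) <- class(s)
    r
  })
  a <- as.data.frame(link_tracks(spots_fwd, tracking_config()))
  b <- as.data.frame(link_tracks(spots_rev, tracking_config()))
  # same set of tracks regardless of the track ids assigned
  canon <- function(d) {
    trks <- lapply(split(d[c("frame", "x", "y")], d$track_id),
                   function(t) t[order(t$frame), ])
    trks[order(vapply(trks, function(t) t$x[1], numeric(1)))]
  }
  expect_equal(canon(a), canon(b), ignore_attr = TRUE)
})

test_that("unordered frames are rejected", {
  spots <- list(make_spots(1, 1, frame_index = 2),
                make_spots(1, 1, frame_index = 1))
  expect_error(link_tracks(spots), "increasing")
})

test_that("tracking recovers most ground-truth positions on a default movie", {
  m <- movie_config(n_frames = 150)   # 10 endosomes, 1 px/frame diffusion
  sim <- simulate_movie(kinetic_params(), m, seed = 21)
  spots <- lapply(seq_len(150), function(t)
    segment_spots(get_frame(sim$movie, t, 1), cooccurrence_config(), t))
  trk <- as.data.frame(link_tracks(spots, tracking_config()))
  truth <- sim$truth$positions
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    cand <- trk[trk$frame == truth$frame[i], , drop = FALSE]
    nrow(cand) > 0 &&
      min(sqrt((cand$x - truth$x[i])^2 + (cand$y - truth$y[i])^2)) < 2
  }, logical(1))
  expect_gt(mean(hit), 0.9)
})

test_that("disk-minus-annulus measurement is zero on uniform images and linear", {
  mov <- array(37, dim = c(5, 2, 40, 40),
               dimnames = list(NULL, c("a", "b"), NULL, NULL))
  attr(mov, "pixel_size_nm") <- 80
  attr(mov, "frame_interval_s") <- 3
  attr(mov, "channel_names") <- c("a", "b")
  class(mov) <- "movie_stack"
  track <- data.frame(frame = 1:5, x = rep(20, 5), y = rep(20, 5))
  tr <- measure_intensity(mov, track, tracking_config())
  expect_true(all(abs(tr$a) < 1e-9))

  m <- movie_config(n_frames = 8, image_shape = c(40L, 40L), n_endosomes = 1,
                    diffusion_step_sd_px = 0, noise_model = "none")
  sim <- simulate_movie(kinetic_params(noise_sd = 0), m, seed = 3,
                        onsets_s = 0)
  p <- sim$truth$positions[1, ]
  track <- data.frame(frame = 1:8, x = rep(p$x, 8), y = rep(p$y, 8))
  t1 <- measure_intensity(sim$movie, track, tracking_config())
  mov2 <- sim$movie
  mov2[] <- mov2 * 3
  t3 <- measure_intensity(mov2, track, tracking_config())
  expect_equal(t3$slow, 3 * t1$slow, tolerance = 1e-9)
})

test_that("the measured peak matches the rendered disk mean of a known spot", {
  m <- movie_config(n_frames = 3, image_shape = c(40L, 40L), n_endosomes = 1,
                    diffusion_step_sd_px = 0, noise_model = "none",
                    background_level = 0)
  k <- kinetic_params(noise_sd = 0, baseline = 1e-6)
  sim <- simulate_movie(k, m, seed = 5, onsets_s = 0)
  p <- sim$truth$positions[1, ]
  track <- data.frame(frame = 1:3, x = rep(p$x, 3), y = rep(p$y, 3))
  cfg <- tracking_config()
  tr <- measure_intensity(sim$movie, track, cfg)
  # render oracle: disk mean of the frame-2 slow spot around the center
  fr <- get_frame(sim$movie, 2, "slow")
  rr2 <- outer((seq_len(40) - 1 - p$y)^2, (seq_len(40) - 1 - p$x)^2, "+")
  oracle <- mean(fr[rr2 <= cfg$disk_radius_px^2])
  expect_equal(tr$slow[2], oracle, tolerance = 0.05)
})

test_that("gap frames are interpolated and flagged", {
  mov <- array(10, dim = c(6, 1, 30, 30))
  attr(mov, "pixel_size_nm") <- 80
  attr(mov, "frame_interval_s") <- 3
  attr(mov, "channel_names") <- "a"
  class(mov) <- "movie_stack"
  track <- data.frame(frame = c(1, 2, 4, 5), x = c(10, 10, 14, 14),
                      y = rep(15, 4))
  tr <- measure_intensity(mov, track, tracking_config())
  expect_equal(nrow(tr), 5L)
  expect_equal(attr(tr, "interpolated"), c(FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("bleach correction recovers an imposed exponential decay", {
  sim <- simulate_traces(n_tracks = 20, seed = 13)
  tr <- sim$traces[[1]]
  decay <- exp(-tr$time_s / 600)
  bleached <- tr
  bleached$slow <- tr$slow * decay
  bleached$transient <- tr$transient * decay
  # reference: whole-movie mean intensity; dominated by background pixels,
  # with a small contribution from the endosome spots
  field <- rowMeans(vapply(sim$traces, function(x) x$slow,
                           numeric(nrow(tr))))
  reference <- (1000 + field) * decay
  fixed <- bleach_correct(bleached, "exponential", reference = reference)
  tau <- attr(fixed, "bleach_tau_s")[["slow"]]
  expect_equal(tau, 600, tolerance = 0.1)
  # the recovered baseline is flat across the movie within 5%
  residual <- decay * exp(tr$time_s / tau)
  expect_lt(max(abs(residual / residual[1] - 1)), 0.05)

  # trace-only fallback: correction at least removes most of the trend
  self <- bleach_correct(bleached, "exponential")
  tau_self <- attr(self, "bleach_tau_s")[["slow"]]
  expect_true(is.finite(tau_self) && tau_self > 0)
  resid_decay <- exp(-1800 * abs(1 / 600 - 1 / tau_self))
  expect_gt(resid_decay, 0.5)       # vs 0.05 left uncorrected

  # no imposed bleaching: correction stays within 2%
  same <- bleach_correct(tr, "exponential")
  expect_equal(same$slow, tr$slow, tolerance = 0.02)

  # model "none" is the identity
  expect_identical(bleach_correct(tr, "none"), tr)
  expect_error(bleach_correct(tr[1:5, ], "exponential"), "short")
})

test_that("bleach correction preserves the order of wave peaks", {
  sim <- simulate_traces(n_tracks = 12, seed = 17)
  tr <- sim$traces[[1]]
  decay <- exp(-tr$time_s / 800)
  bleached <- tr
  bleached$slow <- tr$slow * decay
  field <- rowMeans(vapply(sim$traces, function(x) x$slow,
                           numeric(nrow(tr))))
  fixed <- bleach_correct(bleached, "exponential",
                          reference = (100 + field) * decay)
  w0 <- detect_waves(tr)
  w1 <- detect_waves(fixed)
  p0 <- sort(w0$t_peak[w0$channel == "slow"])
  p1 <- sort(w1$t_peak[w1$channel == "slow"])
  expect_gt(length(p1), 0)
  expect_equal(length(p1), length(p0))
  expect_equal(p1, p0, tolerance = 6 / min(p0))   # within two frames each
})
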