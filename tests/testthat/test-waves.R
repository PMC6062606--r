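test_that("a flat noisy baseline contains no waves", {
  set.seed(1)
  y <- 20 + rnorm(600, 0, 10)
  w <- detect_waves(y, time_s = seq(0, by = 3, length.out = 600))
  expect_equal(nrow(w), 0L)
})

test_that("a noiseless slow wave is recovered with the archetypal dwell", {
  sim <- simulate_traces(kinetic_params(noise_sd = 0, onset_jitter_sd = 1e-9),
                         duration_s = 900, seed = 1, onsets_s = 300)
  w <- detect_waves(sim$traces[[1]])
  slow <- w[w$channel == "slow", ]
  expect_equal(nrow(slow), 1L)
  expect_equal(slow$t_end - slow$t_onset, 195, tolerance = 3 / 195)
  tran <- w[w$channel == "transient", ]
  expect_equal(tran$t_end - tran$t_onset, 80, tolerance = 3 / 80)
})

test_that("onsets of well-separated noisy waves are found within two frames", {
  p <- kinetic_params(noise_sd = 5, onset_jitter_sd = 1e-9)   # 5% amplitude
  sim <- simulate_traces(p, duration_s = 1200, seed = 2,
                         onsets_s = c(150, 750))
  w <- as.data.frame(detect_waves(sim$traces[[1]]))
  err <- match_waves(w, sim$truth)
  expect_true(all(is.finite(err$onset)))
  expect_true(all(err$onset <= 6))
})

test_that("noiseless detection matches the generator oracle exactly", {
  p <- kinetic_params(noise_sd = 0)
  for (seed in 1:5) {
    sim <- simulate_traces(p, n_tracks = 2, seed = seed)
    for (tr in sim$traces) {
      w <- as.data.frame(detect_waves(tr))
      truth <- sim$truth[sim$truth$track_id == attr(tr, "track_id"), ]
      err <- match_waves(w, truth)
      expect_true(all(is.finite(unlist(err))))
      expect_true(all(err$onset <= 3 & err$peak <= 3 & err$end <= 3))
      expect_equal(nrow(w), nrow(truth))     # no spurious waves either
      # detected waves never overlap within a channel
      for (ch in unique(w$channel)) {
        d <- w[w$channel == ch, ]
        d <- d[order(d$t_onset), ]
        if (nrow(d) > 1)
          expect_true(all(d$t_end[-nrow(d)] <= d$t_onset[-1] + 1e-9))
      }
    }
  }
})

test_that("kinetics are recovered without material bias under 10% noise", {
  sim <- simulate_traces(n_tracks = 40, seed = 3)   # defaults: noise_sd 10
  w <- detect_all(sim$traces)
  st <- wave_statistics(structure(w, class = c("wave_set", "data.frame")))
  slow <- st$per_channel[st$per_channel$channel == "slow", ]
  tran <- st$per_channel[st$per_channel$channel == "transient", ]
  expect_equal(slow$t_on_mean, 122, tolerance = 0.1)
  expect_equal(slow$t_off_mean, 73, tolerance = 0.1)
  expect_equal(tran$dwell_mean, 80, tolerance = 0.1)
})

test_that("wave statistics degenerate gracefully and ignore row order", {
  w <- data.frame(channel = "slow", t_onset = 10, t_peak = 50, t_end = 80,
                  amplitude = 100, track_id = 1L)
  st <- wave_statistics(w)
  expect_equal(st$per_channel$dwell_sd, 0)
  expect_equal(st$per_channel$t_on_sd, 0)
  expect_error(wave_statistics(w[0, ]), "undefined")

  sim <- simulate_traces(n_tracks = 6, seed = 4)
  wv <- detect_all(sim$traces)
  shuffled <- wv[sample(nrow(wv)), ]
  a <- wave_statistics(wv)$per_channel
  b <- wave_statistics(shuffled)$per_channel
  expect_equal(a, b)
})

test_that("pooled means equal the weighted per-track means", {
  sim <- simulate_traces(n_tracks = 8, seed = 5)
  wv <- detect_all(sim$traces)
  st <- wave_statistics(wv)
  for (ch in c("slow", "transient")) {
    d <- wv[wv$channel == ch, ]
    per_track <- tapply(d$t_end - d$t_onset, d$track_id, mean)
    ns <- tapply(d$t_onset, d$track_id, length)
    pooled <- sum(per_track * ns) / sum(ns)
    expect_equal(st$per_channel$dwell_mean[st$per_channel$channel == ch],
                 unname(pooled))
  }
})

test_that("periodicity is the onset-to-onset interval per track and channel", {
  w <- data.frame(channel = "slow", track_id = 1L,
                  t_onset = c(0, 300, 600), t_peak = c(122, 422, 722),
                  t_end = c(195, 495, 795), amplitude = 100)
  p <- periodicity(w)
  expect_equal(p$interval_s, c(300, 300))
  expect_equal(nrow(periodicity(w[1, ])), 0L)
  # peak anchoring is an option
  expect_equal(periodicity(w, method = "peak")$interval_s, c(300, 300))
  # track-length filter
  p2 <- periodicity(w, track_frames = c(`1` = 100), min_track_frames = 200)
  expect_equal(nrow(p2), 0L)
})

test_that("generated inter-onset intervals average near one per five minutes", {
  sim <- simulate_traces(n_tracks = 40, seed = 6)
  truth <- sim$truth[sim$truth$channel == "slow", ]
  p <- periodicity(truth)
  expect_gt(nrow(p), 50)
  expect_equal(mean(p$interval_s), 300, tolerance = 0.15)
})

test_that("wave counting uses a half-open window", {
  w <- data.frame(channel = "slow", t_onset = c(0, 150, 300),
                  t_peak = c(10, 160, 310), t_end = c(20, 170, 320),
                  amplitude = 1)
  expect_equal(count_waves(w[0, ], c(0, 300)), 0L)
  expect_equal(count_waves(w, c(0, 300)), 2L)     # onset at 300 excluded
  expect_equal(count_waves(w, c(0, 301)), 3L)
})

test_that("averaged identical segments reproduce the segment with zero SD", {
  p <- kinetic_params(noise_sd = 0, onset_jitter_sd = 1e-9)
  sim <- simulate_traces(p, duration_s = 420, seed = 7, onsets_s = 90)
  seg <- sim$traces[[1]]
  cfg <- detection_config(baseline_window_frames = 40)
  avg <- average_profiles(list(seg, seg, seg), cfg, grid_dt_s = 3)
  expect_true(all(avg$mean >= -1e-9 & avg$mean <= 100 + 1e-9))
  expect_true(all(avg$sd < 1e-9))
  for (ch in c("slow", "transient")) {
    v <- avg$mean[avg$channel == ch]
    expect_equal(min(v), 0, tolerance = 1e-6)
    expect_equal(max(v), 100, tolerance = 1e-6)
  }
})

test_that("the averaged slow peak precedes the averaged transient peak", {
  p <- kinetic_params(noise_sd = 2, onset_jitter_sd = 1e-9)
  segs <- lapply(1:6, function(s)
    simulate_traces(p, duration_s = 420, seed = 100 + s,
                    onsets_s = 90)$traces[[1]])
  cfg <- detection_config(baseline_window_frames = 40)
  avg <- average_profiles(segs, cfg, grid_dt_s = 3)
  pk <- function(ch) {
    d <- avg[avg$channel == ch, ]
    d$time_s[which.max(d$mean)]
  }
  expect_lt(pk("slow"), pk("transient"))
})

test_that("short traces are rejected by the detector", {
  expect_error(detect_waves(rnorm(20), time_s = 1:20), "baseline window")
})
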