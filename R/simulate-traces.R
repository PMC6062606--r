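#' Simulate per-endosome ESCRT recruitment intensity traces
#'
#' Generates two-channel intensity traces for one or more tracked endosomes.
#' Each wave event places a slow/linear wave (rise over `slow_t_on`, fall
#' over `slow_t_off`) and a coordinated fast/transient wave whose onset is
#' anchored so that both channels dissociate synchronously (plus Gaussian
#' jitter). Events arrive as a Poisson process at `wave_rate`; candidate
#' events overlapping an already placed wave are redrawn uniformly over the
#' feasible onset range, so waves on one endosome never superpose.
#'
#' @param params A [kinetic_params()] object.
#' @param duration_s Trace duration in seconds.
#' @param dt_s Sampling interval in seconds; samples lie on the grid
#'   `0, dt_s, 2 dt_s, ...`.
#' @param n_tracks Number of independent tracks to simulate.
#' @param seed Integer seed; identical `(params, seed)` give identical output.
#' @param onsets_s Optional numeric vector (or list of vectors, one per
#'   track) of slow-wave onset times in seconds, overriding the Poisson
#'   process. Useful to force a known number of waves.
#' @return A list with elements `traces` (a list of `intensity_trace` data
#'   frames with columns `time_s`, `slow`, `transient`) and `truth` (a data
#'   frame of generated waves: `track_id`, `channel`, `t_onset`, `t_peak`,
#'   `t_end`, `amplitude`).
#' @examples
#' sim <- simulate_traces(kinetic_params(noise_sd = 0), duration_s = 400,
#'                        seed = 1, onsets_s = 60)
#' subset(sim$truth, channel == "slow")$t_end - subset(sim$truth, channel == "slow")$t_onset
#' @export
simulate_traces <- function(params = kinetic_params(), duration_s = 1800,
                            dt_s = 3, n_tracks = 1, seed = NULL,
                            onsets_s = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  check_pos(duration_s, "duration_s")
  check_pos(dt_s, "dt_s")
  check_pos(n_tracks, "n_tracks")
  dwell_slow <- params$slow_t_on + params$slow_t_off
  dwell_tr <- params$transient_t_on + params$transient_t_off
  if (params$wave_rate > 0 && dwell_slow >= duration_s)
    stop("degenerate configuration: a wave is longer than the trace duration",
         call. = FALSE)
  if (!is.null(onsets_s) && !is.list(onsets_s))
    onsets_s <- rep(list(onsets_s), n_tracks)

  with_seed(seed, {
    time_s <- seq(0, duration_s, by = dt_s)
    traces <- vector("list", n_tracks)
    truth <- vector("list", n_tracks)
    for (tr in seq_len(n_tracks)) {
      onsets <- if (!is.null(onsets_s)) sort(onsets_s[[tr]]) else
        draw_wave_onsets(params$wave_rate, duration_s, dwell_slow)
      waves <- place_waves(onsets, params, dwell_slow, dwell_tr, duration_s)
      slow <- render_channel(time_s, waves[waves$channel == "slow", ],
                             params$baseline,
                             params$incomplete_dissociation_fraction)
      tran <- render_channel(time_s, waves[waves$channel == "transient", ],
                             params$baseline, 0)
      if (params$noise_sd > 0) {
        slow <- slow + stats::rnorm(length(slow), 0, params$noise_sd)
        tran <- tran + stats::rnorm(length(tran), 0, params$noise_sd)
      }
      df <- data.frame(time_s = time_s, slow = slow, transient = tran)
      attr(df, "frame_interval_s") <- dt_s
      attr(df, "channels") <- c("slow", "transient")
      attr(df, "track_id") <- tr
      attr(df, "bleach_corrected") <- FALSE
      attr(df, "normalized") <- FALSE
      class(df) <- c("intensity_trace", "data.frame")
      traces[[tr]] <- df
      if (nrow(waves)) waves$track_id <- tr
      truth[[tr]] <- waves
    }
    truth <- do.call(rbind, truth[vapply(truth, nrow, 1L) > 0])
    if (is.null(truth))
      truth <- data.frame(channel = character(), t_onset = numeric(),
                          t_peak = numeric(), t_end = numeric(),
                          amplitude = numeric(), track_id = integer())
    list(traces = traces, truth = truth)
  })
}

# Poisson onsets with uniform redraw of overlapping candidates.  Candidate
# onsets live on [0, duration - dwell] so the onset intensity equals `rate`
# over the feasible range and every wave fits inside the trace.
draw_wave_onsets <- function(rate, duration_s, dwell) {
  span <- duration_s - dwell
  if (rate <= 0 || span <= 0) return(numeric(0))
  n <- stats::rpois(1L, rate * span)
  if (n == 0L) return(numeric(0))
  cand <- sort(stats::runif(n, 0, span))
  acc <- numeric(0)
  for (o in cand) {
    tries <- 0L
    while (length(acc) && any(o < acc + dwell & o + dwell > acc) &&
           tries < 1000L) {
      o <- stats::runif(1L, 0, span)
      tries <- tries + 1L
    }
    if (!length(acc) || !any(o < acc + dwell & o + dwell > acc))
      acc <- c(acc, o)
  }
  sort(acc)
}

# ground-truth wave table for one track
place_waves <- function(onsets, params, dwell_slow, dwell_tr, duration_s) {
  if (!length(onsets))
    return(data.frame(channel = character(), t_onset = numeric(),
                      t_peak = numeric(), t_end = numeric(),
                      amplitude = numeric()))
  rows <- lapply(onsets, function(o) {
    anchor <- o + dwell_slow - dwell_tr
    jit <- stats::rnorm(1L, 0, params$onset_jitter_sd)
    jit <- max(min(jit, 3 * params$onset_jitter_sd),
               -3 * params$onset_jitter_sd)
    ot <- min(max(anchor + jit, o), duration_s - dwell_tr)
    data.frame(
      channel = c("slow", "transient"),
      t_onset = c(o, ot),
      t_peak = c(o + params$slow_t_on, ot + params$transient_t_on),
      t_end = c(o + dwell_slow, ot + dwell_tr),
      amplitude = c(params$amplitude_slow, params$amplitude_transient)
    )
  })
  do.call(rbind, rows)
}

# piecewise-linear rendering; the peak sample equals baseline + amplitude
# exactly when the peak time lies on the grid
render_channel <- function(time_s, waves, baseline, retain_frac) {
  y <- rep(baseline, length(time_s))
  if (!nrow(waves)) return(y)
  waves <- waves[order(waves$t_onset), ]
  floor_level <- baseline
  for (i in seq_len(nrow(waves))) {
    o <- waves$t_onset[i]; pk <- waves$t_peak[i]; en <- waves$t_end[i]
    a <- waves$amplitude[i]
    peak_level <- baseline + a
    end_level <- baseline + retain_frac * a
    pre <- time_s < o
    y[pre & time_s >= (if (i == 1) -Inf else waves$t_end[i - 1])] <-
      floor_level
    up <- time_s >= o & time_s <= pk
    y[up] <- floor_level + (peak_level - floor_level) * (time_s[up] - o) / (pk - o)
    dn <- time_s > pk & time_s <= en
    y[dn] <- peak_level + (end_level - peak_level) * (time_s[dn] - pk) / (en - pk)
    floor_level <- end_level
    y[time_s > en] <- floor_level
  }
  y
}
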