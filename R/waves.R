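#' Detect ESCRT recruitment waves in an intensity trace
#'
#' The detector operationalizes what is otherwise scored by eye on
#' single-endosome intensity profiles. Stages:
#' 1. moving-median smoothing (`smoothing_window_frames`);
#' 2. robust noise SD from lag-1 differences;
#' 3. a local baseline: samples above a coarse global floor (the
#'    `baseline_percentile` of the smoothed trace plus `k_sigma` noise SDs)
#'    are masked, the mask is grown by `merge_gap_frames`, and the baseline
#'    is the rolling median of the remaining samples over
#'    `baseline_window_frames` (linearly interpolated where a window holds
#'    no baseline samples). The baseline is local so that dissociation can
#'    be scored against a drifting floor, e.g. when the slow channel does
#'    not return fully to baseline;
#' 4. candidate waves are maximal runs of at least `min_above_frames`
#'    smoothed samples above baseline + `k_sigma` * SD, with sub-threshold
#'    gaps up to `merge_gap_frames` bridged (hysteresis); runs whose peak
#'    amplitude is below `min_wave_amplitude` of the smoothed trace range
#'    are discarded;
#' 5. each candidate's onset, peak and end are refined by least-squares
#'    fitting an asymmetric piecewise-linear pulse (rise then fall; the
#'    amplitude is profiled out analytically) over the run plus a few
#'    flanking baseline frames. The flanking frames anchor the onset and
#'    end, which removes the threshold-crossing bias that would otherwise
#'    shorten every wave by roughly `k_sigma * SD / slope` on each side.
#'
#' Refined waves are clipped so that consecutive waves in one channel never
#' overlap.
#'
#' @param trace An `intensity_trace` (detection runs per channel) or a
#'   numeric vector of intensities (then `time_s` must be given).
#' @param cfg A [detection_config()].
#' @param time_s Sample times for a numeric-vector `trace`.
#' @return A `wave_set` data frame: `channel`, `t_onset`, `t_peak`, `t_end`,
#'   `amplitude` (and `track_id` when the trace carries one), ordered by
#'   onset, satisfying `t_onset <= t_peak <= t_end`.
#' @seealso [wave_statistics()], [periodicity()], [count_waves()]
#' @export
detect_waves <- function(trace, cfg = detection_config(), time_s = NULL) {
  stopifnot(inherits(cfg, "detection_config"))
  if (is.numeric(trace) && is.null(dim(trace))) {
    stopifnot(!is.null(time_s), length(time_s) == length(trace))
    w <- detect_waves_series(time_s, trace, cfg)
    w$channel <- rep("series", nrow(w))
    return(wave_set(w[c("channel", "t_onset", "t_peak", "t_end", "amplitude")]))
  }
  stopifnot(inherits(trace, "intensity_trace"))
  chans <- attr(trace, "channels")
  out <- lapply(chans, function(ch) {
    w <- detect_waves_series(trace$time_s, trace[[ch]], cfg)
    if (nrow(w)) w$channel <- ch
    w
  })
  out <- do.call(rbind, out[vapply(out, nrow, 1L) > 0])
  if (is.null(out))
    out <- data.frame(t_onset = numeric(), t_peak = numeric(),
                      t_end = numeric(), amplitude = numeric(),
                      channel = character())
  out <- out[c("channel", "t_onset", "t_peak", "t_end", "amplitude")]
  tid <- attr(trace, "track_id")
  if (!is.null(tid)) out$track_id <- rep(tid, nrow(out))
  wave_set(out)
}

wave_set <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("wave_set", "data.frame")
  df
}

detect_waves_series <- function(tt, y, cfg) {
  empty <- data.frame(t_onset = numeric(), t_peak = numeric(),
                      t_end = numeric(), amplitude = numeric())
  n <- length(y)
  if (n < cfg$baseline_window_frames)
    stop("trace shorter than the baseline window", call. = FALSE)
  ok <- is.finite(y)
  if (!all(ok)) {      # interpolate isolated missing samples
    if (sum(ok) < cfg$baseline_window_frames) return(empty)
    y <- stats::approx(tt[ok], y[ok], tt, rule = 2)$y
  }
  sm_w <- cfg$smoothing_window_frames
  if (sm_w %% 2L == 0L) sm_w <- sm_w + 1L
  sm <- if (sm_w > 1) stats::runmed(y, sm_w) else y
  sig <- max(noise_sd_diff(y), 1e-9)
  b <- local_baseline(tt, sm, cfg, sig)
  above <- sm > b + cfg$k_sigma * sig
  if (!any(above)) return(empty)
  # hysteresis: bridge short sub-threshold gaps, but only when the trace does
  # not actually return near baseline inside the gap (two waves separated by
  # a true baseline visit stay distinct)
  r0 <- rle(above)
  e0 <- cumsum(r0$lengths); s0 <- e0 - r0$lengths + 1L
  for (i in seq_along(r0$values))
    if (!r0$values[i] && r0$lengths[i] <= cfg$merge_gap_frames &&
        i > 1L && i < length(r0$values) &&
        min(sm[s0[i]:e0[i]] - b[s0[i]:e0[i]]) > 0.5 * cfg$k_sigma * sig)
      above[s0[i]:e0[i]] <- TRUE
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  rng <- diff(range(sm))
  waves <- list()
  for (i in which(r$values & r$lengths >= cfg$min_above_frames)) {
    i0 <- starts[i]; i1 <- ends[i]
    pk <- i0 - 1L + which.max(sm[i0:i1])
    amp <- sm[pk] - b[pk]
    if (amp < cfg$min_wave_amplitude * rng) next
    est <- c(tt[i0], tt[pk], tt[i1])
    if (cfg$refine == "tent")
      est <- refine_tent(tt, y, b, i0, i1, est)
    est[1] <- max(est[1], tt[1]); est[3] <- min(est[3], tt[n])
    est[2] <- min(max(est[2], est[1]), est[3])
    waves[[length(waves) + 1L]] <- data.frame(
      t_onset = est[1], t_peak = est[2], t_end = est[3], amplitude = amp)
  }
  if (!length(waves)) return(empty)
  w <- do.call(rbind, waves)
  w <- w[order(w$t_onset), , drop = FALSE]
  # refined intervals must not overlap: clip neighbours at the midpoint
  if (nrow(w) > 1) for (j in seq_len(nrow(w) - 1L)) {
    if (w$t_end[j] > w$t_onset[j + 1L]) {
      mid <- (max(w$t_peak[j], w$t_onset[j + 1L]) +
              min(w$t_end[j], w$t_peak[j + 1L])) / 2
      w$t_end[j] <- max(w$t_peak[j], min(w$t_end[j], mid))
      w$t_onset[j + 1L] <- min(w$t_peak[j + 1L], max(w$t_onset[j + 1L], mid))
    }
  }
  w
}

# masked rolling-median baseline (stage 3 above)
local_baseline <- function(tt, sm, cfg, sig) {
  n <- length(sm)
  b0 <- stats::quantile(sm, cfg$baseline_percentile / 100, names = FALSE)
  mask <- sm > b0 + cfg$k_sigma * sig
  grown <- mask
  g <- cfg$merge_gap_frames
  if (g > 0) for (s in seq_len(g))
    grown <- grown | c(mask[-seq_len(s)], rep(FALSE, s)) |
      c(rep(FALSE, s), mask[seq_len(n - s)])
  h <- cfg$baseline_window_frames %/% 2L
  b <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    free <- j[!grown[j]]
    if (length(free) >= 5L) b[i] <- stats::median(sm[free])
  }
  if (all(is.na(b))) b[] <- b0
  else if (anyNA(b))
    b <- stats::approx(tt[!is.na(b)], b[!is.na(b)], tt, rule = 2)$y
  b
}

# least-squares fit of an asymmetric tent pulse over the run plus flanks;
# the amplitude is profiled out, leaving a 3-parameter search
refine_tent <- function(tt, y, b, i0, i1, init) {
  pad <- 5L
  idx <- max(1L, i0 - pad):min(length(y), i1 + pad)
  r <- y[idx] - b[idx]
  tw <- tt[idx]
  obj <- function(th) {
    if (!(th[1] < th[2] && th[2] < th[3])) return(1e12)
    g <- ifelse(tw < th[1] | tw > th[3], 0,
                ifelse(tw <= th[2], (tw - th[1]) / (th[2] - th[1]),
                       (th[3] - tw) / (th[3] - th[2])))
    sg <- sum(g * g)
    if (sg < 1e-9) return(1e12)
    a <- sum(r * g) / sg
    if (a <= 0) return(1e12)
    sum((r - a * g)^2)
  }
  init <- c(init[1] - 1e-6, init[2], init[3] + 1e-6)
  o <- try(stats::optim(init, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-9)),
           silent = TRUE)
  if (inherits(o, "try-error") || o$convergence != 0 || o$value >= 1e11)
    return(init)
  o$par
}

#' Pooled wave kinetics statistics
#'
#' Mean and SD over all waves (pooled across tracks) of the dwell time
#' (`t_end - t_onset`), onset duration `t_on` (`t_peak - t_onset`) and
#' dissociation duration `t_off` (`t_end - t_peak`), per channel, together
#' with onset-to-onset periodicities and wave counts.
#'
#' @param waves A `wave_set` (possibly rows from several tracks; a
#'   `track_id` column is used for the per-track breakdown and
#'   periodicities).
#' @return A `wave_stats` object: list with `per_channel` (channel, n,
#'   means and SDs of dwell/t_on/t_off, periodicity mean and SD),
#'   `per_track` breakdown, and `n_waves`.
#' @export
wave_statistics <- function(waves) {
  if (is.null(waves) || nrow(waves) == 0L)
    stop("undefined result: no waves supplied", call. = FALSE)
  w <- as.data.frame(waves)
  if (!("track_id" %in% names(w))) w$track_id <- 1L
  w$dwell <- w$t_end - w$t_onset
  w$t_on <- w$t_peak - w$t_onset
  w$t_off <- w$t_end - w$t_peak
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  per_channel <- do.call(rbind, lapply(split(w, w$channel), function(d) {
    p <- periodicity(d)
    data.frame(channel = d$channel[1], n = nrow(d),
               dwell_mean = mean(d$dwell), dwell_sd = sd0(d$dwell),
               t_on_mean = mean(d$t_on), t_on_sd = sd0(d$t_on),
               t_off_mean = mean(d$t_off), t_off_sd = sd0(d$t_off),
               period_mean = if (nrow(p)) mean(p$interval_s) else NA_real_,
               period_sd = if (nrow(p) > 1) stats::sd(p$interval_s) else
                 if (nrow(p)) 0 else NA_real_)
  }))
  rownames(per_channel) <- NULL
  per_track <- stats::aggregate(cbind(dwell, t_on, t_off) ~ channel + track_id,
                                w, mean)
  structure(list(per_channel = per_channel, per_track = per_track,
                 n_waves = nrow(w)),
            class = "wave_stats")
}

#' @export
print.wave_stats <- function(x, digits = 3, ...) {
  cat("Wave kinetics over", x$n_waves, "waves\n")
  df <- x$per_channel
  for (col in names(df)[-1]) df[[col]] <- signif(df[[col]], digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Onset-to-onset periodicity of successive waves
#'
#' Intervals between successive waves of the same channel on the same
#' track; `n` waves give `n - 1` intervals, none for fewer than two waves.
#'
#' @param waves A `wave_set`.
#' @param method `"onset"` (default) or `"peak"`: which event anchors the
#'   interval.
#' @param track_frames Optional named vector giving each track's length in
#'   frames; when supplied, only tracks with at least `min_track_frames`
#'   frames contribute.
#' @param min_track_frames Minimum track length applied with `track_frames`
#'   (default 200).
#' @return Data frame `channel`, `track_id`, `interval_s`.
#' @export
periodicity <- function(waves, method = c("onset", "peak"),
                        track_frames = NULL, min_track_frames = 200) {
  method <- match.arg(method)
  w <- as.data.frame(waves)
  if (!nrow(w))
    return(data.frame(channel = character(), track_id = integer(),
                      interval_s = numeric()))
  if (!("track_id" %in% names(w))) w$track_id <- 1L
  if (!is.null(track_frames)) {
    keep <- names(track_frames)[track_frames >= min_track_frames]
    w <- w[as.character(w$track_id) %in% keep, , drop = FALSE]
  }
  anchor <- if (method == "onset") "t_onset" else "t_peak"
  out <- lapply(split(w, list(w$channel, w$track_id), drop = TRUE),
                function(d) {
    if (nrow(d) < 2L) return(NULL)
    a <- sort(d[[anchor]])
    data.frame(channel = d$channel[1], track_id = d$track_id[1],
               interval_s = diff(a))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(channel = character(), track_id = integer(),
                      interval_s = numeric())
  rownames(out) <- NULL
  out
}

#' Count waves with onset inside a half-open time window
#'
#' @param waves A `wave_set`.
#' @param window Numeric `c(t0, t1)` in seconds; waves with
#'   `t0 <= t_onset < t1` are counted (an onset exactly at `t1` is not).
#' @return Integer count.
#' @export
count_waves <- function(waves, window = c(0, 300)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  w <- as.data.frame(waves)
  if (!nrow(w)) return(0L)
  sum(w$t_onset >= window[1] & w$t_onset < window[2])
}

#' Average normalized wave profiles across segments
#'
#' Each segment (a two-channel trace window containing exactly one
#' coordinated wave) is min-max normalized to `[0, 100]` per channel,
#' aligned at the onset of the chosen anchor channel, resampled to a common
#' grid and averaged pointwise.
#'
#' @param segments List of `intensity_trace` windows.
#' @param cfg A [detection_config()] used to locate the wave in each
#'   segment (use a `baseline_window_frames` no longer than the segments).
#' @param alignment `"transient-onset"` (default) or `"slow-onset"`.
#' @param grid_dt_s Resampling interval of the common grid in seconds.
#' @return Data frame `time_s` (relative to the alignment event),
#'   `channel`, `mean`, `sd`, `n_segments`; the number of rejected segments
#'   (no wave found in the alignment channel) is attached as attribute
#'   `n_rejected`.
#' @export
average_profiles <- function(segments, cfg = detection_config(),
                             alignment = c("transient-onset", "slow-onset"),
                             grid_dt_s = 3) {
  alignment <- match.arg(alignment)
  stopifnot(is.list(segments), length(segments) >= 2L)
  anchor_ch <- if (alignment == "transient-onset") "transient" else "slow"
  per_seg <- list()
  rejected <- 0L
  for (sg in segments) {
    chans <- attr(sg, "channels")
    wv <- try(detect_waves(sg, cfg), silent = TRUE)
    if (inherits(wv, "try-error")) { rejected <- rejected + 1L; next }
    aw <- wv[wv$channel == anchor_ch, , drop = FALSE]
    if (!nrow(aw)) { rejected <- rejected + 1L; next }
    t0 <- aw$t_onset[which.max(aw$amplitude)]
    norm <- sg
    for (ch in chans) {
      v <- sg[[ch]]
      rngv <- range(v, na.rm = TRUE)
      norm[[ch]] <- if (diff(rngv) > 0)
        100 * (v - rngv[1]) / diff(rngv) else v * 0
    }
    per_seg[[length(per_seg) + 1L]] <-
      list(rel = sg$time_s - t0, trace = norm, chans = chans)
  }
  if (length(per_seg) < 2L)
    stop("fewer than two segments contained a wave in the alignment channel",
         call. = FALSE)
  lo <- max(vapply(per_seg, function(s) min(s$rel), numeric(1)))
  hi <- min(vapply(per_seg, function(s) max(s$rel), numeric(1)))
  if (hi <= lo)
    stop("segments do not overlap after alignment", call. = FALSE)
  grid <- seq(lo, hi, by = grid_dt_s)
  chans <- per_seg[[1]]$chans
  out <- list()
  for (ch in chans) {
    m <- vapply(per_seg, function(s)
      stats::approx(s$rel, s$trace[[ch]], grid)$y, numeric(length(grid)))
    m <- matrix(m, nrow = length(grid))
    out[[ch]] <- data.frame(
      time_s = grid, channel = ch,
      mean = rowMeans(m, na.rm = TRUE),
      sd = apply(m, 1, stats::sd, na.rm = TRUE),
      n_segments = rowSums(!is.na(m)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_rejected") <- rejected
  res
}
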