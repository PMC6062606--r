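#' Link per-frame spots into endosome tracks
#'
#' Greedy nearest-neighbour linking: for each frame, candidate links between
#' open tracks and new spots are sorted by distance (ties broken by track
#' then spot index) and assigned greedily; a link over a gap of `g` missed
#' frames is allowed up to `max_disp_px * (g + 1)`. Tracks not extended for
#' more than `max_gap` frames are closed; unmatched spots open new tracks;
#' tracks shorter than `min_track_len` frames are dropped. The tie-break
#' makes the result deterministic and invariant to spot order up to
#' exactly-equal distances.
#'
#' @param spots_per_frame List of `spot_set` data frames ordered by frame.
#'   Frame indices are taken from the `frame_index` attribute when present
#'   (must be strictly increasing), else `1:length(spots_per_frame)`.
#' @param cfg A [tracking_config()].
#' @return A `track_set` data frame: `track_id`, `frame`, `x`, `y`,
#'   `area_px`, `total_intensity`.
#' @export
link_tracks <- function(spots_per_frame, cfg = tracking_config()) {
  stopifnot(is.list(spots_per_frame), inherits(cfg, "tracking_config"))
  frames <- vapply(seq_along(spots_per_frame), function(i) {
    fi <- attr(spots_per_frame[[i]], "frame_index")
    if (is.null(fi) || is.na(fi)) i else as.integer(fi)
  }, integer(1))
  if (any(diff(frames) <= 0))
    stop("spot sets must be ordered by strictly increasing frame",
         call. = FALSE)
  tracks <- list()   # each: list(rows = data.frame, last_frame, x, y, open)
  for (i in seq_along(spots_per_frame)) {
    f <- frames[i]
    sp <- spots_per_frame[[i]]
    if (nrow(sp) && is.finite(cfg$max_spot_area_px))
      sp <- sp[sp$area_px <= cfg$max_spot_area_px, , drop = FALSE]
    open_idx <- which(vapply(tracks, function(tr)
      tr$open && (f - tr$last_frame) <= cfg$max_gap + 1L, TRUE))
    assigned_spot <- rep(FALSE, nrow(sp))
    if (length(open_idx) && nrow(sp)) {
      cand <- expand.grid(ti = open_idx, si = seq_len(nrow(sp)))
      g <- f - vapply(tracks[cand$ti], `[[`, numeric(1), "last_frame")
      dx <- sp$x[cand$si] - vapply(tracks[cand$ti], `[[`, numeric(1), "x")
      dy <- sp$y[cand$si] - vapply(tracks[cand$ti], `[[`, numeric(1), "y")
      cand$dist <- sqrt(dx^2 + dy^2)
      cand <- cand[cand$dist <= cfg$max_disp_px * g, , drop = FALSE]
      cand <- cand[order(cand$dist, cand$ti, cand$si), , drop = FALSE]
      used_track <- logical(length(tracks))
      for (r in seq_len(nrow(cand))) {
        ti <- cand$ti[r]; si <- cand$si[r]
        if (used_track[ti] || assigned_spot[si]) next
        used_track[ti] <- TRUE; assigned_spot[si] <- TRUE
        tracks[[ti]]$rows <- rbind(tracks[[ti]]$rows,
                                   cbind(frame = f, sp[si, , drop = FALSE]))
        tracks[[ti]]$last_frame <- f
        tracks[[ti]]$x <- sp$x[si]; tracks[[ti]]$y <- sp$y[si]
      }
    }
    for (ti in seq_along(tracks))
      if (tracks[[ti]]$open && (f - tracks[[ti]]$last_frame) > cfg$max_gap)
        tracks[[ti]]$open <- FALSE
    for (si in which(!assigned_spot))
      tracks[[length(tracks) + 1L]] <- list(
        rows = cbind(frame = f, sp[si, , drop = FALSE]),
        last_frame = f, x = sp$x[si], y = sp$y[si], open = TRUE)
  }
  keep <- vapply(tracks, function(tr) nrow(tr$rows) >= cfg$min_track_len, TRUE)
  tracks <- tracks[keep]
  if (!length(tracks))
    out <- data.frame(track_id = integer(), frame = integer(), x = numeric(),
                      y = numeric(), area_px = integer(),
                      total_intensity = numeric())
  else
    out <- do.call(rbind, lapply(seq_along(tracks), function(ti)
      cbind(track_id = ti, tracks[[ti]]$rows)))
  rownames(out) <- NULL
  class(out) <- c("track_set", "data.frame")
  out
}

#' Measure background-corrected per-channel intensity along a track
#'
#' For each tracked frame and channel: mean intensity in a disk of
#' `disk_radius_px` at the track position minus the median intensity in the
#' surrounding annulus. Positions on gap frames are linearly interpolated
#' and flagged. A disk extending beyond the image gives `NA` for that frame.
#'
#' @param movie A `movie_stack`.
#' @param track One track: data frame with `frame`, `x`, `y` (0-based px),
#'   e.g. one `track_id` subset of [link_tracks()] output.
#' @param cfg A [tracking_config()].
#' @return An `intensity_trace` data frame with `time_s` and one column per
#'   channel, plus an `interpolated` logical attribute per row.
#' @export
measure_intensity <- function(movie, track, cfg = tracking_config()) {
  stopifnot(inherits(movie, "movie_stack"), is.data.frame(track),
            all(c("frame", "x", "y") %in% names(track)))
  d <- dim(movie)
  chn <- attr(movie, "channel_names")
  dt <- attr(movie, "frame_interval_s")
  frames <- seq(min(track$frame), max(track$frame))
  xs <- stats::approx(track$frame, track$x, frames)$y
  ys <- stats::approx(track$frame, track$y, frames)$y
  interpolated <- !(frames %in% track$frame)
  rout <- cfg$annulus_radii_px[2]
  vals <- matrix(NA_real_, nrow = length(frames), ncol = d[2])
  for (i in seq_along(frames)) {
    x0 <- xs[i]; y0 <- ys[i]
    if (x0 - cfg$disk_radius_px < 0 || x0 + cfg$disk_radius_px > d[4] - 1 ||
        y0 - cfg$disk_radius_px < 0 || y0 + cfg$disk_radius_px > d[3] - 1)
      next
    rows <- max(1L, floor(y0 + 1 - rout)):min(d[3], ceiling(y0 + 1 + rout))
    cols <- max(1L, floor(x0 + 1 - rout)):min(d[4], ceiling(x0 + 1 + rout))
    rr2 <- outer((rows - 1 - y0)^2, (cols - 1 - x0)^2, "+")
    disk <- rr2 <= cfg$disk_radius_px^2
    annu <- rr2 >= cfg$annulus_radii_px[1]^2 & rr2 <= rout^2
    for (ch in seq_len(d[2])) {
      patch <- movie[frames[i], ch, rows, cols]
      vals[i, ch] <- mean(patch[disk]) -
        if (any(annu)) stats::median(patch[annu]) else 0
    }
  }
  df <- data.frame(time_s = (frames - 1) * dt)
  for (ch in seq_len(d[2]))
    df[[if (!is.null(chn)) chn[ch] else paste0("ch", ch)]] <- vals[, ch]
  attr(df, "frame_interval_s") <- dt
  attr(df, "channels") <- if (!is.null(chn)) chn else paste0("ch", seq_len(d[2]))
  attr(df, "interpolated") <- interpolated
  attr(df, "bleach_corrected") <- FALSE
  attr(df, "normalized") <- FALSE
  class(df) <- c("intensity_trace", "data.frame")
  df
}

#' Correct an intensity trace for photobleaching
#'
#' Fits `b * exp(-t / tau)` to a robust lower envelope (rolling 20th
#' percentile) of a reference intensity series — by default the trace's own
#' channel — and divides each channel by the fitted decay normalized to 1 at
#' `t = 0`. A non-convergent or non-decaying fit falls back to no correction
#' with a warning recorded on the result.
#'
#' @param trace An `intensity_trace`.
#' @param model `"exponential"` or `"none"` (identity).
#' @param reference Optional numeric series (e.g. whole-movie mean intensity
#'   per frame, same length as the trace) to fit the decay on; by default
#'   each channel is corrected using its own envelope.
#' @param envelope_window_frames Window of the rolling-percentile envelope.
#' @return The corrected `intensity_trace`; attributes `bleach_corrected`,
#'   `bleach_tau_s` (per channel) and possibly `bleach_warning` are set.
#' @export
bleach_correct <- function(trace, model = c("exponential", "none"),
                           reference = NULL, envelope_window_frames = 60) {
  model <- match.arg(model)
  stopifnot(inherits(trace, "intensity_trace"))
  if (model == "none") return(trace)
  if (nrow(trace) < 10L)
    stop("trace too short to fit a bleaching model (need >= 10 frames)",
         call. = FALSE)
  chans <- attr(trace, "channels")
  t <- trace$time_s
  taus <- stats::setNames(rep(NA_real_, length(chans)), chans)
  warn <- NULL
  for (ch in chans) {
    y <- if (is.null(reference)) trace[[ch]] else reference
    tau <- fit_decay_tau(t, y, envelope_window_frames)
    if (is.na(tau)) {
      warn <- c(warn, sprintf("channel %s: decay fit failed, no correction",
                              ch))
      next
    }
    taus[ch] <- tau
    if (is.finite(tau))
      trace[[ch]] <- trace[[ch]] / exp(-(t - t[1]) / tau)
  }
  attr(trace, "bleach_corrected") <- TRUE
  attr(trace, "bleach_tau_s") <- taus
  if (!is.null(warn)) {
    attr(trace, "bleach_warning") <- warn
    warning(paste(warn, collapse = "; "), call. = FALSE)
  }
  trace
}

# tau of b * exp(-t/tau), fitted in two passes: a rough fit to the rolling
# lower envelope, then a refit restricted to baseline samples after masking
# waves on the roughly-corrected trace.  NA on failure, Inf when flat.
fit_decay_tau <- function(t, y, win) {
  ok <- is.finite(y)
  if (sum(ok) < 10L) return(NA_real_)
  t <- t[ok]; y <- y[ok]
  log_slope <- function(tt, yy) {
    pos <- yy > 0
    if (sum(pos) < 5L) return(NA_real_)
    fit <- try(stats::lm(log(yy[pos]) ~ tt[pos]), silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    stats::coef(fit)[2]
  }
  env <- rolling_quantile(y, win, 0.2)
  s1 <- log_slope(t, env)
  if (!is.finite(s1)) return(NA_real_)
  corrected <- if (s1 < -1e-12) y * exp(-s1 * (t - t[1])) else y
  sig <- noise_sd_diff(corrected)
  floor <- stats::quantile(corrected, 0.2, names = FALSE)
  mask <- corrected > floor + 2 * sig
  n <- length(mask)
  grown <- mask
  for (s in 1:5) grown <- grown | c(mask[-seq_len(s)], rep(FALSE, s)) |
    c(rep(FALSE, s), mask[seq_len(n - s)])
  slope <- if (sum(!grown) >= 10L) log_slope(t[!grown], y[!grown]) else s1
  if (!is.finite(slope)) slope <- s1
  # a flat or rising baseline means no detectable bleaching
  if (slope >= -1e-12) return(Inf)
  tau <- -1 / slope
  if (exp(-(max(t) - min(t)) / tau) > 0.98) return(Inf)
  tau
}

rolling_quantile <- function(x, w, p) {
  n <- length(x); h <- w %/% 2L
  out <- numeric(n)
  for (i in seq_len(n))
    out[i] <- stats::quantile(x[max(1L, i - h):min(n, i + h)], p,
                              names = FALSE)
  out
}
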