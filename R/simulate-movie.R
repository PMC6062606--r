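#' Simulate a multi-channel time-lapse movie of endosomes with ESCRT waves
#'
#' Renders the output of [simulate_traces()] as diffusing Gaussian spots on
#' a camera background. The first channel carries a persistent cargo spot
#' per endosome; the second and third channels carry spots whose integrated
#' intensity follows the slow and transient wave traces. Spot motion is an
#' isotropic random walk reflected at an interior margin so that spots stay
#' measurable. Camera noise is Poisson shot noise plus additive Gaussian
#' read noise (or none).
#'
#' @param k A [kinetic_params()] object (trace noise is not rendered; the
#'   movie's own camera noise model applies instead).
#' @param m A [movie_config()] object.
#' @param seed Integer seed.
#' @param onsets_s Optional forced slow-wave onsets, as in
#'   [simulate_traces()].
#' @return A list with elements `movie` (a `movie_stack`: numeric array
#'   `[frame, channel, y, x]` with calibration attributes), and `truth`
#'   (list: `positions` data frame of true per-frame spot centers in 0-based
#'   pixels, `waves` ground-truth wave table, `traces` the noiseless traces).
#' @export
simulate_movie <- function(k = kinetic_params(), m = movie_config(),
                           seed = NULL, onsets_s = NULL) {
  stopifnot(inherits(k, "kinetic_params"), inherits(m, "movie_config"))
  with_seed(seed, {
    duration <- (m$n_frames - 1L) * m$frame_interval_s
    kk <- k
    kk$noise_sd <- 0
    # a movie shorter than one wave simply contains none
    if (kk$wave_rate > 0 && k$slow_t_on + k$slow_t_off >= duration)
      kk$wave_rate <- 0
    sim <- simulate_traces(kk, duration_s = max(duration, m$frame_interval_s),
                           dt_s = m$frame_interval_s,
                           n_tracks = max(m$n_endosomes, 1L),
                           onsets_s = onsets_s)
    ny <- m$image_shape[1]; nx <- m$image_shape[2]
    margin <- max(10, ceiling(4 * m$psf_sigma_px))
    if (2 * margin >= min(ny, nx)) margin <- floor(min(ny, nx) / 2) - 1
    # random-walk positions, reflected at the margin (0-based pixel coords)
    pos <- NULL
    if (m$n_endosomes > 0) {
      # initial positions kept min_separation_px apart (best effort) so that
      # distinct endosomes start as resolvable spots
      x0 <- numeric(m$n_endosomes); y0 <- numeric(m$n_endosomes)
      for (e in seq_len(m$n_endosomes)) {
        for (try in 1:200) {
          cx <- stats::runif(1, margin, nx - 1 - margin)
          cy <- stats::runif(1, margin, ny - 1 - margin)
          if (e == 1L || min(sqrt((x0[seq_len(e - 1)] - cx)^2 +
                                  (y0[seq_len(e - 1)] - cy)^2)) >=
              m$min_separation_px) break
        }
        x0[e] <- cx; y0[e] <- cy
      }
      pos <- vector("list", m$n_endosomes)
      for (e in seq_len(m$n_endosomes)) {
        x <- numeric(m$n_frames); y <- numeric(m$n_frames)
        x[1] <- x0[e]
        y[1] <- y0[e]
        if (m$n_frames > 1) {
          dx <- stats::rnorm(m$n_frames - 1, 0, m$diffusion_step_sd_px)
          dy <- stats::rnorm(m$n_frames - 1, 0, m$diffusion_step_sd_px)
          for (t in 2:m$n_frames) {
            x[t] <- reflect(x[t - 1] + dx[t - 1], margin, nx - 1 - margin)
            y[t] <- reflect(y[t - 1] + dy[t - 1], margin, ny - 1 - margin)
          }
        }
        pos[[e]] <- data.frame(track_id = e, frame = seq_len(m$n_frames),
                               x = x, y = y)
      }
      pos <- do.call(rbind, pos)
    }

    mov <- array(m$background_level,
                 dim = c(m$n_frames, 3L, ny, nx),
                 dimnames = list(NULL, m$channel_names, NULL, NULL))
    if (m$n_endosomes > 0) {
      for (e in seq_len(m$n_endosomes)) {
        pe <- pos[pos$track_id == e, ]
        trc <- sim$traces[[e]]
        for (t in seq_len(m$n_frames)) {
          mov[t, 1, , ] <- add_spot(mov[t, 1, , ], pe$x[t], pe$y[t],
                                    m$psf_sigma_px, m$cargo_amplitude)
          mov[t, 2, , ] <- add_spot(mov[t, 2, , ], pe$x[t], pe$y[t],
                                    m$psf_sigma_px,
                                    trc$slow[t] * m$counts_per_unit)
          mov[t, 3, , ] <- add_spot(mov[t, 3, , ], pe$x[t], pe$y[t],
                                    m$psf_sigma_px,
                                    trc$transient[t] * m$counts_per_unit)
        }
      }
    }
    if (m$noise_model == "poisson-gaussian") {
      n <- length(mov)
      mov[] <- stats::rpois(n, pmax(mov, 0)) +
        stats::rnorm(n, 0, m$read_noise_sd)
    }
    attr(mov, "pixel_size_nm") <- m$pixel_size_nm
    attr(mov, "frame_interval_s") <- m$frame_interval_s
    attr(mov, "channel_names") <- m$channel_names
    class(mov) <- "movie_stack"
    list(movie = mov,
         truth = list(positions = pos, waves = sim$truth,
                      traces = sim$traces))
  })
}

reflect <- function(x, lo, hi) {
  if (hi <= lo) return(lo)
  w <- hi - lo
  x <- (x - lo) %% (2 * w)
  lo + ifelse(x > w, 2 * w - x, x)
}

# add an integrated-intensity Gaussian spot to a [y, x] frame; 0-based center
add_spot <- function(frame, x0, y0, sigma, integrated) {
  if (integrated <= 0) return(frame)
  r <- ceiling(4 * sigma)
  ny <- nrow(frame); nx <- ncol(frame)
  rows <- max(1L, floor(y0 + 1 - r)):min(ny, ceiling(y0 + 1 + r))
  cols <- max(1L, floor(x0 + 1 - r)):min(nx, ceiling(x0 + 1 + r))
  gy <- exp(-((rows - 1 - y0)^2) / (2 * sigma^2))
  gx <- exp(-((cols - 1 - x0)^2) / (2 * sigma^2))
  frame[rows, cols] <- frame[rows, cols] +
    integrated / (2 * pi * sigma^2) * outer(gy, gx)
  frame
}

#' Extract one channel frame from a movie stack
#'
#' @param movie A `movie_stack` array.
#' @param frame Frame index (1-based).
#' @param channel Channel index or name.
#' @return A numeric `[y, x]` matrix.
#' @export
get_frame <- function(movie, frame, channel) {
  stopifnot(inherits(movie, "movie_stack"))
  if (is.character(channel))
    channel <- match(channel, attr(movie, "channel_names"))
  movie[frame, channel, , ]
}

#' Write / read a movie stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are stored frame-major (`page = (frame - 1) * n_channels +
#' channel`); the sidecar (`<path>.json`) records dimensions, channel names,
#' physical calibration and the intensity scale used to map counts into the
#' unit range of the TIFF pages.
#'
#' @param movie A `movie_stack`.
#' @param path Output TIFF path.
#' @return `write_movie_tiff` returns `path` invisibly; `read_movie_tiff`
#'   returns a `movie_stack`.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie)
  scale <- max(movie, 1e-9)
  lo <- min(movie, 0)
  pages <- vector("list", d[1] * d[2])
  for (t in seq_len(d[1])) for (c in seq_len(d[2]))
    pages[[(t - 1) * d[2] + c]] <- (movie[t, c, , ] - lo) / (scale - lo)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(axes = "TCYX", n_frames = d[1], n_channels = d[2],
               ny = d[3], nx = d[4],
               channel_names = attr(movie, "channel_names"),
               pixel_size_nm = attr(movie, "pixel_size_nm"),
               frame_interval_s = attr(movie, "frame_interval_s"),
               intensity_offset = lo, intensity_scale = scale - lo)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  mov <- array(0, dim = c(meta$n_frames, meta$n_channels, meta$ny, meta$nx),
               dimnames = list(NULL, meta$channel_names, NULL, NULL))
  for (t in seq_len(meta$n_frames)) for (c in seq_len(meta$n_channels))
    mov[t, c, , ] <- pages[[(t - 1) * meta$n_channels + c]] *
      meta$intensity_scale + meta$intensity_offset
  attr(mov, "pixel_size_nm") <- meta$pixel_size_nm
  attr(mov, "frame_interval_s") <- meta$frame_interval_s
  attr(mov, "channel_names") <- meta$channel_names
  class(mov) <- "movie_stack"
  mov
}
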