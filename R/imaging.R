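#' Segment fluorescent spots in one frame
#'
#' Thresholds a single-channel frame (Otsu by default), labels connected
#' components, filters them by area and returns intensity-weighted
#' centroids. Deterministic for fixed input. A constant image yields an
#' empty spot set rather than an error.
#'
#' @param frame_image Numeric `[y, x]` matrix of intensities.
#' @param cfg A [cooccurrence_config()] (threshold method and area gates).
#' @param frame_index Optional frame index stored on the result.
#' @param channel Optional channel label stored on the result.
#' @return A `spot_set`: data frame with columns `x`, `y` (0-based pixel
#'   centroids; x right, y down), `area_px` and `total_intensity`, plus
#'   `pixel_size_nm`, `frame_index` and `channel` attributes.
#' @export
segment_spots <- function(frame_image, cfg = cooccurrence_config(),
                          frame_index = NA_integer_, channel = NA_character_) {
  stopifnot(is.matrix(frame_image), inherits(cfg, "cooccurrence_config"))
  if (length(frame_image) == 0 || !all(is.finite(frame_image)))
    stop("frame_image must be a non-empty finite matrix", call. = FALSE)
  empty <- data.frame(x = numeric(), y = numeric(), area_px = integer(),
                      total_intensity = numeric())
  rng <- range(frame_image)
  thr <- if (rng[1] == rng[2]) Inf else switch(cfg$threshold_method,
    otsu = {
      norm <- (frame_image - rng[1]) / (rng[2] - rng[1])
      th <- rng[1] + EBImage::otsu(norm, range = c(0, 1)) * (rng[2] - rng[1])
      # a frame without foreground: Otsu splits the noise distribution, so
      # require the threshold to clear the background noise floor
      bg <- stats::median(frame_image)
      s <- stats::mad(frame_image)
      if (th < bg + 3 * s) Inf else th
    },
    percentile = stats::quantile(frame_image, cfg$threshold_value / 100,
                                 names = FALSE),
    absolute = cfg$threshold_value)
  mask <- frame_image > thr
  if (!any(mask)) return(spot_set(empty, cfg, frame_index, channel))
  lab <- EBImage::bwlabel(mask)
  lab_v <- as.integer(lab)
  keep <- lab_v > 0L
  labs <- lab_v[keep]
  ints <- frame_image[keep]
  idx <- which(keep)
  rows <- (idx - 1L) %% nrow(frame_image)       # 0-based y
  cols <- (idx - 1L) %/% nrow(frame_image)      # 0-based x
  area <- tabulate(labs)
  wsum <- as.numeric(tapply(ints, labs, sum))
  xc <- as.numeric(tapply(ints * cols, labs, sum)) / wsum
  yc <- as.numeric(tapply(ints * rows, labs, sum)) / wsum
  ok <- area >= cfg$min_area_px & area <= cfg$max_area_px
  spot_set(data.frame(x = xc[ok], y = yc[ok], area_px = area[ok],
                      total_intensity = wsum[ok]),
           cfg, frame_index, channel)
}

spot_set <- function(df, cfg, frame_index, channel) {
  attr(df, "pixel_size_nm") <- cfg$pixel_size_nm
  attr(df, "frame_index") <- frame_index
  attr(df, "channel") <- channel
  class(df) <- c("spot_set", "data.frame")
  df
}

#' Count reference spots co-occurring with query spots
#'
#' A reference (cargo) spot counts as co-occurring when at least one query
#' spot centroid lies strictly closer than `max_dist_nm` (default 400 nm,
#' i.e. 5 pixels at 80 nm; a pair at exactly the threshold does not count).
#' Multiple query spots near one reference spot are not counted twice.
#'
#' @param ref,query `spot_set` objects from the same frame geometry.
#' @param cfg A [cooccurrence_config()].
#' @return Integer count in `[0, nrow(ref)]`.
#' @export
count_cooccurring <- function(ref, query, cfg = cooccurrence_config()) {
  stopifnot(inherits(cfg, "cooccurrence_config"))
  pr <- attr(ref, "pixel_size_nm"); pq <- attr(query, "pixel_size_nm")
  if (!is.null(pr) && !is.null(pq) && !isTRUE(all.equal(pr, pq)))
    stop("ref and query spot sets have different pixel calibrations",
         call. = FALSE)
  if (nrow(ref) == 0L || nrow(query) == 0L) return(0L)
  px <- if (!is.null(pr)) pr else cfg$pixel_size_nm
  d2 <- outer(ref$x, query$x, "-")^2 + outer(ref$y, query$y, "-")^2
  lim2 <- (cfg$max_dist_nm / px)^2
  sum(apply(d2, 1, function(r) any(r < lim2)))
}

#' Per-frame co-occurrence time course across movies
#'
#' Segments the reference and query channels of each movie frame by frame,
#' counts co-occurring reference spots, and averages the per-frame counts
#' across movies.
#'
#' @param movies A `movie_stack` or list of `movie_stack`s sharing frame
#'   interval and pixel size.
#' @param ref_channel,query_channel Channel names or indices.
#' @param cfg A [cooccurrence_config()].
#' @return A `cooccurrence_timecourse`: list with `per_frame` (movie, frame,
#'   time_s, n_ref, n_query, n_cooccur) and `mean_per_frame` (frame, time_s,
#'   mean_cooccur).
#' @export
cooccurrence_timecourse <- function(movies, ref_channel = 1,
                                    query_channel = 2,
                                    cfg = cooccurrence_config()) {
  if (inherits(movies, "movie_stack")) movies <- list(movies)
  if (!length(movies)) stop("empty movie list", call. = FALSE)
  dts <- vapply(movies, attr, numeric(1), "frame_interval_s")
  pxs <- vapply(movies, attr, numeric(1), "pixel_size_nm")
  if (length(unique(dts)) > 1L || length(unique(pxs)) > 1L)
    stop("movies must share frame interval and pixel size", call. = FALSE)
  rows <- list()
  for (mi in seq_along(movies)) {
    mov <- movies[[mi]]
    nT <- dim(mov)[1]
    for (t in seq_len(nT)) {
      rs <- segment_spots(get_frame(mov, t, ref_channel), cfg, t, "ref")
      qs <- segment_spots(get_frame(mov, t, query_channel), cfg, t, "query")
      rows[[length(rows) + 1L]] <- data.frame(
        movie = mi, frame = t, time_s = (t - 1) * dts[1],
        n_ref = nrow(rs), n_query = nrow(qs),
        n_cooccur = count_cooccurring(rs, qs, cfg))
    }
  }
  per_frame <- do.call(rbind, rows)
  mean_per_frame <- stats::aggregate(n_cooccur ~ frame + time_s, per_frame,
                                     mean)
  names(mean_per_frame)[3] <- "mean_cooccur"
  mean_per_frame <- mean_per_frame[order(mean_per_frame$frame), ]
  structure(list(per_frame = per_frame, mean_per_frame = mean_per_frame),
            class = "cooccurrence_timecourse")
}

#' Plot a co-occurrence time course as a grayscale strip
#'
#' White encodes the minimum and black the maximum mean co-occurrence.
#'
#' @param x A `cooccurrence_timecourse`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.cooccurrence_timecourse <- function(x, ...) {
  v <- x$mean_per_frame$mean_cooccur
  graphics::image(x = x$mean_per_frame$time_s, y = 1,
                  z = matrix(v, ncol = 1),
                  col = grDevices::gray(seq(1, 0, length.out = 256)),
                  xlab = "time (s)", ylab = "", yaxt = "n", ...)
  invisible(x)
}

#' Manders colocalization coefficient
#'
#' Fraction of channel A intensity residing in pixels where channel B
#' exceeds `threshold_b`:
#' `MCC = sum(A[B > threshold_b]) / sum(A)`.
#'
#' @param img_a,img_b Numeric arrays of identical shape.
#' @param threshold_b Intensity threshold applied to B (strict `>`).
#' @return A fraction in `[0, 1]`.
#' @examples
#' manders_mcc(c(10, 30, 60, 0), c(1, 0, 5, 9), threshold_b = 2)  # 0.6
#' @export
manders_mcc <- function(img_a, img_b, threshold_b) {
  if (!identical(dim(img_a), dim(img_b)) || length(img_a) != length(img_b))
    stop("images must have the same shape", call. = FALSE)
  tot <- sum(img_a)
  if (tot <= 0)
    stop("undefined result: channel A carries no intensity", call. = FALSE)
  sum(img_a[img_b > threshold_b]) / tot
}
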