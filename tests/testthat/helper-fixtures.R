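# shared fixtures and small utilities used across test files

# a spot_set built by hand (positions in 0-based pixels)
make_spots <- function(x, y, pixel_size_nm = 80, frame_index = 1L) {
  df <- data.frame(x = x, y = y, area_px = rep(3L, length(x)),
                   total_intensity = rep(100, length(x)))
  attr(df, "pixel_size_nm") <- pixel_size_nm
  attr(df, "frame_index") <- frame_index
  attr(df, "channel") <- "test"
  class(df) <- c("spot_set", "data.frame")
  df
}

# brute-force all-pairs co-occurrence oracle (independent of the package
# implementation): number of ref spots with >= 1 query centroid strictly
# closer than max_dist_nm
brute_force_cooccur <- function(ref, query, max_dist_nm, pixel_size_nm) {
  if (nrow(ref) == 0 || nrow(query) == 0) return(0L)
  hits <- 0L
  for (i in seq_len(nrow(ref))) {
    found <- FALSE
    for (j in seq_len(nrow(query))) {
      d <- sqrt((ref$x[i] - query$x[j])^2 + (ref$y[i] - query$y[j])^2) *
        pixel_size_nm
      if (d < max_dist_nm) { found <- TRUE; break }
    }
    if (found) hits <- hits + 1L
  }
  hits
}

# match each ground-truth wave to the nearest detected wave of the same
# channel (by peak time); returns per-truth-wave absolute errors or NA when
# no detection lies within `max_sep` seconds
match_waves <- function(detected, truth, max_sep = 60) {
  out <- lapply(seq_len(nrow(truth)), function(i) {
    d <- detected[detected$channel == truth$channel[i], , drop = FALSE]
    if (!nrow(d)) return(data.frame(onset = NA_real_, peak = NA_real_,
                                    end = NA_real_))
    j <- which.min(abs(d$t_peak - truth$t_peak[i]))
    if (abs(d$t_peak[j] - truth$t_peak[i]) > max_sep)
      return(data.frame(onset = NA_real_, peak = NA_real_, end = NA_real_))
    data.frame(onset = abs(d$t_onset[j] - truth$t_onset[i]),
               peak = abs(d$t_peak[j] - truth$t_peak[i]),
               end = abs(d$t_end[j] - truth$t_end[i]))
  })
  do.call(rbind, out)
}

# pooled detected waves over a list of traces
detect_all <- function(traces, cfg = detection_config()) {
  do.call(rbind, lapply(traces, function(tr) as.data.frame(detect_waves(tr, cfg))))
}
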