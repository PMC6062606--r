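#' Classify ILV diameters into size gates
#'
#' ILVs between 40 and 60 nm (both bounds inclusive) are scored as
#' ESCRT-dependent; 20 to just under 40 nm as small (ESCRT-independent);
#' everything else as `other`.
#'
#' @param diameter_nm Numeric vector of ILV diameters in nm (positive).
#' @param cfg A [morphometry_config()] carrying the gates.
#' @return Factor with levels `small`, `escrt`, `other`.
#' @export
classify_ilv_size <- function(diameter_nm, cfg = morphometry_config()) {
  if (!length(diameter_nm)) return(factor(character(),
                                          levels = c("small", "escrt", "other")))
  if (any(!is.finite(diameter_nm)) || any(diameter_nm <= 0))
    stop("ILV diameters must be positive", call. = FALSE)
  g1 <- cfg$ilv_gate_small_nm; g2 <- cfg$ilv_gate_escrt_nm
  cls <- ifelse(diameter_nm >= g2[1] & diameter_nm <= g2[2], "escrt",
                ifelse(diameter_nm >= g1[1] & diameter_nm < g1[2], "small",
                       "other"))
  factor(cls, levels = c("small", "escrt", "other"))
}

#' Descriptive statistics over EM sections
#'
#' Per-section counts of size-gated ILVs and summary statistics: mean and SD
#' of ESCRT-gated ILVs per section, the fraction of sections with at most
#' one such ILV, the fraction with at least one budding profile (when bud
#' counts are recorded) and counts by size class.
#'
#' @param records A `section_records` object ([simulate_sections()] or
#'   [as_section_records()]).
#' @param cfg A [morphometry_config()].
#' @return A list: `n_sections`, `mean_escrt_per_section`,
#'   `sd_escrt_per_section`, `fraction_le1_escrt`, `fraction_with_bud`,
#'   `counts_by_class`, and `per_section` (dot-plot-ready table with one row
#'   per section).
#' @export
section_statistics <- function(records, cfg = morphometry_config()) {
  stopifnot(inherits(records, "section_records"))
  secs <- records$sections
  if (is.null(secs) || nrow(secs) == 0L)
    stop("undefined result: no sections", call. = FALSE)
  cls <- classify_ilv_size(records$ilvs$diameter_nm, cfg)
  sid <- factor(records$ilvs$section_id, levels = secs$section_id)
  n_escrt <- as.integer(table(sid[cls == "escrt"]))
  n_small <- as.integer(table(sid[cls == "small"]))
  n_other <- as.integer(table(sid[cls == "other"]))
  per_section <- data.frame(section_id = secs$section_id,
                            n_escrt = n_escrt, n_small = n_small,
                            n_other = n_other)
  if ("apparent_diameter_nm" %in% names(secs))
    per_section$apparent_diameter_nm <- secs$apparent_diameter_nm
  frac_bud <- if ("n_bud" %in% names(secs))
    mean(secs$n_bud >= 1) else NA_real_
  list(n_sections = nrow(secs),
       mean_escrt_per_section = mean(n_escrt),
       sd_escrt_per_section = if (nrow(secs) > 1) stats::sd(n_escrt) else 0,
       fraction_le1_escrt = mean(n_escrt <= 1),
       fraction_with_bud = frac_bud,
       counts_by_class = c(small = sum(n_small), escrt = sum(n_escrt),
                           other = sum(n_other)),
       per_section = per_section)
}

#' Classify and measure an ILV budding profile
#'
#' Fits the limiting-membrane plane through the flat flanking segments
#' (total least squares on the first and last five vertices), rotates the
#' contour into that frame, and measures the invagination by horizontal
#' chords at a fine grid of depths: `depth_nm` (plane to tip),
#' `mouth_width_nm` (opening just above the plane), `max_width_nm` (widest
#' chord), `neck_width_nm` (narrowest chord between the plane and the
#' widest point) and, for constricted buds, `neck_length_nm` (extent over
#' which the chord stays within 10% of the neck width). Categories:
#' omega when `neck_width < neck_ratio * max_width`; otherwise pit when
#' `depth < pit_depth_ratio * mouth_width`, else U. The measurement is
#' invariant under rigid motions and vertex-order reversal.
#'
#' @param contour A `bud_contour` or an `n x 2` matrix of vertices in nm.
#' @param cfg A [morphometry_config()].
#' @return A `bud_measurements` list: `category` (`"pit"`, `"U"`, `"omega"`
#'   or `NA` when unclassifiable, with `reason`), `mouth_width_nm`,
#'   `max_width_nm`, `neck_width_nm`, `neck_length_nm` (omega only),
#'   `depth_nm`.
#' @export
classify_bud <- function(contour, cfg = morphometry_config()) {
  pts <- unclass(contour)
  stopifnot(is.matrix(pts), ncol(pts) == 2)
  if (nrow(pts) < 8L)
    stop("a bud contour needs at least 8 vertices", call. = FALSE)
  nf <- 5L
  flank <- rbind(pts[seq_len(nf), ], pts[nrow(pts) - seq_len(nf) + 1L, ])
  ctr <- colMeans(flank)
  sv <- svd(sweep(flank, 2, ctr))
  dir <- sv$v[, 1]
  rms <- sqrt(mean((sweep(flank, 2, ctr) %*% sv$v[, 2])^2))
  if (rms > cfg$flank_residual_nm)
    return(structure(list(category = NA_character_,
                          reason = "flanking membrane not identifiable",
                          flank_rms_nm = rms),
                     class = "bud_measurements"))
  rot <- cbind(dir, c(-dir[2], dir[1]))
  xy <- sweep(pts, 2, ctr) %*% rot
  if (mean(xy[, 2]) < 0) xy[, 2] <- -xy[, 2]       # bud towards +y
  depth <- max(xy[, 2])
  y_lo <- max(1, 2.5 * rms)
  if (depth <= y_lo)
    return(structure(list(category = NA_character_,
                          reason = "no invagination above the membrane plane",
                          flank_rms_nm = rms),
                     class = "bud_measurements"))
  step <- min(0.5, (depth - y_lo) / 40)
  levels_y <- seq(y_lo, depth - step, by = step)
  chords <- vapply(levels_y, function(lv) chord_at(xy, lv), numeric(1))
  okc <- is.finite(chords)
  levels_y <- levels_y[okc]; chords <- chords[okc]
  if (length(chords) < 3L)
    return(structure(list(category = NA_character_,
                          reason = "too few measurable chords",
                          flank_rms_nm = rms),
                     class = "bud_measurements"))
  chords_s <- rolling_median(chords, 5L)
  mouth <- chords_s[1]
  imax <- which.max(chords_s)
  max_w <- chords_s[imax]
  open_idx <- seq_len(imax)
  ineck <- open_idx[which.min(chords_s[open_idx])]
  neck <- chords_s[ineck]
  constricted <- neck < cfg$neck_ratio * max_w
  category <- if (constricted) "omega"
    else if (depth < cfg$pit_depth_ratio * mouth) "pit" else "U"
  neck_len <- NA_real_
  if (constricted) {
    inside <- open_idx[chords_s[open_idx] <= 1.1 * neck]
    neck_len <- max(levels_y[inside])
  }
  structure(list(category = category, mouth_width_nm = mouth,
                 max_width_nm = max_w, neck_width_nm = neck,
                 neck_length_nm = neck_len, depth_nm = depth,
                 flank_rms_nm = rms),
            class = "bud_measurements")
}

#' @export
print.bud_measurements <- function(x, ...) {
  if (is.na(x$category)) {
    cat("unclassifiable bud profile:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("%s-shaped bud: depth %.1f nm, mouth %.1f nm, ",
                     "max width %.1f nm, neck %.1f nm"),
              x$category, x$depth_nm, x$mouth_width_nm, x$max_width_nm,
              x$neck_width_nm))
  if (is.finite(x$neck_length_nm))
    cat(sprintf(", neck length %.1f nm", x$neck_length_nm))
  cat("\n")
  invisible(x)
}

# widest horizontal span of polyline crossings at height `lv`
chord_at <- function(xy, lv) {
  y <- xy[, 2] - lv
  s <- which(y[-1] * y[-length(y)] < 0)
  xs <- (xy[s, 1] + (xy[s + 1, 1] - xy[s, 1]) * (-y[s]) / (y[s + 1] - y[s]))
  xs <- c(xs, xy[y == 0, 1])
  if (length(xs) < 2L) return(NA_real_)
  max(xs) - min(xs)
}

#' Score immunogold particles as proximal to a budding profile
#'
#' A particle is proximal when the distance from its center to the limiting
#' membrane (the contour polyline) is at most `gold_proximity_nm`
#' (inclusive; 40 nm by default, emulating a 40-nm circle drawn around each
#' particle that must touch the membrane).
#'
#' @param gold_xy_nm Numeric `m x 2` matrix (or length-2 vector) of gold
#'   centers, same coordinate frame as the contour.
#' @param contour A `bud_contour` or `n x 2` vertex matrix.
#' @param cfg A [morphometry_config()].
#' @return Logical vector, one flag per particle.
#' @export
gold_near_bud <- function(gold_xy_nm, contour, cfg = morphometry_config()) {
  if (is.null(dim(gold_xy_nm))) gold_xy_nm <- matrix(gold_xy_nm, ncol = 2)
  pts <- unclass(contour)
  unname(vapply(seq_len(nrow(gold_xy_nm)), function(i)
    dist_point_polyline(c(gold_xy_nm[i, 1], gold_xy_nm[i, 2]), pts) <=
      cfg$gold_proximity_nm, logical(1)))
}

dist_point_polyline <- function(p, pts) {
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1, , drop = FALSE]
  ab <- b - a
  ap <- cbind(p[1] - a[, 1], p[2] - a[, 2])
  len2 <- rowSums(ab^2)
  t <- pmin(pmax(ifelse(len2 > 0, rowSums(ap * ab) / len2, 0), 0), 1)
  proj <- a + ab * t
  min(sqrt((p[1] - proj[, 1])^2 + (p[2] - proj[, 2])^2))
}

#' Expected ILVs observed per thin section given a per-endosome wave count
#'
#' Under the slab-capture model, an endosome of radius `R` carrying
#' `wave_rate_per_endosome` ILVs on average shows
#' `rate * h / (2 R + h)` of them per section of thickness `h` when the
#' slab center is uniform over the intersecting range and ILV centers are
#' scored by center-in-slab. The analytic form holds only for a fixed
#' diameter, uniform placement and no conditioning; the Monte-Carlo method
#' delegates to [simulate_sections()] and supports the full population
#' model.
#'
#' @param wave_rate_per_endosome Mean number of ILVs (waves) per endosome.
#' @param pop An [endosome_population()]; `ilv_count_mean` is overridden by
#'   `wave_rate_per_endosome`.
#' @param sec A [section_config()].
#' @param method `"analytic"` or `"montecarlo"`.
#' @return Expected observed ILVs per section (all sizes pooled).
#' @examples
#' expected_ilvs_per_section(1, endosome_population(diameter_sd_nm = 0,
#'                                                  diameter_mean_nm = 251))
#' @export
expected_ilvs_per_section <- function(wave_rate_per_endosome,
                                      pop = endosome_population(),
                                      sec = section_config(),
                                      method = c("analytic", "montecarlo")) {
  method <- match.arg(method)
  check_pos(wave_rate_per_endosome, "wave_rate_per_endosome",
            allow_zero = TRUE)
  if (wave_rate_per_endosome == 0) return(0)
  h <- sec$thickness_nm
  if (method == "analytic") {
    if (pop$diameter_sd_nm > 0 || pop$ilv_placement != "uniform-in-lumen" ||
        sec$conditioning != "none")
      stop(paste("analytic expectation requires a fixed diameter, uniform",
                 "placement and no conditioning"), call. = FALSE)
    R <- max(pop$diameter_mean_nm, pop$diameter_min_nm) / 2
    return(wave_rate_per_endosome * h / (2 * R + h))
  }
  pop$ilv_count_mean <- wave_rate_per_endosome
  pop$small_ilv_rate <- 0
  recs <- simulate_sections(pop, sec)
  mean(recs$sections$n_ilv)
}
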