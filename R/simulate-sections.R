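#' Simulate thin EM sections of spherical multivesicular endosomes
#'
#' Draws spherical endosomes from a truncated-normal diameter distribution,
#' places a Poisson number of ILVs in each lumen, and cuts one slab of
#' thickness `h` per endosome with its center uniform over the full
#' intersecting range `[-(R + h/2), R + h/2]`. An ILV is observed iff its
#' center lies inside the slab (projection-overlap effects are ignored). The
#' apparent endosome diameter is the sphere chord at the slab center (zero
#' when the slab center lies outside the sphere). For a fixed radius `R` and
#' any radial ILV placement the capture probability is exactly
#' `h / (2 R + h)`.
#'
#' @param pop An [endosome_population()] object.
#' @param sec A [section_config()] object (`n_sections`, thickness,
#'   conditioning, seed).
#' @return A `section_records` object: list with `sections` (one row per
#'   section: true and apparent diameters, slab offset, observed ILV count)
#'   and `ilvs` (one row per observed ILV: `section_id`, `diameter_nm`).
#' @examples
#' recs <- simulate_sections(endosome_population(diameter_sd_nm = 0,
#'                                               diameter_mean_nm = 251),
#'                           section_config(n_sections = 200, seed = 1))
#' mean(recs$sections$n_ilv)
#' @export
simulate_sections <- function(pop = endosome_population(),
                              sec = section_config()) {
  stopifnot(inherits(pop, "endosome_population"),
            inherits(sec, "section_config"))
  h <- sec$thickness_nm
  n <- sec$n_sections
  with_seed(sec$seed, {
    D <- draw_truncnorm(n, pop$diameter_mean_nm, pop$diameter_sd_nm,
                        pop$diameter_min_nm)
    R <- D / 2
    z_s <- stats::runif(n, -(R + h / 2), R + h / 2)
    apparent <- 2 * sqrt(pmax(0, R^2 - z_s^2))
    if (sec$conditioning == "min-chord") {
      tries <- 0L
      repeat {
        bad <- apparent < sec$min_chord_nm
        if (!any(bad)) break
        if (tries >= 1000L)
          stop("degenerate configuration: conditioning rejected all sections",
               call. = FALSE)
        nb <- sum(bad)
        D[bad] <- draw_truncnorm(nb, pop$diameter_mean_nm, pop$diameter_sd_nm,
                                 pop$diameter_min_nm)
        R[bad] <- D[bad] / 2
        z_s[bad] <- stats::runif(nb, -(R[bad] + h / 2), R[bad] + h / 2)
        apparent[bad] <- 2 * sqrt(pmax(0, R[bad]^2 - z_s[bad]^2))
        tries <- tries + 1L
      }
    }
    n_big <- stats::rpois(n, pop$ilv_count_mean)
    n_small <- stats::rpois(n, pop$small_ilv_rate)
    sid <- c(rep.int(seq_len(n), n_big), rep.int(seq_len(n), n_small))
    diam <- c(
      pmin(pmax(stats::rnorm(sum(n_big), pop$ilv_diameter_mean_nm,
                             pop$ilv_diameter_sd_nm), 1), D[rep.int(seq_len(n), n_big)] - 1),
      stats::runif(sum(n_small), 20, 40))
    z_ilv <- place_ilv_z(sid, R[sid], diam, pop$ilv_placement)
    seen <- abs(z_ilv - z_s[sid]) <= h / 2
    counts <- tabulate(sid[seen], nbins = n)
    out <- list(
      sections = data.frame(section_id = seq_len(n), true_diameter_nm = D,
                            apparent_diameter_nm = apparent,
                            slab_offset_nm = z_s, n_ilv = counts),
      ilvs = if (any(seen)) {
        o <- order(sid[seen])
        data.frame(section_id = sid[seen][o], diameter_nm = diam[seen][o])
      } else data.frame(section_id = integer(), diameter_nm = numeric()),
      population = pop, config = sec)
    class(out) <- "section_records"
    out
  })
}

draw_truncnorm <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:1000) {
    bad <- x < lower
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

# z-coordinates of ILV centers; the slab axis is z.  For "near-coat" the
# ILVs sit just under the limiting membrane within a 60-degree cap around a
# random coat axis (one axis per endosome), which concentrates them
# radially; the slab-axis projection stays isotropic on average because the
# axis itself is isotropic.
place_ilv_z <- function(sid, R, diam, placement) {
  m <- length(sid)
  if (!m) return(numeric(0))
  r_max <- pmax(R - diam / 2, 0)
  if (placement == "uniform-in-lumen") {
    u <- r_max * stats::runif(m)^(1 / 3)
    return(u * stats::runif(m, -1, 1))
  }
  # per-endosome random coat axis; we only need its z-component and a
  # rotation about it, so draw the axis z-cosine isotropically
  usid <- unique(sid)
  axis_cz <- stats::runif(length(usid), -1, 1)
  axis_sz <- sqrt(1 - axis_cz^2)
  idx <- match(sid, usid)
  cosphi <- stats::runif(m, cos(pi / 3), 1)
  sinphi <- sqrt(pmax(1 - cosphi^2, 0))
  psi <- stats::runif(m, 0, 2 * pi)
  dir_z <- cosphi * axis_cz[idx] + sinphi * cos(psi) * axis_sz[idx]
  (0.95 * r_max) * dir_z
}

#' Assemble EM section records from measurement tables
#'
#' Builds the container consumed by [section_statistics()] from per-section
#' measurement tables such as those recorded manually on electron
#' micrographs.
#'
#' @param sections Data frame with at least `section_id` and
#'   `apparent_diameter_nm`; optional `n_bud` column with the number of
#'   budding profiles per section.
#' @param ilvs Data frame with `section_id` and `diameter_nm`, one row per
#'   observed ILV.
#' @param gold Optional data frame of gold coordinates (`section_id`,
#'   `x_nm`, `y_nm`).
#' @param buds Optional list of `bud_contour` objects.
#' @return A `section_records` object.
#' @export
as_section_records <- function(sections, ilvs, gold = NULL, buds = NULL) {
  stopifnot(is.data.frame(sections), "section_id" %in% names(sections),
            is.data.frame(ilvs),
            all(c("section_id", "diameter_nm") %in% names(ilvs)))
  if (any(ilvs$diameter_nm <= 0))
    stop("ILV diameters must be positive", call. = FALSE)
  if ("apparent_diameter_nm" %in% names(sections)) {
    app <- sections$apparent_diameter_nm[match(ilvs$section_id,
                                               sections$section_id)]
    bad <- !is.na(app) & app > 0 & ilvs$diameter_nm >= app
    if (any(bad))
      warning(sum(bad), " ILV(s) larger than the apparent endosome diameter")
  }
  if (!("n_ilv" %in% names(sections)))
    sections$n_ilv <- as.integer(table(factor(ilvs$section_id,
                                              levels = sections$section_id)))
  out <- list(sections = sections, ilvs = ilvs, gold = gold, buds = buds)
  class(out) <- "section_records"
  out
}
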