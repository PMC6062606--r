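#' Simulate an ILV budding-profile contour
#'
#' Builds an open polyline (in nm) describing a cross-sectioned membrane
#' bud: a flat limiting-membrane flank, the invagination, and a flat flank.
#' Three archetypes are supported, mirroring the morphological binning of
#' budding profiles into shallow pits, U-shaped buds and omega-shaped
#' (neck-constricted) buds. The membrane plane is `y = 0` and the bud
#' extends towards positive `y` (the lumen side).
#'
#' Geometries per category:
#' * `pit`: circular arc with chord `width_nm` and sagitta `depth_nm`
#'   (requires `depth_nm <= width_nm / 2`);
#' * `U`: vertical walls of mouth `width_nm` closed by a semicircular tip,
#'   total depth `depth_nm` (requires `depth_nm >= width_nm / 2`);
#' * `omega`: a constricted channel of width `neck_width_nm` and length
#'   `neck_length_nm` opening into a circular bulb of diameter `width_nm`
#'   (requires `neck_width_nm < width_nm`; the depth follows from the
#'   geometry).
#'
#' @param category `"pit"`, `"U"` or `"omega"`.
#' @param width_nm Maximum internal width of the invagination (nm).
#' @param depth_nm Depth from the membrane plane to the tip (pit and U).
#' @param neck_width_nm,neck_length_nm Neck geometry (omega only).
#' @param noise_nm Uniform vertex jitter bound; each coordinate is displaced
#'   by at most `noise_nm`.
#' @param seed Integer seed for the jitter.
#' @param vertex_spacing_nm Approximate distance between vertices.
#' @param flank_length_nm Length of each flat membrane flank.
#' @return A `bud_contour`: an `n x 2` matrix with columns `x_nm`, `y_nm`
#'   and attributes `category` and `lumen_side`.
#' @export
simulate_bud_contour <- function(category = c("pit", "U", "omega"),
                                 width_nm, depth_nm = NULL,
                                 neck_width_nm = NULL, neck_length_nm = NULL,
                                 noise_nm = 0, seed = NULL,
                                 vertex_spacing_nm = 2, flank_length_nm = 40) {
  category <- match.arg(category)
  check_pos(width_nm, "width_nm")
  check_pos(vertex_spacing_nm, "vertex_spacing_nm")
  check_pos(flank_length_nm, "flank_length_nm")
  check_pos(noise_nm, "noise_nm", allow_zero = TRUE)
  w <- width_nm
  bud <- switch(category,
    pit = {
      check_pos(depth_nm, "depth_nm")
      if (depth_nm > w / 2)
        stop("inconsistent geometry: a pit requires depth <= width / 2",
             call. = FALSE)
      arc_points(w, depth_nm, vertex_spacing_nm)
    },
    U = {
      check_pos(depth_nm, "depth_nm")
      if (depth_nm < w / 2)
        stop("inconsistent geometry: a U-shaped bud requires depth >= width / 2",
             call. = FALSE)
      u_points(w, depth_nm, vertex_spacing_nm)
    },
    omega = {
      check_pos(neck_width_nm, "neck_width_nm")
      check_pos(neck_length_nm, "neck_length_nm")
      if (neck_width_nm >= w)
        stop("inconsistent geometry: omega requires neck_width < width",
             call. = FALSE)
      omega_points(w, neck_width_nm, neck_length_nm, vertex_spacing_nm)
    })
  mouth_half <- bud$mouth_half
  nfl <- max(3L, ceiling(flank_length_nm / vertex_spacing_nm))
  left <- cbind(seq(-(mouth_half + flank_length_nm), -mouth_half,
                    length.out = nfl), 0)
  right <- cbind(seq(mouth_half, mouth_half + flank_length_nm,
                     length.out = nfl), 0)
  pts <- rbind(left, bud$xy, right)
  pts <- pts[!duplicated(round(pts, 9)), ]
  if (noise_nm > 0)
    pts <- with_seed(seed, pts + matrix(stats::runif(length(pts), -noise_nm,
                                                     noise_nm), ncol = 2))
  colnames(pts) <- c("x_nm", "y_nm")
  structure(pts, class = "bud_contour", category = category,
            lumen_side = "+y")
}

# circular arc of chord w and sagitta d, dipping to +y
arc_points <- function(w, d, spacing) {
  rc <- (w^2 / 4 + d^2) / (2 * d)
  cy <- d - rc
  # arc from (-w/2, 0) through (0, d) to (w/2, 0); center (0, cy)
  th1 <- atan2(-cy, -w / 2)
  th2 <- atan2(-cy, w / 2)
  # go through pi/2 (the tip)
  if (th1 < pi / 2) th1 <- th1 + 2 * pi
  npt <- max(8L, ceiling(abs(th1 - th2) * rc / spacing))
  th <- seq(th1, th2, length.out = npt)
  list(xy = cbind(rc * cos(th), cy + rc * sin(th)), mouth_half = w / 2)
}

u_points <- function(w, d, spacing) {
  r <- w / 2
  wall <- d - r
  nw <- max(2L, ceiling(wall / spacing))
  leftwall <- cbind(-r, seq(0, wall, length.out = nw))
  th <- seq(pi, 0, length.out = max(8L, ceiling(pi * r / spacing)))
  tip <- cbind(r * cos(th), wall + r * sin(th))
  rightwall <- cbind(r, seq(wall, 0, length.out = nw))
  list(xy = rbind(leftwall, tip, rightwall), mouth_half = r)
}

omega_points <- function(w, neck, len, spacing) {
  r <- w / 2
  a <- sqrt(r^2 - (neck / 2)^2)
  y0 <- len + a
  nw <- max(2L, ceiling(len / spacing))
  leftwall <- cbind(-neck / 2, seq(0, len, length.out = nw))
  beta <- atan2(a, neck / 2)
  th <- seq(pi + beta, -beta,
            length.out = max(12L, ceiling((pi + 2 * beta) * r / spacing)))
  bulb <- cbind(r * cos(th), y0 + r * sin(th))
  rightwall <- cbind(neck / 2, seq(len, 0, length.out = nw))
  list(xy = rbind(leftwall, bulb, rightwall), mouth_half = neck / 2)
}
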