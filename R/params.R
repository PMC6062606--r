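#' Kinetic parameters of the two ESCRT recruitment archetypes
#'
#' Describes the two wave archetypes seen on single endosomes: a slow/linear
#' one (ESCRT-0/-I-like; accumulation over roughly two minutes) and a
#' fast/transient one (ESCRT-III-like; accumulation within seconds), plus the
#' Poisson rate at which coordinated wave events arrive on one endosome.
#' Within one event the two channels dissociate synchronously: the transient
#' onset is placed at
#' `slow_t_on + slow_t_off - (transient_t_on + transient_t_off)` seconds after
#' the slow onset (115 s at defaults), jittered by `onset_jitter_sd`.
#'
#' @param slow_t_on,slow_t_off Rise and fall durations of the slow archetype
#'   in seconds (defaults 122 and 73).
#' @param transient_t_on,transient_t_off Rise and fall durations of the
#'   transient archetype in seconds (defaults 12 and 68).
#' @param wave_rate Arrival rate of wave events per second (default 1/300,
#'   i.e. one wave per five minutes).
#' @param amplitude_slow,amplitude_transient Wave amplitudes above baseline,
#'   arbitrary intensity units.
#' @param onset_jitter_sd SD (s) of the Gaussian jitter applied to the
#'   transient onset relative to its synchronous-dissociation anchor.
#' @param baseline Constant baseline intensity (must be < amplitudes).
#' @param noise_sd SD of additive Gaussian noise per sample (default 10,
#'   i.e. 10% of the default amplitudes).
#' @param incomplete_dissociation_fraction Fraction of the slow amplitude
#'   retained after dissociation (in `[0, 1)`); the slow channel then declines
#'   to `baseline + fraction * amplitude` rather than to baseline. Default 0.
#' @return An object of class `kinetic_params`.
#' @seealso [simulate_traces()], [simulate_movie()]
#' @export
kinetic_params <- function(slow_t_on = 122, slow_t_off = 73,
                           transient_t_on = 12, transient_t_off = 68,
                           wave_rate = 1 / 300,
                           amplitude_slow = 100, amplitude_transient = 100,
                           onset_jitter_sd = 5,
                           baseline = 20, noise_sd = 10,
                           incomplete_dissociation_fraction = 0) {
  for (nm in c("slow_t_on", "slow_t_off", "transient_t_on", "transient_t_off"))
    check_pos(get(nm), nm)
  check_pos(wave_rate, "wave_rate", allow_zero = TRUE)
  check_pos(onset_jitter_sd, "onset_jitter_sd", allow_zero = TRUE)
  check_pos(noise_sd, "noise_sd", allow_zero = TRUE)
  check_pos(baseline, "baseline", allow_zero = TRUE)
  if (amplitude_slow <= baseline || amplitude_transient <= baseline)
    stop("amplitudes must exceed the baseline", call. = FALSE)
  if (incomplete_dissociation_fraction < 0 || incomplete_dissociation_fraction >= 1)
    stop("incomplete_dissociation_fraction must lie in [0, 1)", call. = FALSE)
  structure(list(
    slow_t_on = slow_t_on, slow_t_off = slow_t_off,
    transient_t_on = transient_t_on, transient_t_off = transient_t_off,
    wave_rate = wave_rate,
    amplitude_slow = amplitude_slow, amplitude_transient = amplitude_transient,
    onset_jitter_sd = onset_jitter_sd, baseline = baseline, noise_sd = noise_sd,
    incomplete_dissociation_fraction = incomplete_dissociation_fraction
  ), class = "kinetic_params")
}

#' Acquisition geometry and rendering parameters of a synthetic movie
#'
#' @param n_frames Number of frames (default 600, i.e. 30 min at 3 s).
#' @param frame_interval_s Frame interval in seconds (default 3, 0.33 Hz).
#' @param pixel_size_nm Lateral pixel size in nm (default 80).
#' @param image_shape Integer `c(ny, nx)` image size in pixels.
#' @param n_endosomes Number of simulated endosome spots.
#' @param diffusion_step_sd_px Per-frame random-walk step SD in pixels.
#' @param psf_sigma_px Isotropic Gaussian PSF sigma in pixels.
#' @param min_separation_px Minimum initial distance between endosome spots
#'   in pixels (best-effort rejection sampling).
#' @param background_level Mean camera background in counts.
#' @param channel_names Ordered channel labels; the first is the persistent
#'   cargo channel, the remaining two carry the slow and transient waves.
#' @param counts_per_unit Photon counts per trace intensity unit used when
#'   rendering ESCRT-channel spots.
#' @param cargo_amplitude Integrated counts of the persistent cargo spot.
#' @param read_noise_sd SD of the additive Gaussian (read) noise in counts.
#' @param noise_model `"poisson-gaussian"` (shot noise plus read noise) or
#'   `"none"` for noiseless rendering.
#' @return An object of class `movie_config`.
#' @export
movie_config <- function(n_frames = 600, frame_interval_s = 3,
                         pixel_size_nm = 80, image_shape = c(96L, 96L),
                         n_endosomes = 10, diffusion_step_sd_px = 1,
                         psf_sigma_px = 1.3, min_separation_px = 12,
                         background_level = 50,
                         channel_names = c("cargo", "slow", "transient"),
                         counts_per_unit = 25, cargo_amplitude = 3000,
                         read_noise_sd = 2,
                         noise_model = c("poisson-gaussian", "none")) {
  check_pos(n_frames, "n_frames")
  check_pos(frame_interval_s, "frame_interval_s")
  check_pos(pixel_size_nm, "pixel_size_nm")
  check_pos(psf_sigma_px, "psf_sigma_px")
  check_pos(n_endosomes, "n_endosomes", allow_zero = TRUE)
  check_pos(diffusion_step_sd_px, "diffusion_step_sd_px", allow_zero = TRUE)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1))
  if (any(image_shape < 4 * psf_sigma_px))
    stop("image_shape is smaller than 4 * psf_sigma_px", call. = FALSE)
  if (length(channel_names) != 3L)
    stop("channel_names must name the cargo, slow and transient channels",
         call. = FALSE)
  structure(list(
    n_frames = as.integer(n_frames), frame_interval_s = frame_interval_s,
    pixel_size_nm = pixel_size_nm, image_shape = as.integer(image_shape),
    n_endosomes = as.integer(n_endosomes),
    diffusion_step_sd_px = diffusion_step_sd_px, psf_sigma_px = psf_sigma_px,
    min_separation_px = min_separation_px,
    background_level = background_level, channel_names = channel_names,
    counts_per_unit = counts_per_unit, cargo_amplitude = cargo_amplitude,
    read_noise_sd = read_noise_sd, noise_model = match.arg(noise_model)
  ), class = "movie_config")
}

#' Endosome and ILV population parameters for the sectioning simulator
#'
#' Endosome diameters follow a normal distribution truncated from below;
#' each endosome carries a Poisson number of intraluminal vesicles (ILVs).
#'
#' @param diameter_mean_nm,diameter_sd_nm Mean and SD of the endosome
#'   diameter distribution in nm (defaults 251 and 129).
#' @param diameter_min_nm Lower truncation bound in nm (default 100).
#' @param ilv_count_mean Poisson mean number of ESCRT-sized ILVs per
#'   endosome (default 1).
#' @param ilv_diameter_mean_nm,ilv_diameter_sd_nm ILV diameter distribution
#'   in nm (defaults 50 and 5).
#' @param ilv_placement `"uniform-in-lumen"` or `"near-coat"` (ILVs
#'   concentrated below a random coat pole).
#' @param small_ilv_rate Poisson mean of additional small (20-40 nm) ILVs
#'   per endosome (default 0).
#' @return An object of class `endosome_population`.
#' @export
endosome_population <- function(diameter_mean_nm = 251, diameter_sd_nm = 129,
                                diameter_min_nm = 100, ilv_count_mean = 1,
                                ilv_diameter_mean_nm = 50,
                                ilv_diameter_sd_nm = 5,
                                ilv_placement = c("uniform-in-lumen", "near-coat"),
                                small_ilv_rate = 0) {
  check_pos(diameter_mean_nm, "diameter_mean_nm")
  check_pos(diameter_sd_nm, "diameter_sd_nm", allow_zero = TRUE)
  check_pos(diameter_min_nm, "diameter_min_nm")
  check_pos(ilv_count_mean, "ilv_count_mean", allow_zero = TRUE)
  check_pos(ilv_diameter_mean_nm, "ilv_diameter_mean_nm")
  check_pos(ilv_diameter_sd_nm, "ilv_diameter_sd_nm", allow_zero = TRUE)
  check_pos(small_ilv_rate, "small_ilv_rate", allow_zero = TRUE)
  if (ilv_diameter_mean_nm >= diameter_min_nm)
    stop("ILV diameters must be smaller than the smallest endosome", call. = FALSE)
  structure(list(
    diameter_mean_nm = diameter_mean_nm, diameter_sd_nm = diameter_sd_nm,
    diameter_min_nm = diameter_min_nm, ilv_count_mean = ilv_count_mean,
    ilv_diameter_mean_nm = ilv_diameter_mean_nm,
    ilv_diameter_sd_nm = ilv_diameter_sd_nm,
    ilv_placement = match.arg(ilv_placement),
    small_ilv_rate = small_ilv_rate
  ), class = "endosome_population")
}

#' Physical sectioning parameters for the slab-capture simulator
#'
#' @param thickness_nm Slab (section) thickness in nm (default 150).
#' @param conditioning `"none"` or `"min-chord"`: retain only sections whose
#'   apparent endosome diameter is at least `min_chord_nm`.
#' @param min_chord_nm Minimum apparent diameter in nm when conditioning.
#' @param n_sections Number of sections to simulate.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `section_config`.
#' @export
section_config <- function(thickness_nm = 150,
                           conditioning = c("none", "min-chord"),
                           min_chord_nm = 0, n_sections = 1000, seed = NULL) {
  check_pos(thickness_nm, "thickness_nm")
  check_pos(min_chord_nm, "min_chord_nm", allow_zero = TRUE)
  check_pos(n_sections, "n_sections")
  structure(list(
    thickness_nm = thickness_nm, conditioning = match.arg(conditioning),
    min_chord_nm = min_chord_nm, n_sections = as.integer(n_sections),
    seed = seed
  ), class = "section_config")
}

#' Spot segmentation and co-occurrence parameters
#'
#' @param max_dist_nm Centroid distance below which two spots from different
#'   channels count as co-occurring, in nm (default 400, i.e. 5 pixels at
#'   80 nm; the comparison is strict `<`).
#' @param pixel_size_nm Pixel size used to convert pixel distances to nm.
#' @param threshold_method `"otsu"`, `"percentile"` or `"absolute"`.
#' @param threshold_value Percentile in `(0, 100)` for `"percentile"`, or an
#'   absolute intensity for `"absolute"`; ignored for `"otsu"`.
#' @param min_area_px,max_area_px Connected-component area gates in pixels.
#' @return An object of class `cooccurrence_config`.
#' @export
cooccurrence_config <- function(max_dist_nm = 400, pixel_size_nm = 80,
                                threshold_method = c("otsu", "percentile", "absolute"),
                                threshold_value = 99,
                                min_area_px = 2, max_area_px = Inf) {
  check_pos(max_dist_nm, "max_dist_nm")
  check_pos(pixel_size_nm, "pixel_size_nm")
  check_pos(min_area_px, "min_area_px", allow_zero = TRUE)
  if (max_area_px < min_area_px)
    stop("max_area_px must be >= min_area_px", call. = FALSE)
  structure(list(
    max_dist_nm = max_dist_nm, pixel_size_nm = pixel_size_nm,
    threshold_method = match.arg(threshold_method),
    threshold_value = threshold_value,
    min_area_px = min_area_px, max_area_px = max_area_px
  ), class = "cooccurrence_config")
}

#' Tracking and intensity-measurement parameters
#'
#' @param max_disp_px Maximum per-frame displacement allowed for a link, in
#'   pixels (scaled by the gap length when closing gaps).
#' @param max_gap Maximum number of missed frames bridged by gap closing.
#' @param min_track_len Minimum track length in frames; shorter tracks are
#'   dropped.
#' @param disk_radius_px Radius of the measurement disk in pixels.
#' @param annulus_radii_px Inner and outer radius of the background annulus.
#' @param max_spot_area_px Optional upper bound on the area of spots used to
#'   seed tracks (emulates restricting analysis to small, single-microdomain
#'   vesicles); `Inf` disables the filter.
#' @return An object of class `tracking_config`.
#' @export
tracking_config <- function(max_disp_px = 5, max_gap = 2, min_track_len = 20,
                            disk_radius_px = 4, annulus_radii_px = c(6, 9),
                            max_spot_area_px = Inf) {
  check_pos(max_disp_px, "max_disp_px")
  check_pos(max_gap, "max_gap", allow_zero = TRUE)
  check_pos(min_track_len, "min_track_len")
  check_pos(disk_radius_px, "disk_radius_px")
  stopifnot(length(annulus_radii_px) == 2L, all(annulus_radii_px > 0),
            annulus_radii_px[1] < annulus_radii_px[2])
  if (annulus_radii_px[1] <= disk_radius_px)
    stop("annulus inner radius must exceed the disk radius", call. = FALSE)
  structure(list(
    max_disp_px = max_disp_px, max_gap = as.integer(max_gap),
    min_track_len = as.integer(min_track_len),
    disk_radius_px = disk_radius_px, annulus_radii_px = annulus_radii_px,
    max_spot_area_px = max_spot_area_px
  ), class = "tracking_config")
}

#' Wave detection parameters
#'
#' Controls the thresholded-run wave detector: traces are median-smoothed,
#' a local baseline is estimated by masking candidate waves and taking a
#' rolling median of the remaining samples, supra-baseline runs are found by
#' `k_sigma` exceedance with hysteresis, and each candidate wave is refined
#' by least-squares fitting an asymmetric piecewise-linear (tent) pulse.
#'
#' @param smoothing_window_frames Moving-median window in frames (odd;
#'   default 3).
#' @param k_sigma Baseline exceedance multiple defining the detection
#'   threshold (default 2).
#' @param min_above_frames Minimum run length above threshold (default 3).
#' @param baseline_window_frames Rolling window for the local baseline
#'   (default 60 frames).
#' @param baseline_percentile Percentile (in `(0, 50]`) used for the coarse
#'   global floor that masks waves before the baseline is computed
#'   (default 20).
#' @param min_wave_amplitude Minimum wave amplitude as a fraction of the
#'   smoothed trace range (default 0.15).
#' @param merge_gap_frames Sub-threshold gaps up to this many frames between
#'   runs are bridged (hysteresis; default 5).
#' @param refine `"tent"` (default) refines onset/peak/end by fitting the
#'   tent pulse; `"none"` keeps the raw threshold-crossing frame times.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(smoothing_window_frames = 3, k_sigma = 2,
                             min_above_frames = 3, baseline_window_frames = 60,
                             baseline_percentile = 20, min_wave_amplitude = 0.15,
                             merge_gap_frames = 5,
                             refine = c("tent", "none")) {
  check_pos(smoothing_window_frames, "smoothing_window_frames")
  check_pos(k_sigma, "k_sigma")
  check_pos(min_above_frames, "min_above_frames")
  check_pos(baseline_window_frames, "baseline_window_frames")
  check_pos(min_wave_amplitude, "min_wave_amplitude", allow_zero = TRUE)
  check_pos(merge_gap_frames, "merge_gap_frames", allow_zero = TRUE)
  if (baseline_percentile <= 0 || baseline_percentile > 50)
    stop("baseline_percentile must lie in (0, 50]", call. = FALSE)
  structure(list(
    smoothing_window_frames = as.integer(smoothing_window_frames),
    k_sigma = k_sigma, min_above_frames = as.integer(min_above_frames),
    baseline_window_frames = as.integer(baseline_window_frames),
    baseline_percentile = baseline_percentile,
    min_wave_amplitude = min_wave_amplitude,
    merge_gap_frames = as.integer(merge_gap_frames),
    refine = match.arg(refine)
  ), class = "detection_config")
}

#' EM morphometry parameters
#'
#' @param ilv_gate_small_nm Diameter gate `[lo, hi)` in nm for small,
#'   ESCRT-independent ILVs (default `c(20, 40)`).
#' @param ilv_gate_escrt_nm Diameter gate `[lo, hi]` in nm for ESCRT-sized
#'   ILVs (default `c(40, 60)`; both bounds inclusive, so 40 nm falls in the
#'   ESCRT gate).
#' @param gold_proximity_nm Distance in nm from a gold particle center to the
#'   limiting membrane below which the particle scores as proximal
#'   (inclusive; default 40).
#' @param pit_depth_ratio Depth/mouth-width ratio separating shallow pits
#'   from U-shaped buds (default 0.5).
#' @param section_thickness_nm Section thickness in nm (default 150).
#' @param neck_ratio Constriction criterion: a bud is omega-shaped when its
#'   minimum opening chord is below `neck_ratio` times its maximum internal
#'   width (default 0.9).
#' @param flank_residual_nm Maximum RMS residual in nm of the membrane-plane
#'   fit through the flanking segments before a contour is rejected as
#'   unclassifiable (default 6).
#' @return An object of class `morphometry_config`.
#' @export
morphometry_config <- function(ilv_gate_small_nm = c(20, 40),
                               ilv_gate_escrt_nm = c(40, 60),
                               gold_proximity_nm = 40,
                               pit_depth_ratio = 0.5,
                               section_thickness_nm = 150,
                               neck_ratio = 0.9,
                               flank_residual_nm = 6) {
  stopifnot(length(ilv_gate_small_nm) == 2L, length(ilv_gate_escrt_nm) == 2L)
  if (!(ilv_gate_small_nm[1] < ilv_gate_small_nm[2] &&
        ilv_gate_small_nm[2] <= ilv_gate_escrt_nm[1] &&
        ilv_gate_escrt_nm[1] < ilv_gate_escrt_nm[2]))
    stop("ILV gates must be ordered and non-overlapping", call. = FALSE)
  check_pos(gold_proximity_nm, "gold_proximity_nm")
  check_pos(pit_depth_ratio, "pit_depth_ratio")
  check_pos(section_thickness_nm, "section_thickness_nm")
  check_pos(neck_ratio, "neck_ratio")
  check_pos(flank_residual_nm, "flank_residual_nm")
  structure(list(
    ilv_gate_small_nm = ilv_gate_small_nm, ilv_gate_escrt_nm = ilv_gate_escrt_nm,
    gold_proximity_nm = gold_proximity_nm, pit_depth_ratio = pit_depth_ratio,
    section_thickness_nm = section_thickness_nm, neck_ratio = neck_ratio,
    flank_residual_nm = flank_residual_nm
  ), class = "morphometry_config")
}
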