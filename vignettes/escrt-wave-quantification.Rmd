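---
title: "Quantifying ESCRT recruitment waves and ILV formation"
author: "escrtwaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ESCRT recruitment waves and ILV formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escrtwaves)
```

# Scope

ESCRT complexes drive cargo sorting and intraluminal vesicle (ILV)
budding on endosomes in repeated, coordinated recruitment events
("waves"): a slow, linear accumulation of ESCRT-0/-I-type components over
roughly two minutes, a seconds-fast burst of ESCRT-III-type components
once the slow component peaks, and synchronous dissociation of both.
`escrtwaves` provides (i) a synthetic-data generator that encodes this
wave model together with a camera model, an endosome/ILV population model
and membrane-bud geometries, and (ii) the measurement pipeline — spot
segmentation, co-occurrence, tracking, wave detection and kinetics, EM
morphometry and stereology — that turns raw traces, movies and section
tables into the study's summary statistics. Because real imaging and EM
data of this kind are rarely deposited, the generator is the reference
against which every analysis stage is validated: each detector is tested
by parameter recovery against known ground truth.

# The wave model

A wave event on one endosome places a pulse in each of two channels:

* **slow channel** (ESCRT-0-like): linear rise from the local floor to
  `baseline + amplitude` over `slow_t_on` (default 122 s), then linear
  fall over `slow_t_off` (default 73 s);
* **transient channel** (ESCRT-III-like): rise over `transient_t_on`
  (12 s), fall over `transient_t_off` (68 s).

Defaults give the archetypal dwell times of 195 s and 80 s. The two
channels are coupled through their *ends*: the transient onset is placed
at `slow_t_on + slow_t_off − (transient_t_on + transient_t_off)` = 115 s
after the slow onset, so both channels dissociate at the same instant.
This synchronous-dissociation anchor also puts the transient onset within
a few seconds of the slow peak (122 s), consistent with the fast
component firing when the slow one has crested. The exact phase relation
is a modelling choice — observed traces constrain the end-point
synchrony more sharply than the onset lag — and per-wave Gaussian jitter
(`onset_jitter_sd`, default 5 s, clamped at ±3 SD) represents the
biological variability of that lag.

Waves arrive as a Poisson process with rate `wave_rate` (default 1/300
s⁻¹, one wave per five minutes). Candidate onsets are drawn on the
feasible range `[0, duration − dwell]` and any candidate overlapping an
already-placed wave is redrawn uniformly, so waves never superpose on one
endosome and the onset intensity stays approximately uniform at the
nominal rate — which is what makes the expected number of onsets in any
five-minute window approximately one at defaults. A configuration whose
wave cannot fit in the trace (`dwell ≥ duration` with a positive rate) is
rejected as degenerate.

Two refinements reflect observed behaviour. First, the slow channel may
dissociate incompletely: with
`incomplete_dissociation_fraction = f > 0` it falls only to
`baseline + f·amplitude`, and subsequent floors persist between waves.
The default is 0 (feature off), because the magnitude of the residual is
not quantified; the wave detector's *rolling* baseline (below) is
designed so that detection still works when it is switched on. Second,
additive Gaussian noise (`noise_sd`, default 10 intensity units = 10% of
the default amplitude) models the photon and readout noise of a
background-corrected trace.

# Movie rendering

`simulate_movie()` renders traces as isotropic Gaussian spots
(`psf_sigma_px`, default 1.3 px at 80 nm/px ≈ 100 nm, a realistic
widefield PSF width) moving by a reflected random walk
(`diffusion_step_sd_px`, default 1 px/frame). The cargo channel carries a
persistent spot per endosome (integrated `cargo_amplitude` counts); the
two ESCRT channels scale the trace value by `counts_per_unit`. Camera
noise is Poisson shot noise on signal plus background plus Gaussian read
noise, or can be switched off entirely. Defaults: 600 frames at 3 s
(30 min at 0.33 Hz), a 96×96-px field (7.7 µm — the scale of a cell
region holding ~10 resolvable endosomes), background 50 counts. Initial
spot positions are kept `min_separation_px` (12 px) apart so distinct
endosomes start resolvable; diffusion can still bring them together
later, which is exactly the regime where greedy tracking degrades — see
Limitations.

What the generator does *not* emulate: PSF anisotropy and defocus,
drift, vignetting or structured background, endosome fission/fusion,
photobleaching (bleaching is *corrected*, not simulated, unless imposed
on traces explicitly), and 3-D motion. Tests passing on this generator
therefore demonstrate correctness of the measurement operations, not
robustness to every real-data artifact.

# Wave detection

The paper-style analysis scores waves by eye; `detect_waves()`
operationalizes it in five steps.

1. **Smoothing**: moving median over `smoothing_window_frames` (3) —
   robust to single-frame outliers.
2. **Noise scale**: σ = 1.4826·median|Δy|/√2, the robust lag-1
   difference estimator; slow wave structure contributes little to
   first differences, so σ tracks the sampling noise.
3. **Baseline**: samples above a coarse global floor (the
   `baseline_percentile` = 20th percentile of the smoothed trace plus
   `k_sigma`·σ) are masked, the mask is dilated by `merge_gap_frames`,
   and the baseline b(t) is the rolling median of the unmasked samples
   over `baseline_window_frames` (60 frames = 180 s), interpolated
   across fully-masked stretches. A *local* baseline is essential when
   the slow channel does not return fully to baseline — dissociation
   must be scored against the current floor, not a global one. The
   mask-then-median construction avoids the downward bias that a plain
   rolling percentile acquires in noise and the upward bias it acquires
   inside long waves.
4. **Candidate runs**: maximal runs of at least `min_above_frames` (3)
   smoothed samples above b(t) + `k_sigma`·σ (k = 2). Sub-threshold
   gaps up to `merge_gap_frames` (5) are bridged *only if* the trace
   does not return near baseline inside the gap (above b + k·σ/2);
   unconditional bridging would merge genuinely distinct waves
   separated by a short baseline visit. Runs whose amplitude is below
   `min_wave_amplitude` (0.15) of the smoothed trace range are
   discarded.
5. **Refinement**: a threshold crossing is reached ~k·σ/slope after the
   true onset (and before the true end), which would bias every dwell
   short by tens of seconds at 10% noise. Each candidate is therefore
   refit by least squares with an asymmetric piecewise-linear pulse
   (onset, peak, end free; amplitude profiled out analytically) over the
   run plus five flanking frames; the flanking baseline frames anchor
   the onset and end without bias, and the fitted rise/fall intersection
   gives a sub-frame peak time. Nelder–Mead from the threshold-crossing
   initialization, 500 iterations, relative tolerance 1e−9; on failure
   the unrefined frame times are kept (`refine = "none"` exposes that
   behaviour directly). Refined intervals are clipped at neighbour
   midpoints so detected waves never overlap.

On noiseless traces the detector recovers every generated wave with
onset, peak and end within one frame; under the default 10% noise the
pooled means of dwell, t_on and t_off for both archetypes are recovered
within a few percent (the test suite and `scripts/acceptance.R` compute
these numbers; nothing beyond what they compute is claimed here).

`wave_statistics()` pools waves across tracks (the pooled mean equals
the wave-count-weighted mean of per-track means); `periodicity()` uses
onset-to-onset intervals (peak-to-peak available as an option — which
one the by-eye analysis used is not determinable, onsets are sharper
under our detector); `count_waves()` uses a half-open window [t0, t1),
so an onset exactly at the window end is excluded. `average_profiles()`
min–max normalizes each segment channel to [0, 100], aligns at the
transient-channel onset by default (the sharpest landmark; slow-onset
alignment is the alternative) and averages on a common grid restricted
to the interval covered by all segments.

# Tracking and intensity measurement

Linking is greedy nearest-neighbour: per frame, candidate
(track, spot) pairs within `max_disp_px·(gap+1)` are assigned in order
of increasing distance, ties broken by track then spot index — fully
deterministic, and invariant to the within-frame spot order except at
exactly equal distances. Gap closing bridges up to `max_gap` (2) missed
frames; tracks shorter than `min_track_len` (20) frames are dropped. A
`max_spot_area_px` filter restricts seeding to small spots, emulating
the restriction of manual tracking to small vesicles with a single
ESCRT microdomain. Greedy linking (rather than a global assignment
solver) is a deliberate simplicity/determinism trade-off: at one wave
per 5 min and ~1 px/frame diffusion the ambiguity rate is low, and the
failure mode (track break at a close encounter) is benign for
per-endosome kinetics.

Intensity per frame and channel is the mean in a disk (`disk_radius_px`
4) at the track position minus the *median* in an annulus (6–9 px) —
the median resists contamination by neighbouring spots. Disk/annulus
radii of the original manual measurements are not reported; these
defaults fit the rendered spot size. Gap-frame positions are linearly
interpolated and flagged; a disk clipped by the image border yields NA
for that frame rather than an error.

`bleach_correct()` fits `b·exp(−t/τ)` and divides it out (normalized to
1 at t = 0). The reference series should be the whole-movie mean
intensity — dominated by background pixels, it pins τ tightly, which is
how the standard ImageJ-style correction behaves. When no reference is
given the trace's own lower envelope is used in two passes (envelope
fit, then refit on wave-masked baseline samples); with waves occupying
~65% of the trace this single-trace estimate is variance-limited and
should be treated as best-effort. A flat or rising envelope is treated
as "no detectable bleaching" (identity, τ = ∞); a failed fit falls back
to no correction with a warning recorded on the result.

# Imaging statistics

Segmentation thresholds each frame (Otsu by default on the frame's own
histogram — the original "semi-automated" operator-tuned thresholds
cannot be reproduced, so a parameter-free default plus percentile /
absolute overrides is the honest choice), labels connected components
(EBImage), filters by area (`min_area_px` 2) and returns
intensity-weighted centroids. An Otsu threshold that fails to clear the
background noise floor (median + 3·MAD) is treated as "no foreground":
on a frame without spots Otsu otherwise just splits the noise
distribution. A constant frame returns an empty spot set, not an error.

Co-occurrence: a reference (cargo) spot counts as co-occurring when at
least one query-channel centroid lies strictly closer than
`max_dist_nm` (400 nm = 5 px at 80 nm/px; the strict inequality follows
the "< 5 px" convention, so a pair at exactly 400 nm does not count).
Each reference spot counts once however many query spots are nearby —
the statistic is "reference spots with a partner", not pairs. Distances
are centroid-to-centroid Euclidean in nm; pixel size is configuration,
never hard-coded. The Manders coefficient is the textbook
MCC = Σᵢ Aᵢ·[Bᵢ > T]/Σᵢ Aᵢ; an all-zero A channel is an undefined
result (error), by contract.

# EM morphometry and stereology

**Size gates.** ILVs are classed `small` in [20, 40) nm and `escrt` in
[40, 60] nm; the boundary at exactly 40 nm goes to the ESCRT gate
(the counting rule is "between 40 and 60 nm", taken inclusive at both
ends) and everything outside is `other`.

**Slab capture.** An endosome of radius R holding an ILV at any radial
position shows it in a section of thickness h with probability
h/(2R+h), when the slab center is uniform over the intersecting range
[−(R+h/2), R+h/2] and the ILV is scored by center-in-slab. The identity
holds for *any* radial placement because the slab-center distribution
is uniform over a range that contains every ILV's capture window — so
uniform-in-lumen and near-coat placement give the same capture rate for
fixed R (they differ once conditioning on the visible profile is
applied). The apparent endosome diameter is the sphere chord at the
slab center. `expected_ilvs_per_section()` gives the analytic value
λ·h/(2R+h) (valid only for fixed diameter, uniform placement, no
conditioning — it refuses otherwise) or a Monte-Carlo estimate through
the generator for the full population model. ILV visibility ignores
projection overlap within the slab (a documented simplification: a
150-nm section projects 2–3 ILV diameters, so occasional occlusion in
real micrographs reduces counts slightly). Whether the published
section counts were implicitly conditioned on visible gold labelling is
unknown; `min-chord` conditioning is available to explore such
selection effects but is off by default.

**Bud profiles.** Synthetic contours are flat membrane flanks plus an
invagination: a circular arc (pit), vertical walls closed by a
semicircle (U), or a constricted channel opening into a circular bulb
(omega). `classify_bud()` fits the membrane plane through the first and
last five vertices by total least squares (RMS residual above
`flank_residual_nm`, 6 nm, means the flanks are not identifiable — the
contour is reported unclassifiable rather than guessed), rotates the
contour into that frame, and measures horizontal chords on a fine depth
grid (≤0.5 nm steps, median-smoothed over 5 levels). Depth is the
maximum distance from the plane; the mouth width is the chord just
above the plane (above the flank-noise band); the neck width is the
minimum chord between the plane and the widest point. A bud is
`omega` when the neck is below `neck_ratio` (0.9) of the maximum width
— the 10% margin keeps vertex noise from turning a straight-walled U
into a constriction; otherwise `pit` when depth < `pit_depth_ratio`
(0.5) × mouth width, else `U`. The published binning was visual, so the
pit/U ratio is an explicit, configurable convention. The omega neck
length is the depth extent over which the chord stays within 10% of the
neck width — for a parallel-walled channel this reproduces the
generating length to within the vertex spacing. All measurements are
invariant under rigid motions and vertex-order reversal.

**Gold proximity.** A particle is proximal when its center lies within
`gold_proximity_nm` (40 nm, inclusive) of the contour polyline. The
source convention — a 40-nm *diameter* circle touching the membrane
versus "closer than 40 nm" — is ambiguous; the 40-nm center-to-membrane
rule is adopted and the radius is configuration.

# Reproducibility plumbing

Every stochastic entry point takes a seed and restores the caller's RNG
state. `run_pipeline()` derives per-stage seeds from the global seed by
a fixed integer recurrence (stages can be re-run independently), stamps
every CSV with an MD5 hash of the configuration and the seed, and is
byte-reproducible for a fixed configuration. Movies are written as
frame-major multi-page TIFF with a JSON sidecar holding axes, channel
names, calibration and the intensity scale.

# Problem sizes

The validation suite works at desk scale, chosen to keep Monte-Carlo
error comfortably below the assertion tolerances: kinetics recovery
pools ≥500 waves per archetype from 120 tracks of 30 simulated minutes;
wave counting uses 64 tracks; slab-capture checks use 10⁵ sections
(3-SE agreement with the closed form) and 3×10⁴ sections for the
population summaries; the end-to-end imaging check uses a 220-frame,
96×96-px, 3-endosome noiseless movie.

# Known limitations

* The wave shape is piecewise linear by default; real transient-channel
  onsets are better described as exponential/cooperative. The linear
  default keeps every downstream estimator analyzable; the tent-fit
  refinement degrades gracefully on smoother shapes (it finds the
  least-squares tent) but its sub-frame precision is then nominal.
* Greedy tracking breaks (rather than mis-assigns) at close encounters;
  densities well above ~10 spots per 96×96 px field will fragment
  tracks.
* Single-trace bleach-correction is variance-limited at high wave duty
  cycle; use a movie-level reference when available.
* The stereology scores center-in-slab visibility and ignores
  projection overlap and section compression.
* Whether a partially-dissociating slow wave should end at the local
  floor crossing (as implemented) or at a fixed fraction of amplitude
  is a convention; with strong incomplete dissociation the two differ,
  and dwell times should be read with that in mind.
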