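# escrtwaves

Quantification of coordinated ESCRT recruitment waves on endosomes and of
intraluminal vesicle (ILV) formation.

## The problem

During receptor down-regulation, endosomes sort ubiquitinated cargo (e.g.
EGF receptor) into ILVs of a multivesicular endosome. The machinery doing
this — the ESCRT complexes 0 through III plus the VPS4 ATPase — is not
resident on the endosome: live-cell imaging of single EGF-positive
endosomes shows *waves* of recruitment. ESCRT-0-like components (HRS)
accumulate slowly and linearly (t<sub>on</sub> ≈ 122 s), ESCRT-III-like
components (CHMP4B) flash in within seconds (t<sub>on</sub> ≈ 12 s) once
the slow component peaks, and both dissociate synchronously
(t<sub>off</sub> ≈ 70 s). Waves repeat roughly once per five minutes, and
electron microscopy of the same system shows about 0.5 ILVs per 150-nm
endosome section — consistent, after correcting for the fraction of the
endosome sampled by a thin section, with one wave producing one ILV.

`escrtwaves` implements the full quantitative pipeline for this kind of
study, for microscopists and image analysts who want to score ESCRT (or
other pulsatile) recruitment dynamics and relate them to EM morphometry:

* **synthetic data with ground truth** — two-channel wave traces,
  rendered multi-channel movies (Gaussian PSF, Poisson + read noise,
  diffusing spots), sectioned endosome populations and bud contours:
  `simulate_traces()`, `simulate_movie()`, `simulate_sections()`,
  `simulate_bud_contour()`;
* **spot imaging** — per-frame segmentation, the 400-nm object
  co-occurrence statistic and Manders colocalization coefficient
  MCC = Σᵢ Aᵢ·[Bᵢ > T] / Σᵢ Aᵢ: `segment_spots()`,
  `count_cooccurring()`, `cooccurrence_timecourse()`, `manders_mcc()`;
* **tracking** — greedy nearest-neighbour linking with gap closing,
  disk-minus-annulus intensity measurement, photobleaching correction:
  `link_tracks()`, `measure_intensity()`, `bleach_correct()`;
* **wave kinetics** — wave detection on intensity traces with a
  model-based (piecewise-linear pulse) refinement, dwell/onset/
  dissociation statistics, periodicity, windowed wave counts, normalized
  average profiles: `detect_waves()`, `wave_statistics()`,
  `periodicity()`, `count_waves()`, `average_profiles()`;
* **EM morphometry and stereology** — 20–40 / 40–60 nm ILV size gates,
  per-section statistics, pit/U/omega bud classification with neck and
  depth measurement, immunogold proximity, and the slab-capture
  expectation E[ILVs per section] = λ·h/(2R+h) for an endosome of radius
  R cut by sections of thickness h: `classify_ilv_size()`,
  `section_statistics()`, `classify_bud()`, `gold_near_bud()`,
  `expected_ilvs_per_section()`;
* **orchestration** — a seeded, hash-stamped pipeline runner:
  `pipeline_config()`, `run_pipeline()`.

## Worked example

Simulate ten 30-minute endosome tracks at the default kinetics (10% noise),
detect the waves, and summarize:

```r
library(escrtwaves)

sim <- simulate_traces(n_tracks = 10, seed = 42)
waves <- do.call(rbind, lapply(sim$traces,
                               function(tr) as.data.frame(detect_waves(tr))))
wave_statistics(waves)
#> Wave kinetics over 100 waves
#>    channel  n dwell_mean dwell_sd t_on_mean t_on_sd t_off_mean t_off_sd
#>       slow 50      191.0     8.54     120.0    7.01       71.0     5.80
#>  transient 50       80.5     4.37      12.2    2.61       68.3     5.26
#>  period_mean period_sd
#>          322       145
#>          321       144
```

The detector recovers the generator's archetypes: slow waves dwell ~191 s
(rise ~120 s, fall ~71 s), transient waves ~80 s with a ~12 s rise —
the kinetic signatures of ESCRT-0- and ESCRT-III-type recruitment. Counting
wave onsets in the first five minutes gives about one wave per endosome:

```r
counts <- vapply(split(waves, waves$track_id), function(w)
  count_waves(w[w$channel == "slow", ], c(0, 300)), integer(1))
mean(counts)
#> [1] 1.1
```

On the EM side, a 251-nm endosome holding one ILV shows it in a 150-nm
section with probability h/(2R+h):

```r
expected_ilvs_per_section(1, endosome_population(diameter_sd_nm = 0))
#> [1] 0.3740648

recs <- simulate_sections(endosome_population(),
                          section_config(n_sections = 20000, seed = 42))
st <- section_statistics(recs)
c(st$mean_escrt_per_section, st$fraction_le1_escrt)
#> [1] 0.355 0.929
```

So one wave per five minutes plus slab sampling predicts roughly 0.35–0.5
ESCRT-sized ILVs per section, with >90% of sections showing at most one —
a single wave forming a single ILV is sufficient to explain the section
counts.

## Vignette

`vignettes/escrt-wave-quantification.Rmd` documents the models and the
numerical choices: the wave generator and its anchoring of transient to
slow waves, the detector's baseline estimation and pulse-fit refinement,
the slab-capture stereology, bud-contour measurement conventions, and the
known limitations of the synthetic data.
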