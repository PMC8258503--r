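# nephrospec

Fourier-transform quantification of kidney microstructures in
super-resolution micrographs of routinely stained histology sections.

Super-resolution imaging of stained kidney biopsies resolves three
structures whose pathological changes are textural: podocyte foot
processes (periodic; effaced in nephrotic disease), tubular mitochondria
(parallel rods; fragmented in tubulointerstitial injury) and the
glomerular basement membrane (smooth intensity along the capillary wall;
irregular in membranous disease). `nephrospec` turns each change into a
number via the 2-D power spectrum of a small ROI, for renal pathologists
and image analysts who want reproducible, label-free morphometry from
routine sections:

* **Foot-process band-power score** — for a 128×128 ROI with centered DFT
  `F(u,v)`, the fraction of spectral magnitude inside the concentric-square
  annulus `(1/16)·N/2 ≤ max(|u|,|v|) < (1/4)·N/2` (912 bins at N = 128):

  `S = Σ_B |F| / Σ_nonDC |F|` — high for intact periodic texture, low under
  effacement.
* **Mitochondrial damage index** — the ROI is cut into its inscribed disc,
  the power spectrum is split into eight 45° sectors, opposite sectors are
  averaged into four axes, and the index is `minor axis / major axis` ∈
  (0, 1] — ≈1 for isotropic (fragmented) texture, ≪1 for oriented
  (healthy tubular) texture.
* **Membrane trace CV** — a traced capillary-wall polyline is linearized to
  180 arc-length samples (bilinear interpolation) and summarised as
  `CV = population sd / mean` — higher = more irregular membrane signal.

Because clinical images are not distributed, the package ships seeded
phantom generators (plane waves, ridge textures with an effacement dial,
rod fields with tunable orientation dispersion, membrane traces with
tunable irregularity) plus self-contained statistics (simple linear
regression, Spearman rho, Mann–Whitney U with exact enumeration), so every
metric is validated against ground truth at test time. See
`vignettes/spectral-metrics.Rmd` for the models, parameter choices and
limitations.

## Worked example

```r
library(nephrospec)

# two synthetic "patients": mild vs severe foot-process effacement
healthy <- lapply(1:3, function(s) make_foot_process_phantom(effacement = 0.1, seed = s))
effaced <- lapply(4:6, function(s) make_foot_process_phantom(effacement = 0.8, seed = s))
tab <- score_roi_batch(c(healthy, effaced), subjects = rep(c("MGA", "MCNS"), each = 3))
tab[tab$level == "subject", ]
#>   roi_id subject   level score_normalized score_raw n_band_bins
#> 7   <NA>     MGA subject            0.353      70.3         912
#> 8   <NA>    MCNS subject            0.102      12.9         912
```

The per-subject mean band score drops from 0.353 to 0.102 as effacement
replaces the period-12 ridge texture with a low-frequency field — the
in-band fraction of spectral magnitude collapses.

```r
damage_index(make_rod_field(orientation_kappa = 100, seed = 1))
#> <damage_result> index 0.3126 (minor 12.12 / major 38.77, major axis 90 deg, axes)
damage_index(make_rod_field(orientation_kappa = 0, rod_length_mean = 3, n_rods = 200, seed = 1))
#> <damage_result> index 0.9919 (minor 21.51 / major 21.68, major axis 135 deg, axes)
```

Aligned 30-px rods (concentration κ = 100, direction 0°) elongate the
spectrum along v — major axis at 90°, index 0.31; short randomly oriented
rods are isotropic — index 0.99.

```r
trace_cv(make_membrane_trace(irregularity = 0.4, seed = 1))
#> <trace_stats> CV 0.3461 (mean 107.4, population sd 37.16, n = 180)

fit_plane_wave(make_plane_wave(128, 0.4, 0.4))[c("omega_x", "omega_y")]
#> $omega_x  [1] 0.4      $omega_y  [1] 0.4
```

A command-line wrapper over the same functions is installed at
`inst/scripts/nephrospec` (phantom synthesis, batch scoring from an ROI
manifest CSV, spectrum export, regression/U-test on CSV columns).

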