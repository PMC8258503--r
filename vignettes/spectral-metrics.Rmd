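---
title: "Spectral texture metrics for kidney micrographs: models, parameters, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral texture metrics for kidney micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephrospec)
```

## The problem

Super-resolution imaging of routinely stained kidney sections resolves three
microstructures whose disease-related changes are textural rather than
object-like: the periodic interdigitation of podocyte foot processes (lost in
effacement), the parallel orientation of tubular mitochondria (lost in
fragmentation), and the smooth intensity of the glomerular basement membrane
along the capillary wall (made irregular by deposits). All three changes are
changes in *spatial-frequency content*, which is why every metric in this
package is built on the 2-D discrete Fourier transform of a small
region of interest (ROI).

The transform convention is fixed throughout: unnormalized forward DFT,
`1/N^2` on the inverse, centered layout with the DC bin at centered index
(0, 0) (matrix position `N/2 + 1` for even `N`), `u` the horizontal
(column) frequency and `v` the vertical (row) frequency, pixel coordinates
0-based with the origin at the top-left. ROIs must be square with an even
side; rectangular or odd-sided input is rejected rather than padded, because
every downstream rule (band membership, sector symmetry, Nyquist exclusion)
is defined on that grid. No apodization window is applied before the FFT;
spectral leakage is accepted and quantified below.

## Foot-process integrity: the band-power score

A healthy foot-process texture is quasi-periodic with a period of roughly
10–15 px at the reference scale (128 px = 4.13 µm, i.e. 32.27 nm/px), so
its spectral magnitude concentrates in a mid-frequency annulus. The score is
the magnitude inside the concentric-square annulus between squares of side
`N/4` and `N/16`:

$$S = \frac{\sum_{(u,v)\in B} |F(u,v)|}{\sum_{(u,v)\neq DC} |F(u,v)|},\qquad
B = \{\, \tfrac{1}{16}\cdot\tfrac{N}{2} \le \max(|u|,|v|) < \tfrac{1}{4}\cdot\tfrac{N}{2} \,\}.$$

At `N = 128` the annulus is `4 <= max(|u|,|v|) <= 15` and contains exactly
912 of the 16383 non-DC bins. Band bounds are half-open (inner inclusive,
outer exclusive) so that nested bands tile the spectrum without overlap; the
DC bin belongs to no band; and the full band `(1, 0)` closes over the
Nyquist row/column so that it covers every non-DC bin — without that closure
the "whole spectrum" band would silently drop the unpaired
highest-frequency row and column of an even grid.

Two flavours are reported. `score_normalized` divides by the total non-DC
magnitude, which makes the score exactly invariant to affine intensity
changes (`a*img + b`): offsets live in DC, gains cancel in the ratio. This
is the default, because section-to-section exposure differences are the
dominant nuisance in stained-section imaging. `score_raw` (mean band
magnitude per bin) is reported alongside for users who want the
unnormalized quantity.

**Linear versus squared magnitude.** The band statistic can be accumulated
as `|F|` (linear, the default) or `|F|^2` (spectral energy,
`magnitude = "squared"`). The choice changes absolute values substantially:
a pure plane wave of angular frequency 0.4 rad/px per axis — whose peak bin
(8, 8) sits comfortably inside the annulus — scores 0.632 under linear
magnitude but 0.993 under energy, because leakage from a non-bin-aligned
frequency decays like `1/|distance|` in amplitude, slowly enough that the
linear sum keeps heavy tails everywhere in the spectrum. Orderings (healthy
vs. effaced, monotone response to degradation) are unaffected, which is why
the package treats the flavour as a reporting choice, keeps linear |F| as
the default, and exposes both.

## Mitochondrial anisotropy: the damage index

Healthy tubular mitochondria run in parallel; their texture is oriented and
its power spectrum elongates perpendicular to the stripes. Fragmented
mitochondria give an isotropic spectrum. The index quantifies this:

1. The square ROI is cut into its inscribed disc (`circular_window()`),
   because the sharp ROI border otherwise injects cross-shaped leakage
   along the `u = 0` and `v = 0` axes that contaminates the axis sectors.
   The pixels outside the disc are replaced by the in-disc mean by default —
   zero fill is available, but mean fill avoids creating a new step edge at
   the disc boundary. (What the out-of-disc pixels should contain is not
   observable from the final spectra alone; both options are kept so the
   choice is explicit.)
2. The power spectrum is split into eight 45° sectors, sector 0 centered
   on the +u axis, half-open bounds `[45s - 22.5°, 45s + 22.5°)` so that
   the diagonal bins at exactly 45° land in sector 1 deterministically.
3. Sector means use only bins inside the inscribed spectral disc of radius
   `N/2`, excluding DC and the Nyquist row/column. The Nyquist exclusion
   preserves exact conjugate symmetry, so `means[s] == means[s+4]` for any
   real image. The radial restriction makes the eight sectors geometrically
   equivalent: the corner bins of a square spectrum reach radius
   `sqrt(2) * N/2` but exist only along the diagonals, so including them
   biases the diagonal sectors low for any radially decaying spectrum — an
   isotropic ring phantom reads a spurious 27% sector imbalance with
   corners included and under 2% without.
4. Opposite sectors are averaged into four axes (0°, 45°, 90°, 135°); the
   major axis is the largest (ties toward the smaller label), the minor
   axis is the one *orthogonal* to the major, and the damage index is
   minor/major, in (0, 1].

The axis rule is used instead of a least-squares ellipse because conjugate
symmetry makes the 8-point radar chart a 4-axis object; a centered-ellipse
fit over the eight polar points is nevertheless available
(`method = "ellipse"`) as a sensitivity check, and agrees in direction on
all phantom families.

## Basement-membrane irregularity: the trace CV

The membrane metric is deliberately simple: a manually traced polyline
along the capillary wall is resampled at 180 equally spaced arc-length
positions (the trace length is fixed regardless of the traced arc, with a
warning when that means upsampling), intensities are read by bilinear
interpolation (exact on affine ramps; nearest-neighbour available), and the
coefficient of variation sd/mean is computed. The *population* sd (divisor
`n`) is the default: the 180 samples are the entire traced object, not a
sample from a larger population. The sample convention is one argument
away, and for 180 samples the two differ by 0.3%.

## The phantom generators

No clinical images are distributed with the package, so every metric is
validated against seeded synthetic phantoms whose ground truth is known by
construction. All generators are pure functions of their arguments
including the seed (they restore the caller's RNG state), and each exposes
one degradation dial chosen to move exactly one metric:

* `make_plane_wave()` — exact sinusoids; used for frequency-recovery and
  band-membership checks.
* `make_foot_process_phantom()` — unit-peak ridges of period 12 px
  (fundamental at centered index ~10.7, inside the scoring band at
  `N = 128`) mixed with a smooth field built from integer-frequency
  cosines with `max(|k|) <= 3` (inside the inner square, so its band score
  is ~0 with no leakage), under an effacement weight `lambda`; additive
  Gaussian noise (sd 0.05 by default) clipped at zero. The texture is
  normalised to unit peak before scaling so the nonnegativity clip never
  bites at zero noise — clipping a too-tall texture would inject broadband
  harmonics and contaminate the band score.
* `make_rod_field()` — Gaussian-profile line segments with axial von Mises
  orientations (angles doubled before sampling, since rods are undirected;
  Best–Fisher rejection sampling), length jittered ±30%. `kappa = 100`
  with 30 px rods emulates parallel tubular mitochondria; `kappa = 0` with
  3 px rods emulates fragmentation.
* `make_membrane_trace()` — `base * exp(g)` with `g` a Gaussian-smoothed
  noise field rescaled to sd `sigma`; multiplicative lognormal bumps keep
  the trace positive without truncation, and CV ≈ `sigma` for small
  `sigma`.

What the phantoms do *not* emulate: the structured-illumination point
spread function and reconstruction artefacts, stain chemistry and
photobleaching, correlated background from neighbouring structures, and
manual ROI/trace placement variability. Passing phantom tests therefore
demonstrates that each metric responds correctly and monotonically to the
geometric property it claims to measure — not that clinical effect sizes
will match on real sections.

## Self-contained statistics

The validation pipeline ranks phantom populations, so the package carries
its own simple linear regression (closed-form, R² as squared Pearson
correlation), Spearman correlation (Pearson on mid-ranks), and Mann–Whitney
U test. The U test uses the exact null distribution — computed by the
rank-sum counting recurrence — when the combined sample is at most 16 and
tie-free, and a tie-corrected, continuity-corrected normal approximation
otherwise; the exact path can be requested explicitly for any tie-free
sizes, and the phantom group comparisons (n = 20 per group) do so. Exact
p-values are tested against a full enumeration oracle for all group sizes
up to 5 and against `wilcox.test` at n = 20.

## Numerical choices and degenerate inputs

* Forward/inverse transforms round-trip to ~1e-15; the engine is tested
  against a naive O(N⁴) DFT at 16×16 and against Parseval's identity up to
  256×256 at 1e-10.
* All-zero (or constant) images have no non-DC magnitude; the normalized
  band score is *signalled as an error*, not returned as 0, since silence
  would poison per-subject means.
* An all-zero sector profile has no major axis; signalled likewise.
* Ties in the major-axis selection break toward the smaller angle label.
* Traces with non-positive mean have no CV; signalled.
* Out-of-bounds polyline vertices are rejected with the offending vertex
  index.
* Plane-wave frequencies at or beyond π rad/px are rejected (aliasing).

## Problem sizes used in the test suite

Property-style suites run at the reference ROI size 128×128 where the
claim concerns the reference protocol (band counts, white-noise score
expectation over 100 seeds, effacement series over 10 λ values × 20
seeds, rod-field comparisons over 20 seeds per group) and at 16–64 px where
the claim is grid-generic (oracle DFT agreement, sector-assignment oracle,
symmetry). These sizes keep the full suite under a minute on one core while
leaving every statistical check well-powered; they are stated here so users
re-running the suite know what was actually measured.

## Known limitations

* The band score's absolute value depends on the magnitude flavour (see
  above); compare scores only within one flavour.
* Band fractions are interpreted as side-length fractions of concentric
  squares. Users changing the ROI size away from 128 px must rescale
  physical expectations: the band tracks *fractional* frequency, while
  biological periodicity is fixed in nm.
* The sector radar uses 45° resolution; textures oriented exactly between
  two axes split their energy and the index is mildly conservative there.
* Manual tracing is assumed for membranes; there is no automatic
  capillary-wall segmentation.
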