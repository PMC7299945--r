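---
title: "Combined PL/Raman imaging of cells and nanodiamonds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined PL/Raman imaging of cells and nanodiamonds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanfnd)
```

## The measurement and the analysis problem

A confocal Raman microscope with 532 nm excitation records, in a single
scan, one spectrum per pixel: Raman scattering from the cell and buffer
plus, wherever a fluorescent nanodiamond (fND) sits in the confocal
volume, broadband photoluminescence (PL) from its nitrogen-vacancy (NV)
centers. The spectrograph grating selects the recorded window. Centred
at 610 nm the window covers the biomolecular fingerprint region
(~700–1700 cm⁻¹) but misses most NV emission; centred at 680 nm it
captures the NV phonon sideband at the price of losing the fingerprint
region. The analysis task is to turn one such cube into (i) a label-free
image of the nucleus and (ii) a map of fND pixels classified by chemical
environment (intracellular or not) and brightness.

The packaged pipeline is deliberately simple and fully deterministic:
band integrals on the Raman-shift axis, and one-dimensional two-cluster
k-means computed exactly.

## C-H sub-band nucleus imaging

The C-H stretching band (~2800–3010 cm⁻¹) mixes lipid CH₂ scattering
(peaking near 2855 cm⁻¹) and protein/compact-DNA scattering (near
2920 cm⁻¹). The nucleus is lipid-poor and protein/DNA-rich, so

* `negative_image()` integrates 2800–2935 cm⁻¹ — the nucleus appears
  dark with high contrast;
* `positive_image()` integrates 2930–3010 cm⁻¹ — the nucleus appears
  bright, with lower contrast because protein signal is high everywhere
  in the cell.

The two windows overlap by 5 cm⁻¹; they are kept at their published
values rather than adjusted, and both are configurable. The full-range
C-H image uses 2800–3030 cm⁻¹ (the full range is not pinned by any
printed value; this covers both sub-bands with a margin). Every map
subtracts a chord (straight line through the window-edge values) before
integrating, so that broadband NV PL under the band does not leak into
the cell image; whether the original analysis baselined these maps is
not documented, and the chord is this package's choice. Chord
endpoints are single channels for `band_integral()`/`band_map()` (the
documented contract); the fingerprint preprocessing (below) averages 3
channels per endpoint because there the chord noise would otherwise
dominate the area normalization.

## Hierarchical five-class fND classification

`classify_fnd()` composes three stages, in a fixed order:

1. **Luminescence.** `pl_feature()` integrates each pixel over a
   Raman-silent window, by default 1800–2700 cm⁻¹, where cells have no
   bands and broadband NV emission dominates, and subtracts a per-cube
   dark offset (median of the 5% dimmest pixels). `detect_luminescent()`
   splits the feature values in two and accepts the split only if the
   raw between-group separation reaches `min_separation` (default 5)
   times the robust noise level (MAD of the map) — the false-positive
   guard: an fND-free cube yields an empty mask.
2. **Chemistry.** `split_by_ch()` groups the luminescent pixels by their
   chord-baselined C-H band area (default window 2800–2980 cm⁻¹) and
   calls a group intracellular when its mean reaches the midpoint
   between the substrate C-H level and the lower quartile of the cell
   population, both estimated from the non-luminescent pixels.
3. **Brightness.** `split_by_intensity()` splits each chemical group by
   the PL feature into low and high grade; degenerate or weakly
   separated groups (and single pixels) are labelled low.

Every pixel ends in exactly one of `NONLUM`, `EXTRA_LOW`, `EXTRA_HIGH`,
`INTRA_LOW`, `INTRA_HIGH`, with the fixed rendering colors (red layer,
dark blue, light blue, yellow, white — black in spectra plots).

### Numerical design of the splits

The optimal 1-d 2-means partition is a split of the sorted values, so
`two_means_1d()` scans all n−1 splits with prefix sums and returns the
global optimum — no seeding, no iterations, first index on ties.
Degenerate input (all values identical) is flagged rather than split.

Two transformations protect the split *placement* without changing what
is being clustered (both are strictly monotone, so they only move the
boundary):

* The luminescence split runs on `log1p(pmax(x, 0) / (5σ))`. On raw
  values, sum-of-squares is dominated by whichever group has the larger
  spread: with few emitters at a 1:10 grade ratio the optimal raw split
  separates the high grade from *everything else*, silently dropping
  dim emitters; with an aggressive compression the optimum instead
  splits the noise bulk. Placing the compression knee at the
  false-positive guard level (5× noise) squashes sub-threshold noise
  while keeping genuine emitters spread out.
* The chemistry split runs on `asinh(x / (5σ_substrate))` (sign-
  preserving, since chord-baselined areas can be negative), and group
  membership is then decided against the substrate/cell reference
  boundary rather than by "high group = inside": when all emitters
  share one environment, the within-group structure reflects only NV
  brightness leakage into the C-H window, and both groups legitimately
  land on the same side.

### Why the C-H score window stops at 2980 cm⁻¹

Under 532 nm excitation the NV⁻ zero-phonon line at 636 nm appears at
~3076 cm⁻¹ on the Raman-shift axis — right beside the C-H band. A chord
endpoint inside the ZPL tail acquires an error proportional to NV
brightness; at the default high-grade amplitude an endpoint at
3030 cm⁻¹ biases the score by roughly −32 000 counts·cm⁻¹, more than
the entire cellular C-H area, whereas an endpoint at 2980 cm⁻¹ keeps
the bias near −7 000 while retaining strong nucleus signal
(~17 000 counts·cm⁻¹). Narrower windows (ending at 2935 or
2950 cm⁻¹) avoid the ZPL entirely but leave the nucleus C-H area within
a few noise units of the substrate, which degrades chemical
localization of nuclear fNDs. 2800–2980 cm⁻¹ is the compromise default;
it is a configuration field, not a constant.

## Fingerprint-region KMCA (comparison method)

`kmca_segment()` implements the classical organelle segmentation:
per-pixel spectra restricted to 700–1700 cm⁻¹, chord-baselined,
normalized to unit band area, then k-means with k-means++ seeding under
a fixed seed (Lloyd iterations, at most 300; `stats::kmeans` performs
the iterations) and labels renumbered by descending cluster size. Two
numerical guards matter on real-world scenes:

* Chord endpoints are means of 3 edge channels — a single noisy channel
  tilts the chord across the 1000 cm⁻¹ window and its error dominates
  the band area.
* The unit-area normalization divides by `max(area, 0.25·q90(area))`.
  Signal-free substrate pixels have band areas that are pure noise
  around zero; dividing by them would inflate noise into unit-area
  pseudo-spectra that capture clusters. Floored pixels therefore
  integrate to *less* than 1 by design; all pixels with genuine signal
  integrate to 1.

`nucleus_agreement()` compares the fingerprint nucleus cluster with the
dark side of the negative image (two-means binarization inside the cell
region, values winsorized at the 95th percentile so hot lipid-droplet
pixels cannot absorb the split) via the Dice coefficient
2|A∩B|/(|A|+|B|).

## The synthetic phantom

`phantom_config()`/`make_phantom()` generate the validation scenes: a
64×64-pixel scan (0.5 µm pixels) of an elliptical cell with nucleus,
nucleolus and lipid droplets on CaF₂ in buffer. Per-pixel expected
spectra are non-negative mixtures of Gaussian-band endmembers with the
published peak positions — protein C-H 2920, lipid C-H 2855, whole-cell
composite 2915, water O-H 3400, CaF₂ 320 cm⁻¹, and a seven-band
fingerprint set (785, 1004, 1095, 1260, 1340, 1450, 1660 cm⁻¹) with
organelle-specific weights. Region recipes follow the biology
qualitatively: the nucleus holds elevated protein weight and 20% of the
cytoplasm's lipid weight (the "very low lipid" statement has no printed
number; 20% is a declared fixture), the nucleolus 1.5× the nucleus
protein, droplets 5× the cytoplasm lipid. Absolute weights are fixtures
chosen so band areas sit at realistic hundreds of counts, not estimates
of any cell line.

**NV emission model.** Two Gaussian ZPLs (575 nm for NV⁰, 636 nm for
NV⁻, σ 1.5/2 nm, photon ratio 1:2.5) on a phonon sideband of seven broad
Gaussians spanning ~620–900 nm. The sideband mixture weight between its
in-band core and its short-wavelength flank was calibrated once by
deterministic root finding so the model satisfies both photophysical
constraints — 4% of photons in the ZPLs, 70% of emission in 670–890 nm —
and the weights are frozen as package constants. `nv_spectrum()` is the
single source of this model for both simulation and the
window-capture analysis (`window_capture_fraction()` reproduces the
*direction* of the grating-sensitivity effect, 680 nm > 610 nm; the
instrument-specific magnitude is out of scope).

**Emitters, optics, noise.** fNDs are single-pixel emitters convolved
with a Gaussian PSF (σ 0.7 px ≈ the 325 nm lateral resolution at 0.5 µm
pixels). Brightness is parameterized in detection units: a low-grade
emitter's brightest pixel carries a PL-window band area of `fnd_snr`
(default 20) times the reference band-area noise; high grade is 10×
that. The reference noise is fixed (3 counts/channel read noise
propagated through the trapezoid), deliberately decoupled from the
actual `read_noise_sd`, so noise-scaling experiments do not rescale the
emitters. Noise is Poisson(expected) plus Gaussian read noise, fully
seeded; identical config + seed gives bitwise-identical cubes, and the
caller's RNG stream is restored afterwards.

**Grating windows.** The default span is 190 nm. At the 680 nm centre
this records ~1703–5894 cm⁻¹: the fingerprint region is lost (as the
method trades it away) while the default PL feature window
(1800–2700 cm⁻¹) and the C-H band remain covered — a narrower span
would make the published feature window unusable at this grating
setting. At 610 nm the same span keeps the fingerprint region, the CaF₂
line and the water band. Fingerprint-segmentation phantoms are
generated with `integration_scale = 4`, reflecting that
fingerprint-region imaging needs substantially longer integration than
combined PL/C-H imaging; the photon budget at scale 1 leaves cluster
separability marginal for the smallest organelle.

**What the phantom does not emulate.** Realistic cell morphology,
intra-organelle texture, autofluorescence, cosmic rays, detector etaloning,
photobleaching, focus drift, fND aggregation and motion. Passing
recovery tests on phantoms therefore demonstrates the *statistical
machinery* (detection calibration, split placement, agreement scoring)
under the stated noise model, not performance on any particular
instrument or cell line.

## Problem sizes and verification

The shipped tests run the pipeline end-to-end on 64×64×~700 cubes
(single scenes for the imaging and segmentation checks; 20 seeded
phantoms for the recovery statistics, with precision, recall, in/out
and grade accuracy each required to average ≥ 0.95 under PSF-ring-
tolerant scoring), verify `two_means_1d` against brute-force split
enumeration up to n = 1000, the NV model against its two photon-budget
constraints by numeric integration, and the optics formulas against
direct arithmetic. `scripts/acceptance.R` recomputes the NV photon
percentages and the protein/lipid endmember peak positions from a fresh
session.

## Known limitations

* The chemical score is a scalar band area; a spectral-shape matched
  filter would separate NV leakage from C-H signal more cleanly at
  extreme brightness.
* The five-class scheme assigns PSF ring pixels of bright emitters to
  the low-grade classes (they are genuinely dimmer); per-emitter
  aggregation is left to downstream analysis.
* `NONLUM` covers both cell and bare substrate; the cell/background
  distinction lives in the C-H intensity layer, not the label map.
* TIFF export stores samples rescaled to [0, 1] with a JSON calibration
  sidecar (the available TIFF writer does not store out-of-range
  floats); absolute values round-trip through the CSV container.
* Anti-Stokes channels, z-stacks and vendor file formats are out of
  scope.
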