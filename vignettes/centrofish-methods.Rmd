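---
title: "centrofish: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{centrofish: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centrofish)
```

This vignette is the package's own account of its science: the generative
model behind the synthetic data, the detector and statistics design, the
numerical conventions, and what the test suite does and does not establish.

## 1. The biological setting

Pericentrin-class PCM scaffold proteins are unusually large (3336 aa in
human pericentrin) and slow to make: at 3–10 aa/s a full-length chain takes
10–20 minutes, while mitotic PCM expansion completes in ~30 minutes. A
polysome-transport model resolves this: the mRNA, carrying up to
`floor(10000/260) = 38` ribosomes (`ribosome_capacity()`), is moved to the
centrosome and translated locally. The package quantifies the imaging
signatures of that model: centrosome-proximal mRNA enrichment, nascent-chain
(N⁺/C⁻) colocalization in a 1–3 µm shell, and translation-dependent
centrosomal protein accumulation.

## 2. The synthetic world

`generate_cell()` renders a 4-channel stack
(`mrna`, `nterm`, `cterm`, `reference`) from `generator_params()`:

* **Geometry.** A 6 × 12.8 × 12.8 µm volume at voxel size
  (0.3, 0.2, 0.2) µm `(z, y, x)` — roughly the central quarter of a mitotic
  cell at confocal sampling. Two PCM blobs, 4 µm apart, model prometaphase
  spindle poles; the `G1` preset has one centrosome.
* **PCM blobs.** Isotropic Gaussians of SD `radius/2` with nominal radius
  1 µm (the reported mean mitotic centrosome radius) and total flux
  `centrosome_amplitude` (2 × 10⁵ a.u. for early M). A Gaussian has no edge,
  so "radius" is given meaning by the segmenter's boundary convention
  (section 4).
* **mRNA spots.** A fraction `proximal_fraction` (0.6 in control) of spots
  is drawn from a centrosome-proximal component whose volumetric density
  decays exponentially with distance, `ρ(r) ∝ exp(-r/λ)`, i.e. radial law
  `r² exp(-r/λ)`; the remainder is uniform background. Proximal distances
  are truncated at the centre's minimum distance to an image face, which
  keeps the radial law analytically integrable (the quadrature oracle used
  in tests) and every proximal spot in bounds. λ defaults to 1.5 µm. The
  uniform-background fraction (0.4) is a free calibration: the source data
  show clear enrichment with a visible cytoplasmic remainder but publish no
  background density, so 40% was fixed once as a plausible value and the
  dispersal presets are defined relative to it.
* **Rendering.** Spots are continuous-position point sources convolved with
  an anisotropic Gaussian PSF, σ = (0.4, 0.25, 0.25) µm, written as exact
  Gaussian integrals over voxel extents (flux is conserved to <1% whenever
  the 4σ support is inside the image) — this is what makes sub-voxel
  localization testable.
* **Translation.** Exactly `round(translating_fraction × n_spots)` spots
  (half, in control) carry a colocalised N-terminus IF source of flux 4000
  a.u. and no C-terminus source; the C-terminus channel is a flat diffuse
  level (full-length protein), 20 a.u.
* **Noise.** Per channel: Poisson on the photon-scaled signal, then additive
  Gaussian read noise (SD 2), on a camera baseline of 10 a.u.; negative
  values are clipped at 0. Defaults give a single-spot peak SNR ≈ 8.

**Density and resolvability.** The spot count (32 per cell) and PSF were
chosen jointly so that the emulated data share a basic property of real
smFISH images: neighbouring spots are mostly resolvable. An early draft of
this world (60 spots, λ = 0.75 µm, σz = 0.6 µm) placed ~23% of spots within
2.4 PSF widths of a neighbour — a density at which *no* detector separates
them and which does not resemble published images; it was restated once to
the current values and frozen. The residual ~7% of merged proximal pairs is
an intended, realistic feature; it is why detected counts run slightly
below truth and why the count-recall requirement sits near 0.9 rather
than 1.

**Presets** (`preset_params()`) fix the published effect sizes relative to
the early-M control: puromycin and harringtonine collapse
`proximal_fraction` to 0.05, set `translating_fraction = 0` and scale PCM
flux × 0.7 (the ~30% acute-puromycin reduction); emetine equals control
(elongation freezing preserves polysomes and localization); late G2 has PCM
flux × 0.5 (twofold maturation increase); G1 has a quarter of the late-G2
spot count (fourfold G1→G2 mRNA increase). `generate_population()` adds
per-cell multiplicative log-normal jitter (SD 0.15 on the log scale) to
count, PCM flux and mean spot flux — enough cell-to-cell spread for
realistic t-tests without drowning the effects.

## 3. Spot detection

`detect_spots()` is a transparent replacement for commercial spot fitting:

1. scale-normalised Laplacian-of-Gaussian filter matched to the expected
   spot σ per axis *in voxel units* (anisotropic voxels handled in filter
   space); σ below one voxel on any axis is rejected with guidance;
2. strict 3D local maxima (26-connectivity) above `k × MAD` of the masked
   response, `k = 5`; plateau ties go to the lexicographically smallest
   `(z, y, x)` voxel;
3. sub-voxel refinement by intensity-weighted centroid of the
   background-subtracted raw image over a 2σ ellipsoid (a full 3D Gaussian
   least-squares fit was considered and not adopted: the centroid meets the
   ≤ 0.5 voxel/axis accuracy target at SNR 8 at a fraction of the cost);
4. integrated intensity = background-subtracted raw sum over a 3σ
   ellipsoid, background = median of a 3–5σ annulus;
5. a **photometric significance filter**: integrated flux must exceed
   `k × (annulus MAD) × sqrt(n_voxels)`. The LoG response to Poisson noise
   has heavier-than-Gaussian tails (measured ~12× the Gaussian exceedance
   rate at 5σ), so the filter threshold alone admits a few false maxima per
   10⁷ voxels; real spots integrate to ~65 noise-SD while these flukes sit
   at 3–5, so the photometric test removes them without costing recall.
   This keeps the blank-image false-positive rate below 1 per megavoxel at
   the default `k`.

Coordinates are voxel-centre based throughout: voxel `i` (1-based) spans
`[(i-1)d, i·d)` with centre `(i-0.5)d`.

## 4. PCM segmentation and the 1/e² boundary

`segment_reference()` finds components with Gaussian pre-smoothing
(σ = 0.1 µm), a detection threshold `max(Otsu within mask, background
median + 5 × MAD)`, and 26-connected components above 0.1 µm³. Because a
Gaussian blob has no sharp edge, the *boundary* of each component is then
refined to the 1/e² level of its background-subtracted peak (beam-waist
convention): for a Gaussian of SD σ that boundary lies at `r = 2σ`, so a
blob rendered with SD `radius/2` is segmented at its nominal radius. A
global Otsu cut would land near half-maximum and report ~0.59 µm for a 1 µm
body — the refinement is what makes "equivalent radius" a calibrated
quantity. Per component the package reports the intensity-weighted centre
of mass, the equivalent radius `(3V/4π)^{1/3}`, and the **sum of original
(unsmoothed, non-background-subtracted) intensities** within the refined
region — deliberately mirroring the convention of summing raw image
intensity inside the fitted volume, with no background subtraction inside
the PCM (an optional local-background mode is a config flag away via the
spot-measurement machinery). At most the top 2 components per cell are
retained, ranked by summed intensity; the rank field is also the hook for
asymmetry analyses between the brighter and dimmer pole.

## 5. Localization statistics

* Distances are Euclidean in µm from spot position to the centrosome's
  intensity-weighted centre of mass (not its surface); spots inside the PCM
  keep their natural bins, since published distributions start at 0 µm.
  Assignment is to the nearest centrosome, ties broken toward rank 1.
* Radial profiles use half-open bins `[a, a + 0.5)` from 0, plus an explicit
  terminal overflow bin, weights = summed spot intensity per bin,
  normalised per cell by total spot intensity, so each cell's fractions sum
  to 1 within 1e-9 and cells with different expression levels contribute
  equally. Whether the source analyses normalised per cell before averaging
  is not documented; per-cell normalisation was chosen (it matches
  "fractions of mRNA" computed per cell and then averaged) and is flagged
  here.
* Aggregation across cells: per-bin unweighted mean with a Student-t 95% CI
  (n − 1 df); a seeded percentile bootstrap (10⁴ resamples) is available
  behind a flag and agrees with the t interval within 20% relative width in
  tests. Biological replicates are pooled, not modelled hierarchically.
* The dispersal statistic is the per-cell intensity-weighted fraction of
  mRNA within 3 µm (configurable) of the nearest centrosome; conditions are
  compared with a two-sided unpaired t-test.

**Welch vs Student.** The source analyses state Student's t-test; the
package defaults to the Welch correction (unequal variances are the norm for
intensity data) and exposes `var_equal = TRUE` for exact parity. This is a
deliberate deviation, recorded here.

## 6. Translation-site calling

`call_translation()` encodes the epitope logic exhaustively: N⁺/C⁻ →
`translating`, N⁺/C⁺ → `ambiguous` (mRNA coincident with full-length
protein; excluded only behind a flag, and kept in shell denominators by
default since the source does not state whether such spots were dropped),
anything else → `mrna_only`. Positivity is `local signal > 3 × annulus MAD`
with a 0.3 µm probe ball and a 2–3× probe-radius annulus
(`measure_channel_at_spot()`); the cutoff is a package calibration — no
numeric criterion is published. `shell_translation_fraction()` restricts to
spots with nearest-centrosome distance in `[1, 3)` µm and reports the
intensity-weighted N⁺ fraction per cell (count weighting behind a flag;
intensity weighting is the default, consistent with using intensity in lieu
of mRNA units). Cells with no shell spots are excluded and logged.

The kinetics calculators are exact arithmetic: `ribosome_capacity()` uses
`floor()` (physical occupancy; the published "as many as 40" is treated as a
rounded upper bound, never asserted as equality) and `synthesis_time()` is
`cds_length_aa / rate`.

## 7. Intensity and count comparisons

`centrosomal_intensity()` sums `sum_intensity` over a cell's (≤2)
centrosome records. `mrna_count()` counts detected spots by default; an
intensity-deconvolved estimate (total / median single-spot intensity) is
available because the original counting method is not specified.
`compare_conditions()` reports group means, fold change, percent change,
the t statistic, two-sided p, and a t-based CI on the mean difference;
degenerate all-equal inputs return `t = 0, p = 1` with a flag rather than
an error.

## 8. What a green suite establishes — and what it does not

The ground truth lets the tests close the loop quantitatively: detection
recall/precision ≥ 0.9 and ≤ 0.5-voxel localization at SNR 8; radial laws
recovered against quadrature oracles; binning identical to brute force on
1000 random instances; the four preset effect sizes (twofold, 30%,
fourfold, 1 µm) recovered through the full image pipeline over 10 seeds;
null t-test size and CI coverage at nominal rates; dispersal contrasts
significant in 10/10 replicates for puromycin/harringtonine and absent for
emetine. What the synthetic world does *not* contain: deconvolution
artefacts, autofluorescent structured background, nuclear exclusion and
cell-boundary geometry, mRNA clustering beyond the radial law, chromatic
shift between channels, and multi-scale ("different sizes") spot
populations — a green suite says the algorithms are correct under the
stated model, not that the model exhausts real data. Condition labels and
cell-cycle stages are always user-supplied metadata, never inferred from
images.

## 9. Interfaces and determinism

Every stochastic step takes an explicit seed; identical seeds give
bit-identical images, tables and CSV bodies (`run_pipeline()` writes a JSON
provenance record with the master seed and a config hash). Images are
in-memory calibrated arrays; the package deliberately ships no TIFF codec —
the installed environment provides none, and the analysis contract is
defined at the level of calibrated arrays and data frames. Arrays produced
by any TIFF reader can be wrapped with `voxel_image()` unchanged.
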