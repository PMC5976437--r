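# centrofish

Quantification of centrosomal mRNA localization and local translation in 3D
single-molecule FISH / immunofluorescence images.

## The problem

During centrosome maturation the pericentriolar material (PCM) expands
rapidly: in human cells the PCM reaches maximal size within ~30 minutes of
mitotic onset, yet a single pericentrin (PCNT) protein — 3336 amino acids —
takes 10–20 minutes to synthesise at typical elongation rates (3–10 aa/s).
One resolution of this kinetic problem is co-translational targeting: *PCNT*
mRNA, loaded with ribosomes as a polysome, is enriched near the centrosome
and translated locally, so nascent protein is delivered where it is
incorporated. Testing this hypothesis from microscopy requires a chain of
quantitative steps:

1. detect individual smFISH spots (each ≈ one mRNA) in 3D with sub-voxel
   accuracy, using spot intensity in lieu of mRNA units;
2. segment the PCM reference bodies and measure their centres of mass and
   summed intensities;
3. measure the distance from every mRNA spot to the *nearest* centrosome and
   build per-cell intensity-weighted radial distributions in 0.5 µm bins;
4. call actively translating spots by the epitope logic
   N-terminus⁺ / C-terminus⁻ (a nascent chain has an N-terminus but not yet
   a C-terminus) within a 1–3 µm shell around the centrosome centre (the
   mean mitotic centrosome radius is ~1 µm, so the shell is "close to, but
   not within" the PCM);
5. compare conditions (translation inhibitors, cell-cycle stages) with
   two-sided unpaired t-tests on per-cell statistics.

`centrofish` implements this pipeline for R, together with a ground-truthed
synthetic 3D image generator (anisotropic Gaussian PSF, Poisson shot noise +
Gaussian read noise, exact per-voxel flux integrals) whose condition presets
encode the published effect sizes — mRNA dispersal under puromycin or
harringtonine but not emetine, a ~30% drop in centrosomal protein after an
acute puromycin pulse, twofold PCM growth from late G2 to early M, and a
fourfold mRNA increase from G1 to late G2 — so that every stage of the
analysis is verifiable against known truth at desk scale.

Images are in-memory calibrated arrays (`voxel_image`, axis order `z, y, x`,
all physical units in µm); all tabular results are plain data frames and the
pipeline writes CSV plus a JSON provenance record.

## Worked example

```r
library(centrofish)

g     <- generate_cell(preset_params("early_M_control", seed = 42))
spots <- detect_spots(g$image)              # sub-voxel LoG spot detection
cs    <- segment_reference(g$image)         # PCM segmentation

nrow(spots)
#> 27                                        # of 32 rendered (some merge)
cs[, c("rank", "z_um", "y_um", "x_um", "radius_um", "sum_intensity")]
#>   rank  z_um  y_um  x_um radius_um sum_intensity
#> 1    1 3.001 6.396 4.403     1.033        155801
#> 2    2 2.998 6.396 8.401     1.030        154960

round(radial_profile(spots, cs)[1:8], 3)    # fraction of mRNA per 0.5 µm bin
#> [0,0.5) [0.5,1) [1,1.5) [1.5,2) [2,2.5) [2.5,3) [3,3.5) [3.5,4)
#>   0.031   0.067   0.112   0.215   0.061   0.240   0.000   0.000

proximal_fraction(spots, cs)                # mRNA within 3 µm of a centrosome
#> 0.726
shell_translation_fraction(list(list(spots = spots, centrosomes = cs)))$per_cell
#> 0.509                                     # N⁺/C⁻ fraction in the 1–3 µm shell
centrosomal_intensity(cs)                   # summed PCM signal, both poles
#> 310761

ribosome_capacity(kinetics_params())        # floor(10,000 nt / 260 nt)
#> 38
synthesis_time(kinetics_params()) / 60      # 3336 aa at 3 aa/s, minutes
#> 18.5
```

The two segmented PCM bodies sit within a few nm of the generating centres,
their equivalent radii recover the nominal 1 µm radius, and about half of
the shell mRNA carries nascent-chain signal, matching the generating
translating fraction of 0.5. `compare_conditions()` /
`compare_dispersal()` then contrast such per-cell statistics between
populations, and `run_pipeline()` orchestrates the whole chain for named
condition presets, writing `spots.csv`, `centrosomes.csv`, `profiles.csv`,
`shell_fractions.csv`, `per_cell_intensity.csv`, `per_cell_counts.csv`,
`comparisons.csv` and `provenance.json` into a run directory.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: the ribosome
occupancy of a 10 knt transcript at 260 nt spacing; the percent reduction in
mean per-cell centrosomal intensity under the acute-puromycin preset versus
the early-mitotic control (30 synthetic cells per arm, 10 replicate seeds,
full segmentation pipeline); and the mean equivalent radius of segmented PCM
bodies across a 30-cell control population. Results are written as JSON.

## Vignette

`vignettes/centrofish-methods.Rmd` documents the generative model, the
detector and segmenter design (thresholding rules, sub-voxel refinement,
the 1/e² boundary convention), the statistical conventions, and the known
limitations of the synthetic world.
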