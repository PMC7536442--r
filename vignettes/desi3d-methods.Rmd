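---
title: "desi3d: methods and design of the 3D DESI-MSI pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{desi3d: methods and design of the 3D DESI-MSI pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desi3d)
```

## The problem

Desorption electrospray ionisation mass spectrometry imaging (DESI-MSI)
rasters an ambient ion source across a tissue section and records one mass
spectrum per pixel. Imaging a series of adjacent sections and stacking them
reconstructs the three-dimensional distribution of each molecular species
through the specimen. The scientific workflow this package implements,
end to end and on open formats, is:

1. simulate (or read from imzML) a series of per-section pixel spectra;
2. normalise each pixel to its total ion current (TIC), pick peaks and bin
   m/z values across all sections onto one axis;
3. rigidly register consecutive sections and stack them into an isotropic
   volume;
4. factorise the pixels-by-bins matrix with non-negative matrix
   factorisation (NMF) to segment molecularly distinct regions;
5. co-localise selected ion distributions with a fluorescence-derived
   hypoxia mask, including a *band-depth* statistic for bands lying in the
   interior of the stained region;
6. annotate signature ions by exact mass and neutral-loss arithmetic.

The emulated acquisition is 15 serial sections at a 120 µm z step imaged
with 120 µm pixels, so voxels are isotropic by construction, and an m/z
50–1200 window in both polarities.

## The synthetic phantom

No public raw data exist for this kind of experiment, so every stage is
validated against a ground-truthed synthetic phantom
(`phantom_spec()` / `build_phantom()` / `render_sections()`). The default
phantom is a tumour-like object with three nested regions, each carrying
its own ion signatures per polarity:

* a **viable** tumour ellipsoid (e.g. a PI(38:4)-like m/z 885.5 channel in
  negative mode),
* an off-centre **hypoxic** core expressing a CA-9-like fluorescence
  marker,
* a thin **band** at intermediate depth inside the core carrying the
  acylcarnitine-like channels (m/z 400.3421, 428.3734 and the 369.2999
  fragment).

Design choices worth making explicit:

* **The tumour extends beyond the sampled z window** (semi-axis 0.8·nz).
  Serial sectioning cuts a window through a larger mass, so every section
  carries substantial tissue. This matters for registration: the spec'd
  chain uses section 0 as the global reference, and a reference section
  with a ~50-pixel tissue cap makes the whole chain ill-posed. The
  geometry validator therefore enforces in-plane containment but only
  z-overlap.
* **The hypoxic core sits off-centre in-plane.** Real perfused rims and
  hypoxic cores are eccentric, and a concentric phantom would make
  rotation recovery ill-posed (every rotation of a rotationally symmetric
  object matches equally well).
* **Noise model:** a per-pixel log-normal TIC factor (default coefficient
  of variation 0.2, mean 1) that TIC normalisation must remove, an
  additive half-normal intensity floor, and 5 ppm Gaussian m/z jitter per
  peak. "10%" noise in the acceptance properties means a TIC coefficient
  of variation of 0.1.
* **Planted misalignment:** each section after the first receives a random
  rigid transform (up to ±10°, ±360 µm); section 0 stays untouched, so
  the truth frame and the registration reference frame coincide.
* **Fluorescence** is rendered on a 4× finer grid than the MSI raster,
  emulating a slide scanner, and must be thresholded and down-sampled
  (`threshold_mask()`, `resample_mask()`) before comparison.

```{r phantom, eval = FALSE}
spec <- phantom_spec(seed = 1)
truth <- build_phantom(spec)
secs <- render_sections(truth, "positive")
truth
```

## Preprocessing and binning

`tic_normalize_section()` scales every pixel spectrum to a common TIC;
all-zero pixels are flagged missing rather than failing the batch.
`pick_peaks()` (profile data only) finds local maxima above
`snr × 1.4826 × MAD` and centroids them by intensity-weighted mean m/z;
plateaus keep the lower-m/z sample so picking is deterministic.
`bin_peaks()` pools every centroid from every pixel, clusters them by 1D
single linkage, and splits any cluster wider than the tolerance at its
largest internal gap. The pipeline default tolerance is 60 ppm — about
four standard deviations of the spread produced by 5 ppm per-peak jitter
across two pixels — so that one planted channel lands in exactly one bin
without merging the distinct lipid channels, which are hundreds of ppm
apart.

## Registration and reconstruction

TIC images carry the structural contrast, but only *before* normalisation
(after it, every pixel sums to the same target). `register_series()`
chains the sections: section 0 is the reference and each later section is
registered to its already-aligned predecessor, the most similar image
available. `estimate_rigid()` searches an angle grid (default ±15° by
0.5°) and, per angle, integer translations by normalized cross-correlation
(NCC). Two refinements matter in practice:

* the translation search is centred on the **intensity-centroid offset**
  between the two images, so the window stays valid when cumulative
  shifts exceed it and end-of-stack sections with differing tissue areas
  do not lock onto a wrong local optimum;
* a Nelder–Mead **polish** of (angle, dx, dy) on the full-warp NCC
  removes the integer-shift interpolation bias, which otherwise flattens
  the angle peak by over a degree.

Ties resolve deterministically to the smaller |angle|, then the smaller
|shift|. On noise-free sections, planted transforms up to ±15° / ±5 px
are recovered within 1° and 0.5 px. `stack_volume()` stacks the aligned
sections; 120 µm pixels at a 120 µm z step give an isotropic volume
(`nz = 15`), and anisotropic inputs warn.

## Segmentation by NMF

`nnmf()` implements Lee–Seung multiplicative updates for the Frobenius
objective with a deterministic NNDSVD initialisation, so a fit is
reproducible without any RNG. Rows of the signature matrix H are scaled
to unit L2 norm (scale absorbed into W). `segment_regions()` assigns each
pixel its argmax component, abstaining (label 0) when the winning share is
below a floor (default 0.5). Because NMF is identifiable only up to
permutation, `match_components()` finds the exact best pairing with
reference signatures by enumerating permutations (ranks here are ≤ 8).
`select_rank()` reports the error curve, replicate stability, and an
elbow choice; the pipeline default is k = 4 (three tissue regions plus
the solvent background).

## Co-localization and the band-depth statistic

`overlap_stats()` restricts everything to tissue pixels (background would
inflate every coefficient) and reports Dice, Manders M1/M2, and Pearson r
between an ion image and a reference mask. Thresholds come from the
isodata (iterative intermeans) method on a 256-bin histogram
(`threshold_mask()`), the "default" threshold of common image software;
it is invariant under positive affine rescaling of the image.

"A band in the midst of the stained region" is operationalized as
**normalized band depth**: within each connected component of the
reference mask, the Euclidean distance transform is rescaled so the
component boundary has depth 0 and its deepest pixel depth 1;
`band_depth()` reports the depth distribution of the ion-positive pixels.
A mid-depth band has median depth near 0.5, a rim near 0, a core near 1.

## Annotation

`theoretical_mz()` computes adduct m/z at nominal (integer) or
monoisotopic scale; `neutral_loss_mz()` subtracts a neutral formula from
a parent m/z. The printed mass arithmetic of the emulated study is
recovered exactly: [M+H]⁺ of palmitoylcarnitine (C23H45NO4) = 400, of
stearoylcarnitine (C25H49NO4) = 428, [M−H]⁻ of PI(38:4) (C47H83O13P) =
885, and loss of trimethylamine (C3H9N, 59) from m/z 428 gives 369.
`annotate_peaks()` matches observed peaks at monoisotopic scale within a
ppm window, gated on polarity; every match is reported as *tentative*
(mass-only evidence), and `fragment_parent_coloc()` adds spatial support
by correlating fragment and parent ion images over tissue.

## The batch pipeline

```{r pipeline, eval = FALSE}
cfg <- default_config()
cfg$seed <- 7L
man <- run_batch(cfg, out_dir = "run")
make_report("run")
```

`run_batch()` executes simulate → preprocess → register → factorise →
annotate → co-localise per polarity (polarities never merge), records
per-stage status and timing in `manifest.json` with MD5 checksums of every
artifact, and writes plain-text artifacts throughout (CSV, JSON, NRRD,
Markdown). A stage failure halts that polarity only. Identical
configurations yield bit-identical artifacts.

## Problem sizes and limitations

The default phantom is 50 × 50 × 15 voxels with ~10 channels per
polarity; a full two-polarity batch runs in about a minute on one CPU.
Known limitations, by design:

* registration is rigid (the emulated workflow treats sections as rigid);
  non-rigid tissue deformation is out of scope;
* adjacent-section fluorescence is treated as already in register with its
  MSI section, as in the emulated overlay workflow (an optional rigid
  pre-registration can be applied by the same machinery);
* annotation is exact-mass only and therefore always tentative; no
  isotope-pattern scoring;
* no significance testing of co-localization (Costes randomization is a
  non-goal).
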