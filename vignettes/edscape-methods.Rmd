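---
title: "Methods: decoding and quantifying spatial A-to-I editing with edscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding and quantifying spatial A-to-I editing with edscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edscape)
```

## The measurement model

In situ sequencing (ISS) of RNA editing interrogates each A-to-I editing
site with a *pair* of padlock probes that differ only in the base reading
the site (A = unedited, G = edited, since inosine base-pairs like
guanosine) and in a 4-nt barcode carried in the probe's linker. Rolling
circle amplification turns each ligated probe into a micron-sized spot
(RCP), and four rounds of sequencing-by-ligation read the barcode as four
fluorescence images (channels A, C, G, T) per cycle. Marker probes
(e.g. *Sst*, *Pcp4*, *Plp1*, *Gfap*) label cell classes; Adar probes report
the editing enzymes themselves.

The analysis chain implemented here is:

1. **Decoding** (`detect_spots()`, `extract_intensities()`, `call_bases()`,
   `match_and_filter()`): spots are found on the general stain after white
   top-hat enhancement and split by watershed; per cycle, each spot's
   called base is the channel with the highest intensity. The per-base
   quality is `max / sum` of the four channel intensities. This statistic
   is the package's normative definition of quality: it is the unique
   simple intensity ratio whose range is exactly 0.25 (all four channels
   equal — no information) to 1 (a single positive channel), the range the
   original CellProfiler/Matlab toolchain reports. The read quality is the
   *minimum* base quality over cycles, and a read passes QC iff its
   quality reaches the threshold and its barcode occurs in the codebook
   (exact matching, no mismatch rescue — the unexpected-read accounting
   below relies on exact matching).
2. **Threshold calibration** (`calibrate_threshold()`): the quality
   threshold is the smallest grid value (step 0.01, matching the
   two-decimal thresholds of 0.35–0.5 used in practice) at which
   codebook-matched reads make up at least 95% of all quality-passing
   reads.
3. **Segmentation** (`segment_nuclei()`, `expand_cells()`): nuclei by Otsu
   threshold, connected components and a distance-transform watershed;
   "shape descriptors" are operationalised as area bounds plus an optional
   solidity filter, which is reproducible where the original descriptor
   set is not documented. Cells are nuclei grown outward by 20 px
   (Euclidean), with contested pixels resolved by a nearest-nucleus
   geodesic watershed, so cells are disjoint and meet at perpendicular
   bisectors.
4. **Quantification** (`editing_level()`, `regional_counts()`,
   `marker_editing()`, `editing_ratio()`): the editing level of a site in
   a stratum is `edited / (edited + unedited)`; the editing ratio divides
   a stratum's level by the level of its complement (region vs rest of
   tissue, marker-positive vs marker-negative cells). Adar2 reads are
   split into active/inactive isoforms by the auto-editing level
   (`adar2_decompose()`; editing at the intronic −1 site creates the
   frameshifted inactive splice isoform), rounding half-up on the
   inactive count.
5. **Single-cell heterogeneity** (`observed_mixed()`, `expected_mixed()`,
   `compare_mixed()`): among cells with ≥ 2 reads of a transcript, the
   observed fraction of "mixed" cells (both variants present) is compared
   with the expectation under independent per-read editing at the pooled
   level *p*, conditioned on the observed per-cell read-count histogram:
   `E[mixed] = Σ f_n (1 − p^n − (1−p)^n) / Σ f_n`. Using the full
   histogram rather than a mean read count matters because the
   expectation is convex in *n*. Under-representation of mixed cells
   signals bimodal, cell-intrinsic editing.
6. **Group comparison** (`kruskal_wallis()`, `dunn_sidak()`): tie-corrected
   Kruskal-Wallis omnibus test with Dunn's pairwise rank z tests and Šidák
   family-wise correction `1 − (1 − p)^m` (Bonferroni behind a flag).

## Coverage filters

All of the study's coverage rules are implemented with inclusive (`≥`)
boundaries and NA propagation (never zero-imputation — low-coverage strata
are reported `NA` with a QC flag, mirroring how such strata are reported
in practice):

| filter | rule | default |
|---|---|---|
| whole tissue | mean over replicates of min(edited, unedited) at some stage | ≥ 500 reads |
| region | combined reads of a site per replicate | ≥ 100 reads |
| marker | replicate-mean cells with marker *and* site transcript | ≥ 100 cells |
| class temporal | qualifying cells per replicate | ≥ 20 cells |

Replicate aggregation is the unweighted mean of per-replicate levels with
the sample SD (pooled-count aggregation is available behind
`pool_counts = TRUE`); the unweighted mean is the default because
reported stage-level values are replicate means with SDs.

## The synthetic scene generator

`simulate_scene()` emulates the statistical structure the analysis
assumes: non-overlapping nuclei in 2D; named disjoint ROI polygons; cell
classes drawn by proportion with class-exclusive marker expression;
per-cell read counts Poisson(`reads_per_cell_mean`); per-read editing
Bernoulli with a per-(site, region, class) probability table; reads
placed uniformly in the soma disk (nucleus + 20 px, minus a one-pixel
interior margin so that rounding a continuous position to a pixel cannot
push a read over the nominal border); intensities with signal on the true
channel, background on the others, a 4×4 crosstalk matrix, and clipped
Gaussian noise. A configurable fraction of reads carries a barcode absent
from the codebook with attenuated signal (`unmatched_signal_factor`,
default 0.3) — real unexpected reads are low-quality artifacts, and this
attenuation is what gives the 95% expected-read-fraction calibration a
quality gradient to work with.

Deliberate simplifications: no tissue autofluorescence, no tile stitching
artifacts, no z-dimension, Gaussian spots instead of a measured PSF, and
region membership decided by the nucleus center (unambiguous ground
truth). Consequently, passing recovery tests demonstrates correctness of
the *computation* under the stated generative model, not robustness to
optical artifacts absent from the model.

Default conditions mirror a typical section at reduced scale: 4-cycle,
4-channel codebooks; nucleus radius 8 px; 20 px expansion; signal 200,
background 20 (10:1); noise as stated per experiment. The test suite uses
scenes of 25–400 cells and up to ~30,000 reads, chosen so that every
stratum under test clears its own coverage filter with room to spare.

## Numerical choices

- **Argmax ties** in base calling break by the fixed channel order
  A < C < G < T; ties have measure zero once noise is present, and a fixed
  rule keeps decoding deterministic.
- **Registration** is exhaustive integer-translation search maximizing
  normalized cross-correlation on the overlap; sub-pixel models are out of
  scope and unnecessary for spot-level decoding with window-max
  extraction (radius 1 window tolerates 1 px residual error).
- **Intensity extraction** takes the window maximum, not the center pixel,
  for the same robustness reason; the window radius is a parameter.
- **Small-sample p-values**: with 2–5 replicates per group the chi-square
  and normal approximations are crude. `kw_exact_p()` enumerates the
  permutation distribution for N ≤ 10; at N = 8 the chi-square p deviates
  from the exact p by up to ~0.15 in the body of the distribution and by
  ~0.05 at the extreme arrangement. Results at these sample sizes carry
  the same caveat the underlying study design does.
- **Mixed-cell denominator**: "cells with at least two reads of the
  transcript" is the implemented rule; an alternative phrasing ("at least
  one read of each variant") circulates for the same analysis but would
  make the observed proportion 1 by construction, so it is documented
  here and not implemented. The editing level entering the expectation is
  pooled over *all* reads of the site in the stratum, including
  single-read cells.
- **Point-in-polygon** is boundary-inclusive so reads exactly on an ROI
  outline are assigned deterministically; overlapping ROIs are rejected
  at load because regional strata must partition reads.
- **Pixel coordinates are 1-based** (R convention) with x = column,
  y = row.

## Known limitations

- One codebook per run; panel versioning (re-barcoded follow-up panels) is
  not modeled.
- Registration is translation-only; rotation/scaling would require the
  upstream microscope stack.
- Tile-edge cell correction and atlas registration are out of scope; ROIs
  are user-supplied polygons.
- The synthetic generator's class-exclusive marker expression makes cell
  typing easier than in tissue, where segmentation errors mix neighboring
  cells' reads; the configurable positivity threshold
  (`classify_cells(min_count = )`) exists for exactly that reason.

## Worked example

```{r example, eval = FALSE}
cfg <- demo_run_config(n_replicates = 2, seed = 1, out_dir = "demo_run")
run <- run_pipeline(cfg)
run                       # 22 sites, 15 retained by the 500-read filter
head(run$aggregated)      # per-(site, region) mean level and SD
head(run$ratios)          # regional editing ratios vs rest of tissue
head(run$mixed)           # observed vs expected mixed cells
```

The demo scene encodes a thalamus/hypothalamus contrast (editing
probabilities 0.65 vs 0.40 at every site) and seven low-abundance sites
that fail the 500-read filter, so the printed run reports 15 of 22 sites
retained and recovers the contrast in `aggregated`.
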