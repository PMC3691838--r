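---
title: "Quantifying the corneal subbasal nerve plexus: methods and design"
author: "cornealSNP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the corneal subbasal nerve plexus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cornealSNP)
```

## The measurement model

In vivo confocal microscopy images the subbasal nerve plexus (SNP) as
bright, gently tortuous, branching fibres of roughly 1–4 px apparent
width on a noisy dark background. The reference acquisition is a
384 × 384 px frame covering 400 × 400 µm (pixel size 400/384 ≈ 1.0417 µm),
optionally as a 30-slice z-stack with 2 µm spacing through the plexus.
Quantification proceeds in two stages:

1. **Fibre segmentation.** The image is background-corrected with a
   morphological white top-hat (disc radius 8 px — about twice the widest
   fibre, so fibres pass and slow illumination structure is removed; an
   additive intensity offset is cancelled exactly). After a 1st/99th
   percentile contrast stretch, a multi-scale Hessian vesselness response
   is computed and thresholded with hysteresis (defaults 0.10/0.25);
   8-connected components smaller than 30 px are discarded.
2. **Medial-axis analysis.** The mask is thinned to a one-pixel skeleton
   with the Guo–Hall two-subiteration algorithm (topology preserving; a
   final pass deletes simple pixels from any residual 2 × 2 block).
   Skeleton pixels with one 8-neighbour are endpoints, pixels with three
   or more are branch candidates, and connected candidate clusters merge
   into one branch node at their centroid. Edges are the traced pixel
   chains between nodes; an isolated cycle receives one artificial
   degree-2 anchor node. Edge length is chain-code length: one pixel size
   per orthogonal step, √2 per diagonal step.

The nine reported parameters follow from mask and graph; nerve fibre
density is defined as total length over area, so NFD × area = length is
an identity of the output, not an empirical fact. Normalisation to 1 mm²
divides counts and total length by the image area; density and average
single-fibre length are intensive and unchanged. Average single-fibre
length is reported in absolute µm (not per-area). Reported lengths and
densities are rounded to 3 decimals, half away from zero; all percentage
trajectories round half away from zero to integers.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `scalesPx` | 1, 2, 3 | px | brackets the 1–4 px apparent fibre width |
| `hysteresisLow/High` | 0.10 / 0.25 | – | skirt vs. seed thresholds on the [0,1] response |
| `minComponentPx` | 30 | px | rejects noise specks and cell fragments |
| `tophatRadiusPx` | 8 | px | background structuring radius |
| `pruneUm` | 5 | µm | removes 1–3 px thinning spurs from endpoints |
| `borderBandPx` | 2 | px | band in which a degree-1 node counts as a border crossing |

Two segmentation choices deserve comment. The vesselness response uses
*linear* (γ = 1) scale normalisation with one structureness constant `c`
(half the maximal Frobenius norm over all scales): subbasal fibres sit at
the fine end of the scale range, and quadratic weighting together with
per-scale normalisation lets the broad, weak coarse-scale skirt pass the
low hysteresis threshold, inflating the mask by ~50 % relative to the
true stroke support; with γ = 1 the segmented component-pixel count
tracks the rendered stroke area within a few percent. Second-derivative
kernels are discretely zero-meaned so a constant image yields an exactly
zero response.

The border band is 2 px rather than the outermost row/column alone:
thinning necessarily retracts the blunt end of a stroke cut by the field
edge by about half the stroke width (~1 px at the 2 px default width), so
a stricter band systematically misses genuine border crossings. The
trade-off is that a true interior fibre end lying within 2 px of the
boundary would be misread as a crossing; in real SNP frames such ends are
rare, and the synthetic generator keeps interior ends ≥ 6 px from the
border so the ambiguity never enters the validation.

Two graph clean-ups absorb junction-scale thinning artifacts: branch
clusters joined by a chain of ≤ 3 px are contracted into one node (a
single anatomical junction is otherwise reported as two), small (≤ 6 px)
self-loops on a branch node — holes where three strokes meet — are
absorbed, and a branch node left with exactly two incident edges (e.g.
after its spur was consumed) is spliced out of the path. Spur pruning
itself removes endpoint edges shorter than 5 µm and re-derives the graph
once; it is disabled wherever the generative oracle expects raw topology.

## The synthetic generator as oracle

`generateScene()` grows fibre *trees* that enter at the field border
(heading within ±20° of the inward normal), propagate as correlated
random walks (heading change SD 0.03 rad per 1 µm step — a curvature
radius of tens of µm, matching the "regular tortuosity" of healthy SNP),
and branch with probability 0.01 per step at ±40°. Defaults (5 trees,
400 µm extent, 2 px stroke width, intensities 0.6–1.0) emulate a healthy
cornea: total length ≈ 2.4–2.6 mm per frame, NFD ≈ 15–16 mm/mm², in the
range of pre-irradiation group means. Rendering draws each fibre as a
Gaussian-profile stroke (FWHM = width), then applies 0.8 px blur,
multiplicative speckle (SD 0.2), a 0.15 background offset and additive
noise (SD 0.05). Everything is driven by one explicit seed; the caller's
RNG state is untouched.

Because every polyline and every topological event is stored, the scene
is its own oracle: counts come from the generative graph, lengths from
the polylines, and the two pixel counts from rasterising the noiseless
mask and centerline. For the oracle to be *exact*, the generated geometry
must be resolvable at the raster scale, so the generator enforces, by
construction: ≥ 6 µm separation between distinct structures, ≥ 12 µm
along a fibre between branch events, no branching within 15 µm of the
border, near-perpendicular border exits (≤ 50° from the normal), and
interior fibre tips ≥ 5 µm clear of every other stroke (tips closer than
that fuse with the neighbouring fibre at mask level; chains are trimmed
back or dropped, with through-nodes spliced, to keep the recorded truth
consistent). These constraints are what the validation suite relies on:
on noiseless scenes with mask pass-through and pruning off, component,
branch, single-fibre and border-crossing counts match the generative
truth exactly, and chain-code total length stays within 5 % (the √2
weighting overestimates straight runs at oblique angles by up to ~8 %,
but corner cutting at curves and end retraction cancel most of it; across
seeds the net error is ~1–4.5 %).

What passing these tests shows — and what it does not. They demonstrate
that segmentation, thinning, graph extraction and metric computation are
internally correct and unbiased under the generative model. Real IVCM
frames additionally contain keratocyte and epithelial textures, dendritic
cells, illumination falloff, motion streaks and genuinely sub-resolution
fibres (< 1 µm), none of which the generator emulates; absolute agreement
with any particular clinical software on real images is therefore not
implied. The noisy-render recovery test (density within ±15 % of truth on
≥ 90 % of scenes; observed median error ≈ 2 %) covers the modelled noise
only.

## Longitudinal and dosimetry conventions

Percent-of-baseline trajectories are computed from group means —
`100 × value(t) / value(baseline)`, rounded half away from zero — not as
means of per-subject percentages; this is the convention that reproduces
the published integer trajectories from the published group tables.
Replicate scans (at least three per zone and visit) aggregate as
arithmetic mean with sample SD (n−1; zero for a single scan), the choice
that reproduces the published cohort dispersion (522 ± 233 Gy from the
prescribed-dose column, median 520 Gy). Cochet–Bonnet sensation is
recorded as filament length (multiples of 5 in 0–60 mm; 50–60 mm is
classified normal) and expressed as percent of baseline with the same
rounding. One documented inconsistency is preserved rather than hidden:
56/58 rounds to 97 %, while the narrative value for the applicator zone
at 7 months is 96 %; the helper returns 97.

Corneal surface doses per zone are fixed fractions of the prescribed
tumour-base dose — 0.44 % adjacent to the plaque, 0.12 % central,
0.015 % distal — rounded to 2 decimals half away from zero. The fractions
are constants of the published Ru-106 plaque isodose geometry; plaque
physics is out of scope. Two printed per-patient cells (2.31 and 4.7 Gy)
differ from the recomputed values (2.32, 4.71) by 0.01; the tests assert
them with a ±0.02 tolerance instead of silently adopting either value.

## Numerical choices and degenerate inputs

* Rounding is always half away from zero, with a 1e-9 guard absorbing
  binary representation error in exact halves.
* 8-connectivity everywhere (masks, skeletons, component labelling);
  labelling is implemented on an explicit pixel graph.
* A constant image passes through contrast normalisation unchanged
  (flagged in metadata) and produces an all-zero ridge response, an empty
  mask and all-zero metrics.
* Empty masks, empty scenes and zero-tree generators are valid and yield
  zeros; a single isolated skeleton pixel is an endpoint node with no
  edges.
* Slice selection from a z-stack defaults to the slice with the highest
  mean ridge response (ties to the lowest index); an explicit index can
  always be given.
* Tests and the acceptance script use 384 px frames for full-pipeline
  checks and 50 noiseless + 20 noisy scenes for the oracle suite — sizes
  at which the whole validation completes in a few minutes on one core
  while keeping count statistics stable.

## Known limitations

* Chain-code length carries a small positive bias on oblique straight
  runs; sub-pixel centerline refinement (which would remove it) is out of
  scope, as are fibre width and tortuosity indices.
* Segmentation parameters were chosen for the reference geometry; frames
  with very different pixel sizes need rescaled `scalesPx`,
  `minComponentPx` and `pruneUm`.
* The generator's resolvability constraints mean the oracle suite does
  not probe sub-resolution junction spacing or grazing border exits;
  on real images such configurations will be resolved arbitrarily, as
  they are by any medial-axis method at this resolution.
* Vendor volume formats are not parsed; physical extent comes from the
  caller or a sidecar file.
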