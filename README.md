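# cornealSNP

Automated morphometry of the corneal subbasal nerve plexus (SNP) from in
vivo confocal microscopy (IVCM), with companion tools for longitudinal
percent-of-baseline analysis, corneal-zone brachytherapy dosimetry, and a
synthetic fibre-scene generator that carries its own ground truth.

## The problem

The SNP is the dense network of unmyelinated nerve fibres between the
corneal basal epithelium and Bowman's membrane (~55–70 µm depth). IVCM
images it non-invasively as hyperreflective, branching, curvilinear fibres
on a dark background — at the reference geometry, a 384 × 384 px frame
covering 400 × 400 µm (1.0417 µm/px). Quantifying how this network
degenerates and regrows (after episcleral Ru-106 plaque brachytherapy,
refractive surgery, in diabetic neuropathy, …) requires turning each frame
into reproducible morphometric numbers.

`cornealSNP` implements the two-stage analysis:

1. **Segmentation** — background top-hat, multi-scale Hessian
   ridge (vesselness) enhancement, hysteresis thresholding and
   small-object removal give the binary fibre mask (the *component
   pixels*).
2. **Topological analysis** — topology-preserving (Guo–Hall) thinning
   reduces the mask to its one-pixel medial axis; skeleton pixels are
   classified by 8-neighbour count into endpoints, branch points and
   border crossings, and the medial-axis network graph is extracted with
   chain-code edge lengths (orthogonal step = 1 px, diagonal = √2 px).

From mask + graph the nine standard parameters are computed, optionally
normalised to 1 mm²:

| parameter | definition |
|---|---|
| component pixels | pixels identified as nerve fibres |
| nerve fibre components | separate nerve fibre networks |
| skeleton pixels | medial-axis pixels |
| single nerve fibres (SNF) | nerve segments between branches and ends (graph edges) |
| total fibre length | Σ chain-code edge lengths, µm |
| average single fibre length | total length / SNF, µm |
| nerve fibre density (NFD) | total length per area, mm/mm² (≡ length/area, exact) |
| connectivity points | fibres entering or leaving the image area |
| branches | branch points of the medial axis |

## Worked example

Generate a healthy-cornea-like synthetic scene, render it with realistic
noise, and quantify it end to end:

```r
library(cornealSNP)

scene <- generateScene(seed = 1)          # ~5 fibre trees in 400 x 400 um
img   <- renderScene(scene)               # 384 x 384 confocal-like image
reportMetrics(quantifyImage(img))
#>   component_pixels nerve_fibre_components skeleton_pixels single_nerve_fibres
#> 1             7363                      5            2208                  35
#>   total_fibre_length_um average_single_fibre_length_um
#> 1              2611.684                          74.62
#>   nerve_fibre_density_mm_per_mm2 connectivity_points branches area_mm2
#> 1                         16.323                  15       15     0.16

reportMetrics(truthMetrics(scene))        # generative ground truth
#>   ... total_fibre_length_um 2557.091, nerve_fibre_density 15.982,
#>       single_nerve_fibres 35, connectivity_points 15, branches 15 ...
```

The pipeline recovers the true density within ~2 % and the true topology
(35 segments, 15 branches, 15 border crossings, 5 networks) exactly. A
field containing 1578 µm of fibre (a typical single frame) has
NFD = 1.578 mm / 0.16 mm² = `9.863` mm/mm²; 19 single fibres in that frame
scale to `118.75` per mm².

The longitudinal and dosimetry helpers work from published group-level
tables:

```r
percentOfBaseline(snpStudyMorphometry(),
                  "nerve_fibre_density_mm_per_mm2", "applicator")$percent
#> [1] 100   5  26  31  85     # collapse at 3 days, regrowth by 7 months
calculatedDoses(278)
#>   prescribed_gy adjacent_gy central_gy distal_gy
#> 1           278        1.22       0.33      0.04
sensationPercent(54, 58)      # Cochet-Bonnet, distal zone at 7 months
#> [1] 93
```

A thin command-line front end wraps the same functions
(`inst/scripts/snp-tool.R`, subcommands `quantify`, `longitudinal`,
`dose`, `simulate`, `selftest`).

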