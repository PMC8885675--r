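# oolite

Granulometric provenance analysis of oolitic limestone.

When an artifact is carved from oolite, the size distribution of its
ooids (sub-millimetre coated carbonate grains) — measurable from micro-CT
cross-sections — can be compared against distributions measured in thin
sections from candidate geological localities. `oolite` implements that
comparison as a tested pipeline for archaeometrists and sedimentary
petrographers:

* **Grain extraction**: grayscale cross-section → binarization (Otsu or
  fixed) → median-filter denoising → distance-transform watershed
  separation → per-object measurement (exact corner-convention Feret
  diameter, circularity 4πA/P², border flags) → shape-based ooid
  selection.
* **Distribution comparison**: natural-log transform; Gaussian KDE with
  the robust Silverman bandwidth h = 0.9·min(σ̂, IQR/1.34)·n^(−1/5); the
  Hellinger distance between per-site densities,

  H²(fᵢ, fⱼ) = 1 − ∫ √(fᵢ(x)·fⱼ(x)) dx,

  (0 = identical, 1 = disjoint; 1 − H² is the Bhattacharyya overlap);
  pairwise matrices, ranking of sites against a pooled reference sample,
  and micro-CT vs thin-section concordance.
* **Ordination**: principal coordinate analysis (Gower double-centering,
  positive eigenvalues only, deterministic sign convention) with a
  distance-correlation diagnostic of representation quality.
* **Inclusion analysis**: half-maximum-height thresholding of dense
  (e.g. limonite) inclusions in 3D volumes, 26-connected labeling,
  moment-tensor ellipsoid axes, and comparison of embedded-inclusion
  means with surface-cavity means.
* **Synthetic oolite**: seeded generators for grain-diameter mixtures,
  rendered cross-sections (hollow ooids, bioclasts, crossbedding layers,
  noise) and rendered volumes, each with ground truth — the basis of the
  package's end-to-end validation.

## Worked example

Five synthetic sites, two of which ("venus-head", "venus-leg") are
samplings of the reference material and one of which ("siteA") is a
planted provenance match generated from the same distribution:

```r
library(oolite)

specs <- list(
  SiteSpec("venus-head", 1, -1.49, 0.45, 400),
  SiteSpec("venus-leg",  1, -1.49, 0.45, 400),
  SiteSpec("siteA",      1, -1.49, 0.45, 400),
  SiteSpec("siteB",      1, -0.55, 0.35, 400),
  SiteSpec("siteC",      1, -2.45, 0.35, 400))
samples <- lapply(seq_along(specs), function(i)
  sampleDiameters(specs[[i]], seed = 100 + i))

summarizeSample(samples[[1]])
#>     mean_mm     sd_mm     min_mm  max_mm   n
#> 1 0.2416756 0.1061209 0.05394748 0.72183 400

(D <- pairwiseDistances(samples))
#> HellingerMatrix: 5 samples
#>            venus-head venus-leg siteA siteB siteC
#> venus-head      0.000     0.058 0.051 0.736 0.713
#> venus-leg       0.058     0.000 0.066 0.746 0.723
#> siteA           0.051     0.066 0.000 0.706 0.723
#> siteB           0.736     0.746 0.706 0.000 0.993
#> siteC           0.713     0.723 0.723 0.993 0.000

distanceToPooled(samples, c("venus-head", "venus-leg"))
#>    site          H
#> 1 siteA 0.05525373
#> 3 siteC 0.71853519
#> 2 siteB 0.74367762

ord <- runPCoA(D)
ord
#> OrdinationResult: 5 sites, 4 retained axes
#>   variance explained: 59.5%, 40.2%, 0.212%, 0.0922%
representationQuality(D, ord, k = 2)
#> [1] 0.9998119
```

The mean grain size of the reference sampling is ~0.24 mm; the two
reference samplings and the planted match sit at mutual Hellinger
distances of ~0.05–0.07 while unrelated sites sit at 0.7–1.0, so the
pooled ranking puts the planted site first by an order of magnitude, and
the first two principal coordinates carry essentially all of the
distance structure.

`runPipeline(config, outputDir, seed)` runs the whole chain (screening by
age/composition, extraction or simulation, comparison, ordination,
optional inclusion stage) and writes a deterministic report bundle
(CSVs, a PCoA plot, a JSON summary and a YAML run log). A thin
command-line dispatcher with `simulate` / `extract` / `compare` /
`ordinate` / `inclusions` / `report` subcommands is installed at
`inst/scripts/oolite-cli.R`.

## Further documentation

The methods vignette (`vignettes/oolite-methods.Rmd`) documents the
statistical model and its assumptions, all tunable parameters with units
and defaults, the numerical choices (quadrature, common-grid
renormalization, watershed tie-breaking, moment-based axis measurement),
what the synthetic generator does and does not emulate, and known
limitations.
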