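# hfmap — homology-feature maps for fibrotic lung CT

`hfmap` quantifies fibrotic lesions (reticulation, honeycombing) on lung
CT slices through the topology of the attenuation field rather than its
intensity statistics. It is aimed at quantitative-imaging researchers who
want a transparent, fully parameterized texture feature with an exact
mathematical definition, plus the machinery to evaluate it end to end.

## The method

For a tile of Hounsfield units, sweep a binarization threshold *t* over
the fibrosis-relevant window (−700 … −400 HU, step 1 HU), taking pixels
with HU ≥ *t* as foreground, and record the Betti numbers of every binary
image:

* **b₀** — number of connected foreground components (8-adjacency),
* **b₁** — number of holes: background components (4-adjacency) not
  reaching the image border.

The sequence (t, b₀(t), b₁(t)) is the tile's **homology profile (HP)**.
Fibrotic tissue, a mixture of dense septal walls and cystic airspaces,
fragments into many components somewhere inside the sweep, so max b₀ is
large; normal aerated lung contains little beyond vessels.

A 32 × 32 tile slides across the slice with stride 8. Each kept tile
(tiles > 95 % outside the lung mask are skipped) contributes its
standardized profile maximum — divided by the pixel area in mm² — to every
pixel it covers; overlapping contributions are summed. The result is the
**homology-feature (HF) map**, and its maximum is the slice feature.
Slices are then classified fibrosis vs non-fibrosis by thresholding the
feature with a cut-off tuned by ROC analysis and the Youden index
(J = sensitivity + specificity − 1) on patient-wise tuning/testing splits,
repeated 5 times.

A synthetic chest phantom (lung ellipses, vessels, subpleural honeycomb
fibrosis with per-wall-segment random attenuation, solid nodules) makes
every stage runnable and testable without clinical data.

## Worked example

```r
library(hfmap)

## one fibrotic phantom slice, full pipeline
ph   <- generatePhantom(phantomSpec(lesion = "fibrosis", seed = 1))
mask <- extractLungMask(ph$slice)
hf   <- computeHFMap(ph$slice, mask, mapParams())
sliceFeature(hf)
#> [1] 528.5714

## the same seed without a lesion
phN <- generatePhantom(phantomSpec(lesion = "none", seed = 1))
sliceFeature(computeHFMap(phN$slice, extractLungMask(phN$slice), mapParams()))
#> [1] 83.67347
```

The fibrotic slice's feature (max of the b₀ HF map, in components per
mm², summed over up to 16 overlapping tiles) is ~6× the normal slice's —
the honeycomb walls fragment into many components inside the threshold
sweep, while the normal lung only contributes its vessels.

The full classification experiment on a 20-patient phantom cohort:

```r
co    <- generateCohort(cohortSpec(baseSeed = 0))      # 10 + 10 patients x 2 slices
feats <- cohortFeatures(co)                            # segment -> HF map -> feature
repeatedExperiment(feats, experimentParams(seed = 0))
#> Repeated slice-wise experiment (positive = fibrosis, 5 repeats)
#>      quantity  mean    sd
#> 1      cutoff 319.2 9.501
#> 2 aurocTuning   1.0 0.000
#> 3    accuracy   1.0 0.000
#> 4 sensitivity   1.0 0.000
#> 5 specificity   1.0 0.000
#> 6   precision   1.0 0.000
```

Every repeat separates the classes perfectly (AUROC 1, all test metrics
1); the tuned cut-off varies slightly across repeats because its midpoint
depends on which patients land in the tuning split — see the methods
vignette (`vignettes/homology-feature-maps.Rmd`) for why that SD is not 0
even under perfect separation.

A command-line front end wrapping the same functions ships in
`inst/scripts/hfmap.R` (subcommands `segment`, `run`, `classify`,
`experiment`, `phantom`, `sweep`).

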