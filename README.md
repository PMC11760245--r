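# cellanchor

Cell-anchored registration of multimodal histopathology images — align
H&E and multiplexed immunofluorescence (MxIF) at single-cell level using
nothing but cell segmentation outputs.

## The problem

Joint H&E + MxIF analysis needs to know which cell is which across the two
images of a tissue core. Pixel-based registration of gigapixel pathology
scans is slow and brittle; but cell segmentation tables (centroids plus
per-cell morphology, e.g. QuPath measurement exports) already exist in any
single-cell workflow. `cellanchor` treats registration as point-set
alignment over those centroids:

1. **Unit normalization** — centroids are converted to micrometers with the
   per-modality pixel size, removing the scale degree of freedom, so the
   similarity transform

   ```
   M = | S·cosθ  −S·sinθ  dx |
       | S·sinθ   S·cosθ  dy |
       |   0        0      1 |
   ```

   runs rigid with S = 1.
2. **Coherent Point Drift (rigid)** — the moving centroids parameterize a
   Gaussian mixture, the fixed centroids are data plus a uniform outlier
   term; EM yields a coarse transform (rotation via determinant-corrected
   SVD, so never a reflection), with coarse 4-orientation restarts.
3. **Graph-matching refinement** — subgraphs are sampled from cell-dense
   regions (Gaussian KDE, density ≥ 0.5), a 50 µm source window against a
   150 µm CPD-mapped target window, edges between cells closer than 15 µm.
   Node affinities come from morphology (perimeter, solidity), edge
   affinities from length differences; Reweighted Random Walk Matching
   (RRWM) on the sparse association matrix produces a soft assignment,
   hardened by a Hungarian solver, filtered by Locality Preserving Matching
   (LPM). The surviving pairs give the refined transform (robust rigid
   Procrustes), which is accepted only if it does not increase a model-free
   alignment cost versus CPD.
4. **Evaluation** — against annotated landmark pairs: mean mapped-landmark
   distance ΔD (µm), translation difference ΔT (µm), rotation difference
   Δθ (degrees).
5. **Concordance** — after alignment: nearest-cell pairing with
   N=0 / N=1 / N>1 triage, Pearson correlation of paired features, regional
   density grids and tumor-composition similarity maps.

A synthetic TMA-core generator (`generate_core_pair()`) with known ground
truth — density hotspots, centroid jitter, dropout, over-/under-segmentation
— makes the whole pipeline testable offline.

## Worked example

```r
library(cellanchor)

pair   <- generate_core_pair(synthetic_profile("degraded", n_cells = 1000, seed = 42))
report <- align(pair$source, pair$target, landmarks = pair$landmarks, seed = 42)
print(report)
#> <alignment_report>
#>   CPD transform:     <rigid_transform> theta = 0.0876118 rad (5.02 deg), scale = 1, t = (19.8845, -10.0672) um
#>   refined transform: <rigid_transform> theta = 0.0876118 rad (5.02 deg), scale = 1, t = (19.8845, -10.0672) um
#>   matches: 138 putative, 106 kept by LPM over 8 window(s)
#>   refined metrics:   <alignment_metrics> deltaD = 0.1831 um, deltaT = 0.07298 um, deltaTheta = 0.01979 deg
#>   warnings:
#>    - RRWM did not converge within the iteration cap; returning current iterate
#>    - refined transform rejected (alignment cost 1.716 > CPD 1.68); keeping CPD
```

The core was generated with a true transform of 5° rotation and a
(20, −10) µm shift, then degraded with 20% cell dropout per side, 1 µm
centroid jitter and 2% split/merge segmentation errors. The report shows
the recovered transform (5.02°, (19.88, −10.07) µm), the match bookkeeping
(138 putative cell pairs pooled over 8 windows, 106 surviving the locality
filter), and the landmark errors against ground truth: mean landmark
distance 0.18 µm, translation error 0.07 µm, rotation error 0.02°. The
last warning documents the no-regression gate: here the CPD estimate was
already marginally better than the graph-matching refit, so the pipeline
kept it.

Command-line equivalents (`exec/cellanchor`):

```sh
cellanchor simulate --out sim --seed 42 --profile degraded
cellanchor align --source sim/source_cells.tsv --target sim/target_cells.tsv \
                 --landmarks sim/landmarks.tsv --out results --seed 42
cellanchor evaluate --transform results/transform.json \
                    --landmarks sim/landmarks.tsv --out metrics.json
```

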