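---
title: "Cell-anchored registration of multimodal histopathology images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-anchored registration of multimodal histopathology images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellanchor)
```

## The problem

Multiplexed immunofluorescence (MxIF) and H&E staining view the same tissue
through different lenses: MxIF quantifies dozens of protein markers per cell,
H&E shows the morphology pathologists actually read. Joint cell-level
analysis requires knowing which cell is which across the two images — but
the images come from different scanners at different pixel sizes, the tissue
core sits at a different position and orientation on each slide, and direct
pixel-based registration is expensive and brittle for gigapixel pathology
data.

`cellanchor` sidesteps the pixels entirely. Cell segmentation is a
prerequisite of any downstream single-cell analysis, so per-cell centroid
tables already exist for both modalities. Registration then becomes a
point-set alignment problem over a few thousand centroids per
tissue-microarray (TMA) core rather than an image problem over hundreds of
millions of pixels.

## Transformation model

A TMA core is small (under a millimeter), so warping within a core is
negligible and alignment is modeled as a similarity transform

$$
M \;=\;
\begin{pmatrix}
S\cos\theta & -S\sin\theta & d_x\\
S\sin\theta & \phantom{-}S\cos\theta & d_y\\
0 & 0 & 1
\end{pmatrix}
$$

with rotation $\theta$, isotropic scale $S$ and translation $(d_x, d_y)$;
the translation magnitude is $T=\sqrt{d_x^2+d_y^2}$. Coordinates follow the
image convention of the segmentation exports (origin top-left, y downward);
$\theta$ is measured in that frame. Both centroid sets are converted to
micrometers on ingestion by multiplying with the per-modality pixel size
(e.g. 0.325 µm/px for a typical MxIF scan, 0.212 µm/px for H&E), after
which the inter-modality scale is 1 and every downstream stage runs rigid
(`fix_scale = TRUE`). Only the landmark-derived ground-truth fit leaves $S$
free, as a check that the data really are at scale 1. Non-rigid
deformation models are deliberately out of scope: at core scale they mostly
fit noise, and discontinuous control points can introduce regional
distortions worse than the rigidity error.

## Stage 1 — coarse alignment by rigid Coherent Point Drift

`cpd_align()` treats the moving (H&E) centroids as centers of an isotropic
Gaussian mixture and the fixed (MxIF) centroids as data drawn from it, plus
a uniform outlier component with weight $w$. EM alternates soft
correspondence (E-step) with closed-form updates of rotation (SVD of the
posterior-weighted cross-covariance, determinant-corrected so reflections
are impossible), translation, and the mixture variance $\sigma^2$
(M-step). The negative log-likelihood is non-increasing by construction —
the suite asserts this on every run — and iteration stops when its relative
change drops below the tolerance.

Key choices, all configurable through `cpd_config()`:

* **`w = 0.1`** — outlier weight. Cells washed off during restaining or
  segmented in only one modality act as outliers; 10% is a realistic rate
  for restained sections and the estimate is not sensitive to it.
* **`tolerance = 1e-6`, `max_iterations = 150`** — convergence control;
  typical cores converge in 20–60 iterations.
* **$\sigma^2$ initialization** — pooled mean squared distance between the
  two sets after centroid alignment, the cited method's convention.
* **Orientation restarts (`restarts = TRUE`)** — EM is local and cores may
  be placed at arbitrary rotations, so the four coarse orientations (0°,
  90°, 180°, 270°) are each probed for `probe_iterations = 10` EM steps and
  the best final objective is continued to convergence. The probe-then-
  continue scheme keeps the objective trace of the winning chain monotone.
* **`supercell_cap = 20000`** — inputs beyond this size are first reduced by
  `supercell_reduce()`, which replaces proximity clusters (single-linkage at
  `supercell_linkage = 20` µm, computed with a bucket grid and union-find so
  no full distance matrix is formed) by their centroid means. This is the
  scalability route toward whole-slide inputs. The reduce step is iterated
  to a fixpoint: a single pass is not idempotent, because two cluster means
  can land within the linkage distance even when no member pair was.

## Stage 2 — refinement by windowed graph matching

CPD aligns *densities*, not cells. To obtain explicit one-to-one cell
correspondences, small subgraphs are matched:

1. **Window sampling.** A Gaussian KDE (`kde_bandwidth = 25` µm, half the
   source window, so density is smooth at window scale) ranks source cells;
   cells with min-max-normalized density ≥ 0.5 are eligible window centers
   and `n_windows = 8` are drawn without replacement under the run seed.
   Dense regions carry the clearest architecture; sparse regions are most
   affected by segmentation noise. If nothing passes the cutoff the top
   density decile is used, with a warning.
2. **Subgraphs.** The source graph takes cells in a 50 µm square around the
   center; the target graph takes cells in a 150 µm square around the
   CPD-mapped center, the slack absorbing any residual CPD error at that
   location. "Window size" is interpreted as side length. Edges connect
   cells closer than 15 µm, storing the length.
3. **Affinities.** Node affinity is a Gaussian kernel (scale 1.0) on the
   difference of standardized morphology features (perimeter, solidity).
   Standardization pools both graphs' nodes: per-graph z-scores would let
   the same physical cell score differently in the two windows, which
   defeats the purpose of a cross-graph similarity. Edge affinity is a
   Gaussian kernel on edge-length differences (`edge_length_scale = 2` µm,
   roughly the length noise induced by ~1 µm centroid jitter on both
   endpoints). Both are assembled into the sparse Lawler association
   matrix $K$ over candidate assignments.
4. **Candidate gating.** A target node is an admissible candidate for a
   source node only within `candidate_radius = 8` µm of the source node's
   CPD-mapped position. This carries the positional prior already implicit
   in the 50→150 µm window construction down to node level. It matters:
   with length-only edge affinities, the association matrix rewards
   high-degree spurious candidates (every source-edge/target-edge
   combination contributes), and in our benchmarks the unconstrained solver
   returned assignments scoring well below the true one on its own
   objective. Eight micrometers — about one cell diameter — comfortably
   covers CPD residual plus centroid jitter while leaving a handful of
   genuine competitors for the structural terms to resolve. Set it to `Inf`
   to disable gating.
5. **RRWM.** Reweighted random walks on the association graph: power
   iteration with $K$, interleaved with an inflation step
   ($\beta = 30$), Sinkhorn row/column normalization (10 sweeps) pushing
   the distribution toward the matching polytope, and mixing with weight
   `rrwm_alpha = 0.2` on the affinity-driven walk (the reweighted jump
   carries the rest — the jump-dominant mixing of the reference
   implementations; the walk-dominant alternative scored consistently worse
   on the quadratic objective in our benchmarks). The walk starts from the
   masked node affinities rather than uniform, since the exponential
   reweighting otherwise locks onto association-graph degree noise in the
   first iteration. Convergence at `1e-6`, cap 300 iterations (hitting the
   cap returns the current iterate with a warning).
6. **Discretization.** The soft assignment is hardened with a Hungarian
   maximum-score assignment (implemented in the package — the potentials
   formulation with a vectorized relaxation loop; surplus nodes of the
   larger side stay unmatched; ties resolve deterministically by index
   order). On every random graph pair of up to six nodes the suite checks
   the result equals exhaustive best-permutation matching.
7. **Pooling and locality filtering.** Pairs are pooled across windows
   (deduplicated, keeping the best affinity; one-to-one is enforced per
   window only) and filtered by Locality Preserving Matching: for each
   putative pair, a cost counts how many of its `lpm_k = 8` nearest
   neighbors among the putative pairs fail to be shared between source and
   target space; two passes, permissive then strict
   (`lpm_lambda1 = 6`, `lpm_lambda2 = 4`), the second recomputing
   neighborhoods among first-pass survivors so clustered false matches
   cannot vouch for each other. Under any global similarity with no noise
   every pair is kept, exactly.
8. **Final fit.** The surviving pairs determine the refined transform by a
   rigid Procrustes fit. Locality filtering cannot remove *near-miss*
   matches — a neighboring cell a few micrometers from the true
   counterpart moves coherently with the neighborhood — so the fit trims
   residuals iteratively (3 robust sigmas, calibrated from the residual
   median under a Rayleigh model) before the final estimate.

### When the refinement is accepted

The pipeline returns the refined transform only if it does not increase a
model-free alignment cost — the trimmed (70%) mean nearest-neighbor
distance between mapped source cells and target cells — relative to the CPD
transform; otherwise it falls back to CPD, recording why. This generalizes
the obvious fallback on refinement *failure* to refinement *regression*: a
refinement stage should never make the output worse. The gate earns its
keep at the extremes. When CPD is already excellent (clean synthetic cores:
it uses every cell through soft correspondences and is statistically hard to
beat with a hard-pair subset fit), the gate keeps CPD; when cell content
disagrees between modalities and CPD's density alignment is biased, the
verified one-to-one pairs win. Both decisions are made from the data alone.

## Evaluation metrics

Given landmark pairs (manually annotated corresponding cells; two pairs
determine the similarity, eight per core is the recommended workload), the
ground-truth transform is fit with free scale, and an estimate is scored
by:

* $\Delta D$ — mean distance (µm) between each target landmark and the
  corresponding source landmark mapped through the *estimated* transform;
* $\Delta T = |T' - T|$ — translation magnitude difference (µm);
* $\Delta\theta = |\theta' - \theta|$ — rotation difference, reported in
  degrees and wrapped to $[0°, 180°]$ (treated as unsigned).

## The synthetic core generator

`generate_core_pair()` emulates exactly what the pipeline consumes — two
centroid-plus-morphology tables with a known transform between them — so
every stage is testable without any external data.

* **Geometry**: a disc of radius 400 µm (a TMA core ~850 µm across at H&E
  pixel size), default 1,000 cells, half uniform and half in five Gaussian
  hotspots (sd 40 µm) mimicking spatially varying density.
* **Morphology**: per-cell lognormal nuclear area (median 35 µm²),
  perimeter tied to area through a roughness factor, Beta(36, 4) solidity,
  lognormal stain intensity — drawn once per cell and shared by both sides
  before perturbation, so cross-modal feature concordance is high by
  construction.
* **Perturbations, independent per side**: centroid jitter; dropout (cells
  washed off or missed); over-segmentation (a cell splits into two children
  ±2 µm along a random axis); under-segmentation (a cell fuses with its
  nearest neighbor at their midpoint).
* **Profiles**: `clean` (no noise), `restained` (5% dropout, 0.5 µm jitter,
  1% splits/merges, 5% feature noise), `serial` (30% dropout, 2 µm jitter,
  decorrelated features — an adjacent section images *different* physical
  cells), `degraded` (20% dropout, 1 µm jitter, 2% splits/merges — the
  stress condition for transform recovery).
* **Landmarks**: eight mutually distant cells surviving intact on both
  sides, taken post-transform but pre-jitter, so they map exactly under the
  returned ground-truth transform.
* The `base_index` feature identifies the underlying base cell on both
  sides, letting tests audit match correctness directly.

What the generator does **not** emulate: systematic biases of particular
segmentation models (e.g. DAPI-sensitivity merging adjacent nuclei in
characteristic patterns), tissue folding or warping, staining color, or
spatially correlated feature noise. Passing tests therefore demonstrate
algorithmic correctness under controlled violations, not performance on any
particular real dataset.

## Numerical choices and degenerate inputs

* $\sigma^2$ is floored at $10^{-10}$; hitting the floor (exact data) ends
  EM with a warning and a converged flag.
* Transform parameter recovery from a matrix rejects reflections and
  anisotropic blocks; fits with all source points coincident raise a
  degenerate-configuration error.
* Ingestion drops rows with non-finite coordinates (warning with count);
  an empty table is an error, a single cell gets an all-ones density with
  a warning.
* Fewer putative pairs than `lpm_k + 1` leaves the locality filter
  undefined; everything is kept, with a warning.
* All sampling (window centers, node down-sampling) is seeded; identical
  seeds, inputs and configuration give byte-identical reports (timing
  fields excluded from serialization by default).
* Transform JSON is written with 17 significant digits so doubles
  round-trip bit-exactly.

## Problem sizes in the test suite

The suite exercises cores of 200–1,000 cells: transform recovery at 1,000
cells (clean and 20 degraded replicates), solver-versus-enumeration checks
on graphs of up to 6 nodes (50 pairs), locality filtering on 200-pair sets
(20 replicates), and concordance ordering on 400-cell cores (20 replicate
pairs). These sizes were chosen so the full suite characterizes every
claimed property while remaining comfortable to run routinely; the
algorithms themselves operate unchanged on full-size cores (a few thousand
cells), and the super-cell path covers larger inputs.

## Known limitations

* Rigid-only: genuine tissue warping within a core is not modeled; for
  whole slides the super-cell reduction gives scalability but not local
  deformation handling.
* Node affinities use two morphology features; modalities whose
  segmentations disagree systematically on perimeter/solidity will lean
  almost entirely on the structural (edge) terms and the positional prior.
* The candidate gate assumes CPD lands within ~8 µm of the truth. If CPD
  fails entirely (wrong orientation basin despite restarts), the refinement
  cannot rescue it; the no-regression gate then simply returns the CPD
  result, and the failure is visible in the landmark metrics.
* Cross-modal concordance statistics pair cells by proximity; in regions of
  heavy over/under-segmentation the N>1 and N=0 classes flag, but do not
  resolve, the ambiguity.
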