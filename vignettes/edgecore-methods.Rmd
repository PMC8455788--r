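---
title: "Edge-core instance segmentation of kidney cysts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-core instance segmentation of kidney cysts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Autosomal dominant polycystic kidney disease (ADPKD) fills both kidneys
with up to thousands of fluid-filled cysts. Total kidney volume (TKV) is
the established imaging biomarker, but two kidneys of equal TKV can carry
very different cyst loads, so per-cyst biomarkers — total cyst volume
(TCV, mL), cyst count, and the cystic index (percent of the kidney
occupied by cysts) — add phenotypic information. Measuring them requires
*instance* segmentation: every individual cyst gets its own label, even
when dozens of cysts are clustered and touching in a T2-weighted MR volume
with 3–9 mm slices.

Object-detection approaches (Mask R-CNN style) do not scale to thousands
of 3D instances. `edgecore` implements the alternative: a semantic
*edge-core* representation. Each instance map is converted to a 3-class
voxel map — background (0), a one-voxel *edge* shell (1), and the
instance interior *core* (2). A slice-wise convolutional network only ever
learns the 3-class problem; instances are recovered afterwards by a
class-agnostic geometric decoder, because the cores of distinct touching
cysts are separated by edge voxels.

## The two codecs

**Dilation variant (initial model).** Per cyst, core = the cyst itself,
edge = its one-voxel 6-connected outer dilation shell; cysts are painted
onto one canvas in ascending label order ("cyst-by-cyst"), each painting
edge then core. A later cyst's shell therefore overwrites earlier cores at
interfaces. Decoding is plain 6-connected component labeling of the core
class. On clustered cysts this round trip loses the interface voxels —
the codec-induced TCV bias that `codec_fidelity_study()` measures (about
−7% on the package's clustered phantoms) — and it was the motivation for
the erosion variant. `encode_dilation(..., overlap = "core")` provides the
lossless alternative in which a voxel that is core of any instance stays
core; it preserves volume but fuses touching instances at decode time.

**Erosion variant (final model).** The exam is first up-sampled to a
working grid (bicubic for intensities; per-label trilinear + 0.5 threshold
for masks), every instance is opened (erosion then dilation, 6-connected
cross), and then: core = 3D erosion of the instance, edge = the one-voxel
inner shell plus a 2D per-slice 4-connected outer shell (the 2D outer edge
counteracts the core/edge class imbalance that up-sampling produces).
Opening is what makes the codec exactly invertible: for an opened set
`O = dilate(erode(O))`, so the decoder's one-voxel dilation of the eroded
core reproduces each instance voxel for voxel, and cores of distinct
instances are provably never 6-adjacent. The encoder refuses un-opened
inputs rather than silently dropping an instance whose erosion is empty.

## The decoder

`decode_final()` composes five steps on the working grid:

1. **Distance transform.** Exact Euclidean distance to the nearest
   background voxel, computed separably. Distances are measured in units
   of the finest voxel dimension with per-axis weights
   `spacing / min(spacing)`: on an isotropic working grid this is plain
   voxel units, and on an anisotropic grid it keeps digitized spheres
   spherical in the watershed metric instead of flattening them into
   pancakes whose distance plateaus fragment.
2. **Seeded watershed.** Priority-flood (Meyer) watershed of the negated
   distance map restricted to the core mask, 6-connectivity. Seeds are the
   regional maxima of the distance map after h-maxima suppression of depth
   `h = 1`, detected on a lightly smoothed copy (two mean-filter passes
   over the 6-neighborhood); flooding uses the raw distances. The
   smoothing flattens one-voxel digitization bumps that would otherwise
   seed spurious basins, while genuine two-cyst necks — whose depth is a
   large fraction of the peak — keep distinct seeds. Voxels where two
   basins meet stay unlabeled (ridges).
3. **Recovery.** 6-connected components of the still-unlabeled core voxels
   (ridges, and small cores whose smoothed peak fell below `h`) are
   appended starting at one plus the last watershed label, so every core
   voxel carries exactly one label (a conservation property the tests
   assert).
4. **Instance dilation.** One 6-connected dilation round re-absorbs the
   inner edge. A voxel adjacent to several instances goes to the neighbor
   with the larger core distance value; exact ties go to the first
   competing neighbor in a fixed spatial scan order, a label-independent
   rule chosen so that dilation commutes with relabeling. The dilation is
   deliberately not constrained to the edge class, since exact inversion
   requires claiming the inner shell wherever it lies.
5. **Down-sampling and size filter.** Nearest-neighbor sampling at block
   centers back to the original grid, then removal of instances below 4
   voxels — the noise floor used when the reference standard was traced —
   with survivors relabeled `1..K` in ascending old-label order.

`decode_initial()` is the initial model's decoder: 6-connected components
of the core class, nothing else.

## Resampling

The working grid multiplies slices by 3 and brings the in-plane matrix to
a common size (512 in the clinical configuration; twice the phantom's
in-plane size at desk scale). Sampling is cell-centered
(`out = (j + 0.5)/scale − 0.5`), so physical extent is preserved exactly
when spacing is rescaled. Intensities use Keys cubic convolution
(`a = −0.5`); label maps are interpolated per label as binary masks
(trilinear, threshold 0.5, larger value wins conflicts, ties to the
smaller label) because interpolating label integers directly would create
spurious intermediate labels. Down-sampling is nearest-neighbor, which
avoids re-thresholding ambiguity and preserves small instances. Labels
can vanish under resampling but never appear.

## The synthetic phantom

`generate_phantom()` builds desk-scale exams with the geometry that makes
decoding hard: two ellipsoidal kidneys; digitized spherical cysts (a voxel
belongs to a cyst iff its center lies inside the sphere in mm
coordinates, so thick slices produce flattened voxel spheres and
single-slice cysts, the pathology the z-up-sampling addresses); clustered
placements at near-kissing distance so instances are 6-adjacent; mixed
hyperintense and hypointense ("complicated") cyst intensities; a bright
renal-pelvis-like confounder that is not a cyst; additive Gaussian noise.

Defaults, chosen once as the study conditions: 96×96×24 voxels at
1.5×1.5×4.5 mm (in-plane spacing near the clinical median and the typical
3:1 slice anisotropy), 30 cysts with log-normal radii (median 4.5 mm,
`sdlog` 0.35, clamped to [3, 12] mm so every cyst has at least a 2-voxel
in-plane radius), cluster fraction 0.5, hypointense fraction 0.15, noise
SD 0.04 against tissue contrasts of 0.05–0.9.

Two placement rules keep the geometry physical. Overlapping placements are
truncated, never merged — the earlier label keeps every contested voxel
and the later placement keeps the largest 6-connected remainder — because
abutting cysts are distinct objects. And any placement that would lose
more than 10% of its sphere to earlier cysts is rejected and retried:
pressurized cysts meet across shallow contact lenses, whereas deep
interpenetration would carve hourglass or crescent remnants that no real
cyst resembles (and whose eroded cores are genuinely ambiguous to any
geometric decoder).

The phantom deliberately does not model MR physics — no bias fields,
Rician noise, or partial-volume spectra — and only spherical cysts are
generated. Tests passing on phantoms therefore validate the geometric
pipeline (codecs, watershed, resampling, counting), not the trained
network's robustness to real MR appearance.

## The predictor contract and the network

The pipeline depends only on a contract: a slice predictor maps a
4-channel stack `[slice z−1, slice z, slice z+1, kidney mask at z]` (the
neighbor slices zero-padded at the volume ends) to per-voxel class
probabilities summing to 1. Intensities are normalized per volume to
[0, 1] by the 1st–99th percentiles inside the kidney mask, which makes
the stack invariant to field-strength-dependent intensity ranges.

`build_inception_unet()` provides a real implementation in base R:
encoder stages of inception blocks (parallel 1×1/3×3/5×5 convolutions,
ReLU, concatenation) with stride-2 convolutions and dropout, a mirrored
decoder with nearest-neighbor up-convolutions and skip concatenations,
and a final 1×1 convolution with softmax. Convolutions are im2col matrix
products; the backward pass is hand-written (the `dX` of a same-padded
convolution is itself a convolution of the zero-upsampled output gradient
with the flipped, channel-transposed kernel) and is verified against
central finite differences in the test suite. Training minimizes
`1 − J`, the soft Jaccard `J = (Σpr + ε)/(Σp + Σr − Σpr + ε)` with
`ε = 1`, averaged over the edge and core classes, using Adam with the
published defaults (200 epochs, batch 6, learning rate 1e-3); weights are
He-initialized and every stochastic choice (init, shuffling, dropout) is
governed by explicit seeds, so training is bit-reproducible. Exact filter
counts and depth are configurable; the defaults (depth 2, 4 filters per
branch) are sized for desk-scale training, where a single-exam overfit run
shows the loss falling within a dozen epochs.

Exam-level prediction applies each ensemble member slice by slice and
majority-votes the classes voxel-wise; a three-way split falls back to
the largest summed probability, remaining exact ties to core > edge >
background precedence (cores carry the instances, so they must survive).
Voxels outside the kidney mask are forced to background. Member selection
after cross-validation keeps the three candidates with the best mean
edge/core Jaccard on validation exams. An `oracle_predictor()` that
replays a known semantic map makes the whole pipeline testable without
trained weights; full-scale clinical training is out of scope here.

## Quantification and agreement statistics

Similarity between segmentations is computed on binarized masks: Dice,
Jaccard, precision, recall, and ARVC `= |V_pred − V_ref| / V_ref` (the
*reference* volume in the denominator; this convention reproduces the
published reader-vs-model means from the per-exam volumes). Empty-vs-empty
pairs score 1 on the overlap metrics and 0 on ARVC so phantom edge cases
stay defined. TCV is the labeled voxel count times the voxel volume;
the cystic index is `100 × TCV / TKV`.

Bland–Altman agreement uses percent differences relative to the pair mean,
`d = 100(a − b) / ((a + b)/2)`, with bias = mean and precision = the
sample (n−1) standard deviation — the only convention that reproduces all
three published TCV triples from the bundled five-exam reader table, which
ships as `inst/extdata/reader_study.csv` and is exposed by
`reader_study()`. Regression agreement reports the OLS slope, intercept
and `R²` (squared Pearson correlation, hence symmetric and sign-blind).
One known discrepancy, reproduced rather than hidden: the reader-1-vs-model
count `R²` recomputes to 0.83 from the printed per-exam counts, not the
published 0.82.

## Numerical choices and degenerate inputs

* Class codes are fixed at {0, 1, 2} = {background, edge, core} in files
  and channels; semantic maps are stored as 8-bit NIfTI, instance maps
  with an integer width chosen from the largest label.
* The watershed suppression depth `h = 1` (finest-voxel units) and the
  two smoothing passes were fixed from the geometry of the two regimes —
  digitization bumps are ~1 voxel on broad plateaus, genuine necks are a
  large fraction of the peak — not tuned per dataset.
* Ties are deterministic everywhere: the smaller label wins
  label-interpolation ties, a fixed neighbor scan order wins dilation
  ties, FIFO ordering breaks equal watershed priorities, and class
  precedence core > edge > background breaks exact vote ties.
* Empty inputs (no cysts, empty masks, all-background semantic maps) pass
  through every stage and are covered by tests; an empty kidney mask with
  non-empty cysts makes the cystic index an error rather than an Inf.
* Physical units: spacing is mm, volumes mL (1000 mm³), biases and
  precisions percent.

## Desk-scale problem sizes

The bundled studies run on one CPU: the codec fidelity study uses 20
phantoms of 96×96×24 voxels (working grid 192×192×72, roughly 30 cysts
each); the training smoke test overfits one 64×64×12 exam for a dozen
epochs; the reader-study statistics are closed-form on five exams. These
sizes exercise every code path of the full-scale configuration (512
in-plane, 3Z slices, 60 exams) without its runtime.

## Known limitations

* The erosion codec guarantees exact inversion only for opened instances;
  cysts whose opening is empty (single-voxel specks) are legitimately
  dropped when building the reference standard.
* A cyst whose eroded core genuinely disconnects (extreme thinness or
  concavity) will decode as two instances; the phantom's contact-lens
  placement rule keeps such shapes out of the study conditions, and on
  clinical data the up-sampling step plays the same role.
* The dilation-variant loss figures depend on how much the cysts touch;
  they are a qualitative contrast (strictly negative bias vs volume
  neutrality), not a calibrated clinical estimate.
* The slice predictor is trained here only at reduced scale; nothing in
  the package reproduces the published trained weights or their clinical
  accuracy tables.
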