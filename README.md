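# edgecore

Fully automated 3D instance segmentation of kidney cysts in T2-weighted MR
volumes of polycystic (ADPKD) kidneys, built around an *edge-core* semantic
representation.

Counting and measuring individual cysts — total cyst volume (TCV, mL), cyst
count, and the cystic index (100 × TCV / TKV) — requires giving every cyst
its own label even when dozens of them touch. Object detection does not
scale to thousands of 3D instances, so `edgecore` takes the semantic route:
an instance map is encoded as three voxel classes,

    0 = background,  1 = edge (one-voxel instance shell),  2 = core,

a slice-wise predictor only ever learns this 3-class problem, and instances
are recovered geometrically. The invertible encoder (the "erosion" variant)
opens each instance, takes core = 3D erosion and edge = inner shell + 2D
per-slice outer shell; the decoder runs a seeded watershed on the Euclidean
distance transform of the core class, recovers ridge voxels by connected
components, dilates each instance by one voxel (exactly undoing the
erosion: for an opened set O, dilate(erode(O)) = O), down-samples to the
original grid and drops instances under 4 voxels. A simpler "dilation"
variant codec (core = cyst, edge = outer dilation shell, cyst-by-cyst) is
included for contrast: it loses interface voxels on clustered cysts, which
is what motivated the erosion design.

The package also provides NIfTI I/O, the exam up/down-sampling (bicubic
intensities, per-label trilinear masks, 512-in-plane / 3Z working grid in
the clinical configuration), a from-scratch slice-wise inception U-Net with
soft-Jaccard (1 − J, ε = 1) Adam training and majority-voting ensembles, a
seeded cystic-kidney phantom generator, voxel-wise similarity metrics, and
Bland–Altman / regression reader-agreement statistics.

## Worked example

```r
library(edgecore)

## reader agreement on the bundled five-exam study
tab <- reader_study()
agreement_report(tab$tcv_reader1, tab$tcv_reader2)
#> bias -9.0% +/- 7.2% | R^2 = 1.00 (slope 1.000, intercept 24.384)
agreement_report(tab$tcv_reader2, tab$tcv_model)
#> bias 9.5% +/- 30.8% | R^2 = 0.98 (slope 0.921, intercept -30.878)
```

The first line says reader 1 measured ~9% smaller TCVs than reader 2 with a
7% spread (percent differences relative to the pair mean, n−1 SD); the
second compares reader 2 with the automated model the same way.

```r
## a synthetic exam and the full codec round trip
ph <- generate_phantom(phantom_spec(seed = 7))
cyst_stats(ph$truth, ph$kidney)
#> TCV 22.95 mL | 30 cysts | cystic index 5.6%

shape <- dim(ph$truth$data)
up     <- upsample_exam(ph$volume, ph$truth, inplane_target = shape[1] * 2L, z_factor = 3L)
opened <- open_instances(up$labels)
dec    <- decode_final(encode_erosion(opened), shape)
ref    <- filter_small(downsample_labels(opened, shape), 4L)
similarity(dec, ref)
#> Dice 1.000 | Jaccard 1.000 | precision 1.000 | recall 1.000 | ARVC 0.000
cyst_stats(dec)
#> TCV 21.35 mL | 30 cysts | cystic index NA
```

Encoding the opened reference to edge-core and decoding it back reproduces
it exactly — every cyst, every voxel (the decoded TCV of 21.35 mL differs
from the raw truth's 22.95 mL only by the opening that defines the
reference standard). `codec_fidelity_study()` repeats this over batches of
seeded phantoms and contrasts it with the lossy dilation-variant round
trip.

A command-line wrapper ships in `inst/cli/edgecore` with subcommands
`phantom`, `encode`, `decode`, `segment` (including a `--mock-oracle` mode
that runs the whole pipeline without trained weights), `train`, and
`evaluate`.

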