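# slicenet

Microscopy-image recognition of induced pluripotent stem cells (iPSCs) and
their derived lineages — mesenchymal stem cells (MSC), retinal ganglion
cells (RGC) and retinal pigment epithelium (RPE) — with a **multi-slice
tensor CNN**, a **hybrid PCA + SVM head**, and an ordinal
**differentiation-degree score** for iPSC-RPE images. The intended users
are stem-cell labs that grade differentiation by eye today and want a
reproducible, auditable scoring pipeline, and computational people who
want every stage testable without proprietary image data.

## The model

One image, five views. The input tensor `x` (512 × 512 × 3) enters a
"macro" branch through a 2 × 2 average pool, and its four quadrants
(256 × 256 × 3, fixed order TL/TR/BL/BR) enter four "micro" branches.
Every branch applies

```
[conv 3×3×32 → maxpool 2×2 → conv 3×3×64 → maxpool 2×2 → conv 3×3×128 → maxpool 2×2]
```

with same-padding and ReLU, yielding five 32 × 32 × 128 maps. These are
concatenated on channels (32 × 32 × 640), merged by a 3 × 3 × 128
convolution, dropped out at 0.5, average-pooled to 16 × 16 × 128 and
flattened to a 32,768-dimensional feature vector; a 128-unit dense layer
and a 4-way softmax close the network. Training: Adam (lr 1e-3),
categorical cross-entropy, batch 8, inputs scaled to [−1, 1], seeded
end-to-end. The net, backprop and optimizer are implemented in base R over
BLAS; backprop is verified against finite differences in the tests.

After training, `calibrate()` truncates the network at the flatten layer;
the hybrid head then applies per-feature max-abs scaling to [−1, 1]
(fitted on training features only), PCA to k = 512, and a one-vs-one SVM
(RBF, C = 1 by default; LDA projector available for ablation). For RPE
grading, the package finds the PCA axis that separates the RPE and iPSC
clusters at 0 (largest standardized mean difference among the leading
axes) and uses the oriented coordinate along it as the differentiation
score: further from the iPSC cluster = more differentiated.

A synthetic phenotype generator (sharp-bordered colonies, fibroblast
streaks, branching neurites, pigment patches with controlled areal
fraction) makes the whole pipeline testable; pigment coverage is defined
by a luminance threshold (< 90/255) so it is exactly countable.

## Worked example

A complete run at the package's scaled-down study conditions (canvas 64,
32 images/class, 10 epochs — about five minutes on one CPU):

```r
library(slicenet)
res <- run_pipeline(list(
  counts = c(IPSC = 32, MSC = 32, RGC = 32, RPE = 32),
  canvas_side = 64, train_frac = 0.75, epochs = 10, seed = 0,
  out_dir = "slicenet_demo"))
print(res$report)
print(res$axis)
head(res$scores, 3)
```

```
Overall accuracy: 96.9%  (n = 32)
Confusion matrix (rows = true, cols = recognized):
      recognized
true   IPSC MSC RGC RPE
  IPSC   10   0   0   0
  MSC     0   7   0   0
  RGC     0   0   7   0
  RPE     0   0   1   7
     recall precision f_score
IPSC  100.0     100.0   100.0
MSC   100.0     100.0   100.0
RGC   100.0      87.5    93.3
RPE    87.5     100.0    93.3
<separating_axis> dim 0 (0-based), orientation +1, SMD 3.22, sided 98.7% (IPSC vs RPE)
  sample_id coordinate rank
1  RPE_0105   8.862048    1
2  RPE_0109   8.670837    2
3  RPE_0120   6.133027    3
```

Reading the output: 31 of 32 held-out synthetic images are recognized (one
weakly pigmented RPE is taken for an RGC image); the iPSC and RPE clusters
separate on PCA dimension 0, with 98.7% of training samples on the correct
side of zero; and the scored test RPEs are ranked by their oriented
coordinate — larger means more differentiated. The ranked manifest and all
per-stage artifacts land in `out_dir`. On real microscopy data the
published setting is canvas 512, 19 epochs and k = 512, i.e.
`run_pipeline(list(counts = ..., epochs = 19))` with the defaults.

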