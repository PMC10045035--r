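---
title: "Filtering long-read SV callsets with pixel-encoded alignment evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering long-read SV callsets with pixel-encoded alignment evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(svpixel)
```

## The method

`svpixel` post-processes a merged multi-caller structural-variant callset
from long-read alignments. The premise: a true SV call of any size leaves a
characteristic arrangement of alignment evidence around its breakpoints, and
a small convolutional network can learn that arrangement from images far
more robustly than hand-tuned support-count thresholds can. The pipeline has
two stages.

**Training.** Candidate records from several callers are merged (same type,
breakpoints within `merge_dist`, length ratio at least `size_sim`; the
merged record keeps member-median coordinates and the union of caller
names). Candidates are labeled positive/negative by one-to-one matching
against a ground-truth VCF, encoded into images, purged of suspect negative
labels (below), class-balanced per SV type, and used to train one classifier
per type.

**Detection.** A new candidate set is merged, encoded with the same
configuration, and every INS/DEL/INV/DUP candidate whose score exceeds 0.5
(strictly) is kept. Translocations bypass the imaging entirely: TRA records
are clustered by a breakpoint-distance rule and reported when enough
distinct callers agree.

### Signature extraction

Two classes of evidence are read from the BAM, in 0-based half-open
coordinates (VCF positions are converted at the boundary):

* *Intra-alignment*: each `I`/`D` CIGAR operation of length at least
  `min_sig_len` (default 50 bp, the conventional SV size floor) in a primary
  alignment. A deletion fragment spans the deleted reference interval; an
  insertion fragment is anchored at the insertion locus with a synthetic
  span equal to the inserted length, used only for drawing.
* *Inter-alignment*: adjacent segment pairs of a split read, ordered along
  the read. A reference gap exceeding the read gap by more than `min_delta`
  (default 50 bp) is deletion evidence over the gap; the converse is
  insertion evidence at the junction; reference overlap of the two segments
  marks both as duplication evidence; opposite orientations mark both as
  inversion evidence. Pairs on different chromosomes are translocation
  breakpoint evidence and are never imaged.

Secondary and duplicate alignments are ignored; supplementary alignments
contribute only to split-read signatures. A configurable mapping-quality
floor (default 20) suppresses ambiguous mappings. The defaults here are our
choices — standard long-read SV-calling practice — since only the 50 bp
distance-change threshold is dictated by the method itself.

### Encoding

The search region scales with the event so that events of any size produce
comparable images: `[bpt_left - svl, bpt_right + svl]` for DEL/DUP,
`[pos - svl, pos + 2*svl]` for INS. Inversions can reach hundreds of
kilobases, so INV candidates longer than `alpha` are encoded from two
breakpoint windows (`[bpt_left - alpha, bpt_left + alpha/2]`,
`[bpt_right + alpha/2, bpt_right + alpha]`) drawn side by side with a
one-pixel separator; `alpha` defaults to 10 kb, which bounds the worst-case
INV canvas at 20 kb of sequence and keeps memory flat. Channel values follow
the three per-type rules given in the README; all channels are exactly 0 or
255, and containment is tested on the *unclipped* fragment extent so a
fragment jutting out of the window is not mistaken for a contained one.

Fragments are stacked into rows like a pileup. The stack height is
`round(depth * max_stack_depth_factor)` where `depth` is the measured
primary-alignment coverage of the region — this is the coverage
normalization: at 10x and at 30x a fully supported event fills roughly the
same fraction of image rows, so one model serves datasets of different
depths. Fragments are packed greedily (sorted by start, first collision-free
row, dropped when the stack is full — a deterministic, coverage-faithful
overflow rule).

Rasterization paints each fragment onto the `image_width`-bin column grid
directly: every bin the fragment's span touches is set, so a 60 bp fragment
remains visible inside a 300 kb window. We deliberately did *not* build a
base-pair-resolution canvas and nearest-neighbor-sample its columns: column
sampling at stride `span/width` would silently drop any fragment narrower
than one bin, exactly the fragments short-event support consists of. The row
axis *is* nearest-neighbor resampled from the depth-sized stack to
`image_height`, which preserves the binary channel values and the
row-fraction semantics in both the up- and down-sampling direction. Images
default to 128x128 (any multiple of 8 at least 32 works; the tests and the
acceptance script use 32x32, which keeps the full suite desk-scale while
leaving every property intact).

Overlap compositing: fragments are drawn in sorted order into distinct rows,
so overwriting only occurs if a row is reused; we draw one row per fragment
(not per read), reusing rows only for column-disjoint fragments.

### Mislabel elimination

Truth sets are incomplete, so some training "negatives" are real variants
with full support — exactly the samples that teach the model the wrong
thing. Each image is flattened to a row vector by the weighted channel sum
`sum_k (R*w^2 + G*w + B)` per column with `w = 256` (each pixel becomes a
24-bit code, so distinct channel patterns cannot collide within a pixel; the
sum over rows makes the features invariant to stacking order). The rows are
centered, projected onto the top `n_components = 10` principal components
(sign convention: largest-magnitude loading positive, for determinism), and
clustered with k-means (`c = 8` clusters per SV type, 10 restarts, fixed
seed). Negatives in any cluster whose positive fraction reaches
`purity_threshold = 0.5` are removed; positives are never removed, and
samples are removed, never relabeled.

The removal criterion is the one genuinely open design point: "clusters
containing incorrectly labeled samples" admits several readings, and we
operationalize it as majority-positive clusters. The threshold, `c` and the
component count are configurable; clustering runs per SV type because the
feature scales of the four encodings differ. Flattening is applied to the
fixed-size post-rescale image so all rows have equal length.

### The classifier

Three convolution blocks (3x3 kernels over the 3 input channels, widths
16/32/64, ReLU, 2x2 max-pool) and two fully connected layers (256, 64) with
dropout 0.5, ending in a single sigmoid unit. The "3x3x3 kernel" is read as
a 3x3 spatial kernel over the three color channels — the inputs are 2-D RGB
images, not voxel data. Widths, the optimizer (Adam, 1e-3), batch size (64)
and epoch count are not fixed by the method; the defaults are ordinary
choices for a network this size and all are arguments. Training minimizes
binary cross-entropy; a stratified held-out fraction (default 0.2) tracks
AUC per epoch, and the checkpoint with the best held-out AUC is kept, ties
broken toward lower training loss so that late, better-calibrated weights
win once AUC saturates (with nearly separable synthetic data AUC hits 1.0
in the first epoch while blank-image scores are still near 0.5).

There is no deep-learning runtime in this package's dependency stack, so the
network — im2col convolutions, max-pool argmax bookkeeping, inverted
dropout, Adam — is implemented directly on R's BLAS matrix algebra. At
32x32 this trains a 1000-image type in well under a minute on one CPU.
Everything is seeded: initialization, the train/validation split, shuffling,
dropout masks; training twice with one seed gives bit-identical weights.

The detection rule is fixed at *score > 0.5 strictly*: a candidate scoring
exactly 0.5 is dropped.

### TRA merging and evaluation

Two TRA records are the same event iff both chromosome pairs match and both
breakpoint distances are at most `gamma` (default 1000 bp). Records are
processed in canonical order; each joins the first cluster whose
representative (member-wise median breakpoints) it matches, and clusters
with at least `c0` distinct callers (default 2, the weakest non-trivial
consensus) are reported. Greedy-vs-closure agreement holds when events are
separated by a few `gamma` — the regime the method targets; pathological
chains can split differently, which is inherent to any single-pass rule.

Precision, recall and F1 use the same one-to-one matcher as training labels
(`refdist` 1000 bp, `pctsize` 0.7 — Truvari-flavored defaults), so a model
is scored by exactly the notion of correctness it was taught. Undefined
ratios (zero denominators) are reported as `NA`, never as 0.

## The simulator

`simulateDataset` synthesizes alignment records directly — no read aligner
runs — because the package tests signature handling, not mapping. Reads tile
each contig at the target coverage with Gaussian lengths (default 1.5 kb
mean; configurable up to tens of kb). Reads spanning a DEL/INS carry the
corresponding `D`/`I` operation with Gaussian length jitter (`jitter_sd`,
default 10 bp); deletions longer than the read emit split pairs jumping the
deleted interval; inversions emit orientation-flipped split segments
(including breakpoint-crossing reads, so arbitrarily large INVs encode);
duplications emit reference-overlapping split pairs, either spanning the
unit or crossing the copy junction. A background small-indel rate (default
0.1 per read, 10-30 bp) exercises the signature length floor. Decoy
candidates are half signature-free random loci drawn from the event-free
contig tails and half truth copies shifted 1.5-3 kb (beyond `refdist`), so
planted labels are recoverable exactly. Events are haploid by default
(every spanning read is a carrier); `het = TRUE` makes carriers a fair coin.

Default event lengths are 100-600 bp (INS/DEL), 300-2000 bp (INV) and
300-1200 bp (DUP). The DUP ceiling is a geometric constraint, not a tuning
knob: a tandem-duplication overlap signature requires the read to be longer
than the duplicated unit, so with 1.5 kb reads longer default DUPs would be
structurally invisible to any split-read method.

What the simulator does *not* emulate: sequencing errors at base level
(SEQ fields are placeholders), alignment ambiguity and MAPQ variation,
diploid phasing, clustered/overlapping events, and reference bias. Passing
tests therefore demonstrate that the encoding, the mislabel elimination and
the classifier behave as designed on clean, well-separated signatures; they
do not certify performance on real data, where label noise and mapping
artifacts are the dominant difficulty.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by choice:
32x32 images, simulated contigs of 0.1-17 Mb, coverages 10-30x, 100-2000
events, classifiers trained for 2-12 epochs. Learnability is checked on 500
positives + 500 negatives per SV type (held-out AUC at least 0.9); the
end-to-end property — filtering strictly increases F1 with recall loss at
most 0.05 — runs on two independent 30x datasets with 100 truth events and
56 decoys each, three jittered pseudo-callers. Degenerate inputs are defined,
not errors: a candidate with no overlapping signature encodes to an all-zero
image ("no support"), an empty candidate VCF yields a valid header-only
output, and an empty truth set makes recall `NA` with a warning. Ties are
fixed everywhere (fragment sort by start/end/read id, greedy cluster order
by sorted breakpoints, k-means seeds), so every stage is reproducible
byte-for-byte under one seed.

## Known limitations

* TRA events are merged, never filtered — breakpoint-pair evidence does not
  fit the read-stack encoding.
* The mislabel rule removes whole negatives; it cannot rescue mislabeled
  positives.
* Merged records keep median coordinates; breakpoint refinement is out of
  scope, as are genotyping and multi-sample VCFs.
* Very large duplications (longer than the reads) leave no overlap
  signature and encode as unsupported; real pipelines would fall back to
  depth-based evidence, which this package does not model.
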