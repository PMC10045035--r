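# svpixel

Image-based filtering of long-read structural variant (SV) callsets.

## The problem

Long-read SV callers (Sniffles, PBSV, SVIM, cuteSV, ...) disagree: merging
their callsets recovers sensitivity but floods the result with false
positives, and every caller's precision/recall balance hinges on
hard-to-pick parameters such as the minimum number of supporting reads.
`svpixel` takes the opposite route: it merges the callsets first, then
learns what real variant support *looks like* in the alignments and removes
candidates that lack it.

For each candidate insertion (INS), deletion (DEL), inversion (INV) or
duplication (DUP), the alignment evidence inside a length-scaled search
region — intra-alignment `I`/`D` CIGAR operations and split-read segment
geometry (reference gaps, overlaps, orientation flips) — is drawn into a
fixed-size three-channel image. Each evidence fragment is a colored bar in a
read stack whose height tracks local coverage, with channels set by three
rules (for INS/DEL/DUP):

* **B = 255** if the fragment lies completely inside the search region,
* **G = 255** if the fragment midpoint falls between the two breakpoints
  `bpt_left`..`bpt_right`,
* **R = 255** if the fragment is shorter than `2 x svl` (the candidate
  length), strict.

For INV, B marks split-read evidence and R marks orientation-discordant
segments. The search region is `[bpt_left - svl, bpt_right + svl]` for
DEL/DUP, `[pos - svl, pos + 2 svl]` for INS, and for INV longer than a
threshold `alpha` two windows around the breakpoints,
`[bpt_left - alpha, bpt_left + alpha/2]` and
`[bpt_right + alpha/2, bpt_right + alpha]`.

A compact CNN — three blocks of (3x3 convolution, ReLU, 2x2 max-pool), two
fully connected layers with dropout, one sigmoid unit — is trained on
candidates labeled against a truth set; a candidate is kept at detection
time iff its score exceeds 0.5. Because truth sets are incomplete, some
"false positives" are real variants; before training, each image is
flattened by

    ArrE[i, j] = sum_k ( R[k,j] * w^2 + G[k,j] * w + B[k,j] ),  w = 256,

reduced by PCA and clustered with k-means, and negative samples that
co-cluster with positives are eliminated from the training set.

Translocations (TRA) are never imaged. TRA records `T_a`, `T_b` are merged
when `Chr_a1 = Chr_b1`, `Chr_a2 = Chr_b2`, `|Pos_a1 - Pos_b1| <= gamma` and
`|Pos_a2 - Pos_b2| <= gamma` (default `gamma` = 1000 bp), and a merged event
is reported when at least `c0` distinct callers support it (default 2).

Evaluation uses `Pre = TP/(TP+FP)`, `Rec = TP/(TP+FN)` and their harmonic
mean `F1`, with a one-to-one Truvari-style matcher (breakpoint distance
`refdist`, size ratio `pctsize`).

## Worked example

```r
library(svpixel)

cfg  <- simConfig(contigs = c(chr1 = 9e5, chr2 = 6e5), coverage = 30,
                  n_events = c(INS = 8, DEL = 8, INV = 5, DUP = 5, TRA = 3),
                  n_decoys = c(INS = 6, DEL = 6, INV = 4, DUP = 4),
                  seed = 424242)
sim  <- simulateDataset(cfg, "simdata")
enc  <- encoderConfig(image_width = 32, image_height = 32)

img  <- encodeCandidate(sim$bam, sim$truth[svType(sim$truth) == "DEL"][1], enc)
img
#> EncodedImage 32x32x3 (truth.DEL.9 DEL), 11/32 rows carry signal

cand <- c(sim$truth, sim$decoys)          # contaminated candidate set
svScore(cand, sim$truth)
#> SVEvalResult  TP: 26  FP: 20  FN: 0
#>   precision 0.5652  recall 1.0000  F1 0.7222
```

Training and filtering end to end (paths as written by the simulator; in
real use the VCFs come from upstream callers):

```r
tp  <- trainPipeline(sim$bam, c(calls = sim$decoy_vcf, truthy = sim$truth_vcf),
                     sim$truth_vcf, "model", config = enc, epochs = 12, seed = 1)
det <- detectPipeline(sim$bam, c(calls = sim$decoy_vcf, truthy = sim$truth_vcf),
                      tp$checkpoints, "filtered.vcf", config = enc, seed = 1)
```

The output VCF carries `SVTYPE`, `END`, `SVLEN` and `SUPPORT` (number of
agreeing callers) in INFO, plus provenance header lines. A shell front end
with `simulate` / `train` / `detect` / `evaluate` subcommands is installed
as `exec/svpixel`.

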