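---
title: "Methods: chromatin binding and transcriptional memory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin binding and transcriptional memory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memochip)
library(dplyr)
```

memochip implements the computational workflow of a T-cell transcriptional
memory study built around stimulus-dependent chromatin binding of a signaling
kinase (PKC-theta): ChIP-seq peak annotation, between-condition count
normalization, classification of stimulation-response expression profiles,
binding-by-group enrichment statistics, signal/motif matrices around binding
sites, kinase peptide-array profiling, and per-cell nuclear-translocation
quantification. Because the raw sequencing, array and imaging data of such
studies are rarely re-usable at desk scale, the package ships seeded
generators that produce every input the pipeline consumes, with planted
ground truth, so that each analysis stage can be validated end to end.

This vignette documents the models, conventions and numerical choices, and
what the synthetic data do and do not establish about real data.

## Coordinates and interval operations

All genomic intervals are 0-based, half-open (BED convention); GTF input is
converted on read. Peak merging is strand-blind and reduces any interval set
to the minimal sorted non-overlapping cover — this is how per-condition peak
files are pooled into consensus regions. Overlap counting uses a >= 1 bp
criterion with no read-extension step, mirroring the practice of treating the
original peak files as reads when scoring consensus regions. Peak length
filtering defaults to >= 175 bp, the conventional low-complexity cutoff for
broad-peak calls in this workflow.

## Genomic annotation

Each region is annotated against its nearest transcript, chosen by the
smallest absolute distance between the region midpoint and the transcript TSS
(TSS = `start` on the plus strand, `end - 1` on the minus strand). Ties are
broken by lexicographic transcript id so results are reproducible. The
category is then decided against that transcript alone:

* promoter: region overlaps the strand-aware window 1 kb upstream of the TSS;
* upstream: overlaps the window 10 kb to 1 kb upstream;
* 5'UTR / 3'UTR / exon / intron: overlaps the corresponding gene feature,
  with precedence promoter > 5utr > 3utr > exon > intron when several
  overlap;
* intergenic otherwise.

Nearest-gene-by-TSS with promoter-first precedence mirrors common annotator
behavior; window sizes are arguments (`promoter_bp`, `upstream_bp`) with the
1 kb / 10 kb defaults above. Since published annotations of this kind derive
from tools with unstated arbitration (and proportions depend on the genome
build and array), per-category proportions are validated against an analytic
partition of a constructed single-transcript genome rather than against any
published percentage.

Chromatin-state annotation assigns each region the state with the largest
base overlap from a six-state segmentation (permissive, transcription,
enhancer, repressed, heterochromatin, quiescent). Ties break in that fixed
order; regions overlapping no segment fall back to quiescent, the state
defined by the absence of marks.

## Non-log MA normalization

Counts of regions common to two samples define the pairs
(M, A) = (count_A - count_B, (count_A + count_B)/2) on the raw (non-log)
scale. The model `m = b0 + b1 * a` is fitted by robust M-estimation by
default (Huber weights, tuning constant 1.345, convergence tolerance 1e-8,
at most 50 iterations, via `MASS::rlm`), or by OLS. Robustness matters
because genuinely differential peaks are outliers with respect to the
technical trend and should not drag the normalization line. Sample B is then
adjusted toward the reference A: `adjusted_b = count_b + (b0 + b1 * a_i)`,
floored at zero. For regions in multiple pairs, `a_i` is the mean pair
average; regions unique to sample B fall back to `a_i = count_b` and are
flagged (`paired = FALSE`) — whether unique peaks should be adjusted at all
is a judgment call, so the flag lets users drop them.

Because OLS residuals are orthogonal to any affine function of A, refitting
the model on adjusted counts returns coefficients at numerical zero; the test
suite asserts |b0| < 1 count and |b1| < 0.01 on every seed. Fits refuse to
extrapolate below `min_common = 10` pairs.

The generator plants bias directly in (M, A) space: `a` is drawn negative
binomial (mean 200, dispersion 0.1 — overdispersion typical of tag counts),
`m = b0 + b1 * a` plus centered negative-binomial noise, and the two counts
are reconstructed as `a ± m/2`, rounded and floored. Planting in the fitted
coordinates makes the planted coefficients exactly the regression truth;
reconstruction rounding is mean-zero and leaves OLS recovery unbiased. The
default planted values (b0 = 20 counts, b1 = 0.1) represent a noticeable but
realistic library-size/efficiency bias.

## Expression-group classification

The four-condition design is NS (non-stimulated) -> primary stimulation ->
stimulus withdrawal (SW) -> secondary re-stimulation. Each stimulation is
compared against its immediately preceding state: `i1 = primary - NS`,
`i2 = secondary - SW`, both log2. With the conventional overexpression
cutoff of 0.5 log2 (`up_threshold`):

| up after 1° | up after 2° | extra condition        | group                  |
|-------------|-------------|------------------------|------------------------|
| yes         | no          |                        | primary_specific       |
| no          | yes         |                        | secondary_specific     |
| yes         | yes         | `i2 - i1 >= margin`    | transcriptional_memory |
| yes         | yes         | otherwise              | activation_compliant   |
| no          | no          |                        | nonresponsive          |

`memory_margin` defaults to `up_threshold` (0.5 log2): transcriptional-memory
genes respond markedly more strongly on re-stimulation, but no printed margin
exists for this distinction, so the package re-uses the overexpression
cutoff and exposes it as an argument. Only magnitude is modeled — response
kinetics ("faster") would need time-course data that the four-condition
matrix does not carry. Downregulation folds into "not up"; no repressed
groups are defined. Genes with non-finite inductions are excluded with a
warning, never silently.

The generator plants `(i1, i2)` = (e, 0), (0, e), (e, e), (e, 2e), (0, 0)
per group with effect e = 1.0 log2 and Gaussian noise sd 0.1 on every
condition value. The memory group's planted `i2 - i1 = e` clears the margin
by 0.5 log2, i.e. 2.5 noise standard deviations of the relevant contrast;
expected recovery is above 99%, which the tests assert.

## Binding enrichment and overlap patterns

Enrichment of a gene group for binding is tested with Fisher's exact test on
the 2x2 group-membership x bound-status table, one-sided "greater" by
default: the scientific question is enrichment, and the one-sided p is
exactly the hypergeometric upper tail. A two-sided alternative and
Benjamini-Hochberg correction across groups are available by argument but
off by default (per-group tests are conventionally reported uncorrected in
this setting). The reported odds ratio is the sample odds ratio
`(a*d)/(b*c)`; a Haldane 0.5 correction is applied only when a zero cell
occurs and is flagged in the output.

Overlap patterns across the four conditions merge all peaks into consensus
regions and mark each region "+" per condition iff one of that condition's
peaks overlaps it by >= 1 bp. Counts sum to the number of consensus regions
and the all-"-" pattern is impossible by construction.

## Signal matrices and motif proximity

Tag-density heatmap matrices use 100-bp bins spanning ±3000 bp around each
region center (`floor((start+end)/2)`); a tag is assigned by its midpoint to
`floor((tag_mid - (center - flank))/bin)`. The midpoint convention is the
simplest defensible choice for heatmaps (read-extension conventions apply to
overlap counting, not binning) and is documented rather than hidden. Matrix
totals conserve in-window tags; heatmap rows are ordered by decreasing total
signal, a deterministic presentation rule.

PWM scanning scores both strands of the ±250 bp window around each center
with log2 odds against the background (uniform by default). A hit requires
`score >= score_fraction * max_attainable_score`, with `score_fraction` 0.8
by default — published figures of this kind rarely state the match
threshold, so it is an explicit argument rather than a constant. Non-ACGT
bases score -Inf and can never produce a hit through them; windows past
chromosome ends are clipped with a warning.

## Peptide-array profiling

Replicate aggregation drops replicates flagged as asymmetric-spot artifacts
(the criterion is visual, so flags are input data, not inferred), then
reports mean ± sample sd. An optional, explicitly-enabled MAD rule can
additionally reject replicates beyond `k` scaled median absolute deviations.
The default layout is three spots on each of three subarrays, nine instances
per peptide.

Phospho-positive calls use a strict threshold: positive iff mean > 57,500
units, the conventional background cutoff for these arrays; signals at the
threshold are negative. Because this cutoff is acknowledged as arbitrary,
the package never derives one silently — `suggest_thresholds()` reports
candidates (background mean + 2 sd; 95th percentile of no-kinase controls)
for the user to apply deliberately.

Modification effects compare each modified peptide with its unmodified
parent of identical sequence: `delta = mean(modified) - mean(parent)`,
labelled promote/inhibit/neutral around a `promote_margin`. Multi-modified
peptides are attributed to the full combination, never decomposed into
additive single-residue effects. The synthetic library tiles 20-mers over a
synthetic 60-residue toy histone embedding an RxRxxS motif with downstream
serines and flanking lysines; planted effects are ±5,000 units with
replicate noise sd 500, so the planted sign is ~10 replicate standard errors
away from zero and sign recovery is essentially deterministic. The generator
also implements the pre-phosphorylation blocking rule — a pS planted on a
motif acceptor serine forces the peptide's signal below threshold — which the
tests exercise end to end as a generator property, not as a claim about real
chemistry.

Kinase-motif scanning returns all (including overlapping) 1-based match
starts of patterns like `RxRxxS`.

## Imaging quantification

The nuclear translocation ratio is `Fn/c = (Fn - Fb)/(Fc - Fb)` from mean
nuclear, cytoplasmic and background intensities; the cytoplasm is the cell
mask minus the nuclear mask. Means (not medians) feed the formula's
single-value inputs; medians are available by flag. Cells with `Fc <= Fb`
are excluded with a recorded reason and counted. Background is per-field by
default (one background mask per image); per-cell backgrounds can be passed
by supplying per-cell masks. Colocalization is the sample Pearson
correlation over masked pixels, requiring >= 2 pixels and non-degenerate
variance in both channels. Cohort comparisons use the Mann-Whitney test,
exact for both groups <= 20 without ties, otherwise the tie-corrected normal
approximation.

The image generator renders each cell as a cytoplasmic disk (radius 20 px)
with a concentric nuclear disk (radius 9 px) on a flat background
(levels 10/60, nucleus set so the true ratio is 2.0), plus Gaussian pixel
noise (sd 2). With ~250 nuclear pixels per cell the recovered cohort mean is
well within 5% of the planted ratio.

## Determinism and problem sizes

Every generator is a pure function of the configuration seed; `simulate_all()`
writes a byte-identical file tree for the same seed. Validation problem
sizes were chosen so the whole suite runs in about two minutes on a single
core while keeping each check statistically meaningful: 100 seeded random
instances per oracle comparison, 100 simulation seeds for normalization
recovery (2000 common peaks each), 500 genes for classification recovery,
and a full simulate -> normalize -> annotate -> classify -> enrich -> matrix
chain on the two-chromosome toy genome.

## What the synthetic data do not show

The generators emulate structure, not biology: negative-binomial counts and
Gaussian log2 noise are parameterized conveniences, not estimates of any
real library; the toy histone is synthetic; disk-shaped cells ignore
segmentation error, which in real images usually dominates the error budget
of Fn/c. Passing recovery tests therefore demonstrates correctness of the
computations under the stated models — it does not validate peak calling,
array preprocessing or cell segmentation, all of which are upstream of this
package and out of its scope.
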