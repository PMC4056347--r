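---
title: "Methods: paired tumor-normal profiling of low-purity cancer genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired tumor-normal profiling of low-purity cancer genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoprofiler)
```

oncoprofiler implements an integrated genomic-profiling workflow for paired
tumor/blood samples in which the tumor cell fraction (purity) is low — the
situation typical of diffuse-type gastric cancer, whose cells infiltrate
stromal tissue and resist clean macrodissection. This vignette describes the
statistical models and procedures behind each stage, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
numerical choices made where the methods left room.

## Purity from depth-ratio peaks

The depth of a genomic window in the tumor read track, relative to the
matched normal, reflects the average copy number of the cell mixture. With
purity $\pi$ and tumor copy number $c$, the expected tumor:normal ratio is
proportional to $(\pi c + 2(1-\pi))/2$. Cancer genomes carry heterozygous
deletions ($c = 1$), so the ratio histogram of a tumor-bearing sample shows
(at least) two peaks: a diploid (2N) mode at ratio $R_{2n}$ and a haploid
(1N) peak at $R_{1n} = R_{2n}(1 - \pi/2)$. Inverting,

$$ P \;=\; \frac{2\,(R_{2n} - R_{1n})}{R_{2n}}, $$

clamped to $[0, 1]$. The formula is invariant to global rescaling of either
track, so the windowed ratios (default window: 50 kb, the scale at which
single-copy shifts separate cleanly from depth noise at ~30x coverage) are
median-normalized purely for readable diagnostics.

Peak finding is a Gaussian kernel density (Silverman's default bandwidth)
whose local maxima above a relative prominence floor (default 10% of the
maximal density) are the peaks; the global mode is assigned 2N and the
highest peak strictly below it 1N (ties toward the lower ratio). Windows
whose normal depth falls below 10 reads are excluded before ratios are
formed to avoid ratio blow-ups, and fewer than 200 usable windows is an
error rather than a guess.

Below roughly $\pi = 0.5$ the 1N peak merges into the diploid peak and peak
assignment becomes unreliable. The fallback anchors $R_{1n}$ on somatic
deletion regions called from discordant read pairs: candidate regions are
somatic deletions not overlapping any blood (germline) deletion; a candidate
whose mean ratio exceeds the 2N reference is discarded as a false positive;
the mean ratio over the surviving regions is $R_{1n}$. The 2N reference
$R_{2n}$ is, symmetrically, the **mean** ratio over windows outside all
candidate regions — using the global density mode here would mix a modal
estimator with an average and biases the estimate low by a few points at low
purity, because the 1N shoulder drags the mode down. When no candidate
survives, the result is `method = "undetermined"` rather than a number.

The fallback triggers when the peak-mode estimate would fall below 0.5 or no
second peak clears the prominence floor. At a true purity of exactly 0.5
depth noise legitimately lands either side of the trigger, so both modes are
treated as valid answers there.

## The somatic filter cascade

Somatic SNV/indel calling takes the tumor and blood call sets plus a blood
pileup and applies six fixed stages, each logged with removal counts:
(1) tumor calls with read depth outside $[5, 200]$ or call quality below 20
are dropped; (2) calls present in the blood call set (position + alleles)
are subtracted; (3) calls at which the blood pileup shows depth $\ge 3$ and
alternate-allele ratio $\ge 0.2$ are dropped as residual germline evidence;
(4) only uniquely mapped calls are kept; (5) inside segmental-duplication
regions ($\ge 90\%$ identity, supplied as a BED mask) a call must have been
detected by both whole-genome and whole-exome sequencing; (6) calls present
in known-variant exclusion lists (dbSNP-style, panel-of-normals-style) are
removed. The stages are pure per-record predicates, so the surviving set is
independent of stage order; the order above only shapes the audit trail, and
a test asserts exactly that. Tumor positions missing from the blood pileup
are treated as blood depth 0 (stage 3 passes) and counted in a warning; the
pileup depth used is total depth.

Consequence annotation translates the affected codon on the coding strand of
the gene models: synonymous, nonsynonymous, nonsense (stop gain; grouped
with nonsynonymous wherever ns counts are used), splice-site (within the two
intronic bases flanking an exon boundary), frameshift (CDS indel of length
not divisible by 3), in-frame indel, or noncoding. The mutation rate is the
count of somatic SNVs and small indels inside the sufficiently covered CDS
mask (coverage floor 5 reads) divided by the mask size in megabases. The
substitution spectrum collapses the 12 raw substitution types onto the six
pyrimidine-referenced classes (G>A counts as C>T, and so on).

## Poisson driver-gene scoring

The neutral expectation for each gene's nonsynonymous count is anchored on
the cohort's synonymous mutations: with cohort totals $N_{ns}$, $N_s$ and
total efficiently covered length $L$ (bases with normal depth $\ge 4$ and
tumor depth $\ge 3$), the background nonsynonymous rate per covered base is
$(N_{ns}/N_s) \cdot N_s / L = N_{ns}/L$, and a gene with covered length
$\ell$ expects $\lambda = \ell \, N_{ns}/L$ nonsynonymous mutations
(optionally weighted by a per-gene nonsynonymous-site fraction; identity
weighting is the default since the background description uses only the
global ratio). The p-value is the Poisson upper tail
$P(X \ge k \mid \lambda)$, with $P = 1$ at $k = 0$; genes with zero observed
mutations stay in the table at $p = 1$ so the multiplicity family is well
defined, and genes with zero covered bases are excluded and reported. The
driver score is $-\log_{10}$ of the Benjamini-Hochberg adjusted p-value —
published driver-score columns of this design sit consistently below
$-\log_{10}$ of the raw p, indicating an unstated adjustment, and BH is the
standard choice; the raw p-value is always reported alongside. Indels and
splice-site SNVs are tallied separately and can be switched into the
observed count.

A note on calibration: the Poisson tail is discrete. At per-gene
expectations far below 1 — the realistic regime for an 18-sample cohort —
the achievable rejection level below 0.05 is $P(X \ge 2)$, orders of
magnitude smaller, so the test is strongly conservative and a nominal-level
check is meaningless there. The package therefore reads type-I calibration
in the near-continuous regime (per-gene expected counts of roughly 8-25,
obtained by varying covered lengths), where the discrete tail tracks its
nominal level (analytically ~0.040 for that mixture), and reads *power* in
the realistic sparse regime, where five excess nonsynonymous mutations drive
a gene to the top of the ranking essentially always.

## Structural-variation signals, breakage and fusions

Uniquely and discordantly mapped read pairs are classified by geometry
against the concordant insert distribution (median 500 bp, MAD 50 bp,
$k = 3$ by default): cross-chromosome pairs are interchromosomal
translocation evidence; same-strand pairs inversion; convergent pairs with
span above median $+ k\cdot$MAD deletion, below median $- k\cdot$MAD
insertion, and above 1 Mb intrachromosomal translocation. Same-class pairs
whose corresponding ends each lie within a join distance (default 400 bp,
reusing the breakpoint-equivalence radius) are single-linkage clustered;
clusters of at least 4 pairs ("more than three") become structural-variation
signals (SVSs) whose breakpoint intervals span the supporting read ends.
Output ordering is deterministic and input-order invariant.

A somatic SVS is one with no blood SVS (of any type) whose two breakpoints
both lie within 400 bp (inclusive); 401 bp keeps the signal. A gene is
broken when an SVS breakpoint interval overlaps its transcribed span; the
`exon_filter` flag first discards SVSs with neither breakpoint in an exon.
The flag defaults **off** because published per-sample breakage tables list
intronic breakpoints (e.g. CDH1 intron 2) as breakage, while the stricter
exonic convention is the one used for cohort-level impaired-gene tallies —
the two conventions genuinely coexist and the flag makes the choice
explicit. Fusion candidates are SVSs of interchromosomal type whose
breakpoints fall in two distinct genes with at least 11 supporting pairs
("above 10"); both thresholds are exposed as parameters but default to the
strict readings.

Fusion transcript structure joins the 5' partner's exons upstream of its
breakpoint to the 3' partner's exons downstream of its breakpoint
(transcription order, strand aware; partial exons contribute their retained
CDS). The fusion is in frame when the total retained CDS length is a
multiple of 3 and frameshift otherwise — a deliberate, simple junction
arithmetic on the retained lengths; a frameshifted 3' partner is expected to
terminate prematurely, which the codon-walk test verifies on a constructed
sequence. A breakpoint upstream of the 5' partner's CDS start flags the
candidate non-coding.

## Copy number and integration

Copy-number segmentation is a transparent BIC-penalized bottom-up merge of
binned log2 tumor:normal count ratios (library-size normalized, 0.5
pseudocount): adjacent segments merge while the smallest increase in
within-segment sum of squares, scaled by a robust noise variance estimated
from first differences, stays below the per-breakpoint penalty
$\lambda$ (default 100; bins default 1 kb). It matches the ($\lambda$, bin
size) interface of likelihood-based segmenters but is an approximation —
exact segment boundaries of those tools are not reproduced, and the
merge order is deterministic with ties resolved leftmost. Segments classify
as duplicated above $+0.2$ and deleted below $-0.2$ (strict inequalities:
$\pm 0.2$ exactly is neutral, following the wording "smaller than / larger
than"); array-CGH data use $+0.152173$ / $-0.135797$. Purity is *not* used
to rescale ratios before classification — the thresholds are applied to raw
log2 ratios, which is why sensitivity to single-copy events decays as purity
drops (at $\pi = 0.2$ a heterozygous deletion shifts log2 by only $-0.15$);
a diagnostic can report purity-adjusted ratios but never feeds the
classifier. Gene-level status is the state covering the largest fraction of
the gene span, requiring at least 50% coverage, ties resolving to neutral.

The alteration matrix unions, per gene and sample, point mutations (SNVs
with product-altering consequences; indels), gene-level copy gain/loss, and
SVS breakage, in the layout of published per-gene alteration tables.
Mutual-exclusivity counts partition the cohort by presence of two category
sets (defaults: point mutation vs. copy loss), and the cohort comparison
counts mutated genes per group with
$n_{union} = n_A + n_B - n_{common}$ asserted on every output.

## What the synthetic cohort does and does not emulate

The generator is first-class, tested code and defines the conditions under
which the pipeline's guarantees are read:

* **Depth**: negative-binomial window counts (default dispersion 0.0025,
  ~5% CV per 50-kb window at 32x, matching real WGS overdispersion rather
  than Poisson noise; dispersion 0 degrades to Poisson). CNV events scale
  the tumor mean by the admixture factor — exactly the mixture the purity
  model assumes.
* **Variants**: germline variants (default 1000/Mb, the human heterozygosity
  scale) appear in both tables at allele fraction 0.5; somatic variants
  (default 2/Mb, the gastric-cancer exonic scale) only in the tumor at
  allele fraction $\pi/2$, copy-number adjusted inside CNV events. Coding
  somatic SNVs are drawn nonsynonymous vs synonymous at the configured ns/s
  ratio (default 2.5) by rejection sampling against the actual CDS sequence,
  so annotation recovers the generating classes exactly; driver genes
  receive a configured excess of nonsynonymous SNVs.
* **Read pairs**: each injected SV emits its supporting pairs with ends
  scattered ±150 bp (default) around the true breakpoints and the
  type-appropriate geometry; germline SVs appear in both samples; noise
  pairs scatter uniformly and do not cluster to the 4-pair floor.

Not emulated: read-level artifacts (mapping ambiguity beyond a boolean
flag, strand bias, FFPE damage), mutational-signature composition
(substitutions are uniform, so spectra are only structurally tested),
subclonal heterogeneity (one clone at fixed purity), overlapping CNVs and
complex rearrangements, and sequence context around indels. Passing tests
therefore demonstrate correctness of the estimators and rules under the
stated noise model, not robustness to every artifact of real libraries.

Problem sizes used by the test-suite and acceptance runs: 100-Mb genomes
(2,000 depth windows) for purity recovery over the 0.2-0.9 grid with 20
seeds per point; 20-30-Mb genomes with 150-300 genes for variant-level
checks; 100 null cohorts of 300 genes and 50 driver cohorts of 500 genes
for scoring calibration and power. These keep each run in seconds while
leaving estimator standard errors well inside the asserted tolerances.

## Degenerate inputs and numerical conventions

All intervals are 0-based half-open internally; variant positions 1-based
(VCF convention); on-disk formats follow their own conventions. Windows
misaligned between tumor and normal are an error naming the first mismatch.
Empty CDS masks, zero synonymous cohorts (background undefined — the error
asks for pseudocounts rather than inventing them), non-finite log2 ratios
and inverted peak assignments are errors; empty variant sets, empty blood
SVS lists and gene-free breakpoints are quietly legal. Clustering,
segmentation and matrix construction are deterministic under input
permutation, and every generator is byte-reproducible from its seed.

## Limitations

Purity estimation assumes a diploid-dominant genome with usable heterozygous
deletions; whole-genome duplicated tumors would misplace the 2N mode (joint
purity/ploidy grids are deliberately out of scope). The driver model has no
per-gene covariates (expression, replication timing) and inherits the
conservatism of discrete Poisson tails at sparse counts. SV typing from
read-pair geometry alone cannot distinguish dispersed duplication classes,
and breakpoint resolution is the read-end span, not base-pair precise.
Copy-number calls at low purity are bounded by the unscaled-threshold
convention discussed above.
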