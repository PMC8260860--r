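---
title: "Annotating regulatory regions and testing causal-variant enrichment"
author: "EpiEnrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating regulatory regions and testing causal-variant enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EpiEnrich)
library(GenomicRanges)
```

## The problem

Genome-wide association studies report variants, but most trait-associated
SNPs fall outside coding sequence, and which of them are causal is obscured
by linkage disequilibrium. One route to prioritizing them is functional
annotation: profile histone modifications (H3K4Me3, H3K4Me1, H3K27ac,
H3K27Me3) and CTCF binding by ChIP-seq across tissues, call peaks, and ask
whether putative causal variants are concentrated inside the resulting
regulatory regions. EpiEnrich implements that analysis chain as a tested,
reusable pipeline: consensus peaks from replicated peak calls, gene-activity
classification from RNA-seq counts, promoter/proximal region construction,
tissue-versus-rest differential binding, a peak-height-versus-expression
correlation screen, base-pair enrichment of SNP sets with hypergeometric
significance, distance-to-TSS stratification, chromatin-state overlap
enrichment, and LD pruning.

Every stage can be exercised on synthetic data with planted ground truth, so
the statistical machinery is testable without any sequencing data.

## Consensus peaks

Replicate peak calls disagree at their edges and drop peaks stochastically.
The consensus treats each genomic base as a voting unit: a base enters the
consensus when it is under a peak in at least `minSupport` samples (default
2), and maximal runs of such bases become the consensus intervals. Support is
counted per sample — several overlapping intervals inside one sample still
contribute one vote. Useful consequences, which the tests assert against a
per-base bitmap oracle: consensus with `minSupport = 1` is the merged union;
raising the threshold never increases covered bases; and identical
replicates return themselves.

Coordinates are handled throughout in the `GRanges` convention (1-based,
closed). BED-family files (0-based, half-open) and 1-based SNP tables are
converted at the reader boundary, the same contract `rtracklayer` uses, so a
single internal convention holds everywhere. A SNP "under" a region is
decided after conversion, which reproduces half-open boundary semantics
exactly (a SNP at a region's excluded end base does not count).

## Gene activity, promoters, proximal regions

Activity calls use hard count thresholds: a gene is *active* in a tissue
when every animal's count exceeds 200 there, *inactive* when every animal's
count is below 10, and *ambiguous* otherwise; both comparisons are strict.
A *tissue-specific* active gene is additionally below 10 in every sample of
every other tissue. The thresholds are exposed as `activeMin` and
`inactiveMax` but the defaults are the analysis constants the pipeline is
built around. Counts are consumed as provided (normalized upstream); the
package deliberately does not re-normalize RNA-seq counts.

The promoter is the 2 kb immediately upstream of the TSS (strand-aware,
clipped at chromosome edges; the TSS base itself excluded) and the proximal
region the 8 kb immediately upstream of the promoter, so the two never
overlap. When a gene model carries several transcripts, the gene-level TSS
is the 5'-most start on the gene's strand.

## Counts, normalization, differential binding

Fragment counts in consensus peaks follow a one-base-overlap rule, and a
fragment spanning several peaks increments all of them. Normalization uses
trimmed-mean-of-M-values (TMM) scale factors with the *full* library size
(total fragments per sample, from the sample sheet) rather than in-peak
column sums; the TMM computation is delegated to `edgeR::calcNormFactors`
with the canonical 30%/5% trims and the factors are re-centred to geometric
mean 1. Counts-per-million add a prior count (default 0.5) so log values
stay finite at zero.

A peak is called differentially bound in a tissue when its normalized
signal differs from the mean of all other tissues at p < 0.05 **and** more
than two-fold in either direction. The two-fold filter dominates this
criterion at small replicate numbers, and the per-peak p-value function is
pluggable; the default is a Welch two-sample t-test on TMM-normalized
log2-CPM, a deliberate, documented substitution for a negative-binomial
GLM — self-contained, calibrated under the null (the acceptance suite
checks the joint false-call rate stays below 1%), and with ≥ 90% power for
planted 4-fold effects at 3-versus-15 samples under negative-binomial noise
with dispersion 0.1. With unbalanced designs the "rest" mean can average
samples (default) or tissue means (`restAverage = "tissues"`).

## The correlation screen

Every consensus peak is paired with every gene whose TSS lies within 100 kb
of the peak anchor — the summit for narrow peaks (point-source marks), the
midpoint for broad ones. Pearson correlation of normalized peak signal
against gene counts across matched samples, with the two-sided p-value from
the t-transform with n − 2 degrees of freedom, flags peak–gene pairs at
p < 0.05. Under the null about 5% of pairs are significant with an even
positive/negative split; an excess, or a skewed direction split (negative
for the repressive mark H3K27Me3, positive for activating marks), is the
signal. Zero-variance vectors make r undefined; such pairs are flagged and
excluded from summaries rather than silently dropped.

## The enrichment statistic

The core quantity is the base-pair enrichment fold

\[
\mathrm{fold} = \frac{C/A}{B/D},
\]

where A is the number of autosomal bases under the tested regions, B the
number of (deduplicated, autosomal) SNP positions, C the number of SNPs
under the regions, and D the autosomal genome size. Significance treats
bases as exchangeable units of a hypergeometric draw — A positions drawn
from D, of which B are SNPs — giving one-sided tails
P(X ≥ C) for enrichment and P(X ≤ C) for depletion, reported separately.
Only autosomes are tested; D is the summed autosome length. The same fold
arithmetic, applied to base counts of (state, annotation) pairs, gives the
chromatin-state overlap enrichment; the segmentation is consumed as input
(state learning is out of scope).

For distance stratification, peaks (by anchor) and SNPs are split into
100-kb distance-to-nearest-TSS bands up to 1 Mb. Within a band, A is the
covered bp of the band's peaks, B the band's SNPs, C their intersection,
and D defaults to the number of autosomal bases whose own distance falls in
the band — the matched reference for the question "is the concentration
inside peaks explained by proximity to genes?" — with a flag
(`bandD = FALSE`) to use the global D instead, since either reading of the
procedure is defensible. Bands with fewer than 10 SNPs are reported `NA`
rather than as unstable estimates.

## LD pruning

To prevent a clump of SNPs in high LD from driving enrichment, SNP sets are
thinned so that no two retained SNPs within a 1-Mb window have dosage
r² ≥ 0.5. The scan is greedy in genomic order (or ascending p-value in
`by_pvalue` mode, which therefore keeps each LD region's most significant
SNP); a SNP is dropped when it exceeds the threshold against any
already-retained SNP in the window. A reference implementation's exact
removal order is ordering-dependent and is not reproduced; the normative
behaviour here is the retention contract itself, which the tests verify by
exhaustive post-hoc scan: the retained set never contains a within-window
pair at or above the threshold, and pruning is idempotent. The `stepSnps`
argument (default 50) chunks the scan and is validated, but results are
fully determined by the contract; anchoring the window at every retained
SNP, rather than only at every 50th, guarantees the contract for all pairs
within the window. r² is the squared Pearson correlation of 0/1/2 dosages
over pairwise-complete observations (haplotype-based r² would differ
slightly); a zero-variance SNP has undefined r² and is treated as never
pruning a partner, with a warning.

## What the synthetic data emulate

`simConfig()` fixes the study conditions; the generators are pure functions
of it (identical output for identical config, including the seed):

* **Genome and genes** — 10 chromosomes × 5 Mb, all autosomal, with 400
  non-overlapping genes of mixed strand placed in the first 60% of each
  chromosome. The gene-free remainder populates the distant
  distance-to-TSS bands up to and beyond 1 Mb, which a uniformly gene-dense
  toy genome would leave empty.
* **Peaks** — a latent consensus skeleton with per-sample dropout (20%),
  edge jitter (±50 bp) and 10% background peaks, so a min-support-2
  consensus is non-trivial. Mean widths default to 500 bp for narrow and
  1100 bp for broad peaks, typical of point-source versus domain marks.
* **Counts** — negative-binomial with dispersion 0.1 (ChIP/RNA
  overdispersion, not Poisson) over a 6-tissue × 3-animal grid with
  per-sample library sizes. Planted structure: a labelled subset of peaks
  with a tissue-specific fold; active/inactive/tissue-specific genes
  *constructed* to satisfy the >200/<10 rules (shifted and truncated count
  draws), so ground-truth labels are guaranteed consistent with the emitted
  matrix; and peak–gene pairs sharing a latent per-sample factor at a
  target correlation of 0.9, with low dispersion and high means for those
  features so count noise attenuates the realized correlation only mildly
  (to ≈ 0.84 at the defaults).
* **SNPs** — each SNP falls inside the region bases with probability
  ρ·A/D — an in-region density of ρ times the genome-wide mean density —
  which makes the enrichment fold a consistent estimator of ρ. (Defining ρ
  against the *outside* density instead would make the estimand
  ρD/(ρA + D − A), which is not ρ once regions cover a non-negligible
  genome fraction; the chosen convention is the one under which
  "planted fold ρ" means what it says.) Band-specific planting allocates
  SNPs evenly across distance bands and applies a per-band ρ.
* **Genotypes** — block LD: consecutive SNPs are noisy copies of one
  latent haplotype pair, with the allele-flip probability solved from the
  target within-block dosage r² ((1−2ε)⁴ = r²); blocks are independent.
* **Segmentation** — a 7-state tiling dominated by a quiescent state, with
  an "active promoter" state preferentially placed over the promoters of
  planted-active genes so its overlap enrichment exceeds 1.

What the generators do **not** emulate: genomic sequence content,
mappability and GC structure, realistic LD decay (blocks are rectangular),
batch effects, and the mixed 16/18-sample designs of real multi-mark
experiments (a 16-sample panel is emulated as 8 tissues × 2 animals where
needed). Passing tests therefore demonstrate the correctness and
calibration of the statistical machinery under its stated model, not
robustness to artefacts of real sequencing data.

## Numerical and design choices

* Hypergeometric tails are computed with `phyper`; the test suite checks
  them against exact pmf summation via `lchoose` to 1e-10.
* The fold is reported as `(C/A)/(B/D)`; the algebraic identity
  `C·D/(A·B)` holds to floating-point rounding and is asserted as such.
* `A = 0` or `B = 0` yields an explicitly *undefined* result (all `NA`,
  `defined = FALSE`), never a silent 0/0.
* Degenerate inputs: empty peak files are valid (empty sets); a
  `minSupport` above the sample count warns and returns an empty
  consensus; narrow peaks without summits fall back to midpoints with a
  warning; chromosomes without a TSS give `NA` distances and are excluded
  from stratified analyses.
* Consensus construction per mark pools all samples (tissues and animals
  jointly); building per tissue is a matter of passing a different list of
  peak sets.
* Problem sizes in the test suite are chosen for fast, well-powered
  checks: 1–50 Mb synthetic genomes, 10⁴ SNPs for fold recovery (binomial
  error ≈ 1%), 500 replicates for null calibration, 10⁴ null pairs for
  screen calibration, 2000 peaks for differential binding.
* The pipeline writes a manifest (package version, seed, parameters, md5
  per output) with no timestamps, so a rerun under the same configuration
  is byte-identical — asserted end to end in the tests.

## Known limitations

The Welch-on-log2-CPM differential-binding test does not model
mean–dispersion relationships as a negative-binomial GLM would; with two
replicates per group its p-values are coarse, and the two-fold filter is
doing most of the work (as intended by the calling criterion). The
enrichment model treats bases as exchangeable, ignoring local SNP density
and mappability structure; the distance stratification and LD pruning are
the two confounder controls provided. Dosage r² slightly understates
haplotype r². The screen reports raw p-values by design — the quantity of
interest is the exceedance of the 5% null rate, not individual pairs —
with optional BH columns for users who want them.
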