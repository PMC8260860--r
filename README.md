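# EpiEnrich

Annotation of regulatory regions from replicated histone-mark / CTCF
ChIP-seq peak calls, and base-pair enrichment testing of putative causal
variants (QTL, eQTL, splice QTL, conserved sites) inside those regions.

Most trait-associated variants are non-coding, and linkage disequilibrium
hides which ones are causal. A standard prioritization strategy is to ask
whether candidate causal SNPs are over-represented in functional regions —
ChIP-seq peaks, chromatin states, peaks whose height tracks gene
expression. EpiEnrich implements that analysis chain for anyone working
with multi-tissue, multi-animal epigenomic designs (the defaults mirror a
bovine 6-tissue, 3-animal study layout with autosomes named "1"..."29"-style):

* **Consensus peaks** — positions under a peak in ≥ 2 samples, merged into
  maximal intervals (`consensusPeaks`).
* **Gene activity** — a gene is active in a tissue when all animals have a
  count over 200, inactive when all are under 10; tissue-specific genes are
  active in one tissue and under 10 everywhere else
  (`classifyGeneActivity`, `tissueSpecificActive`); 2-kb promoters and 8-kb
  proximal regions (`buildPromoters`, `buildProximal`).
* **Differential binding** — a peak is differentially bound in a tissue
  when its TMM-normalized signal differs from the mean of the other
  tissues at P < 0.05 and more than two-fold
  (`differentialBindingTest`).
* **Correlation screen** — Pearson correlation of peak height against the
  expression of every gene within 100 kb of the peak anchor
  (`pairPeaksGenes`, `correlatePeakGene`, `correlatedPeakSet`).
* **Enrichment** — the core statistic, for a SNP set against a region set:

  ```
  fold = (C/A) / (B/D)
  ```

  with A = bases under regions, B = SNPs, C = SNPs under regions, D =
  autosomal genome size; one-sided hypergeometric tails P(X ≥ C) and
  P(X ≤ C) for enrichment and depletion (`snpEnrichment`). The same
  arithmetic stratified by 100-kb distance-to-TSS bands up to 1 Mb
  (`distanceStratifiedEnrichment`, bands with < 10 SNPs reported NA) and
  applied to chromatin-state segmentations (`stateOverlapEnrichment`).
* **LD pruning** — windowed thinning so no retained pair within 1 Mb has
  dosage r² ≥ 0.5, with a significance-aware mode that keeps each LD
  region's most significant SNP (`windowPrune`).
* **Synthetic data** — seeded generators for every input (genome, genes,
  replicate peak calls, NB counts with planted tissue effects and
  peak–gene correlations, SNP sets with planted enrichment, block-LD
  genotypes, chromatin-state segmentations), so the whole pipeline runs
  and is tested without external data (`simConfig`, `simulate*`).
* **Pipeline** — `runPipeline()` orchestrates
  simulate → consensus → annotate → diffbind → correlate → enrich → prune
  into a run directory of TSV/BED outputs plus a checksummed, seed-stamped
  manifest; reruns are byte-identical.

## Worked example

Simulate a genome with replicated peak calls and a SNP set planted at
3-fold enrichment inside peaks, then recover the fold:

```r
library(EpiEnrich)
library(GenomicRanges)

cfg  <- simConfig(seed = 42, nChroms = 4, chromLengthBp = 2e6, nGenes = 120,
                  nPeaks = 800, nSnps = 3000, snpRho = 3)
ann  <- simulateAnnotation(cfg)
reps <- simulatePeaks(cfg, ann$genome, nSamples = 6)
cons <- consensusPeaks(reps$samples, ann$genome, minSupport = 2)
names(cons) <- sprintf("peak_%d", seq_along(cons))

snps <- simulateSnps(cfg, ann$genome, cons)$snps
snpEnrichment(snps, cons, ann$genome)
#> EnrichmentResult [simulated_snps in consensus]
#>   A=421713 region bp, B=3000 SNPs, C=461 overlapping, D=8000000 bp
#>   fold=2.915  p(enrich)=2.93e-92  p(deplete)=1
```

The 3000 SNPs were planted so that their density inside the 421,713 bases
of consensus peak is three times the genome-wide average; 461 of them land
in peaks, the fold estimate is 2.92, and the hypergeometric enrichment tail
is vanishingly small. Stratifying by distance to the nearest TSS shows the
enrichment is not an artefact of peaks and SNPs both clustering near genes
— the fold stays near 3 in every populated band:

```r
distanceStratifiedEnrichment(snps, cons, ann$genes, ann$genome)[1:3, ]
#>   lower upper      A    B   C       D  fold
#> 1 0e+00 1e+05 271221 1930 288 5130137 2.823
#> 2 1e+05 2e+05  21681  148  23  400000 2.867
#> 3 2e+05 3e+05  19916  162  25  400000 3.099
```

`runPipeline(outDir, pipelineConfig(sim = cfg))` runs the same stages (plus
counts, differential binding, the correlation screen, state overlap and LD
pruning) end to end and writes every table, BED file and a manifest under
`outDir`.

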