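# darkome

Dark-proteome classification and comparative statistics for
multi-taxon protein datasets.

Surveys of predicted proteomes from poorly characterised eukaryote
lineages (the motivating case: 47 dinoflagellate transcriptomes,
3.37M proteins) consistently find that a large fraction of proteins —
over a third — share no significant sequence similarity with any
functionally characterised database entry. `darkome` is an R package
for classifying these **dark proteins** and computing the statistics
such a survey reports, for researchers doing comparative genomics of
under-annotated lineages.

## The classification

Proteins are clustered into homologous sets (orthogroups) by an
external tool; similarity searches against reference databases give a
per-protein hit flag. The core rule propagates evidence over sets:

* a set *S* is **dark** ⇔ no member of *S* has a significant hit;
  every member of *S* inherits the set's status;
* a singleton is dark ⇔ it has no hit;
* dark ∩ clustered = **high-confidence dark** (recovered in ≥ 2
  sequences, so unlikely to be an assembly artefact);
  dark ∩ singleton = **low-confidence dark**,

so that `#dark = #high + #low` holds exactly. Around the rule the
package provides: dataset QC (redundancy reduction keeping longest
representatives, completeness as conserved-gene recovery, the
inclusion/exclusion rule), the taxon-pairwise dark-set sharing matrix
`M[i,j] = |sets with i and j| / |sets with i|`, single-copy ortholog
selection and supermatrix assembly with occupancy statistics,
Robinson–Foulds tree comparison `RF / 2(n−3)`, Fisher exact
enrichment (two-sided, point-probability method) with
Benjamini–Hochberg correction, GO enrichment with the elimination
correction, a resampling amino-acid composition test, and a
ground-truthed synthetic cohort generator that makes the whole
pipeline testable end to end.

## Worked example

```r
library(darkome)

cfg <- cohort_config(n_taxa = 20, n_orders = 5, n_families = 2000, seed = 42)
res <- run_pipeline(cfg, false_pos = 0, false_neg = 0)
res$summary
#> summary_report: 42042 proteins; 15095 dark ( 35.9 %); 5309 high-confidence / 9786 low-confidence

# zero-noise hits recover the planted truth exactly
sum(res$partition$proteins$dark !=
      res$cohort$truth_dark[res$partition$proteins$protein_id])
#> [1] 0

# lineage-restricted dark families produce within-order sharing blocks
sharing_block_means(res$sharing, res$cohort$order_assignment)
#> $within
#> [1] 0.5847295
#> $between
#> [1] 0.02287524
```

The numbers mean: of 42,042 generated proteins, 35.9% were planted
dark and all of them are recovered by set propagation when the
simulated similarity search makes no errors; a taxon shares on
average ~58% of its dark sets with taxa of its own order but ~2% with
other orders, the block structure that marks dark families as lineage
innovations.

The `analysis/` directory holds the numbered stage drivers
(`01_simulate.R` … `07_report.R`); each is a thin narrative script
over the package functions that prints what it found and writes its
tables under `results/analysis/`.

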