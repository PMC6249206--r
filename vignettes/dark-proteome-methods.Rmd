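---
title: "Methods: dark-proteome classification and its statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dark-proteome classification and its statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkome)
```

## The problem

Large multi-taxon protein surveys — typically predicted proteomes from
dozens of transcriptomes, as in dinoflagellates and other poorly
sampled eukaryote lineages — routinely find that a third or more of
all predicted proteins have no significant similarity to any
functionally characterised database entry. `darkome` implements the
classification of these "dark" proteins and the comparative statistics
that accompany such a survey, on top of inputs produced by standard
external tools (similarity searches in tabular format, graph-based
orthology clustering, domain scans, trees).

## The darkness rule

The unit of classification is the homologous set (orthogroup): a
cluster of two or more putatively homologous proteins. Given a
per-protein hit flag (at least one retained database match after the
e-value filter, default 1e-5, over the union of the reference
databases searched), `classify_darkness()` applies:

* a **set is dark** iff *no* member has a hit;
* a **clustered protein** inherits its set's status — a hit-less
  protein in a set with an annotated member is annotated by
  propagation;
* a **singleton** is dark iff it has no hit;
* dark clustered proteins are the **high-confidence** class (their
  recovery in several sequences argues against assembly artefacts);
  dark singletons are the **low-confidence** class.

This reading of the rule is the one under which the class counts are
additive: dark = high-confidence + low-confidence, which is the
arithmetic a survey's count ledger must satisfy. The alternative
reading — any hit-less member darkens the whole set — would instead
count annotated-by-propagation members as dark; it is available as
`rule = "any_hitless"` for sensitivity analysis, but it breaks the
additivity above and is not the default.

Hit descriptions are screened for informativeness
(`classify_hit_description()`): descriptions containing
"hypothetical", "uncharacterized/-ised", "predicted", "putative", or a
token ending in "-containing"/"-like" are uninformative. A dark
protein that picks up only uninformative matches in a broader database
stays dark; reclassification on informative matches is deliberately
not automatic. Transmembrane annotation is accepted only as the
consensus (logical AND) of two predictors.

## QC rules

`deduplicate_proteins()` reproduces 100%-identity redundancy removal
within one dataset: a sequence identical to, or an exact full-length
substring of, another is collapsed onto the longest representative
(length ties broken by lexicographically smaller identifier, which
makes the reduction deterministic and idempotent). Completeness is
recovery of conserved reference sets — the fraction of reference
proteins hit at e-value at most 1e-10. The dataset-exclusion rule
removes a dataset iff it has fewer than 1000 proteins, or it
simultaneously exceeds all three missing-gene thresholds (80% / 40% /
65% for the three reference collections) *and* recovers under 80% of
the core conserved genes. The four completeness conditions form a
conjunction; each is also exposed via `qc_thresholds()`. Bacterial
contamination (tabular-hit identity strictly above 90%) is reported
but never triggers removal below 1%, since HSP-level identity
overstates full-length identity.

## Sharing of dark sets between taxa

`compute_sharing()` builds the row-normalised co-membership matrix
over the multi-taxon dark sets: `M[i, j]` is the proportion of row
taxon *i*'s sets that also contain taxon *j*. The denominator is the
number of *multi-taxon dark* sets containing the row taxon — this
keeps rows comparable across taxa with very different set counts; pass
any other set collection to get the all-sets variant. The matrix is
asymmetric by construction; the diagonal is 1 for every taxon in at
least one set. Supplying a phylogeny's leaf order as `taxa` reproduces
tree-ordered heat-map layouts.

## Phylogenomics support

`select_single_copy_sets()` keeps sets spanning at least `min_taxa`
(default 10) distinct taxa in which every taxon has exactly one
sequence except at most one taxon with two copies; that taxon's two
sequences are removed from the emitted set (the two copies cannot be
told apart, so neither is trustworthy as *the* ortholog). Sets where
all taxa are strictly single-copy are admitted only under
`allow_strict_single_copy = TRUE`; the default demands the
one-duplicated-taxon pattern, matching the selection that the
supermatrix statistics were defined for.

`overlap_trim()` removes poorly overlapping rows from an alignment: a
residue column of row *s* is good when at least `res_overlap`
(default 0.5) of the *other* rows hold a residue there, and *s* is
kept when good columns are at least `seq_overlap`% (default 50) of its
residue columns. All removals are decided in a single pass against the
original alignment — no cascade — so the result does not depend on row
order.

`build_supermatrix()` concatenates per-set alignments, pads absent
taxa with the undetermined symbol (`-` by default, treated as a gap in
occupancy; configurable), and reports 1-based inclusive partition
boundaries plus per-taxon occupancy = determined cells / total length.
Alignment inference and tree search stay external: the package emits
FASTA and a RAxML-style partition file.

`robinson_foulds()` compares two unrooted leaf-labelled trees as the
size of the symmetric difference of their non-trivial bipartition
sets, normalised by `2(n - 3)`. Branch lengths and support values are
ignored; rooted inputs are handled as unrooted (the two root-child
splits collapse to one).

## Enrichment statistics

`fisher_enrichment()` tests each annotation identifier in a 2x2 table
of foreground versus background-minus-foreground (the foreground is
part of the background universe, so leaving it in the contrast would
count every foreground protein twice; the full-background variant is
available via `subtract_foreground = FALSE`). The two-sided exact
p-value is the point-probability hypergeometric sum — the sum of all
table probabilities not exceeding the observed table's, with a 1e-7
relative tolerance against floating-point ties. Both over- and
under-representation are reported via the sample odds ratio.

Multiple testing uses the Benjamini-Hochberg step-up adjustment
(`bh_adjust()`). One property worth stating precisely: BH is *not*
idempotent as a transformation of p-values — re-adjusting adjusted
values inflates them (e.g. (0.1, 0.9) adjusts to (0.2, 0.9), which
re-adjusts to (0.4, 0.9)) — but its *decisions* are stable:
thresholding the adjusted values at any level reproduces the step-up
rejection rule exactly, which is what the adjustment is for. The test
suite asserts the decision-level property.

A related caveat governs what a clean enrichment run can promise: BH
controls the false discovery *rate*, not the per-run probability of
any false positive. With one strong true enrichment present, the
rank-2 step-up threshold admits a roughly 2.6-sigma null fluctuation,
so on the order of 10% of seeded runs will show one spurious
identifier at `p_adj <= 0.05` even when the generator plants nothing
else. The planted-enrichment checks are therefore phrased per
identifier across runs (no null identifier is repeatedly significant;
the mean false-positive count per run stays well under one), not as
"every run is perfectly clean".

`go_elim_enrichment()` implements the elimination correction for the
GO hierarchy: annotations are first up-propagated along the DAG (the
true-path rule; stated explicitly because input tables usually list
only the most specific terms), terms are tested leaves-first in
reverse topological order, and whenever a term's p-value is at or
below `elim_alpha` its genes are removed from all ancestor terms
before those are tested. `elim_alpha` defaults to 0.01, the customary
default of the elimination method; with `elim_alpha = 0` the
procedure reduces exactly to per-term Fisher tests.

`aa_composition_test()` is the resampling test for composition
differences: per replicate, 100 sequences per group are drawn without
replacement, per-sequence amino-acid proportions are compared by a
two-sample t-test per amino acid, and the 20 p-values are BH-adjusted
*within* the replicate; an amino acid is significant when its
adjusted p is at or below 0.05 in at least 95% of replicates. The
t-test defaults to the Welch (unequal-variance) form — the safer
choice when group variances differ, as they do between short dark and
long annotated proteins; `pooled_variance = TRUE` restores the
textbook pooled form. Amino acids with zero variance in both samples
of a replicate contribute p = 1 for that replicate. The default is
10,000 replicates; the test suite runs 1000, which already stabilises
the >= 95% criterion to within a few replicates.

## The synthetic cohort generator

Every downstream stage is testable without external data because
`generate_cohort()` plants known structure:

* **Scale**: 47 taxa in 8 orders by default (the cohort geometry of
  the survey the package models) with 2000 families as the default
  problem size — about 45,000 proteins, large enough for stable rate
  estimates while keeping a full pipeline run in seconds. The test
  suite uses 20-taxon / 2000-family cohorts (~40,000 proteins) for
  end-to-end checks and smaller ones for unit tests.
* **Rates** (defaults are the study conditions): 63.9% of families
  dark; family sizes 2 + negative-binomial with means 4.26 (dark) and
  36.12 (annotated); 24% of proteins are singletons, 97.13% of them
  dark; dark families confined to a single order with probability 0.9;
  sequence lengths log-normal with medians 109 (dark) and 292
  (annotated) residues and sdlog 0.45.
* **Sequences**: a family founder is drawn i.i.d. per residue from the
  class composition profile; members are copies mutated at 0.1 per
  site, so identity within families is ~90% and clustering structure
  is meaningful. Singletons get fresh founders. The two default
  composition profiles differ mildly in a few residues, mirroring the
  observation that dark and annotated proteins have largely similar
  composition.
* **Annotations**: hit flags flip truth with configurable false
  positive/negative rates; domains are assigned i.i.d. per protein at
  a 1% baseline prevalence (a realistic per-domain rate — the union
  over thousands of domain families is what reaches tens of percent),
  with planted (domain, group, odds-ratio) enrichments realised by
  raising the within-group odds to the target; each domain maps to a
  term in a randomly generated acyclic hierarchy whose edges always
  point to lower term indices.
* **Determinism**: one integer seed; each stage derives its own
  sub-stream from it, so cohorts are byte-identical across runs and
  stages can be re-run in isolation.

Parameterisation note: the generator is sized by `n_families` rather
than by a per-taxon protein count; the expected cohort size is
`n_families x mean family size / (1 - singleton_fraction)`, and
per-taxon counts follow from the taxon-assignment process. A separate
`dark_singleton_fraction` controls singleton darkness, since family
darkness alone says nothing about unclustered proteins. The paper-free
parameters (family-size dispersion 1.5, length sdlog 0.45, mutation
rate 0.1, domain prevalence 0.01) are fixed once at values a
transcriptome survey would call realistic and are not tuned.

What the generator does **not** emulate: codon-level transcripts or
splice structure, realistic similarity-score distributions (hits are
Bernoulli flips of truth), sequencing error, contamination, or
homology detectable only by alignment (members are positionally
mutated copies, so family structure is exact). Consequently, passing
tests show that the classification, bookkeeping and statistics are
correct given their inputs — not that any upstream search or
clustering tool is well configured for real data.

## Numerical conventions and degenerate inputs

Displayed ratios are rounded half-up (`round_half_up()`, `percent()`):
base R's round-half-to-even differs at exact ties, and half-up is the
convention under which every printed ratio in the modelled survey's
ledger reproduces. Unrounded values are always retained alongside.
Count identities (dark = high + low; clustered + singletons = total;
dark sets + annotated sets = all sets; multi-taxon + taxon-specific =
dark sets; mean size x set count = member count) are asserted before
rounding in `build_summary()`. Empty classes yield `NA` means rather
than 0; empty set collections, empty reference sets, universe
mismatches and malformed input rows are errors, with line numbers
where a file is involved. All readers reject rather than repair.

## Known limitations

* The darkness rule needs a complete hit-flag universe; proteins
  missing from the flags are an error, not silently annotated.
* Substring-aware deduplication is quadratic in the worst case
  (mitigated by length-bucketed search); it targets per-dataset use,
  not cross-cohort pools.
* The single-copy selection with 10+ taxa rarely admits *dark* sets
  in scaled-down synthetic cohorts — dark families average 4.26
  members — so the dark share of selected sets is only informative at
  survey scale.
* GO elimination follows the classic algorithm but processes terms in
  one reverse-topological sweep; ties between equally deep siblings
  are resolved by term order, as in the reference implementation's
  level-wise processing.
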