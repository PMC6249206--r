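#!/usr/bin/env Rscript
# Stage 5: phylogenomics support. Single-copy set selection (>= 10 taxa,
# at most one taxon duplicated, the duplicated taxon dropped), overlap
# trimming, supermatrix assembly with occupancy statistics, and a
# Robinson-Foulds comparison of trees built from dark versus annotated
# co-membership profiles. Sequence alignment itself is outside this
# pipeline; member sequences are right-padded to equal length, which
# suffices for occupancy and partition bookkeeping.

suppressPackageStartupMessages(library(darkome))
suppressPackageStartupMessages(library(ape))
out <- "results/analysis"

cfg <- cohort_config(seed = 20260929)
cohort <- generate_cohort(cfg)
clusters <- truth_clusters(cohort)
hits <- generate_hit_table(cohort, false_pos = 0.03, false_neg = 0.02)
partition <- classify_darkness(clusters, hits)

sel <- select_single_copy_sets(clusters, min_taxa = 10)
n_sel <- nrow(sel$selection)
dark_flag <- setNames(partition$sets$dark, partition$sets$set_id)
n_dark_sel <- sum(dark_flag[sel$selection$set_id])
cat("single-copy sets:", n_sel, "selected;", n_dark_sel,
    sprintf("dark (%.1f%%)\n",
            if (n_sel > 0) 100 * n_dark_sel / n_sel else NA))
write.table(sel$selection, file.path(out, "05_single_copy_sets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

if (n_sel >= 2) {
  seq_of <- setNames(cohort$proteins$sequence, cohort$proteins$protein_id)
  alns <- lapply(split(sel$members, sel$members$set_id), function(m) {
    s <- seq_of[m$protein_id]
    w <- max(nchar(s))
    setNames(paste0(s, strrep("-", w - nchar(s))), m$taxon_id)
  })
  alns <- lapply(alns, function(a) overlap_trim(a, 0.5, 50)$alignment)
  alns <- alns[vapply(alns, length, 1L) >= 2]
  sm <- build_supermatrix(alns, taxa = names(cohort$order_assignment))
  print(sm)
  cat(sprintf("mean per-taxon contribution: %.2f%% (undetermined %.2f%%)\n",
              100 * mean(sm$occupancy), 100 * (1 - mean(sm$occupancy))))
  write_partitions(sm, file.path(out, "05_partitions.txt"))
  write_fasta(data.frame(protein_id = names(sm$sequences),
                         sequence = unname(sm$sequences)),
              file.path(out, "05_supermatrix.fasta"))
}

# trees from dark vs annotated co-membership sharing; distance is
# 1 - symmetrised sharing
tree_from_sets <- function(set_ids) {
  M <- compute_sharing(clusters$sets[clusters$sets$set_id %in% set_ids, ],
                       taxa = names(cohort$order_assignment))
  nj(as.dist(1 - (M + t(M)) / 2))
}
dark_multi <- partition$sets$set_id[partition$sets$dark &
                                      partition$sets$n_taxa >= 2]
ann_multi <- partition$sets$set_id[!partition$sets$dark &
                                     partition$sets$n_taxa >= 2]
t_dark <- tree_from_sets(dark_multi)
t_ann <- tree_from_sets(ann_multi)
write_newick(t_dark, file.path(out, "05_tree_dark.nwk"))
write_newick(t_ann, file.path(out, "05_tree_annotated.nwk"))
rf <- robinson_foulds(t_dark, t_ann)
cat(sprintf("dark-set vs annotated-set tree: RF = %d (normalised %.2f)\n",
            rf$rf, rf$normalised))
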