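#' @title Summary reporting and pipeline orchestration
#' @description Computes every headline summary number of a
#'   dark-proteome survey from the underlying counts, with half-up
#'   display rounding and the count identities asserted before rounding,
#'   and orchestrates the full pipeline on a synthetic cohort.
#' @name reporting
NULL

#' Build the summary report
#'
#' Derives the headline statistics of a darkness partition and asserts
#' the count identities before any rounding: dark = high + low;
#' proteins = clustered + singletons; sets = dark + annotated sets;
#' multi-taxon + taxon-specific = dark sets; mean set size x set count
#' = member count per class.
#'
#' @param partition a [classify_darkness()] result.
#' @param selection optional [select_single_copy_sets()] result; adds
#'   the fraction of selected sets that are dark.
#' @param features optional named logical vector over the
#'   high-confidence dark proteins (conserved structural feature
#'   present); adds the annotated-feature percentage.
#' @return object of class `summary_report`: a list of named scalars
#'   (unrounded) plus a `display` list with the conventional roundings.
#' @export
build_summary <- function(partition, selection = NULL, features = NULL) {
  stopifnot(inherits(partition, "darkness_partition"))
  p <- partition$proteins
  s <- partition$sets

  n_proteins <- nrow(p)
  n_dark <- sum(p$dark)
  n_high <- sum(p$class == "high_confidence_dark")
  n_low <- sum(p$class == "low_confidence_dark")
  n_clustered <- sum(p$clustered)
  n_singletons <- sum(!p$clustered)
  n_sets <- nrow(s)
  n_dark_sets <- sum(s$dark)
  spec <- partition_set_specificity(partition)
  sizes <- set_size_statistics(partition)

  stopifnot(n_dark == n_high + n_low,
            n_proteins == n_clustered + n_singletons,
            n_sets == n_dark_sets + sizes$n_annotated_sets,
            spec$n_multi_taxon + spec$n_taxon_specific == n_dark_sets,
            sizes$n_dark_members == n_high ||
              is.na(sizes$mean_dark))
  if (!is.na(sizes$mean_dark)) {
    stopifnot(abs(sizes$mean_dark * sizes$n_dark_sets -
                    sizes$n_dark_members) < 1e-6)
  }

  per_taxon <- tapply(p$dark, p$taxon_id, mean)
  dark_singletons <- sum(!p$clustered & p$dark)

  rep_ <- list(
    n_proteins = n_proteins,
    n_dark = n_dark,
    n_high_confidence = n_high,
    n_low_confidence = n_low,
    n_clustered = n_clustered,
    n_singletons = n_singletons,
    n_sets = n_sets,
    n_dark_sets = n_dark_sets,
    n_multi_taxon_dark_sets = spec$n_multi_taxon,
    n_taxon_specific_dark_sets = spec$n_taxon_specific,
    mean_dark_set_size = sizes$mean_dark,
    mean_annotated_set_size = sizes$mean_annotated,
    dark_fraction = n_dark / n_proteins,
    per_taxon_dark_fraction = as.list(per_taxon))
  disp <- list(
    dark_pct = percent(n_dark, n_proteins, 2),
    high_confidence_pct = percent(n_high, n_proteins, 1),
    high_of_clustered_pct = if (n_clustered > 0)
      percent(n_high, n_clustered, 2) else NA_real_,
    low_of_singletons_pct = if (n_singletons > 0)
      percent(dark_singletons, n_singletons, 2) else NA_real_,
    dark_set_pct = if (n_sets > 0)
      percent(n_dark_sets, n_sets, 1) else NA_real_,
    multi_taxon_pct = if (n_dark_sets > 0)
      percent(spec$n_multi_taxon, n_dark_sets, 2) else NA_real_,
    mean_dark_set_size = sizes$mean_dark_2dp,
    mean_annotated_set_size = sizes$mean_annotated_2dp)

  if (!is.null(selection)) {
    sel_ids <- selection$selection$set_id
    dark_flag <- stats::setNames(s$dark, s$set_id)[sel_ids]
    if (anyNA(dark_flag)) {
      stop("build_summary(): selected set(s) outside the partition: ",
           paste(utils::head(sel_ids[is.na(dark_flag)], 5), collapse = ", "))
    }
    rep_$n_selected_sets <- length(sel_ids)
    rep_$n_dark_selected_sets <- sum(dark_flag)
    disp$dark_selected_pct <- if (length(sel_ids) > 0)
      percent(sum(dark_flag), length(sel_ids), 1) else NA_real_
  }
  if (!is.null(features)) {
    high_ids <- p$protein_id[p$class == "high_confidence_dark"]
    absent <- setdiff(high_ids, names(features))
    if (length(absent)) {
      stop("build_summary(): feature flags missing for protein(s): ",
           paste(utils::head(absent, 5), collapse = ", "))
    }
    rep_$n_feature_annotated <- sum(features[high_ids])
    disp$feature_annotated_pct <- if (length(high_ids) > 0)
      percent(sum(features[high_ids]), length(high_ids), 1) else NA_real_
  }
  rep_$display <- disp
  class(rep_) <- "summary_report"
  rep_
}

#' @export
print.summary_report <- function(x, ...) {
  cat("summary_report:", x$n_proteins, "proteins;",
      x$n_dark, "dark (", x$display$dark_pct, "%);",
      x$n_high_confidence, "high-confidence /",
      x$n_low_confidence, "low-confidence\n")
  invisible(x)
}

#' Write a summary report
#'
#' Serialises a report as JSON (unrounded values plus display
#' roundings) and as a two-column TSV of the scalar statistics.
#'
#' @param report a [build_summary()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_summary <- function(report, dir) {
  stopifnot(inherits(report, "summary_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  scal <- report[!vapply(report, is.list, TRUE)]
  utils::write.table(
    data.frame(statistic = names(scal), value = unlist(scal)),
    file.path(dir, "summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Stages run in order: cohort generation, hit simulation, redundancy
#' QC check, darkness classification over the truth-consistent
#' clusters, sharing matrix over the multi-taxon dark sets, single-copy
#' set selection, optional planted-domain enrichment, and the summary
#' report. Re-running with an identical configuration reproduces
#' identical outputs.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory; when given, stage outputs are
#'   written there as TSV/JSON.
#' @param false_pos,false_neg hit-simulation error rates.
#' @param min_taxa single-copy selection threshold.
#' @return list with elements `cohort`, `hits`, `partition`, `sharing`,
#'   `selection`, `enrichment` (`NULL` unless enrichments were
#'   planted), `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL, false_pos = 0,
                         false_neg = 0, min_taxa = 10) {
  stopifnot(inherits(config, "cohort_config"))
  cohort <- generate_cohort(config)
  hits <- generate_hit_table(cohort, false_pos, false_neg,
                             seed = config$seed)
  clusters <- truth_clusters(cohort)
  partition <- classify_darkness(clusters, hits)
  dark_multi <- partition$sets$set_id[partition$sets$dark &
                                        partition$sets$n_taxa >= 2L]
  sharing <- if (length(dark_multi)) {
    compute_sharing(
      clusters$sets[clusters$sets$set_id %in% dark_multi, , drop = FALSE],
      taxa = names(cohort$order_assignment))
  } else NULL
  selection <- select_single_copy_sets(clusters, min_taxa = min_taxa)
  enrichment <- NULL
  if (!is.null(config$planted_enrichments)) {
    annot <- generate_domain_annotations(cohort, config)
    groups <- cohort$order_assignment[cohort$proteins$taxon_id]
    fg_group <- config$planted_enrichments$group[1]
    fg <- cohort$proteins$protein_id[groups == fg_group]
    enrichment <- fisher_enrichment(
      stats::setNames(annot$domains, c("protein_id", "identifier")),
      fg, cohort$proteins$protein_id)
  }
  summary <- build_summary(partition, selection = selection)
  out <- list(cohort = cohort, hits = hits, partition = partition,
              sharing = sharing, selection = selection,
              enrichment = enrichment, summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    utils::write.table(partition$proteins,
                       file.path(out_dir, "darkness_proteins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(partition$sets,
                       file.path(out_dir, "darkness_sets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sharing)) {
      utils::write.table(as.data.frame(sharing),
                         file.path(out_dir, "sharing_matrix.tsv"),
                         sep = "\t", quote = FALSE, row.names = TRUE)
    }
    utils::write.table(selection$selection,
                       file.path(out_dir, "single_copy_selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enrichment)) {
      utils::write.table(enrichment,
                         file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_summary(summary, out_dir)
  }
  out
}
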