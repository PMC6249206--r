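#' @title Darkness classification over homology clusters
#' @description The core classification: a protein is "dark" (of unknown
#'   function) when neither it nor any member of its homologous set has a
#'   significant database match. Clustered dark proteins form the
#'   high-confidence class (supported by recovery in multiple sequences);
#'   dark singletons form the low-confidence class.
#' @name homology_darkness
NULL

#' Classify proteins as dark or annotated
#'
#' Under the default rule (`"all_hitless"`) a homologous set is dark iff
#' none of its members has a database hit, and every member inherits the
#' set's status; a singleton is dark iff it has no hit. Dark clustered
#' proteins are `high_confidence_dark`, dark singletons
#' `low_confidence_dark`. The alternative literal rule (`"any_hitless"`)
#' darkens a set as soon as any member lacks a hit and is provided for
#' sensitivity analysis.
#'
#' @param clusters a [cluster_table()].
#' @param hit_flags named logical vector (or data.frame with
#'   `protein_id`, `hit`): does each protein have a significant match?
#' @param rule `"all_hitless"` (default) or `"any_hitless"`.
#' @return object of class `darkness_partition`: list with `proteins`
#'   (data.frame `protein_id`, `taxon_id`, `clustered`, `dark`, `class`)
#'   and `sets` (data.frame `set_id`, `size`, `n_taxa`, `dark`,
#'   `taxon_specific`).
#' @export
classify_darkness <- function(clusters, hit_flags,
                              rule = c("all_hitless", "any_hitless")) {
  rule <- match.arg(rule)
  stopifnot(inherits(clusters, "cluster_table"))
  if (is.data.frame(hit_flags)) {
    hit_flags <- stats::setNames(as.logical(hit_flags$hit),
                                 hit_flags$protein_id)
  }
  all_ids <- c(clusters$sets$protein_id, clusters$singletons$protein_id)
  absent <- setdiff(all_ids, names(hit_flags))
  if (length(absent)) {
    stop("classify_darkness(): no hit flag for protein(s): ",
         paste(utils::head(absent, 5), collapse = ", "))
  }

  s <- clusters$sets
  hit_s <- unname(hit_flags[s$protein_id])
  n_hits_per_set <- tapply(hit_s, s$set_id, sum)
  n_members <- tapply(rep(1L, nrow(s)), s$set_id, sum)
  set_dark <- if (rule == "all_hitless") {
    n_hits_per_set == 0L
  } else {
    n_hits_per_set < n_members
  }
  n_taxa_per_set <- tapply(s$taxon_id, s$set_id,
                           function(x) length(unique(x)))
  sets <- data.frame(set_id = names(n_members),
                     size = as.integer(n_members),
                     n_taxa = as.integer(n_taxa_per_set[names(n_members)]),
                     dark = unname(set_dark[names(n_members)]),
                     stringsAsFactors = FALSE)
  sets$taxon_specific <- sets$dark & sets$n_taxa == 1L

  p_clustered <- data.frame(
    protein_id = s$protein_id, taxon_id = s$taxon_id,
    clustered = rep(TRUE, nrow(s)),
    dark = unname(set_dark[s$set_id]) %||% logical(0),
    stringsAsFactors = FALSE)
  sing <- clusters$singletons
  p_single <- data.frame(
    protein_id = sing$protein_id, taxon_id = sing$taxon_id,
    clustered = rep(FALSE, nrow(sing)),
    dark = !unname(hit_flags[sing$protein_id]),
    stringsAsFactors = FALSE)
  proteins <- rbind(p_clustered, p_single)
  proteins$class <- ifelse(!proteins$dark, "annotated",
                           ifelse(proteins$clustered,
                                  "high_confidence_dark",
                                  "low_confidence_dark"))
  structure(list(proteins = proteins, sets = sets, rule = rule),
            class = "darkness_partition")
}

#' @export
print.darkness_partition <- function(x, ...) {
  cat("darkness_partition:", nrow(x$proteins), "proteins;",
      sum(x$proteins$dark), "dark (",
      sum(x$proteins$class == "high_confidence_dark"), "high-confidence,",
      sum(x$proteins$class == "low_confidence_dark"), "low-confidence);",
      sum(x$sets$dark), "of", nrow(x$sets), "sets dark\n")
  invisible(x)
}

#' Multi-taxon versus taxon-specific dark sets
#'
#' @param partition a [classify_darkness()] result.
#' @return list with `n_multi_taxon` (dark sets spanning >= 2 taxa) and
#'   `n_taxon_specific` (dark sets confined to one taxon); the two sum
#'   to the number of dark sets.
#' @export
partition_set_specificity <- function(partition) {
  stopifnot(inherits(partition, "darkness_partition"))
  d <- partition$sets[partition$sets$dark, , drop = FALSE]
  list(n_multi_taxon = sum(d$n_taxa >= 2L),
       n_taxon_specific = sum(d$n_taxa == 1L))
}

#' Mean sizes of dark and annotated sets
#'
#' Computed as member count / set count per class; returns the unrounded
#' values alongside a 2-decimal half-up display rounding. An empty class
#' yields `NA` with a note rather than a number.
#'
#' @param partition a [classify_darkness()] result, or a data.frame of
#'   sets with `size` and `dark` columns.
#' @return list with `mean_dark`, `mean_annotated` (unrounded),
#'   `mean_dark_2dp`, `mean_annotated_2dp`, and counts.
#' @export
set_size_statistics <- function(partition) {
  sets <- if (inherits(partition, "darkness_partition")) {
    partition$sets
  } else partition
  stopifnot(all(c("size", "dark") %in% names(sets)))
  mean_of <- function(sub) {
    if (nrow(sub) == 0L) NA_real_ else sum(sub$size) / nrow(sub)
  }
  md <- mean_of(sets[sets$dark, , drop = FALSE])
  ma <- mean_of(sets[!sets$dark, , drop = FALSE])
  list(mean_dark = md, mean_annotated = ma,
       mean_dark_2dp = if (is.na(md)) NA_real_ else round_half_up(md, 2),
       mean_annotated_2dp = if (is.na(ma)) NA_real_ else round_half_up(ma, 2),
       n_dark_sets = sum(sets$dark), n_annotated_sets = sum(!sets$dark),
       n_dark_members = sum(sets$size[sets$dark]),
       n_annotated_members = sum(sets$size[!sets$dark]))
}

#' Is a database hit description informative?
#'
#' A description is uninformative when (case-insensitively) it contains
#' "hypothetical", "uncharacterized"/"uncharacterised", "predicted",
#' "putative", or a token ending in "-containing" or "-like".
#'
#' @param description character vector of hit descriptions.
#' @return logical vector: `TRUE` when informative.
#' @export
classify_hit_description <- function(description) {
  d <- tolower(description)
  uninformative <-
    stri_detect_regex(d, "hypothetical|uncharacteri[sz]ed|predicted|putative") |
    stri_detect_regex(d, "\\S+-(containing|like)\\b")
  !uninformative
}

#' Consensus transmembrane calls
#'
#' A protein is considered transmembrane only when both predictors agree
#' (logical AND).
#'
#' @param flags_a,flags_b named logical vectors over the same proteins.
#' @return named logical vector.
#' @export
consensus_transmembrane <- function(flags_a, flags_b) {
  if (!setequal(names(flags_a), names(flags_b))) {
    stop("consensus_transmembrane(): protein universes differ")
  }
  flags_a & flags_b[names(flags_a)]
}
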