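#' @title Dataset QC: redundancy reduction, completeness, contamination
#' @description Per-dataset quality control mirroring a multi-taxon
#'   transcriptome survey: exact-redundancy removal keeping the longest
#'   representative, completeness scored as recovery of conserved
#'   reference gene sets, flagging of putative bacterial contaminants,
#'   and the dataset inclusion/exclusion rule.
#' @name qc_filtering
NULL

#' Remove redundant protein sequences within one dataset
#'
#' Removes sequences that are identical to, or exact full-length
#' substrings of, another sequence in the same dataset, keeping the
#' longest member of each identity group (length ties broken by
#' lexicographically smaller identifier). This reproduces 100%-identity
#' clustering with longest-representative selection.
#'
#' @param records data.frame of protein records (one taxon).
#' @return list with `retained` (data.frame, input order preserved) and
#'   `removed` (data.frame `protein_id`, `representative_id`).
#' @export
deduplicate_proteins <- function(records) {
  stopifnot(all(c("protein_id", "sequence") %in% names(records)))
  if ("taxon_id" %in% names(records) &&
      length(unique(records$taxon_id)) > 1L) {
    stop("deduplicate_proteins(): records span multiple taxa: ",
         paste(unique(records$taxon_id), collapse = ", "))
  }
  n <- nrow(records)
  if (n <= 1L) {
    return(list(retained = records,
                removed = data.frame(protein_id = character(),
                                     representative_id = character(),
                                     stringsAsFactors = FALSE)))
  }
  seq_ <- records$sequence
  id_ <- records$protein_id
  # exact duplicates: keep the lexicographically smallest id per sequence
  o <- order(seq_, id_)
  first_of_seq <- !duplicated(seq_[o])
  rep_of <- stats::setNames(rep(id_[o][first_of_seq],
                                times = diff(c(which(first_of_seq),
                                               length(o) + 1L))),
                            id_[o])
  removed_dup <- id_[rep_of[id_] != id_]

  # substring containment among distinct sequences, longest first
  uniq_idx <- which(!(id_ %in% removed_dup))
  ulen <- nchar(seq_[uniq_idx])
  ord <- uniq_idx[order(-ulen, id_[uniq_idx])]
  usq <- seq_[ord]
  uid <- id_[ord]
  uln <- nchar(usq)
  contained_in <- rep(NA_character_, length(ord))
  # for each distinct length, search against the concatenation of all
  # strictly longer sequences ('#' separator prevents cross-boundary hits)
  lens <- unique(uln)
  for (L in lens[-1]) {
    longer <- which(uln > L)
    hay <- paste(usq[longer], collapse = "#")
    offs <- cumsum(nchar(usq[longer]) + 1L)
    qs <- which(uln == L)
    loc <- stri_locate_first_fixed(hay, usq[qs])
    found <- !is.na(loc[, 1])
    if (any(found)) {
      host <- findInterval(loc[found, 1] - 1L, c(0L, offs),
                           rightmost.closed = FALSE)
      contained_in[qs[found]] <- uid[longer][host]
    }
  }
  removed_sub <- uid[!is.na(contained_in)]
  rep_sub <- stats::setNames(contained_in[!is.na(contained_in)], removed_sub)

  removed_ids <- c(removed_dup, removed_sub)
  # representative of an exact duplicate may itself be substring-removed;
  # follow one level (substring hosts are never removed themselves)
  rep_all <- c(rep_of[removed_dup], rep_sub)
  lift <- rep_all %in% removed_sub
  rep_all[lift] <- rep_sub[rep_all[lift]]
  keep <- !(id_ %in% removed_ids)
  retained <- records[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       removed = data.frame(protein_id = removed_ids,
                            representative_id = unname(rep_all),
                            stringsAsFactors = FALSE))
}

#' Completeness as recovery of a conserved reference set
#'
#' A reference protein is recovered when at least one query from the
#' dataset hits it at or below the e-value threshold.
#'
#' @param hits hit table (queries = dataset proteins, subjects =
#'   reference proteins).
#' @param reference_ids identifiers of the full reference set.
#' @param max_evalue significance threshold.
#' @return list with `recovery`, `missing` (= 1 - recovery),
#'   `n_recovered`, `n_reference`.
#' @export
assess_completeness <- function(hits, reference_ids, max_evalue = 1e-10) {
  if (length(reference_ids) == 0L) {
    stop("assess_completeness(): empty reference set")
  }
  sig <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  nrec <- length(intersect(unique(sig$subject_id), reference_ids))
  list(recovery = nrec / length(reference_ids),
       missing = 1 - nrec / length(reference_ids),
       n_recovered = nrec, n_reference = length(reference_ids))
}

#' Flag putative bacterial contaminants
#'
#' Queries matching a bacterial reference at strictly greater than the
#' identity threshold are flagged; matches at exactly the threshold are
#' not.
#'
#' @param hits hit table versus a bacterial reference.
#' @param n_proteins total proteins in the dataset (denominator).
#' @param min_identity strict identity threshold (percent).
#' @return list with `fraction`, `flagged` (query ids), `n_flagged`.
#' @export
flag_bacterial <- function(hits, n_proteins, min_identity = 90) {
  stopifnot(n_proteins >= 0)
  flagged <- unique(hits$query_id[hits$percent_identity > min_identity])
  frac <- if (n_proteins > 0) length(flagged) / n_proteins else 0
  list(fraction = frac, flagged = flagged, n_flagged = length(flagged))
}

#' Default dataset-exclusion thresholds
#'
#' @return list of thresholds used by [filter_datasets()]: minimum
#'   protein count 1000; missing-gene thresholds 0.80 / 0.40 / 0.65 for
#'   the three reference sets; minimum conserved-gene recovery 0.80.
#' @export
qc_thresholds <- function() {
  list(min_proteins = 1000,
       busco_missing_max = c(alveolata_stramenopiles = 0.80,
                             eukaryota = 0.40,
                             protists = 0.65),
       ceg_recovery_min = 0.80)
}

#' Apply the dataset inclusion/exclusion rule
#'
#' A dataset is removed iff it has fewer than `min_proteins` proteins, or
#' it simultaneously exceeds all three missing-gene thresholds and falls
#' below the conserved-gene recovery threshold (a conjunction). The
#' bacterial-contamination fraction is reported but never triggers
#' removal below 1%.
#'
#' @param qc data.frame with one row per dataset: `taxon_id`,
#'   `n_proteins`, three `missing_*` columns in the order of
#'   `thresholds$busco_missing_max`, `ceg_recovery`, and optionally
#'   `bacterial_fraction`.
#' @param thresholds see [qc_thresholds()].
#' @return `qc` with added columns `decision` (`"retain"`/`"remove"`)
#'   and `reasons` (comma-separated).
#' @export
filter_datasets <- function(qc, thresholds = qc_thresholds()) {
  need <- c("taxon_id", "n_proteins", "ceg_recovery")
  miss_cols <- grep("^missing_", names(qc), value = TRUE)
  if (!all(need %in% names(qc)) || length(miss_cols) != 3L) {
    stop("filter_datasets(): qc needs taxon_id, n_proteins, ceg_recovery ",
         "and exactly three missing_* columns")
  }
  if (anyNA(qc[c(need, miss_cols)])) {
    stop("filter_datasets(): missing QC field(s) for taxon ",
         qc$taxon_id[which(rowSums(is.na(qc[c(need, miss_cols)])) > 0)[1]])
  }
  too_small <- qc$n_proteins < thresholds$min_proteins
  mm <- thresholds$busco_missing_max
  incomplete <- rep(TRUE, nrow(qc))
  for (k in 1:3) incomplete <- incomplete & (qc[[miss_cols[k]]] > mm[[k]])
  incomplete <- incomplete & (qc$ceg_recovery < thresholds$ceg_recovery_min)
  qc$decision <- ifelse(too_small | incomplete, "remove", "retain")
  qc$reasons <- ""
  qc$reasons[too_small] <- "min_proteins"
  qc$reasons[incomplete] <- trimws(paste(qc$reasons[incomplete],
                                         "incomplete"), "left")
  qc$reasons[incomplete & too_small] <- "min_proteins,incomplete"
  qc
}
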