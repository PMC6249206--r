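#' @title Readers and writers for external formats
#' @description Strict readers for the formats the pipeline ingests:
#'   protein FASTA, tabular similarity-search results (12/13-column
#'   tab-separated), cluster membership tables (orthogroup and CD-HIT
#'   dialects) and Newick trees. Readers reject malformed input rather
#'   than repairing it, and error messages carry line numbers.
#' @name io_formats
NULL

# Amino-acid letters accepted in protein sequences.
AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Namespace protein identifiers by taxon
#'
#' Internal identifiers are `"taxon|local_id"` so that identifiers remain
#' globally unique when many per-taxon datasets are pooled.
#'
#' @param taxon_id taxon label (no `|`).
#' @param local_id per-dataset protein identifier.
#' @return character vector of namespaced identifiers.
#' @export
namespace_id <- function(taxon_id, local_id) {
  if (any(grepl("|", taxon_id, fixed = TRUE))) {
    stop("taxon_id must not contain '|'")
  }
  paste0(taxon_id, "|", local_id)
}

#' Split namespaced protein identifiers
#'
#' @param protein_id identifiers of the form `"taxon|local"`; identifiers
#'   without a `|` yield `NA` taxon.
#' @return data.frame with columns `taxon_id`, `local_id`.
#' @export
split_protein_id <- function(protein_id) {
  has_ns <- grepl("|", protein_id, fixed = TRUE)
  taxon <- ifelse(has_ns, sub("\\|.*$", "", protein_id), NA_character_)
  local <- ifelse(has_ns, sub("^[^|]*\\|", "", protein_id), protein_id)
  data.frame(taxon_id = taxon, local_id = local, stringsAsFactors = FALSE)
}

#' Read a protein FASTA file
#'
#' Records preserve input order; a single trailing `*` stop symbol is
#' stripped. Sequences may contain the 20 standard amino-acid letters plus
#' any letters in `allow`; anything else is rejected. Duplicate identifiers
#' and empty sequences are errors.
#'
#' @param path FASTA file.
#' @param taxon_id taxon of origin for every record; if `NULL`, taken from
#'   a `taxon|local` namespaced header when present.
#' @param allow extra letters tolerated beyond the 20 standard ones.
#' @return data.frame with columns `protein_id`, `taxon_id`, `sequence`,
#'   `length`.
#' @export
read_fasta <- function(path, taxon_id = NULL, allow = "X") {
  if (!file.exists(path)) stop("read_fasta(): no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("read_fasta(): duplicate identifier(s) in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  seqs <- as.character(aa)
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs))) {
    stop("read_fasta(): empty sequence for id(s): ",
         paste(utils::head(ids[!nzchar(seqs)], 5), collapse = ", "))
  }
  ok <- c(AA_STANDARD, strsplit(paste(allow, collapse = ""), "")[[1]])
  bad <- !stri_detect_regex(seqs, paste0("^[", paste(ok, collapse = ""), "]+$"))
  if (any(bad)) {
    stop("read_fasta(): non-standard letters in sequence(s): ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  }
  if (is.null(taxon_id)) {
    taxon <- split_protein_id(ids)$taxon_id
  } else {
    stopifnot(length(taxon_id) == 1L)
    taxon <- rep(taxon_id, length(ids))
  }
  data.frame(protein_id = ids, taxon_id = taxon, sequence = seqs,
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write protein records as FASTA
#'
#' @param records data.frame with `protein_id` and `sequence` columns.
#' @param path output file.
#' @param width line-wrap width (columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- records$protein_id
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

BLAST6_COLS <- c("query_id", "subject_id", "percent_identity", "aln_length",
                 "mismatches", "gap_opens", "q_start", "q_end", "s_start",
                 "s_end", "evalue", "bitscore")

#' Read tabular similarity-search results
#'
#' Parses the 12-column tab-separated tabular dialect (an optional 13th
#' column is kept as `subject_description`) and drops rows whose e-value
#' exceeds `max_evalue`. Non-numeric e-value fields are an error reported
#' with their line number.
#'
#' @param path tab-separated hits file.
#' @param max_evalue retain rows with `evalue <= max_evalue`.
#' @return data.frame of retained hits, with an attribute `n_dropped`
#'   giving the number of rows removed by the e-value filter.
#' @export
read_tabular_hits <- function(path, max_evalue = Inf) {
  if (!file.exists(path)) stop("read_tabular_hits(): no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 13)),
      c(BLAST6_COLS, "subject_description"))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop("read_tabular_hits(): line ", which(nf < 12L)[1],
         " has ", nf[nf < 12L][1], " fields (expected 12 or 13)")
  }
  ev <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 11L)))
  if (anyNA(ev)) {
    stop("read_tabular_hits(): non-numeric e-value at line ", which(is.na(ev))[1])
  }
  if (any(ev < 0)) {
    stop("read_tabular_hits(): negative e-value at line ", which(ev < 0)[1])
  }
  out <- data.frame(
    query_id         = vapply(fields, `[[`, "", 1L),
    subject_id       = vapply(fields, `[[`, "", 2L),
    percent_identity = as.numeric(vapply(fields, `[[`, "", 3L)),
    aln_length       = as.integer(vapply(fields, `[[`, "", 4L)),
    mismatches       = as.integer(vapply(fields, `[[`, "", 5L)),
    gap_opens        = as.integer(vapply(fields, `[[`, "", 6L)),
    q_start          = as.integer(vapply(fields, `[[`, "", 7L)),
    q_end            = as.integer(vapply(fields, `[[`, "", 8L)),
    s_start          = as.integer(vapply(fields, `[[`, "", 9L)),
    s_end            = as.integer(vapply(fields, `[[`, "", 10L)),
    evalue           = ev,
    bitscore         = as.numeric(vapply(fields, `[[`, "", 12L)),
    subject_description = vapply(
      fields, function(f) if (length(f) >= 13L) f[[13L]] else NA_character_, ""),
    stringsAsFactors = FALSE)
  keep <- out$evalue <= max_evalue
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Best hit per query
#'
#' Reduces a hit table to one row per query: lowest e-value, ties broken by
#' highest bitscore, then by lexicographically smallest subject identifier.
#'
#' @param hits data.frame as returned by [read_tabular_hits()].
#' @return data.frame with one row per distinct `query_id`.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$query_id, hits$evalue, -hits$bitscore, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Construct a cluster table
#'
#' A cluster table holds homologous sets of two or more proteins (long
#' format: one row per member) plus the unclustered singletons. Every
#' protein may appear at most once across sets and singletons; sets of one
#' member are moved to the singleton list.
#'
#' @param members data.frame with columns `set_id`, `taxon_id`,
#'   `protein_id`.
#' @param singletons data.frame with columns `taxon_id`, `protein_id`
#'   (may be empty).
#' @return an object of class `cluster_table` with elements `sets` and
#'   `singletons`.
#' @export
cluster_table <- function(members, singletons = NULL) {
  stopifnot(all(c("set_id", "taxon_id", "protein_id") %in% names(members)))
  if (is.null(singletons)) {
    singletons <- data.frame(taxon_id = character(), protein_id = character(),
                             stringsAsFactors = FALSE)
  }
  if (anyDuplicated(members$protein_id) &&
      anyDuplicated(unique(members[c("set_id", "protein_id")])$protein_id)) {
    dup <- members$protein_id[duplicated(members$protein_id)]
    in2 <- unique(members[c("set_id", "protein_id")])
    dup2 <- unique(in2$protein_id[duplicated(in2$protein_id)])
    if (length(dup2)) {
      stop("cluster_table(): protein(s) in more than one set: ",
           paste(utils::head(dup2, 5), collapse = ", "))
    }
  }
  if (anyDuplicated(members$protein_id)) {
    stop("cluster_table(): duplicated membership for protein(s): ",
         paste(utils::head(unique(
           members$protein_id[duplicated(members$protein_id)]), 5),
           collapse = ", "))
  }
  both <- intersect(members$protein_id, singletons$protein_id)
  if (length(both)) {
    stop("cluster_table(): protein(s) both clustered and singleton: ",
         paste(utils::head(both, 5), collapse = ", "))
  }
  sizes <- table(members$set_id)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    move <- members$set_id %in% small
    singletons <- rbind(singletons,
                        members[move, c("taxon_id", "protein_id")])
    members <- members[!move, , drop = FALSE]
  }
  rownames(members) <- NULL
  rownames(singletons) <- NULL
  structure(list(sets = members, singletons = singletons),
            class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  cat("cluster_table:", length(unique(x$sets$set_id)), "sets,",
      nrow(x$sets), "clustered proteins,",
      nrow(x$singletons), "singletons\n")
  invisible(x)
}

#' Per-set taxon copy counts
#'
#' @param clusters a [cluster_table()].
#' @return data.frame with columns `set_id`, `taxon_id`, `n_copies`.
#' @export
cluster_copy_counts <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_table"))
  tab <- as.data.frame(table(clusters$sets$set_id, clusters$sets$taxon_id),
                       stringsAsFactors = FALSE)
  names(tab) <- c("set_id", "taxon_id", "n_copies")
  tab <- tab[tab$n_copies > 0L, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Read a cluster membership file
#'
#' Two dialects are supported. `orthogroup_tsv`: one group per line,
#' `set_id: member member ...` with members separated by whitespace or
#' tabs. `cdhit_clstr`: CD-HIT `.clstr` blocks (`>Cluster n` headers
#' followed by one member per line). Members are expected to be
#' `taxon|local` namespaced; un-namespaced members get taxon `NA`.
#'
#' @param path input file.
#' @param dialect one of `"orthogroup_tsv"`, `"cdhit_clstr"`.
#' @return a [cluster_table()]; one-member groups become singletons.
#' @export
read_clusters <- function(path, dialect = c("orthogroup_tsv", "cdhit_clstr")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_clusters(): no such file: ", path)
  lines <- readLines(path)
  if (dialect == "orthogroup_tsv") {
    lines <- lines[nzchar(trimws(lines))]
    ids <- sub(":.*$", "", lines)
    bad <- !grepl(":", lines, fixed = TRUE)
    if (any(bad)) {
      stop("read_clusters(): line ", which(bad)[1], " has no 'set_id:' prefix")
    }
    membs <- strsplit(trimws(sub("^[^:]*:", "", lines)), "[\t ]+")
    set_id <- rep(ids, lengths(membs))
    protein_id <- unlist(membs, use.names = FALSE)
    protein_id <- protein_id[nzchar(protein_id)]
  } else {
    hdr <- grepl("^>Cluster", lines)
    if (!any(hdr)) stop("read_clusters(): no '>Cluster' headers found")
    set_id_all <- cumsum(hdr)
    mem_lines <- lines[!hdr & nzchar(trimws(lines))]
    set_id <- paste0("CL", set_id_all[!hdr & nzchar(trimws(lines))] - 1L)
    m <- regmatches(mem_lines, regexpr(">[^.]*\\.\\.\\.", mem_lines))
    if (length(m) != length(mem_lines)) {
      bad <- which(!grepl(">[^.]*\\.\\.\\.", mem_lines))[1]
      stop("read_clusters(): unparseable member line ", bad)
    }
    protein_id <- sub("\\.\\.\\.$", "", sub("^>", "", m))
  }
  tax <- split_protein_id(protein_id)$taxon_id
  members <- data.frame(set_id = set_id, taxon_id = tax,
                        protein_id = protein_id, stringsAsFactors = FALSE)
  cluster_table(members)
}

#' Read a Newick tree
#'
#' @param path Newick file (one tree).
#' @return an `ape` `phylo` object with unique leaf labels.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("read_newick(): no such file: ", path)
  txt <- paste(readLines(path), collapse = "")
  parse_newick(txt)
}

# Shared validation for Newick text.
parse_newick <- function(txt) {
  n_open <- stri_count_fixed(txt, "(")
  n_close <- stri_count_fixed(txt, ")")
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick text (", n_open, " '(' vs ",
         n_close, "')')")
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick text")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  tree
}

#' Write a tree as Newick text
#'
#' @param tree an `ape` `phylo` object.
#' @param path optional output file; if `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
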