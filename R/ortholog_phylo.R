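#' @title Single-copy ortholog selection, supermatrix assembly, tree
#'   comparison
#' @description Support computations for phylogenomics on homologous
#'   sets: selection of (near-)single-copy sets, overlap-based taxon
#'   trimming of alignments, concatenation into a partitioned
#'   supermatrix with occupancy statistics, and Robinson-Foulds
#'   comparison of trees.
#' @name ortholog_phylo
NULL

#' Select single-copy ortholog sets
#'
#' A set is selected when it spans at least `min_taxa` distinct taxa and
#' every taxon is represented exactly once except (in the default mode)
#' exactly one taxon X with two copies; both of taxon X's sequences are
#' then removed from the emitted set. With
#' `allow_strict_single_copy = TRUE`, sets where every taxon has exactly
#' one copy are also admitted (nothing removed).
#'
#' @param clusters a [cluster_table()].
#' @param min_taxa minimum distinct taxa per selected set (>= 2).
#' @param allow_strict_single_copy also admit all-single-copy sets.
#' @return list with `selection` (data.frame `set_id`, `n_taxa`,
#'   `dropped_taxon`) and `members` (long data.frame of emitted
#'   sequences, the duplicated taxon removed).
#' @export
select_single_copy_sets <- function(clusters, min_taxa = 10,
                                    allow_strict_single_copy = FALSE) {
  stopifnot(inherits(clusters, "cluster_table"))
  if (min_taxa < 2) stop("select_single_copy_sets(): min_taxa must be >= 2")
  cc <- cluster_copy_counts(clusters)
  sel_rows <- lapply(split(cc, cc$set_id), function(d) {
    n_taxa <- nrow(d)
    if (n_taxa < min_taxa) return(NULL)
    dup <- d$taxon_id[d$n_copies == 2L]
    singles <- sum(d$n_copies == 1L)
    if (length(dup) == 1L && singles == n_taxa - 1L) {
      data.frame(set_id = d$set_id[1], n_taxa = n_taxa,
                 dropped_taxon = dup, stringsAsFactors = FALSE)
    } else if (allow_strict_single_copy && singles == n_taxa) {
      data.frame(set_id = d$set_id[1], n_taxa = n_taxa,
                 dropped_taxon = NA_character_, stringsAsFactors = FALSE)
    } else NULL
  })
  selection <- do.call(rbind, sel_rows[!vapply(sel_rows, is.null, TRUE)])
  if (is.null(selection)) {
    selection <- data.frame(set_id = character(), n_taxa = integer(),
                            dropped_taxon = character(),
                            stringsAsFactors = FALSE)
  }
  selection <- selection[order(selection$set_id), , drop = FALSE]
  rownames(selection) <- NULL
  mem <- clusters$sets[clusters$sets$set_id %in% selection$set_id, ,
                       drop = FALSE]
  drop_tx <- stats::setNames(selection$dropped_taxon, selection$set_id)
  keep <- is.na(drop_tx[mem$set_id]) | mem$taxon_id != drop_tx[mem$set_id]
  members <- mem[keep, , drop = FALSE]
  rownames(members) <- NULL
  list(selection = selection, members = members)
}

# Validate and convert an alignment (named character vector of gapped
# sequences) to a character matrix, rows = taxa.
aln_matrix <- function(aln) {
  if (length(aln) == 0L) stop("empty alignment")
  if (is.null(names(aln)) || anyDuplicated(names(aln))) {
    stop("alignment rows must have unique taxon names")
  }
  if (length(unique(nchar(aln))) != 1L) {
    stop("alignment rows differ in length")
  }
  do.call(rbind, strsplit(aln, "", fixed = TRUE))
}

#' Overlap-based taxon trimming of an alignment
#'
#' For each row, a residue column is "good" when the fraction of the
#' other rows holding a residue (non-gap) there is at least
#' `res_overlap`; the row is kept when its good columns make up at least
#' `seq_overlap` percent of its residue columns. Removal is decided in a
#' single pass against the original alignment (no cascade).
#'
#' @param aln named character vector of equal-length gapped sequences.
#' @param res_overlap column-level overlap fraction in `[0, 1]`.
#' @param seq_overlap row-level percentage threshold in `[0, 100]`.
#' @return list with `alignment` (kept rows) and `removed` (taxon
#'   names).
#' @export
overlap_trim <- function(aln, res_overlap = 0.5, seq_overlap = 50) {
  M <- aln_matrix(aln)
  if (nrow(M) < 2L) stop("overlap_trim(): need >= 2 rows")
  res <- M != "-"
  col_res <- colSums(res)
  n <- nrow(M)
  keep <- logical(n)
  for (s in seq_len(n)) {
    mine <- res[s, ]
    if (!any(mine)) { keep[s] <- TRUE; next }   # all-gap row: vacuous
    frac_others <- (col_res - mine) / (n - 1)
    good <- sum(mine & frac_others >= res_overlap)
    keep[s] <- good >= (seq_overlap / 100) * sum(mine)
  }
  list(alignment = aln[keep], removed = names(aln)[!keep])
}

#' Concatenate alignments into a partitioned supermatrix
#'
#' Taxa absent from a partition are padded with the undetermined symbol.
#' Per-taxon occupancy (contribution) is the fraction of determined
#' (non-gap, non-undetermined) characters over the full concatenated
#' length.
#'
#' @param alignments named list of alignments (each a named character
#'   vector of equal-length gapped sequences); list names become
#'   partition names.
#' @param taxa global taxon order; defaults to the union in order of
#'   first appearance.
#' @param undetermined padding symbol for absent taxa (default `-`,
#'   treated identically to a gap in occupancy).
#' @return object of class `supermatrix`: list with `sequences` (named
#'   character vector), `partitions` (data.frame `name`, `start`, `end`;
#'   1-based inclusive), `occupancy` (named numeric) and `length`.
#' @export
build_supermatrix <- function(alignments, taxa = NULL, undetermined = "-") {
  stopifnot(length(alignments) > 0L)
  if (is.null(names(alignments))) {
    names(alignments) <- sprintf("p%04d", seq_along(alignments))
  }
  widths <- integer(length(alignments))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    if (is.null(names(a)) || anyDuplicated(names(a))) {
      stop("build_supermatrix(): duplicate or missing taxon in partition ",
           names(alignments)[i])
    }
    if (length(unique(nchar(a))) != 1L) {
      stop("build_supermatrix(): unequal row lengths in partition ",
           names(alignments)[i])
    }
    widths[i] <- nchar(a[[1]])
  }
  if (is.null(taxa)) {
    taxa <- unique(unlist(lapply(alignments, names), use.names = FALSE))
  }
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  parts <- data.frame(name = names(alignments), start = starts, end = ends,
                      stringsAsFactors = FALSE)
  blocks <- lapply(seq_along(alignments), function(i) {
    a <- alignments[[i]]
    pad <- strrep(undetermined, widths[i])
    out <- rep(pad, length(taxa))
    hit <- match(names(a), taxa)
    if (anyNA(hit)) {
      stop("build_supermatrix(): taxa outside the global list in partition ",
           names(alignments)[i])
    }
    out[hit] <- unname(a)
    out
  })
  seqs <- do.call(paste0, blocks)
  names(seqs) <- taxa
  total <- sum(widths)
  det <- vapply(seqs, function(s) {
    total - stri_count_fixed(s, "-") -
      (if (undetermined != "-") stri_count_fixed(s, undetermined) else 0L)
  }, numeric(1))
  structure(list(sequences = seqs, partitions = parts,
                 occupancy = det / total, length = total),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("supermatrix:", length(x$sequences), "taxa,", x$length,
      "columns in", nrow(x$partitions), "partitions; mean occupancy",
      round(100 * mean(x$occupancy), 2), "%\n")
  invisible(x)
}

#' Write a RAxML-style partition file
#'
#' One line per partition: `PROT, name = start-end`.
#'
#' @param sm a [build_supermatrix()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(sm, path) {
  stopifnot(inherits(sm, "supermatrix"))
  writeLines(sprintf("PROT, %s = %d-%d", sm$partitions$name,
                     sm$partitions$start, sm$partitions$end), path)
  invisible(path)
}

# Canonical non-trivial bipartitions of an unrooted tree, as strings.
# Each split is represented by the leaf subset NOT containing the
# alphabetically first leaf, kept only when both sides have >= 2 leaves.
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    side <- labs[p]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2L && length(side) <= n - 2L) {
      out <- c(out, paste(sort(side), collapse = "\r"))
    }
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' The symmetric-difference count over non-trivial bipartitions of two
#' unrooted leaf-labelled trees, with the normalised value
#' `rf / (2 (n - 3))`. Support values and branch lengths are ignored;
#' rooted inputs are treated as unrooted.
#'
#' @param t1,t2 `phylo` objects on the same leaf set (n >= 4).
#' @return list with `rf` (count) and `normalised` in `[0, 1]`.
#' @export
robinson_foulds <- function(t1, t2) {
  l1 <- t1$tip.label; l2 <- t2$tip.label
  if (!setequal(l1, l2)) {
    stop("robinson_foulds(): leaf sets differ; only in tree 1: {",
         paste(setdiff(l1, l2), collapse = ", "), "}; only in tree 2: {",
         paste(setdiff(l2, l1), collapse = ", "), "}")
  }
  n <- length(l1)
  if (n < 4L) stop("robinson_foulds(): need >= 4 leaves")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  list(rf = rf, normalised = rf / (2 * (n - 3)))
}
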