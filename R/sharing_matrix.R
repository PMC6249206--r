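#' @title Taxon-pairwise sharing of dark protein sets
#' @description For the multi-taxon dark sets, how often does each pair
#'   of taxa co-occur? Row-normalised co-membership produces the
#'   asymmetric sharing matrix behind the survey's heat map: entry
#'   `M[i, j]` is the proportion of row-taxon i's sets that also contain
#'   taxon j.
#' @name sharing_matrix
NULL

#' Compute the taxon-pairwise sharing matrix
#'
#' `M[i, j] = |sets containing both i and j| / |sets containing i|`.
#' Taxa that belong to no set get a zero row and are reported in the
#' `empty_taxa` attribute. The matrix is generally asymmetric; the
#' diagonal is 1 for every taxon in at least one set.
#'
#' @param sets data.frame with `set_id` and `taxon_id` columns (one row
#'   per member), typically the multi-taxon dark sets.
#' @param taxa row/column order; defaults to sorted taxa present. Supply
#'   a tree's leaf order (e.g. `tree$tip.label`) to follow a phylogeny.
#' @return square numeric matrix with `dimnames = list(taxa, taxa)` and
#'   attribute `empty_taxa`.
#' @export
compute_sharing <- function(sets, taxa = NULL) {
  stopifnot(all(c("set_id", "taxon_id") %in% names(sets)))
  if (nrow(sets) == 0L) stop("compute_sharing(): empty set collection")
  if (is.null(taxa)) taxa <- sort(unique(sets$taxon_id))
  # taxon x set incidence (presence, not copy count)
  mem <- unique(sets[c("set_id", "taxon_id")])
  mem <- mem[mem$taxon_id %in% taxa, , drop = FALSE]
  set_ids <- unique(mem$set_id)
  B <- matrix(0L, nrow = length(taxa), ncol = length(set_ids),
              dimnames = list(taxa, set_ids))
  B[cbind(match(mem$taxon_id, taxa), match(mem$set_id, set_ids))] <- 1L
  co <- B %*% t(B)                      # co-membership counts
  denom <- diag(co)
  M <- co / ifelse(denom > 0, denom, 1)
  M[denom == 0, ] <- 0
  attr(M, "empty_taxa") <- taxa[denom == 0]
  M
}

#' Within- versus between-order mean sharing
#'
#' Summarises the block structure of a sharing matrix: the mean of
#' off-diagonal entries for taxon pairs in the same order versus pairs
#' in different orders.
#'
#' @param M matrix from [compute_sharing()].
#' @param order_assignment named character vector taxon -> order.
#' @return list with `within`, `between`.
#' @export
sharing_block_means <- function(M, order_assignment) {
  taxa <- rownames(M)
  ord <- order_assignment[taxa]
  same <- outer(ord, ord, "==")
  offdiag <- !diag(TRUE, nrow(M))
  list(within = mean(M[same & offdiag]),
       between = mean(M[!same & offdiag]))
}
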