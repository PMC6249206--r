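#' @title Enrichment and composition statistics
#' @description Per-identifier Fisher exact enrichment with
#'   Benjamini-Hochberg correction, Gene Ontology enrichment with the
#'   elimination correction for the term hierarchy, and a resampling
#'   test for amino-acid composition differences between two groups of
#'   sequences.
#' @name enrichment_stats
NULL

# Two-sided Fisher exact p for the 2x2 table [[a, b], [c, d]] by the
# point-probability method: sum of hypergeometric table probabilities
# not exceeding the observed table's probability (with a small relative
# tolerance against floating-point ties).
fisher_p_twosided <- function(a, b, c, d) {
  K <- a + b                       # draws (foreground size)
  n_with <- a + c                  # positives in the urn
  N <- a + b + c + d
  support <- max(0L, K - (N - n_with)):min(K, n_with)
  probs <- stats::dhyper(support, n_with, N - n_with, K)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input values must lie in
#' `[0, 1]`.
#'
#' @param pvals numeric vector of p-values.
#' @return adjusted p-values, in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("bh_adjust(): p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Fisher exact enrichment of annotation identifiers
#'
#' For every identifier annotated in the foreground or the background, a
#' 2x2 table contrasts the foreground against the rest of the background
#' (the foreground is part of the background universe and is subtracted
#' from it by default). The two-sided exact p-value comes from the
#' point-probability hypergeometric method; p-values are BH-adjusted
#' across identifiers and results are sorted by adjusted p.
#'
#' @param annotations data.frame with columns `protein_id`,
#'   `identifier` (one row per assignment).
#' @param foreground protein ids of the foreground group.
#' @param background protein ids of the background universe; must
#'   contain the foreground.
#' @param subtract_foreground contrast foreground versus background
#'   minus foreground (default); `FALSE` contrasts against the full
#'   background.
#' @return data.frame with columns `identifier`, `k` (foreground
#'   positives), `K` (foreground size), `n` (background positives),
#'   `N` (background size), `odds_ratio`, `p`, `p_adj`, `direction`.
#' @export
fisher_enrichment <- function(annotations, foreground, background,
                              subtract_foreground = TRUE) {
  stopifnot(all(c("protein_id", "identifier") %in% names(annotations)))
  foreground <- unique(foreground)
  background <- unique(background)
  extra <- setdiff(foreground, background)
  if (length(extra)) {
    stop("fisher_enrichment(): foreground not contained in background (",
         length(extra), " id(s) outside)")
  }
  ann <- annotations[annotations$protein_id %in% background, , drop = FALSE]
  ids <- sort(unique(ann$identifier))
  K <- length(foreground)
  N <- length(background)
  rest <- if (subtract_foreground) setdiff(background, foreground) else background
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    with_id <- unique(ann$protein_id[ann$identifier == ids[i]])
    k <- length(intersect(with_id, foreground))
    n <- length(intersect(with_id, background))
    c_ <- length(intersect(with_id, rest))
    d_ <- length(rest) - c_
    a <- k; b <- K - k
    p <- fisher_p_twosided(a, b, c_, d_)
    or <- (a * d_) / (b * c_)
    if (is.nan(or)) or <- 1        # 0/0: no signal either way
    direction <- if (or > 1) "over" else if (or < 1) "under" else "none"
    out[[i]] <- data.frame(identifier = ids[i], k = k, K = K, n = n, N = N,
                           odds_ratio = or, p = p,
                           direction = direction,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(identifier = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      odds_ratio = numeric(), p = numeric(),
                      p_adj = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  res$p_adj <- bh_adjust(res$p)
  res <- res[order(res$p_adj, res$p, res$identifier),
             c("identifier", "k", "K", "n", "N", "odds_ratio", "p",
               "p_adj", "direction")]
  rownames(res) <- NULL
  res
}

#' GO enrichment with the elimination correction
#'
#' Annotations are first up-propagated along the DAG (a gene annotated
#' to a term is annotated to all its ancestors). Terms are then tested
#' from the leaves upward (reverse topological order); whenever a term's
#' Fisher p-value is at or below `elim_alpha`, the genes annotated to it
#' are removed from all its ancestor terms before those are tested. The
#' reported p-value is the post-elimination one.
#'
#' @param gene2go data.frame with columns `protein_id`, `go_id`.
#' @param dag data.frame with columns `child`, `parent` (edges towards
#'   the root); must be acyclic.
#' @param foreground,background protein id vectors (foreground within
#'   background).
#' @param elim_alpha significance threshold that triggers elimination.
#' @param subtract_foreground as in [fisher_enrichment()].
#' @return data.frame as [fisher_enrichment()], one row per GO term,
#'   BH-adjusted across terms and sorted by adjusted p.
#' @export
go_elim_enrichment <- function(gene2go, dag, foreground, background,
                               elim_alpha = 0.01,
                               subtract_foreground = TRUE) {
  stopifnot(all(c("protein_id", "go_id") %in% names(gene2go)))
  stopifnot(all(c("child", "parent") %in% names(dag)))
  foreground <- unique(foreground)
  background <- unique(background)
  if (length(setdiff(foreground, background))) {
    stop("go_elim_enrichment(): foreground not contained in background")
  }
  terms <- sort(unique(c(gene2go$go_id, dag$child, dag$parent)))
  g <- igraph::make_empty_graph(n = length(terms), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = terms)
  if (nrow(dag)) {
    g <- igraph::add_edges(g, rbind(match(dag$child, terms),
                                    match(dag$parent, terms)))
    if (!igraph::is_dag(g)) stop("go_elim_enrichment(): DAG contains a cycle")
  }
  # children before parents (edges point child -> parent)
  topo <- igraph::topo_sort(g, mode = "out")$name

  gg <- gene2go[gene2go$protein_id %in% background, , drop = FALSE]
  ann <- split(gg$protein_id, gg$go_id)
  ann <- lapply(ann, unique)
  # up-propagate along the DAG: parent inherits child's genes
  for (tm in topo) {
    parents <- igraph::neighbors(g, tm, mode = "out")$name
    for (pa in parents) {
      ann[[pa]] <- union(ann[[pa]], ann[[tm]])
    }
  }

  K <- length(foreground)
  rest_all <- if (subtract_foreground) {
    setdiff(background, foreground)
  } else background
  removed <- stats::setNames(vector("list", length(terms)), terms)
  out <- list()
  for (tm in topo) {
    genes <- setdiff(ann[[tm]] %||% character(), removed[[tm]])
    k <- length(intersect(genes, foreground))
    n <- length(genes)
    c_ <- length(intersect(genes, rest_all))
    d_ <- length(rest_all) - c_
    a <- k; b <- K - k
    p <- fisher_p_twosided(a, b, c_, d_)
    or <- (a * d_) / (b * c_)
    if (is.nan(or)) or <- 1
    out[[tm]] <- data.frame(
      identifier = tm, k = k, K = K, n = n, N = length(background),
      odds_ratio = or, p = p,
      direction = if (or > 1) "over" else if (or < 1) "under" else "none",
      stringsAsFactors = FALSE)
    if (p <= elim_alpha && length(genes)) {
      anc <- setdiff(igraph::subcomponent(g, tm, mode = "out")$name, tm)
      for (pa in anc) removed[[pa]] <- union(removed[[pa]], genes)
    }
  }
  res <- do.call(rbind, out[terms])
  res$p_adj <- bh_adjust(res$p)
  res <- res[order(res$p_adj, res$p, res$identifier), ]
  rownames(res) <- NULL
  res
}

# Per-sequence amino-acid proportion matrix (n x 20); letters outside
# the 20 standard ones are ignored in the denominator.
aa_proportions <- function(sequences) {
  counts <- vapply(AA_STANDARD,
                   function(a) stri_count_fixed(sequences, a),
                   numeric(length(sequences)))
  counts <- matrix(counts, nrow = length(sequences),
                   dimnames = list(NULL, AA_STANDARD))
  counts / pmax(rowSums(counts), 1)
}

# Vectorised two-sample t-test p-values per column. Welch by default;
# `pooled` restores the equal-variance form. Columns with zero variance
# in both samples yield p = 1.
ttest_cols <- function(xa, xb, pooled = FALSE) {
  n1 <- nrow(xa); n2 <- nrow(xb)
  m1 <- colMeans(xa); m2 <- colMeans(xb)
  v1 <- apply(xa, 2, stats::var); v2 <- apply(xb, 2, stats::var)
  if (pooled) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[v1 + v2 == 0] <- 1
  p
}

#' Resampling test for amino-acid composition differences
#'
#' Per replicate, `sample_size` sequences are drawn without replacement
#' from each group; for each of the 20 amino acids the per-sequence
#' proportions are compared by a two-sample t-test and the 20 p-values
#' are BH-adjusted within the replicate. An amino acid is flagged
#' significant when its adjusted p-value is at or below `alpha` in at
#' least `criterion * reps` replicates.
#'
#' @param group_a,group_b character vectors of protein sequences (or
#'   data.frames with a `sequence` column); each at least `sample_size`
#'   long.
#' @param sample_size sequences sampled per group per replicate.
#' @param reps number of replicates.
#' @param alpha significance level on the BH-adjusted p-value.
#' @param criterion fraction of replicates that must be significant.
#' @param seed integer seed.
#' @param pooled_variance use the pooled-variance t-test instead of the
#'   Welch form.
#' @return object of class `composition_test`: data.frame with one row
#'   per amino acid: `aa`, `n_significant_reps`, `significant`,
#'   `mean_prop_a`, `mean_prop_b`; attributes `reps`, `criterion`.
#' @export
aa_composition_test <- function(group_a, group_b, sample_size = 100,
                                reps = 10000, alpha = 0.05,
                                criterion = 0.95, seed = 1L,
                                pooled_variance = FALSE) {
  if (is.data.frame(group_a)) group_a <- group_a$sequence
  if (is.data.frame(group_b)) group_b <- group_b$sequence
  if (length(group_a) < sample_size || length(group_b) < sample_size) {
    stop("aa_composition_test(): both groups must have at least ",
         sample_size, " sequences")
  }
  set.seed(derive_seed(seed, "aatest"))
  pa <- aa_proportions(group_a)
  pb <- aa_proportions(group_b)
  n_sig <- integer(20L)
  for (r in seq_len(reps)) {
    xa <- pa[sample.int(nrow(pa), sample_size), , drop = FALSE]
    xb <- pb[sample.int(nrow(pb), sample_size), , drop = FALSE]
    p_adj <- bh_adjust(ttest_cols(xa, xb, pooled = pooled_variance))
    n_sig <- n_sig + (p_adj <= alpha)
  }
  res <- data.frame(aa = AA_STANDARD,
                    n_significant_reps = n_sig,
                    significant = n_sig >= criterion * reps,
                    mean_prop_a = colMeans(pa),
                    mean_prop_b = colMeans(pb),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "reps") <- reps
  attr(res, "criterion") <- criterion
  class(res) <- c("composition_test", class(res))
  res
}
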