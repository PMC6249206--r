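# Shared fixtures: small configurations, random problem instances and
# independent brute-force oracles used across test files.

small_config <- function(seed = 1L, ...) {
  cohort_config(n_taxa = 8, n_orders = 3, n_families = 120, seed = seed, ...)
}

# Random clustering instance: proteins split into sets (>= 2 members),
# singletons, random taxa and random hit flags.
random_darkness_instance <- function(n_proteins, n_taxa = 5, p_hit = 0.4) {
  ids <- sprintf("p%04d", seq_len(n_proteins))
  taxa <- sample(sprintf("t%d", seq_len(n_taxa)), n_proteins, replace = TRUE)
  n_clustered <- if (n_proteins >= 4) {
    2 * sample.int(floor(n_proteins / 2) - 1, 1)
  } else 0
  members <- NULL
  if (n_clustered >= 2) {
    idx <- seq_len(n_clustered)
    # random set sizes >= 2 covering idx
    set_of <- integer(n_clustered)
    s <- 0L; i <- 1L
    while (i <= n_clustered) {
      size <- min(sample(2:5, 1), n_clustered - i + 1L)
      if (size == 1L) { set_of[i - 1L] <- s; set_of[i] <- s; i <- i + 1L; next }
      s <- s + 1L
      set_of[i:(i + size - 1L)] <- s
      i <- i + size
    }
    members <- data.frame(set_id = sprintf("S%03d", set_of),
                          taxon_id = taxa[idx], protein_id = ids[idx],
                          stringsAsFactors = FALSE)
  }
  sing_idx <- setdiff(seq_len(n_proteins), seq_len(n_clustered))
  singletons <- data.frame(taxon_id = taxa[sing_idx],
                           protein_id = ids[sing_idx],
                           stringsAsFactors = FALSE)
  clusters <- cluster_table(
    members %||% data.frame(set_id = character(), taxon_id = character(),
                            protein_id = character()),
    singletons)
  hits <- stats::setNames(stats::runif(n_proteins) < p_hit, ids)
  list(clusters = clusters, hits = hits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force darkness oracle: double loop over proteins and sets.
oracle_darkness <- function(clusters, hits, rule = "all_hitless") {
  res <- list()
  sets <- split(clusters$sets$protein_id, clusters$sets$set_id)
  for (pid in clusters$sets$protein_id) {
    own <- NULL
    for (sid in names(sets)) if (pid %in% sets[[sid]]) own <- sets[[sid]]
    dark <- if (rule == "all_hitless") {
      all(!hits[own])
    } else {
      any(!hits[own])
    }
    res[[pid]] <- c(dark = dark, clustered = TRUE)
  }
  for (pid in clusters$singletons$protein_id) {
    res[[pid]] <- c(dark = !unname(hits[pid]), clustered = FALSE)
  }
  out <- do.call(rbind, res)
  data.frame(protein_id = rownames(out), dark = as.logical(out[, "dark"]),
             clustered = as.logical(out[, "clustered"]),
             stringsAsFactors = FALSE)
}

# Independent bipartition oracle for unrooted trees: for every internal
# edge collect the tip set below it by walking the edge matrix.
oracle_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  out <- character(0)
  anchor <- sort(tree$tip.label)[1]
  internal <- tree$edge[, 2][tree$edge[, 2] > n]
  for (node in internal) {
    side <- tips_below(node)
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) >= 2 && length(side) <= n - 2) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  unique(out)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# Random protein sequences from a composition vector.
random_seqs <- function(n, len, profile = rep(1 / 20, 20)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, len, replace = TRUE, prob = profile), collapse = "")
  }, character(1))
}

# Write lines to a temp file, return path.
tmpfile <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
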