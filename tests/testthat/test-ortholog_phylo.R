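mk_clusters <- function(copies) {
  # copies: named list set_id -> named integer vector taxon -> n_copies
  rows <- do.call(rbind, lapply(names(copies), function(sid) {
    cc <- copies[[sid]]
    data.frame(set_id = sid,
               taxon_id = rep(names(cc), cc),
               stringsAsFactors = FALSE)
  }))
  rows$protein_id <- sprintf("%s|%s_%d", rows$taxon_id, rows$set_id,
                             stats::ave(seq_len(nrow(rows)),
                                        paste(rows$set_id, rows$taxon_id),
                                        FUN = seq_along))
  cluster_table(rows)
}

test_that("single-copy selection admits the one-duplicated-taxon pattern", {
  eleven <- stats::setNames(rep(1L, 11), sprintf("t%02d", 1:11))
  cl <- mk_clusters(list(
    good = c(eleven, tX = 2L),                      # 12 taxa, one duplicated
    small = c(stats::setNames(rep(1L, 8), sprintf("t%02d", 1:8)), tX = 2L),
    twodup = c(stats::setNames(rep(1L, 10), sprintf("t%02d", 1:10)),
               tX = 2L, tY = 2L),
    strict = stats::setNames(rep(1L, 12), sprintf("t%02d", 1:12))))
  sel <- select_single_copy_sets(cl, min_taxa = 10)
  expect_identical(sel$selection$set_id, "good")
  expect_identical(sel$selection$dropped_taxon, "tX")
  # both copies of the duplicated taxon are removed from the emitted set
  emitted <- sel$members[sel$members$set_id == "good", ]
  expect_identical(nrow(emitted), 11L)
  expect_false("tX" %in% emitted$taxon_id)
  # the strict-single-copy flag also admits the all-single-copy set
  sel2 <- select_single_copy_sets(cl, min_taxa = 10,
                                  allow_strict_single_copy = TRUE)
  expect_setequal(sel2$selection$set_id, c("good", "strict"))
  expect_error(select_single_copy_sets(cl, min_taxa = 1), "min_taxa")
})

test_that("selection is invariant to input ordering", {
  set.seed(31)
  cls <- lapply(1:12, function(i) {
    n <- sample(8:14, 1)
    cc <- stats::setNames(rep(1L, n), sprintf("t%02d", 1:n))
    if (runif(1) < 0.5) cc[sample(n, 1)] <- 2L
    cc
  })
  names(cls) <- sprintf("og%02d", 1:12)
  a <- select_single_copy_sets(mk_clusters(cls), min_taxa = 10)
  b <- select_single_copy_sets(mk_clusters(rev(cls)), min_taxa = 10)
  expect_identical(a$selection, b$selection)
})

test_that("overlap trimming removes exactly the hand-computed taxa", {
  # rowD's residues sit where the other three rows are all gaps
  aln <- c(A = "AAAA----", B = "AAAA----", C = "AAAA----", D = "----TTTT")
  tr <- overlap_trim(aln, res_overlap = 0.5, seq_overlap = 50)
  expect_identical(tr$removed, "D")
  expect_identical(names(tr$alignment), c("A", "B", "C"))
  # gapless alignments lose nothing
  g <- c(A = "MKLV", B = "MRLV", C = "MKIV")
  expect_identical(overlap_trim(g)$removed, character(0))
  # a vacuous residue threshold keeps everything
  expect_identical(overlap_trim(aln, res_overlap = 0)$removed, character(0))
  # partial overlap: row E has half its residues in covered columns
  aln2 <- c(A = "AAAA--", B = "AAAA--", C = "AAAA--", E = "--TTTT")
  tr2 <- overlap_trim(aln2, res_overlap = 0.5, seq_overlap = 50)
  expect_identical(tr2$removed, character(0))   # 2 of 4 residues good = 50%
  tr3 <- overlap_trim(aln2, res_overlap = 0.5, seq_overlap = 51)
  expect_identical(tr3$removed, "E")
  expect_error(overlap_trim(c(A = "MK")), ">= 2 rows")
})

test_that("supermatrix concatenation pads absences and tracks occupancy", {
  a1 <- c(tA = "MKLV-QRSTW", tB = "MKLVWQRSTW")      # width 10
  a2 <- c(tA = "ACDEFGHIKLMNPQR", tC = "ACDEF----LMNPQR")  # width 15
  sm <- build_supermatrix(list(g1 = a1, g2 = a2))
  expect_identical(sm$length, 25L)
  expect_identical(sm$partitions$start, c(1L, 11L))
  expect_identical(sm$partitions$end, c(10L, 25L))
  expect_equal(sm$occupancy[["tA"]], (9 + 15) / 25)
  expect_equal(sm$occupancy[["tB"]], 10 / 25)
  expect_equal(sm$occupancy[["tC"]], 11 / 25)
  expect_identical(nchar(sm$sequences[["tB"]]), 25L)
  expect_identical(substr(sm$sequences[["tB"]], 11, 25), strrep("-", 15))
  # single alignment: supermatrix is the alignment itself
  sm1 <- build_supermatrix(list(only = a1))
  expect_identical(unname(sm1$sequences), unname(a1))
  # disjoint taxa: every row half padded by partition
  smd <- build_supermatrix(list(x = c(tA = "AAAA"), y = c(tB = "TTTT")))
  expect_identical(unname(smd$sequences["tA"]), "AAAA----")
  expect_identical(unname(smd$sequences["tB"]), "----TTTT")
  expect_error(build_supermatrix(list(bad = c(tA = "AA", tA = "AA"))),
               "duplicate")
})

test_that("concatenation conserves determined characters over random alignments", {
  set.seed(41)
  taxa <- sprintf("t%02d", 1:12)
  alns <- lapply(1:50, function(i) {
    n <- sample(4:12, 1)
    w <- sample(5:40, 1)
    rows <- vapply(seq_len(n), function(j) {
      s <- strsplit(random_seqs(1, w), "")[[1]]
      s[runif(w) < 0.2] <- "-"
      paste(s, collapse = "")
    }, character(1))
    stats::setNames(rows, sample(taxa, n))
  })
  sm <- build_supermatrix(alns, taxa = taxa)
  expect_identical(sm$length, sum(vapply(alns, function(a) nchar(a[[1]]), 1L)))
  # per-taxon determined characters are conserved
  per_taxon_in <- vapply(taxa, function(tx) {
    sum(vapply(alns, function(a) {
      if (!tx %in% names(a)) return(0L)
      nchar(gsub("-", "", a[[tx]], fixed = TRUE))
    }, integer(1)))
  }, integer(1))
  per_taxon_out <- vapply(taxa, function(tx) {
    nchar(gsub("-", "", sm$sequences[[tx]], fixed = TRUE))
  }, integer(1))
  expect_identical(per_taxon_out, per_taxon_in)
  expect_equal(unname(sm$occupancy), unname(per_taxon_in / sm$length))
  # partition file is emitted in RAxML style
  f <- tempfile()
  write_partitions(sm, f)
  lines <- readLines(f)
  expect_length(lines, 50L)
  expect_match(lines[1], "^PROT, .+ = 1-\\d+$")
})

test_that("robinson-foulds matches the bipartition oracle", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_identical(robinson_foulds(t1, t1)$rf, 0L)
  expect_equal(robinson_foulds(t1, t1)$normalised, 0)
  r <- robinson_foulds(t1, t2)
  expect_identical(r$rf, 2L)
  expect_equal(r$normalised, 1.0)
  set.seed(51)
  for (i in 1:100) {
    a <- ape::rtree(8)
    b <- ape::rtree(8)
    b$tip.label <- sample(a$tip.label)
    got <- robinson_foulds(a, b)
    expect_identical(got$rf, oracle_rf(a, b))
    expect_equal(got$normalised, got$rf / 10)
    # symmetry
    expect_identical(robinson_foulds(b, a)$rf, got$rf)
    expect_lte(got$rf, 10L)
  }
})

test_that("robinson-foulds validates leaf sets", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(robinson_foulds(t1, t3), "E")
  tiny <- ape::read.tree(text = "(A,B,C);")
  expect_error(robinson_foulds(tiny, tiny), ">= 4")
})

test_that("robinson-foulds agrees with an established implementation", {
  skip_if_not_installed("phangorn")
  set.seed(61)
  for (i in 1:25) {
    a <- ape::rtree(10)
    b <- ape::rtree(10)
    b$tip.label <- sample(a$tip.label)
    expect_identical(robinson_foulds(a, b)$rf,
                     as.integer(phangorn::RF.dist(ape::unroot(a),
                                                  ape::unroot(b))))
  }
})
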