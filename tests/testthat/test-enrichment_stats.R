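# Independent enumeration oracle: two-sided Fisher p for [[a,b],[c,d]]
# from first principles (log-binomial coefficients, explicit sum).
oracle_fisher_p <- function(a, b, c, d) {
  K <- a + b; N <- a + b + c + d; nw <- a + c
  support <- max(0, K - (N - nw)):min(K, nw)
  logp <- lchoose(nw, support) + lchoose(N - nw, K - support) - lchoose(N, K)
  probs <- exp(logp)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

mk_ann <- function(with_id, identifier = "D1") {
  data.frame(protein_id = with_id, identifier = identifier,
             stringsAsFactors = FALSE)
}

test_that("fisher enrichment reproduces hand-constructed tables", {
  # symmetric 1/1/1/1 table: p = 1
  bg <- sprintf("g%d", 1:4)
  res <- fisher_enrichment(mk_ann(c("g1", "g3")), c("g1", "g2"), bg)
  expect_equal(res$p, 1.0)
  # [[8,2],[2,8]]: matches exhaustive enumeration
  fg <- sprintf("g%d", 1:10)
  bg20 <- sprintf("g%d", 1:20)
  ann <- mk_ann(c(sprintf("g%d", 1:8), "g11", "g12"))
  res2 <- fisher_enrichment(ann, fg, bg20)
  expect_equal(res2$p, oracle_fisher_p(8, 2, 2, 8), tolerance = 1e-12)
  expect_identical(res2$direction, "over")
  expect_identical(res2$k, 8L)
  # absent from foreground, present in background: under-representation
  res3 <- fisher_enrichment(mk_ann(sprintf("g%d", 11:18)), fg, bg20)
  expect_identical(res3$direction, "under")
  expect_error(fisher_enrichment(mk_ann("x"), c("a", "zzz"), c("a", "b")),
               "foreground not contained")
})

test_that("two-sided p matches fisher.test across random tables", {
  set.seed(71)
  for (i in 1:150) {
    t <- matrix(rpois(4, sample(1:12, 1)), 2)
    expect_equal(darkome:::fisher_p_twosided(t[1, 1], t[1, 2],
                                             t[2, 1], t[2, 2]),
                 stats::fisher.test(t)$p.value, tolerance = 1e-9)
  }
})

test_that("bh adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # step-up reference implementation on random vectors
  set.seed(81)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    m <- length(p)
    o <- order(p)
    ref <- numeric(m)
    ref[o] <- rev(cummin(rev(pmin(1, p[o] * m / seq_len(m)))))
    expect_equal(bh_adjust(p), ref, tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p - 1e-15))
    expect_true(all(bh_adjust(p) <= 1))
    # order independence
    perm <- sample(m)
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm], tolerance = 1e-12)
    # decision-level stability: thresholding adjusted p reproduces the
    # step-up rejection rule at any level
    for (alpha in c(0.01, 0.05, 0.2)) {
      ps <- sort(p)
      k <- suppressWarnings(max(which(ps <= alpha * seq_len(m) / m)))
      rejected_stepup <- if (is.finite(k)) p <= ps[k] else rep(FALSE, m)
      expect_identical(bh_adjust(p) <= alpha, rejected_stepup)
    }
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("go elimination removes significant children's genes from ancestors", {
  genes <- paste0("g", 1:20)
  fg <- paste0("g", 1:10)
  # child carries all the signal; parent inherits it only via propagation
  g2g <- data.frame(protein_id = paste0("g", 1:8), go_id = "GO:child")
  dag <- data.frame(child = "GO:child", parent = "GO:parent")
  res <- go_elim_enrichment(g2g, dag, fg, genes, elim_alpha = 0.05)
  p_child <- res$p[res$identifier == "GO:child"]
  p_parent <- res$p[res$identifier == "GO:parent"]
  # naive parent p (propagated, no elimination) equals the child's
  expect_lt(p_child, 0.05)
  expect_gt(p_parent, p_child)
  expect_equal(p_parent, 1.0)
  # child above elim_alpha: parent keeps its naive (propagated) p
  res2 <- go_elim_enrichment(g2g, dag, fg, genes, elim_alpha = 1e-6)
  expect_equal(res2$p[res2$identifier == "GO:parent"], p_child,
               tolerance = 1e-12)
})

test_that("edgeless dag reduces go elimination to per-term fisher", {
  set.seed(91)
  genes <- paste0("g", 1:60)
  fg <- sample(genes, 25)
  g2g <- data.frame(
    protein_id = sample(genes, 80, replace = TRUE),
    go_id = sample(c("GO:1", "GO:2", "GO:3"), 80, replace = TRUE))
  g2g <- unique(g2g)
  dag0 <- data.frame(child = character(), parent = character())
  res <- go_elim_enrichment(g2g, dag0, fg, genes)
  naive <- fisher_enrichment(
    stats::setNames(g2g, c("protein_id", "identifier")), fg, genes)
  expect_equal(stats::setNames(res$p, res$identifier)[naive$identifier],
               stats::setNames(naive$p, naive$identifier),
               tolerance = 1e-12)
  # elim_alpha = 0 never triggers elimination even with edges
  dag <- data.frame(child = c("GO:2", "GO:3"), parent = c("GO:1", "GO:1"))
  res0 <- go_elim_enrichment(g2g, dag, fg, genes, elim_alpha = 0)
  prop <- res0[res0$identifier %in% c("GO:2", "GO:3"), ]
  expect_equal(stats::setNames(prop$p, prop$identifier)[c("GO:2", "GO:3")],
               stats::setNames(naive$p, naive$identifier)[c("GO:2", "GO:3")],
               tolerance = 1e-12)
})

test_that("cyclic dags are rejected", {
  g2g <- data.frame(protein_id = "g1", go_id = "GO:1")
  dag <- data.frame(child = c("GO:1", "GO:2"), parent = c("GO:2", "GO:1"))
  expect_error(go_elim_enrichment(g2g, dag, "g1", c("g1", "g2")), "cycle")
})

test_that("vectorised t-tests agree with t.test", {
  set.seed(95)
  xa <- matrix(rnorm(200), ncol = 4)
  xb <- matrix(rnorm(160, mean = 0.3), ncol = 4)
  p_welch <- darkome:::ttest_cols(xa, xb)
  p_pool <- darkome:::ttest_cols(xa, xb, pooled = TRUE)
  for (j in 1:4) {
    expect_equal(p_welch[j], t.test(xa[, j], xb[, j])$p.value,
                 tolerance = 1e-12)
    expect_equal(p_pool[j], t.test(xa[, j], xb[, j], var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # zero variance in both samples gives p = 1
  za <- cbind(xa, 1); zb <- cbind(xb, 1)
  expect_equal(darkome:::ttest_cols(za, zb)[5], 1)
})

test_that("composition test is calibrated on identical distributions", {
  set.seed(97)
  g <- random_seqs(300, 120)
  res <- aa_composition_test(g, g, sample_size = 100, reps = 200, seed = 7)
  expect_lte(sum(res$significant), 1)
  expect_true(all(res$n_significant_reps >= 0 &
                    res$n_significant_reps <= 200))
  expect_error(aa_composition_test(g[1:50], g, sample_size = 100),
               "at least 100")
})

test_that("composition test detects a planted alanine shift", {
  set.seed(98)
  base <- rep(1 / 20, 20)
  shifted <- base
  shifted[1] <- shifted[1] + 0.05          # +5 points on alanine
  shifted <- shifted / sum(shifted)
  ga <- random_seqs(600, 300, base)
  gb <- random_seqs(600, 300, shifted)
  res <- aa_composition_test(ga, gb, sample_size = 100, reps = 200, seed = 9)
  expect_true(res$significant[res$aa == "A"])
})
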