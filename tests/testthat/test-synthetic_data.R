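test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$truth_families, b$truth_families)
  expect_identical(a$truth_dark, b$truth_dark)
  d <- generate_cohort(small_config(seed = 8))
  expect_false(identical(a$proteins$sequence, d$proteins$sequence))
})

test_that("config validation names the offending field", {
  expect_error(cohort_config(dark_family_fraction = 1.2),
               "dark_family_fraction")
  expect_error(cohort_config(family_size_means = c(dark = 0.9, annotated = 36)),
               "family_size_means")
  bad_prof <- list(dark = rep(0.06, 20), annotated = aa_profile <- rep(1 / 20, 20))
  expect_error(cohort_config(aa_profiles = bad_prof), "aa_profiles")
  expect_error(
    cohort_config(planted_enrichments = data.frame(
      domain = "D", group = "G", odds_ratio = -1)),
    "odds_ratio")
})

test_that("dark_family_fraction = 0 plants no dark families", {
  cfg <- small_config(seed = 3, dark_family_fraction = 0)
  co <- generate_cohort(cfg)
  fam_dark <- tapply(co$truth_dark[co$truth_families$protein_id],
                     co$truth_families$set_id, any)
  expect_false(any(fam_dark))
})

test_that("realised dark-set fraction lands in the binomial 99% CI", {
  cfg <- cohort_config(n_taxa = 20, n_orders = 5, n_families = 2000,
                       dark_family_fraction = 0.639, seed = 7)
  co <- generate_cohort(cfg)
  fam_dark <- tapply(co$truth_dark[co$truth_families$protein_id],
                     co$truth_families$set_id, all)
  ci <- qbinom(c(0.005, 0.995), 2000, 0.639) / 2000
  expect_gte(mean(fam_dark), ci[1])
  expect_lte(mean(fam_dark), ci[2])
})

test_that("per-taxon protein counts sum to the cohort size", {
  co <- generate_cohort(small_config(seed = 5))
  expect_identical(sum(table(co$proteins$taxon_id)), nrow(co$proteins))
  # every protein is in exactly one family or a singleton
  expect_false(anyDuplicated(co$truth_families$protein_id) > 0)
  expect_true(all(co$truth_families$protein_id %in% co$proteins$protein_id))
  # dark flags constant within families
  by_fam <- tapply(co$truth_dark[co$truth_families$protein_id],
                   co$truth_families$set_id,
                   function(x) length(unique(x)))
  expect_true(all(by_fam == 1L))
})

test_that("lineage restriction confines dark families to one order", {
  cfg <- small_config(seed = 9, lineage_restriction = 1)
  co <- generate_cohort(cfg)
  fam_tax <- split(co$truth_families$taxon_id, co$truth_families$set_id)
  fam_dark <- tapply(co$truth_dark[co$truth_families$protein_id],
                     co$truth_families$set_id, all)
  n_orders <- vapply(fam_tax, function(tx) {
    length(unique(co$order_assignment[tx]))
  }, integer(1))
  expect_true(all(n_orders[fam_dark[names(n_orders)]] == 1L))
})

test_that("hit simulation respects the error rates", {
  co <- generate_cohort(small_config(seed = 2))
  # zero noise: hit flags are exactly the negation of truth darkness
  h0 <- generate_hit_table(co, false_pos = 0, false_neg = 0)
  expect_identical(h0$hit, !unname(co$truth_dark[h0$protein_id]))
  # false positives on dark proteins within binomial 99% CI
  cfg <- cohort_config(n_taxa = 10, n_orders = 2, n_families = 1200,
                       dark_family_fraction = 1, singleton_fraction = 0,
                       seed = 4)
  cod <- generate_cohort(cfg)
  n_dark <- sum(cod$truth_dark)
  expect_gt(n_dark, 3000)
  h <- generate_hit_table(cod, false_pos = 0.05, false_neg = 0, seed = 11)
  n_hits <- sum(h$hit[cod$truth_dark[h$protein_id]])
  ci <- qbinom(c(0.005, 0.995), n_dark, 0.05)
  expect_gte(n_hits, ci[1])
  expect_lte(n_hits, ci[2])
  expect_error(generate_hit_table(co, false_pos = 1.4), "rates")
})

test_that("domain background is homogeneous when nothing is planted", {
  cfg <- cohort_config(n_taxa = 12, n_orders = 3, n_families = 550,
                       domain_prevalence = 0.05, seed = 21)
  co <- generate_cohort(cfg)
  expect_gt(nrow(co$proteins), 10000)
  an <- generate_domain_annotations(co, cfg)
  grp <- co$order_assignment[co$proteins$taxon_id]
  # pooled over domains: presence of each of the first 5 domains vs group
  pvals <- vapply(sprintf("DOM%03d", 1:5), function(d) {
    has <- co$proteins$protein_id %in%
      an$domains$protein_id[an$domains$domain == d]
    suppressWarnings(chisq.test(table(grp, has))$p.value)
  }, numeric(1))
  expect_gt(min(pvals) * 5, 0.01)   # Bonferroni-style guard at p > 0.01
})

test_that("planted odds ratios are realised within sampling error", {
  cfg <- cohort_config(n_taxa = 12, n_orders = 3, n_families = 550,
                       domain_prevalence = 0.05, seed = 31,
                       planted_enrichments = data.frame(
                         domain = "DOM001", group = "Order2",
                         odds_ratio = 4))
  co <- generate_cohort(cfg)
  an <- generate_domain_annotations(co, cfg)
  grp <- co$order_assignment[co$proteins$taxon_id]
  expect_gt(min(table(grp)), 2000)
  has <- co$proteins$protein_id %in%
    an$domains$protein_id[an$domains$domain == "DOM001"]
  a <- sum(has & grp == "Order2"); b <- sum(!has & grp == "Order2")
  c_ <- sum(has & grp != "Order2"); d <- sum(!has & grp != "Order2")
  or <- (a * d) / (b * c_)
  expect_gte(or, 2.5)
  expect_lte(or, 6.4)
})

test_that("generated GO DAG is acyclic and topologically sortable", {
  cfg <- small_config(seed = 13)
  co <- generate_cohort(cfg)
  an <- generate_domain_annotations(co, cfg)
  g <- igraph::graph_from_data_frame(an$go_dag)
  expect_true(igraph::is_dag(g))
  expect_length(igraph::topo_sort(g), igraph::vcount(g))
})

test_that("empty cohort yields an empty hit table", {
  cfg <- cohort_config(n_taxa = 2, n_orders = 1, n_families = 0,
                       singleton_fraction = 0, seed = 1)
  co <- generate_cohort(cfg)
  expect_identical(nrow(co$proteins), 0L)
  expect_identical(nrow(generate_hit_table(co, 0, 0)), 0L)
})

test_that("cohort artifacts round-trip through disk", {
  co <- generate_cohort(small_config(seed = 17))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  tx <- unique(co$proteins$taxon_id)[1]
  back <- read_fasta(file.path(d, paste0(tx, ".faa")))
  orig <- co$proteins[co$proteins$taxon_id == tx, ]
  expect_identical(back$protein_id, orig$protein_id)
  expect_identical(back$sequence, orig$sequence)
  cfg_back <- yaml::read_yaml(file.path(d, "config.yaml"))
  expect_identical(cfg_back$n_families, co$config$n_families)
})
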