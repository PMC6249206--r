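#' @title Synthetic multi-taxon protein cohorts with known ground truth
#' @description Generates protein cohorts that emulate a multi-taxon
#'   transcriptome survey: taxa grouped into orders, homologous families
#'   planted as mutated copies of a founder sequence, a configurable
#'   fraction of families "dark" (no database annotation), dark families
#'   smaller and more lineage-restricted than annotated ones, and
#'   singletons with fresh founders. Ground truth (family membership,
#'   darkness, planted domain enrichments) is carried alongside so every
#'   downstream stage can be validated exactly.
#' @name synthetic_data
NULL

# Default amino-acid composition for annotated proteins (approximate
# average proteome frequencies) and a mildly shifted profile for dark
# proteins (a few residues differ, as observed between the two classes).
aa_profile_annotated <- function() {
  p <- c(A = 8.3, C = 1.4, D = 5.5, E = 6.7, F = 3.9, G = 7.1, H = 2.3,
         I = 6.0, K = 5.8, L = 9.7, M = 2.4, N = 4.1, P = 4.7, Q = 3.9,
         R = 5.5, S = 6.6, T = 5.4, V = 6.9, W = 1.1, Y = 2.9)
  p / sum(p)
}

aa_profile_dark <- function() {
  p <- aa_profile_annotated() * 100
  # dark proteins skew slightly towards small/polar residues
  p["S"] <- p["S"] + 1.5; p["A"] <- p["A"] + 1.0
  p["E"] <- max(p["E"] - 1.5, 0.1); p["L"] <- max(p["L"] - 1.0, 0.1)
  p / sum(p)
}

#' Configuration for a synthetic cohort
#'
#' Defaults emulate the 47-taxon dinoflagellate transcriptome survey the
#' package models: eight orders, 63.9% of homologous families dark, mean
#' family sizes 4.26 (dark) versus 36.12 (annotated), 24% of proteins
#' unclustered singletons (97.13% of them dark), log-normal sequence
#' lengths with medians 109 (dark) and 292 (annotated) residues, and
#' strong lineage restriction of dark families.
#'
#' @param n_taxa number of taxa.
#' @param n_orders number of order-level groups taxa are assigned to
#'   (round-robin); ignored when `order_assignment` is given.
#' @param order_assignment optional named character vector taxon -> order.
#' @param n_families number of multi-member homologous families to plant.
#' @param dark_family_fraction probability that a family is dark.
#' @param family_size_means mean sizes (>= 2) of dark and annotated
#'   families, named `c(dark=, annotated=)`.
#' @param family_size_dispersion negative-binomial size parameter for the
#'   (size - 2) excess; larger is closer to Poisson.
#' @param singleton_fraction fraction of all proteins that are singletons.
#' @param dark_singleton_fraction probability a singleton is dark.
#' @param lineage_restriction probability that a dark family is confined
#'   to a single order.
#' @param aa_profiles list with 20-simplex composition vectors `dark` and
#'   `annotated` (named by amino-acid letter).
#' @param length_medians median sequence lengths, named
#'   `c(dark=, annotated=)`.
#' @param length_sdlog log-scale standard deviation of lengths.
#' @param mutation_rate per-site substitution probability applied to the
#'   family founder for each member.
#' @param planted_enrichments data.frame with columns `domain`, `group`
#'   (an order label), `odds_ratio` (> 0), or `NULL`.
#' @param n_background_domains number of unenriched background domains.
#' @param domain_prevalence baseline probability a protein carries any
#'   given domain.
#' @param seed integer seed; all stages derive sub-streams from it.
#' @return a validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_taxa = 47,
                          n_orders = 8,
                          order_assignment = NULL,
                          n_families = 2000,
                          dark_family_fraction = 0.639,
                          family_size_means = c(dark = 4.26, annotated = 36.12),
                          family_size_dispersion = 1.5,
                          singleton_fraction = 0.24,
                          dark_singleton_fraction = 0.9713,
                          lineage_restriction = 0.9,
                          aa_profiles = list(dark = aa_profile_dark(),
                                             annotated = aa_profile_annotated()),
                          length_medians = c(dark = 109, annotated = 292),
                          length_sdlog = 0.45,
                          mutation_rate = 0.1,
                          planted_enrichments = NULL,
                          n_background_domains = 20,
                          domain_prevalence = 0.01,
                          seed = 1L) {
  cfg <- list(n_taxa = as.integer(n_taxa), n_orders = as.integer(n_orders),
              order_assignment = order_assignment,
              n_families = as.integer(n_families),
              dark_family_fraction = dark_family_fraction,
              family_size_means = family_size_means,
              family_size_dispersion = family_size_dispersion,
              singleton_fraction = singleton_fraction,
              dark_singleton_fraction = dark_singleton_fraction,
              lineage_restriction = lineage_restriction,
              aa_profiles = aa_profiles,
              length_medians = length_medians,
              length_sdlog = length_sdlog,
              mutation_rate = mutation_rate,
              planted_enrichments = planted_enrichments,
              n_background_domains = as.integer(n_background_domains),
              domain_prevalence = domain_prevalence,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  chk_prop <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop("cohort_config: '", nm, "' must be a proportion in [0, 1]")
    }
  }
  if (cfg$n_taxa < 1L) stop("cohort_config: 'n_taxa' must be >= 1")
  if (cfg$n_families < 0L) stop("cohort_config: 'n_families' must be >= 0")
  chk_prop(cfg$dark_family_fraction, "dark_family_fraction")
  chk_prop(cfg$singleton_fraction, "singleton_fraction")
  chk_prop(cfg$dark_singleton_fraction, "dark_singleton_fraction")
  chk_prop(cfg$lineage_restriction, "lineage_restriction")
  chk_prop(cfg$mutation_rate, "mutation_rate")
  if (cfg$singleton_fraction >= 1) {
    stop("cohort_config: 'singleton_fraction' must be < 1")
  }
  if (any(cfg$family_size_means <= 1)) {
    stop("cohort_config: 'family_size_means' must both exceed 1")
  }
  for (nm in c("dark", "annotated")) {
    p <- cfg$aa_profiles[[nm]]
    if (length(p) != 20L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("cohort_config: 'aa_profiles$", nm,
           "' must be a 20-vector summing to 1")
    }
  }
  if (!is.null(cfg$planted_enrichments)) {
    pe <- cfg$planted_enrichments
    if (!all(c("domain", "group", "odds_ratio") %in% names(pe))) {
      stop("cohort_config: 'planted_enrichments' needs columns ",
           "domain, group, odds_ratio")
    }
    if (any(pe$odds_ratio <= 0)) {
      stop("cohort_config: 'planted_enrichments' odds_ratio must be > 0")
    }
  }
  if (is.null(cfg$order_assignment)) {
    orders <- paste0("Order", seq_len(max(cfg$n_orders, 1L)))
    taxa <- sprintf("t%02d", seq_len(cfg$n_taxa))
    cfg$order_assignment <- stats::setNames(
      orders[((seq_len(cfg$n_taxa) - 1L) %% length(orders)) + 1L], taxa)
  } else {
    if (length(cfg$order_assignment) != cfg$n_taxa) {
      stop("cohort_config: 'order_assignment' must name all ", cfg$n_taxa,
           " taxa")
    }
  }
  cfg
}

# Draw a family size >= 2 with the requested mean.
draw_family_sizes <- function(n, mean_size, dispersion) {
  if (n == 0L) return(integer())
  2L + stats::rnbinom(n, size = dispersion, mu = mean_size - 2)
}

# Generate one founder sequence (integer-coded residues).
draw_founder <- function(len, profile) {
  sample.int(20L, len, replace = TRUE, prob = profile)
}

# Mutate founder: each site substituted with prob `rate` by a draw from
# the class profile.
mutate_seq <- function(founder, rate, profile) {
  if (rate <= 0) return(founder)
  hit <- stats::runif(length(founder)) < rate
  n <- sum(hit)
  if (n) founder[hit] <- sample.int(20L, n, replace = TRUE, prob = profile)
  founder
}

code_to_string <- function(code) {
  paste(AA_STANDARD[code], collapse = "")
}

#' Generate a synthetic cohort
#'
#' Plants `n_families` homologous families: each is dark with probability
#' `dark_family_fraction`, gets a size drawn around the class mean, a
#' founder sequence drawn i.i.d. from the class composition, and members
#' produced by per-site mutation of the founder. Dark families are
#' confined to a single order with probability `lineage_restriction`;
#' members are assigned to taxa sampled within the family's scope.
#' Singletons (fresh founders, no family) are added so that they make up
#' `singleton_fraction` of all proteins. Identical configuration and seed
#' reproduce the cohort exactly.
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`: list with `proteins`
#'   (data.frame `protein_id`, `taxon_id`, `sequence`, `length`),
#'   `truth_families` (data.frame `set_id`, `taxon_id`, `protein_id`),
#'   `truth_dark` (named logical per protein), `order_assignment`, and
#'   the `config` used.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  config <- validate_cohort_config(config)
  set.seed(derive_seed(config$seed, "cohort"))
  taxa <- names(config$order_assignment)
  orders <- config$order_assignment

  nf <- config$n_families
  fam_dark <- stats::runif(nf) < config$dark_family_fraction
  sizes <- integer(nf)
  sizes[fam_dark] <- draw_family_sizes(sum(fam_dark),
                                       config$family_size_means[["dark"]],
                                       config$family_size_dispersion)
  sizes[!fam_dark] <- draw_family_sizes(sum(!fam_dark),
                                        config$family_size_means[["annotated"]],
                                        config$family_size_dispersion)
  restricted <- fam_dark & (stats::runif(nf) < config$lineage_restriction)

  order_levels <- unique(orders)
  fam_rows <- vector("list", nf)
  seqs <- vector("list", nf)
  meds <- config$length_medians
  for (i in seq_len(nf)) {
    cls <- if (fam_dark[i]) "dark" else "annotated"
    prof <- config$aa_profiles[[cls]]
    len <- max(10L, round(stats::rlnorm(1, log(meds[[cls]]),
                                        config$length_sdlog)))
    founder <- draw_founder(len, prof)
    scope <- if (restricted[i]) {
      taxa[orders == sample(order_levels, 1L)]
    } else taxa
    mem_taxa <- sample(scope, sizes[i], replace = TRUE)
    mseq <- character(sizes[i])
    for (j in seq_len(sizes[i])) {
      mseq[j] <- code_to_string(
        mutate_seq(founder, config$mutation_rate, prof))
    }
    fam_rows[[i]] <- data.frame(
      set_id = sprintf("F%05d", i), taxon_id = mem_taxa,
      stringsAsFactors = FALSE)
    seqs[[i]] <- mseq
  }
  fam <- do.call(rbind, fam_rows)
  n_clustered <- if (is.null(fam)) 0L else nrow(fam)

  sf <- config$singleton_fraction
  n_single <- round(n_clustered * sf / (1 - sf))
  sing_dark <- stats::runif(n_single) < config$dark_singleton_fraction
  sing_taxa <- if (n_single) sample(taxa, n_single, replace = TRUE) else character()
  sing_seq <- character(n_single)
  for (i in seq_len(n_single)) {
    cls <- if (sing_dark[i]) "dark" else "annotated"
    prof <- config$aa_profiles[[cls]]
    len <- max(10L, round(stats::rlnorm(1, log(meds[[cls]]),
                                        config$length_sdlog)))
    sing_seq[i] <- code_to_string(draw_founder(len, prof))
  }

  # assemble protein table; per-taxon running index gives local ids
  all_taxa <- c(if (n_clustered) fam$taxon_id else character(), sing_taxa)
  all_seq <- c(unlist(seqs, use.names = FALSE) %||% character(), sing_seq)
  pid <- if (length(all_taxa)) {
    local <- stats::ave(seq_along(all_taxa), all_taxa, FUN = seq_along)
    namespace_id(all_taxa, sprintf("p%06d", local))
  } else character()
  proteins <- data.frame(protein_id = pid, taxon_id = all_taxa,
                         sequence = all_seq, length = nchar(all_seq),
                         stringsAsFactors = FALSE)
  truth_families <- if (n_clustered) {
    data.frame(set_id = fam$set_id, taxon_id = fam$taxon_id,
               protein_id = pid[seq_len(n_clustered)],
               stringsAsFactors = FALSE)
  } else {
    data.frame(set_id = character(), taxon_id = character(),
               protein_id = character(), stringsAsFactors = FALSE)
  }
  truth_dark <- c(if (n_clustered) rep(fam_dark, sizes), sing_dark)
  names(truth_dark) <- pid

  structure(list(proteins = proteins,
                 truth_families = truth_families,
                 truth_dark = truth_dark,
                 order_assignment = orders,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$proteins), "proteins,",
      length(unique(x$truth_families$set_id)), "families,",
      sum(!names(x$truth_dark) %in% x$truth_families$protein_id),
      "singletons;", round(100 * mean(x$truth_dark), 1), "% dark\n")
  invisible(x)
}

#' Cluster table from cohort ground truth
#'
#' Truth-consistent clustering: families become homologous sets,
#' unclustered proteins become singletons.
#'
#' @param cohort a [generate_cohort()] result.
#' @return a [cluster_table()].
#' @export
truth_clusters <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  clustered <- cohort$truth_families$protein_id
  sing <- cohort$proteins[!cohort$proteins$protein_id %in% clustered,
                          c("taxon_id", "protein_id")]
  cluster_table(cohort$truth_families, sing)
}

#' Simulate database hit flags for a cohort
#'
#' Emulates a similarity search against annotated reference databases: a
#' truth-annotated protein receives a hit with probability
#' `1 - false_neg`; a truth-dark protein with probability `false_pos`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param false_pos probability a dark protein receives a spurious hit.
#' @param false_neg probability an annotated protein fails to hit.
#' @param seed integer seed.
#' @return data.frame with columns `protein_id`, `taxon_id`, `hit`
#'   (logical).
#' @export
generate_hit_table <- function(cohort, false_pos = 0, false_neg = 0,
                               seed = cohort$config$seed) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (false_pos < 0 || false_pos > 1 || false_neg < 0 || false_neg > 1) {
    stop("generate_hit_table(): rates must be in [0, 1]")
  }
  set.seed(derive_seed(seed, "hits"))
  n <- nrow(cohort$proteins)
  if (n == 0L) {
    return(data.frame(protein_id = character(), taxon_id = character(),
                      hit = logical(), stringsAsFactors = FALSE))
  }
  dark <- unname(cohort$truth_dark[cohort$proteins$protein_id])
  if (anyNA(dark)) {
    stop("generate_hit_table(): protein(s) missing from truth_dark")
  }
  p_hit <- ifelse(dark, false_pos, 1 - false_neg)
  data.frame(protein_id = cohort$proteins$protein_id,
             taxon_id = cohort$proteins$taxon_id,
             hit = stats::runif(n) < p_hit,
             stringsAsFactors = FALSE)
}

#' Simulate domain annotations and a GO DAG
#'
#' Background domains are assigned homogeneously across groups at the
#' baseline prevalence. For every planted `(domain, group, odds_ratio)`
#' the within-group prevalence is raised so the odds of carrying the
#' domain in the target group versus the rest equal the requested odds
#' ratio. Each domain maps to one GO term in a randomly generated acyclic
#' term hierarchy (edges child -> parent, always towards lower term
#' index, hence acyclic).
#'
#' @param cohort a [generate_cohort()] result.
#' @param config the [cohort_config()]; its `planted_enrichments`,
#'   `n_background_domains` and `domain_prevalence` fields are used.
#' @param seed integer seed.
#' @return list with `domains` (data.frame `protein_id`, `domain`),
#'   `gene2go` (data.frame `protein_id`, `go_id`), `go_dag` (data.frame
#'   `child`, `parent`), and `truth_enriched` (data.frame `domain`,
#'   `group`).
#' @export
generate_domain_annotations <- function(cohort, config = cohort$config,
                                        seed = config$seed) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  pe <- config$planted_enrichments
  groups <- unname(cohort$order_assignment[cohort$proteins$taxon_id])
  if (!is.null(pe)) {
    missing_grp <- setdiff(pe$group, unique(groups))
    if (length(missing_grp)) {
      stop("generate_domain_annotations(): planted group(s) not in cohort: ",
           paste(missing_grp, collapse = ", "))
    }
    if (any(pe$odds_ratio <= 0)) {
      stop("generate_domain_annotations(): odds_ratio must be > 0")
    }
  }
  set.seed(derive_seed(seed, "domains"))
  n <- nrow(cohort$proteins)
  p0 <- config$domain_prevalence
  doms <- sprintf("DOM%03d", seq_len(config$n_background_domains))
  planted_doms <- if (is.null(pe)) character() else unique(pe$domain)
  all_doms <- c(doms, setdiff(planted_doms, doms))

  rows <- vector("list", length(all_doms))
  for (k in seq_along(all_doms)) {
    d <- all_doms[k]
    p <- rep(p0, n)
    if (!is.null(pe) && d %in% pe$domain) {
      for (r in which(pe$domain == d)) {
        odds1 <- pe$odds_ratio[r] * p0 / (1 - p0)
        p[groups == pe$group[r]] <- odds1 / (1 + odds1)
      }
    }
    has <- stats::runif(n) < p
    if (any(has)) {
      rows[[k]] <- data.frame(protein_id = cohort$proteins$protein_id[has],
                              domain = d, stringsAsFactors = FALSE)
    }
  }
  domains <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(domains)) {
    domains <- data.frame(protein_id = character(), domain = character(),
                          stringsAsFactors = FALSE)
  }

  # one GO term per domain; DAG edges always point to a lower index
  nt <- length(all_doms)
  go_ids <- sprintf("GO:%07d", seq_len(nt))
  dag <- if (nt >= 2L) {
    child_idx <- 2:nt
    parent_idx <- vapply(child_idx,
                         function(i) sample.int(i - 1L, 1L), 1L)
    data.frame(child = go_ids[child_idx], parent = go_ids[parent_idx],
               stringsAsFactors = FALSE)
  } else {
    data.frame(child = character(), parent = character(),
               stringsAsFactors = FALSE)
  }
  gene2go <- data.frame(protein_id = domains$protein_id,
                        go_id = go_ids[match(domains$domain, all_doms)],
                        stringsAsFactors = FALSE)
  truth <- if (is.null(pe)) {
    data.frame(domain = character(), group = character(),
               stringsAsFactors = FALSE)
  } else pe[, c("domain", "group")]
  list(domains = domains, gene2go = gene2go, go_dag = dag,
       truth_enriched = truth)
}

#' Write cohort artifacts to disk
#'
#' Per-taxon FASTA (wrapped at 60 columns), truth tables as TSV, the GO
#' DAG as a two-column child/parent TSV and the configuration as YAML.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param annotations optional [generate_domain_annotations()] result.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, annotations = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tx in unique(cohort$proteins$taxon_id)) {
    recs <- cohort$proteins[cohort$proteins$taxon_id == tx, ]
    write_fasta(recs, file.path(dir, paste0(tx, ".faa")), width = 60)
  }
  utils::write.table(cohort$truth_families,
                     file.path(dir, "truth_families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(protein_id = names(cohort$truth_dark),
               dark = unname(cohort$truth_dark)),
    file.path(dir, "truth_dark.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  cfg_out <- cfg[setdiff(names(cfg), "aa_profiles")]
  cfg_out$order_assignment <- as.list(cfg_out$order_assignment)
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  if (!is.null(annotations)) {
    utils::write.table(annotations$domains, file.path(dir, "domains.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(annotations$go_dag, file.path(dir, "go_dag.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
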