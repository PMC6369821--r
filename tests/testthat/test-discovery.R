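make_acgt <- function(pos, ref, A, C, G, T, chrom = "chr2L") {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = pos, ref = ref,
             A = A, C = C, G = G, T = T, stringsAsFactors = FALSE)
}

test_that("variant calling applies the full filter cascade", {
  cfg <- discovery_config(min_depth = 20, min_alt_reads = 3,
                          min_alt_fraction = 0.05, max_alt_fraction = 0.95)
  # depth 50, alt G = 5 -> called
  v <- call_variants(make_acgt(100L, "A", 45L, 0L, 5L, 0L), cfg)
  expect_equal(nrow(v), 1L)
  expect_equal(v$alt, "G")
  expect_equal(v$alt_fraction, 0.1)
  # homozygous-SNP-like: alt fraction 1.0 rejected by max_alt_fraction
  expect_equal(nrow(call_variants(make_acgt(100L, "A", 0L, 0L, 50L, 0L), cfg)), 0L)
  # below min_alt_reads
  expect_equal(nrow(call_variants(make_acgt(100L, "A", 48L, 0L, 2L, 0L), cfg)), 0L)
  # below min_depth
  expect_equal(nrow(call_variants(make_acgt(100L, "A", 10L, 0L, 5L, 0L), cfg)), 0L)
  # SNP exclusion list wins regardless of counts
  cfg_snp <- discovery_config(snp_exclude = sites("chr2L", 100L))
  expect_equal(nrow(call_variants(make_acgt(100L, "A", 45L, 0L, 5L, 0L), cfg_snp)), 0L)
  # empty input
  expect_equal(nrow(call_variants(make_acgt(integer(0), character(0),
                                            integer(0), integer(0),
                                            integer(0), integer(0)))), 0L)
})

test_that("raising any discovery threshold never adds a variant (monotonicity)", {
  set.seed(42)
  n <- 300
  counts <- make_acgt(seq_len(n) * 10L, sample(c("A", "C", "G", "T"), n, TRUE),
                      rpois(n, 30), rpois(n, 2), rpois(n, 6), rpois(n, 2))
  base_cfg <- discovery_config(min_depth = 10, min_alt_reads = 2,
                               min_alt_fraction = 0.02, max_alt_fraction = 0.98)
  base_ids <- with(call_variants(counts, base_cfg), paste(pos, alt))
  harder <- list(
    discovery_config(min_depth = 25, min_alt_reads = 2, min_alt_fraction = 0.02,
                     max_alt_fraction = 0.98),
    discovery_config(min_depth = 10, min_alt_reads = 5, min_alt_fraction = 0.02,
                     max_alt_fraction = 0.98),
    discovery_config(min_depth = 10, min_alt_reads = 2, min_alt_fraction = 0.10,
                     max_alt_fraction = 0.98),
    discovery_config(min_depth = 10, min_alt_reads = 2, min_alt_fraction = 0.02,
                     max_alt_fraction = 0.80))
  for (cfg in harder) {
    ids <- with(call_variants(counts, cfg), paste(pos, alt))
    expect_true(all(ids %in% base_ids))
  }
})

test_that("conversion tally counts twelve classes and the A-to-I signature fraction", {
  v <- data.frame(ref = c(rep("A", 60), rep("T", 28), rep("C", 12)),
                  alt = c(rep("G", 60), rep("C", 28), rep("T", 12)),
                  stringsAsFactors = FALSE)
  tal <- conversion_tally(v)
  expect_equal(nrow(tal), 12L)
  expect_equal(sum(tal$n), nrow(v))
  expect_equal(attr(tal, "ag_fraction"), 0.88)
  all_ct <- conversion_tally(data.frame(ref = rep("C", 5), alt = rep("T", 5)))
  expect_equal(attr(all_ct, "ag_fraction"), 0)
})

test_that("synthetic artifact rate is reflected in the conversion tally", {
  truth <- synthetic_truth(n_populations = 2, replicates = 2, n_sites = 150,
                           mean_depth = 200, snp_rate = 0,
                           conversion_noise_rate = 0.3, seed = 7)
  sim <- gen_counts(truth)
  cm <- sim$counts
  pooled <- data.frame(chrom = cm$sites$chrom, pos = cm$sites$pos, ref = "A",
                       A = rowSums(cm$base$A), C = rowSums(cm$base$C),
                       G = rowSums(cm$base$G), T = rowSums(cm$base$T),
                       stringsAsFactors = FALSE)
  v <- call_variants(pooled, discovery_config(min_depth = 20, min_alt_reads = 3,
                                              min_alt_fraction = 0.05))
  tal <- conversion_tally(v)
  n_ag <- tal$n[tal$conversion == "A>G"]
  n_ac <- tal$n[tal$conversion == "A>C"]
  # noise positions called as A>C; their share tracks the planted rate
  expect_gt(n_ac, 0)
  expect_equal(attr(tal, "ag_fraction"), n_ag / (n_ag + n_ac), tolerance = 1e-12)
  expect_lt(abs(n_ac / 150 - 0.3), 0.12)   # ~ conversion_noise_rate
})

test_that("known/novel split is a partition", {
  s <- sites("chr2L", c(100L, 200L, 300L))
  known <- sites("chr2L", c(100L, 300L, 999L))
  sp <- split_known_novel(s, known)
  expect_equal(nrow(sp$known), 2L)
  expect_equal(nrow(sp$novel), 1L)
  expect_equal(nrow(sp$known) + nrow(sp$novel), nrow(s))
  expect_length(intersect(site_id(sp$known), site_id(sp$novel)), 0L)
  all_novel <- split_known_novel(s, sites(character(0), integer(0)))
  expect_equal(nrow(all_novel$novel), 3L)
})

test_that("locus chaining follows the gap rule and matches brute force", {
  s <- sites("chr2L", c(100L, 150L, 260L))
  cl <- cluster_loci(s, locus_gap = 100)
  expect_equal(cl$assignment$locus, c(1L, 1L, 2L))   # gaps 50, 110
  expect_equal(cl$loci$n_sites, c(2L, 1L))
  single <- cluster_loci(sites("chrX", 5L))
  expect_equal(single$loci$n_sites, 1L)

  set.seed(99)
  rs <- sort(sample(1:20000, 200))
  rnd <- sites(sample(c("chr2L", "chr3R"), 200, TRUE), rs,
               sample(c("+", "-"), 200, TRUE))
  got <- cluster_loci(rnd, locus_gap = 100)$assignment$locus
  want <- brute_chain(rnd, 100)
  expect_equal(canon_partition(got), canon_partition(want))
  # locus count identity: n_loci = n_sites - #adjacent same-chrom/strand pairs
  # with gap < 100
  o <- order(rnd$chrom, rnd$strand, rnd$pos)
  so <- rnd[o, ]
  adj <- sum(diff(so$pos) < 100 & so$chrom[-1] == so$chrom[-200] &
             so$strand[-1] == so$strand[-200])
  expect_equal(max(got), 200 - adj)
})

test_that("locus chaining is invariant to input order", {
  set.seed(3)
  s <- sites("chr2L", sample(1:5000, 80))
  shuffled <- s[sample(nrow(s)), ]
  a <- cluster_loci(s, 100)
  b <- cluster_loci(shuffled, 100)
  key_a <- split(site_id(a$assignment), a$assignment$locus)
  key_b <- split(site_id(b$assignment), b$assignment$locus)
  expect_setequal(
    unname(vapply(key_a, function(x) paste(sort(x), collapse = ","), "")),
    unname(vapply(key_b, function(x) paste(sort(x), collapse = ","), "")))
})

test_that("annotation summaries count categories and repeat overlap", {
  s <- sites("chr2L", (1:10) * 100L)
  an <- site_annotation(s,
                        known = rep(c(TRUE, FALSE), c(5, 5)),
                        category = rep(c("nonsynonymous", "intron"), 5),
                        repeat_overlap = c(rep(FALSE, 5), TRUE, TRUE, TRUE, TRUE, FALSE))
  summ <- annotation_summary(s, an)
  expect_equal(sum(summ$by_category$known), 5)
  expect_equal(sum(summ$by_category$novel), 5)
  expect_equal(unname(summ$repeat_fraction["novel"]), 0.8)
  expect_equal(unname(summ$repeat_fraction["known"]), 0)
  # no annotations: everything intergenic and novel
  bare <- annotation_summary(s, NULL)
  expect_equal(bare$by_category$novel[bare$by_category$category == "intergenic"], 10)
})

test_that("discovery recall and false calls respond to planted truth", {
  set.seed(21)
  truth <- synthetic_truth(n_populations = 2, replicates = 3, n_sites = 100,
                           base_levels = runif(100, 0.1, 0.6),
                           mean_depth = 120, snp_rate = 0.2, seed = 21)
  sim <- gen_counts(truth)
  cm <- sim$counts
  pooled <- data.frame(chrom = cm$sites$chrom, pos = cm$sites$pos,
                       ref = cm$sites$ref_base,
                       A = rowSums(cm$base$A), C = rowSums(cm$base$C),
                       G = rowSums(cm$base$G), T = rowSums(cm$base$T),
                       stringsAsFactors = FALSE)
  cfg <- discovery_config()
  v <- call_variants(pooled, cfg)
  vg <- v[v$alt == "G", ]
  true_pos <- sim$truth$sites$pos
  art_pos <- sim$artifact_sites$pos
  recall <- mean(true_pos %in% vg$pos)
  expect_gt(recall, 0.9)
  # artifact positions are homozygous/heterozygous SNP-like; the 0.95 cap
  # removes the homozygous ones and the SNP list the rest
  called_art <- intersect(art_pos, vg$pos)
  expect_true(all(vg$alt_fraction[vg$pos %in% called_art] <= 0.95))
  cfg_snp <- discovery_config(snp_exclude = sim$artifact_sites)
  v2 <- call_variants(pooled, cfg_snp)
  expect_length(intersect(art_pos, v2$pos), 0L)
})
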