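# isoform string order as the package produces it (site 1 = first character)
isoform_keys_for_test <- function(k) {
  g <- expand.grid(rep(list(c("A", "G")), k), stringsAsFactors = FALSE)[, k:1]
  apply(g, 1, paste, collapse = "")
}

test_that("cluster finding chains nearby sites and drops singletons", {
  s <- sites("chr2L", c(10L, 45L, 120L))
  cl <- find_clusters(s, 40)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$pos, c(10L, 45L))   # 35 < 40; 120 is a singleton
  chained <- find_clusters(sites("chr2L", c(10L, 49L, 88L)), 40)
  expect_length(chained, 1L)
  expect_equal(chained[[1]]$pos, c(10L, 49L, 88L))
})

test_that("cluster partitions equal brute-force connected components", {
  set.seed(61)
  for (rep in 1:5) {
    s <- sites("chr2L", sort(sample(1:2000, 60)))
    cl <- find_clusters(s, 40)
    comp <- brute_chain(s, 40)
    brute <- unname(Filter(function(x) length(x) >= 2,
                           split(s$pos, canon_partition(comp))))
    got <- lapply(cl, function(x) x$pos)
    expect_equal(got, brute)
  }
})

test_that("isoform counting enforces the spanning rule and marginal consistency", {
  cl <- sites("chr2L", c(100L, 130L))
  calls <- rbind(
    matrix(rep(c("A", "A"), 6), 6, 2, byrow = TRUE),
    c("A", "G"), c("G", "A"), c("G", "G"), c("G", "G"))
  ic <- isoform_counts(calls, cl, strand_adjust = FALSE)
  expect_equal(as.integer(ic), c(6L, 1L, 1L, 2L))
  expect_equal(names(ic), c("AA", "AG", "GA", "GG"))
  expect_equal(isoform_marginals(ic), c(0.3, 0.3))
  # reads not covering every site (NA) or with non-A/G calls are discarded
  calls2 <- rbind(calls, c("A", NA), c("C", "G"))
  ic2 <- isoform_counts(calls2, cl, strand_adjust = FALSE)
  expect_equal(sum(ic2), 10L)
  # minus-strand site: genome-strand C complements to G
  cl_minus <- sites("chr2L", c(100L, 130L), c("+", "-"))
  ic3 <- isoform_counts(rbind(c("A", "C"), c("A", "T")), cl_minus)
  expect_equal(unname(ic3["AG"]), 1L)
  expect_equal(unname(ic3["AA"]), 1L)
})

test_that("independence expectation is the product distribution", {
  e <- expected_independent(c(0.5, 0.5))
  expect_equal(unname(e), rep(0.25, 4))
  e2 <- expected_independent(c(0, 0.3))
  expect_equal(unname(e2[c("GA", "GG")]), c(0, 0))
  expect_equal(unname(e2["AA"]), 0.7)
  expect_equal(unname(e2["AG"]), 0.3)
  e3 <- expected_independent(c(0.29, 0.34))
  expect_equal(unname(e3["AA"]), 0.4686, tolerance = 1e-12)
  expect_equal(unname(e3["GG"]), 0.0986, tolerance = 1e-12)
  expect_equal(sum(e3), 1, tolerance = 1e-12)
  # marginals of the expectation reproduce the inputs exactly
  expect_equal(isoform_marginals(e3), c(0.29, 0.34), tolerance = 1e-12)
})

test_that("independence expectation equals the constrained multinomial MLE", {
  # oracle: maximize the multinomial likelihood over independent joint tables
  # parameterized by (p1, p2) on a 2-site cluster
  counts <- c(AA = 30, AG = 14, GA = 9, GG = 7)
  negll <- function(par) {
    tab <- expected_independent(par)
    -sum(counts * log(tab[names(counts)]))
  }
  fit <- optim(c(0.5, 0.5), negll, method = "L-BFGS-B",
               lower = 1e-6, upper = 1 - 1e-6)
  expect_equal(fit$par, isoform_marginals(counts), tolerance = 1e-5)
  # and the implied table matches expected_independent at the MLE
  expect_equal(expected_independent(fit$par),
               expected_independent(isoform_marginals(counts)),
               tolerance = 1e-4)
})

test_that("observed equals expected gives zero differences and p near 1", {
  # counts drawn exactly at independence: 0.5/0.5 -> 25 each
  ic <- structure(c(AA = 25L, AG = 25L, GA = 25L, GG = 25L))
  res <- observed_vs_expected(list(ic, ic, ic))
  expect_equal(res$mean_diff, rep(0, 4))
  expect_equal(res$p_value, rep(1, 4))
})

test_that("full linkage produces the coregulation sign signature", {
  # only AA and GG reads with marginals 0.3: diff(GG) = 0.3 - 0.09 = +0.21
  ic <- c(AA = 70L, AG = 0L, GA = 0L, GG = 30L)
  res <- observed_vs_expected(list(ic, ic, ic))
  expect_equal(res$mean_diff[res$isoform == "GG"], 0.21, tolerance = 1e-12)
  expect_equal(res$mean_diff[res$isoform == "AA"], 0.21, tolerance = 1e-12)
  expect_equal(res$mean_diff[res$isoform == "AG"], -0.21, tolerance = 1e-12)
  expect_equal(res$mean_diff[res$isoform == "GA"], -0.21, tolerance = 1e-12)
  expect_equal(sum(res$mean_diff), 0, tolerance = 1e-12)
  # the signature generalizes: on fully linked draws, all-A and all-G diffs
  # are positive and every mixed isoform negative
  joint <- joint_isoform_table(rep(0.25, 3), mode = "fully_linked")
  iso <- gen_cluster_reads(joint, 3000, seed = 5)
  icc <- isoform_counts(
    do.call(rbind, strsplit(iso, "")), sites("chr2L", c(1L, 10L, 20L)),
    strand_adjust = FALSE)
  res3 <- observed_vs_expected(list(icc))
  mixed <- !res3$isoform %in% c("AAA", "GGG")
  expect_true(all(res3$mean_diff[!mixed] > 0))
  expect_true(all(res3$mean_diff[mixed] <= 0))
})

test_that("independent draws show differences within Monte-Carlo error of zero", {
  joint <- joint_isoform_table(c(0.3, 0.4), mode = "independent")
  set.seed(9)
  reps <- lapply(1:3, function(r) {
    iso <- gen_cluster_reads(joint, 5000, seed = 100 + r)
    isoform_counts(do.call(rbind, strsplit(iso, "")),
                   sites("chr2L", c(1L, 10L)), strand_adjust = FALSE)
  })
  res <- observed_vs_expected(reps)
  expect_true(all(abs(res$mean_diff) < 0.02))
  expect_true(all(res$p_value > 0.01))
})

test_that("population-vs-others isoform comparisons gate on a 10-point difference", {
  sheet <- make_sheet(4, 3)
  # focal population pop01 strongly linked, others independent; replicate
  # counts jittered so the Welch test has within-group variance
  linked <- lapply(c(0L, 2L, -2L), function(d)
    c(AA = 60L + d, AG = 2L, GA = 2L, GG = 36L - d))
  indep <- lapply(rep(c(0L, 3L, -3L), 3), function(d)
    c(AA = 42L + d, AG = 28L, GA = 18L, GG = 12L - d))
  counts <- c(linked, indep)
  names(counts) <- sheet$sample_id
  res <- isoform_population_diff(counts, sheet, "pop01")
  gg <- res[res$isoform == "GG", ]
  expect_true(gg$flagged)
  expect_gt(abs(gg$mean_diff), 0.10)
  # small differences are not flagged even if consistent
  near <- lapply(c(0L, 3L, -3L), function(d)
    c(AA = 45L + d, AG = 25L, GA = 18L, GG = 12L - d))
  counts2 <- c(near, indep)
  names(counts2) <- sheet$sample_id
  res2 <- isoform_population_diff(counts2, sheet, "pop01")
  expect_false(any(res2$flagged))
})

test_that("sequential-editing asymmetry is recovered as a precedence order", {
  # pattern where every edited isoform includes editing at site 1
  counts <- c(AAA = 40L, GAA = 20L, GGA = 15L, GAG = 10L, GGG = 15L,
              AGA = 0L, AAG = 0L, AGG = 0L)
  ord <- ordering_inference(counts[isoform_keys_for_test(3)], noise_floor = 0.02)
  expect_setequal(paste(ord$before, ord$after), c("1 2", "1 3"))
  # symmetric mixed patterns yield no order
  sym <- c(AA = 50L, AG = 10L, GA = 10L, GG = 30L)
  expect_equal(nrow(ordering_inference(sym)), 0L)
  # simulated sequential truth (site 1 first) is recovered
  joint <- joint_isoform_table(c(0.5, 0.3), mode = "sequential")
  iso <- gen_cluster_reads(joint, 4000, seed = 17)
  ic <- isoform_counts(do.call(rbind, strsplit(iso, "")),
                       sites("chr2L", c(1L, 10L)), strand_adjust = FALSE)
  ord2 <- ordering_inference(ic)
  expect_equal(nrow(ord2), 1L)
  expect_equal(c(ord2$before, ord2$after), c(1L, 2L))
})
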