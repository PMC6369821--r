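#' Define a synthetic editing-study ground truth
#'
#' Builds the design of a simulated comparative editing study: a panel of
#' populations with replicates, per-site true editing levels (shared across
#' populations except at planted population-specific sites), a negative-
#' binomial coverage model, beta-binomial within-replicate overdispersion,
#' and optional SNP-like artifact positions for discovery testing. The default
#' design mirrors a typical population-resolved study: 10 populations x 3
#' replicates, mean depth 300, mild overdispersion (rho = 0.01) so replicate
#' levels are highly reproducible.
#'
#' @param n_populations number of populations (default 10).
#' @param replicates replicates per population (default 3).
#' @param n_sites number of true editing sites (default 200).
#' @param base_levels optional vector of true levels; by default drawn from
#'   Beta(1.2, 4) (editing levels are mostly low, some sites high).
#' @param specific data.frame with columns `site` (index), `population`
#'   (label or index) and `shift` (added to that population's true level,
#'   clipped to `[0, 1]`); NULL for none.
#' @param mean_depth negative-binomial mean per replicate (default 300).
#' @param nb_size negative-binomial size (dispersion) parameter; larger is
#'   closer to Poisson (default 10). `Inf` gives fixed depth = mean_depth.
#' @param rho beta-binomial intra-class correlation of the per-replicate
#'   editing probability (default 0.01; 0 = pure binomial).
#' @param snp_rate expected number of SNP-like artifact positions per true
#'   site (default 0); artifacts get alt fraction ~0.5 or ~1.0.
#' @param conversion_noise_rate per-site probability of a low-level non-A-to-G
#'   mismatch artifact position (default 0).
#' @param seed integer seed stored with the truth and used by [gen_counts()].
#' @return object of class `synthetic_truth`: sites, level matrix
#'   (sites x populations), design, coverage/artifact models.
#' @export
synthetic_truth <- function(n_populations = 10, replicates = 3, n_sites = 200,
                            base_levels = NULL, specific = NULL,
                            mean_depth = 300, nb_size = 10, rho = 0.01,
                            snp_rate = 0, conversion_noise_rate = 0,
                            seed = 1L) {
  stopifnot(n_populations >= 1, replicates >= 1, n_sites >= 1,
            mean_depth > 0, rho >= 0, rho < 1)
  set.seed(seed)
  if (is.null(base_levels)) base_levels <- stats::rbeta(n_sites, 1.2, 4)
  base_levels <- rep_len(base_levels, n_sites)
  pops <- paste0("pop", sprintf("%02d", seq_len(n_populations)))
  levels <- matrix(base_levels, n_sites, n_populations,
                   dimnames = list(NULL, pops))
  if (!is.null(specific) && nrow(specific) > 0) {
    pop_idx <- if (is.numeric(specific$population)) specific$population
      else match(specific$population, pops)
    if (anyNA(pop_idx)) stop("unknown population in `specific`")
    for (r in seq_len(nrow(specific))) {
      i <- specific$site[r]
      levels[i, pop_idx[r]] <-
        min(1, max(0, levels[i, pop_idx[r]] + specific$shift[r]))
    }
    specific <- data.frame(site = specific$site, population = pops[pop_idx],
                           shift = specific$shift, stringsAsFactors = FALSE)
  }
  s <- sites("chr2L", seq_len(n_sites) * 1000L, "+")
  structure(list(sites = s, populations = pops, replicates = replicates,
                 levels = levels, specific = specific,
                 mean_depth = mean_depth, nb_size = nb_size, rho = rho,
                 snp_rate = snp_rate,
                 conversion_noise_rate = conversion_noise_rate,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", nrow(x$sites), "sites,", length(x$populations),
      "populations x", x$replicates, "replicates\n")
  cat("  mean depth", x$mean_depth, "(NB size", x$nb_size, "), rho", x$rho, "\n")
  if (!is.null(x$specific))
    cat("  planted specific sites:", nrow(x$specific), "\n")
  invisible(x)
}

# one beta-binomial draw per element: p_rep ~ Beta with mean p, icc rho
rbetabinom <- function(n, size, p, rho) {
  p <- rep_len(p, n); size <- rep_len(size, n)
  if (rho <= 0) return(stats::rbinom(n, size, p))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  pr <- ifelse(p <= 0, 0, ifelse(p >= 1, 1, stats::rbeta(n, pmax(a, 1e-12),
                                                         pmax(b, 1e-12))))
  stats::rbinom(n, size, pr)
}

#' Generate replicate-level base counts from a synthetic truth
#'
#' Per (site, replicate): total coverage is negative binomial, the edited (G)
#' count beta-binomial around the population's true level. Full genome-strand
#' A/C/G/T counts are emitted; optional artifacts are appended as extra
#' positions: SNP-like sites with alt fraction around 0.5 or 1.0 in every
#' sample, and sporadic non-A-to-G conversion noise.
#'
#' @param truth `synthetic_truth`.
#' @param seed overrides the truth's stored seed when given.
#' @return list with `counts` (`edit_counts` with full base counts; SNP-like
#'   artifact positions, when present, are appended as extra rows so discovery
#'   filters can be exercised against them), `sheet` (`sample_sheet`),
#'   `truth`, and `artifact_sites` (sites data.frame).
#' @export
gen_counts <- function(truth, seed = NULL) {
  set.seed(if (is.null(seed)) truth$seed else seed)
  ns <- nrow(truth$sites)
  pops <- truth$populations
  reps <- truth$replicates
  sample_ids <- as.vector(t(outer(pops, seq_len(reps),
                                  function(p, r) paste0(p, "_r", r))))
  sheet <- sample_sheet(sample_ids, rep(pops, each = reps),
                        rep(seq_len(reps), length(pops)))
  nk <- length(sample_ids)
  tot <- matrix(
    if (is.finite(truth$nb_size))
      stats::rnbinom(ns * nk, mu = truth$mean_depth, size = truth$nb_size)
    else rep(truth$mean_depth, ns * nk),
    ns, nk)
  p <- truth$levels[, rep(seq_along(pops), each = reps), drop = FALSE]
  g <- matrix(rbetabinom(ns * nk, as.vector(tot), as.vector(p), truth$rho),
              ns, nk)
  a <- tot - g
  s <- truth$sites
  baseA <- ifelse(matrix(s$strand == "+", ns, nk), a, 0L)
  baseG <- ifelse(matrix(s$strand == "+", ns, nk), g, 0L)
  baseT <- ifelse(matrix(s$strand == "+", ns, nk), 0L, a)
  baseC <- ifelse(matrix(s$strand == "+", ns, nk), 0L, g)
  # sporadic non-A-to-G conversion noise on top of true sites
  if (truth$conversion_noise_rate > 0) {
    noisy <- which(stats::runif(ns) < truth$conversion_noise_rate)
    for (i in noisy) {
      extra <- stats::rbinom(nk, pmax(1L, tot[i, ]), 0.08)
      baseC[i, ] <- baseC[i, ] + extra   # A>C mismatch noise on plus strand
    }
  }
  all_sites <- s
  artifact_sites <- sites(character(0), integer(0), character(0))
  # SNP-like artifact positions (heterozygous ~0.5 or homozygous ~1.0)
  n_art <- stats::rpois(1, truth$snp_rate * ns)
  if (n_art > 0) {
    apos <- max(s$pos) + seq_len(n_art) * 1000L + 500L
    artifact_sites <- sites("chr2L", apos, "+")
    hom <- stats::runif(n_art) < 0.5
    atot <- matrix(stats::rnbinom(n_art * nk, mu = truth$mean_depth,
                                  size = truth$nb_size), n_art, nk)
    af <- ifelse(hom, 1.0, 0.5)
    ag <- matrix(stats::rbinom(n_art * nk, as.vector(atot),
                               rep(af, nk)), n_art, nk)
    all_sites <- rbind(s, artifact_sites)
    pad <- function(m, extra) rbind(m, extra)
    baseA <- pad(baseA, atot - ag); baseG <- pad(baseG, ag)
    baseC <- pad(baseC, matrix(0L, n_art, nk))
    baseT <- pad(baseT, matrix(0L, n_art, nk))
    a <- pad(a, atot - ag); g <- pad(g, ag)
  }
  cm <- edit_counts(all_sites, sample_ids, a, g,
                    base = list(A = baseA, C = baseC, G = baseG, T = baseT))
  list(counts = cm, sheet = sheet, truth = truth,
       artifact_sites = artifact_sites)
}

#' Joint isoform distribution for a simulated site cluster
#'
#' Builds the joint distribution over editing isoforms of a k-site cluster
#' (k = 2..4) with the given per-site marginal edited fractions:
#' - "independent": product distribution;
#' - "fully_linked": all sites edited together or none (requires equal
#'   marginals p: all-G with probability p, all-A otherwise);
#' - "sequential": editing at site 1 is required for editing at any later
#'   site; conditional on site 1 being edited, later sites are edited
#'   independently with probability marginal/p1 (requires p1 >= all others);
#' - "custom": a user table (named over isoform strings), validated to sum to
#'   1; its marginals become the truth.
#'
#' @param marginals per-site true edited fractions.
#' @param mode one of "independent", "fully_linked", "sequential", "custom".
#' @param table named probability vector for mode "custom".
#' @return named numeric vector over all 2^k isoform strings (sums to 1),
#'   with attribute `marginals`.
#' @export
joint_isoform_table <- function(marginals,
                                mode = c("independent", "fully_linked",
                                         "sequential", "custom"),
                                table = NULL) {
  mode <- match.arg(mode)
  if (mode == "custom") {
    k <- nchar(names(table)[1])
    keys <- isoform_keys(k)
    if (!setequal(names(table), keys))
      stop("custom table must be named over all 2^k isoform strings")
    tab <- as.numeric(table[keys]); names(tab) <- keys
    if (abs(sum(tab) - 1) > 1e-9) stop("custom table must sum to 1")
    if (any(tab < 0)) stop("probabilities must be non-negative")
    attr(tab, "marginals") <- isoform_marginals(tab)
    return(tab)
  }
  k <- length(marginals)
  if (k < 2 || k > 4) stop("cluster size must be 2-4")
  if (any(marginals < 0 | marginals > 1)) stop("marginals must be in [0, 1]")
  keys <- isoform_keys(k)
  tab <- switch(mode,
    independent = expected_independent(marginals),
    fully_linked = {
      if (max(marginals) - min(marginals) > 1e-9)
        stop("fully_linked mode requires equal marginals")
      p <- marginals[1]
      out <- stats::setNames(numeric(length(keys)), keys)
      out[paste(rep("A", k), collapse = "")] <- 1 - p
      out[paste(rep("G", k), collapse = "")] <- p
      out
    },
    sequential = {
      p1 <- marginals[1]
      if (any(marginals[-1] > p1 + 1e-12))
        stop("sequential mode requires the first site's marginal to be largest")
      cond <- if (p1 > 0) marginals[-1] / p1 else rep(0, k - 1)
      out <- vapply(keys, function(key) {
        bits <- strsplit(key, "")[[1]] == "G"
        if (!bits[1]) {
          if (any(bits[-1])) 0 else 1 - p1
        } else {
          p1 * prod(ifelse(bits[-1], cond, 1 - cond))
        }
      }, numeric(1))
      names(out) <- keys
      out
    })
  stopifnot(abs(sum(tab) - 1) < 1e-9)
  got <- isoform_marginals(tab)
  if (max(abs(got - marginals)) > 1e-9)
    stop("internal error: joint table marginals do not match")
  attr(tab, "marginals") <- marginals
  tab
}

#' Simulate spanning reads over a site cluster
#'
#' Draws editing-isoform strings from a joint table, optionally emitting them
#' as toy SAM alignment records spanning the cluster for end-to-end pileup and
#' phasing tests.
#'
#' @param joint joint isoform distribution (see [joint_isoform_table()]).
#' @param n_reads number of spanning reads.
#' @param seed RNG seed.
#' @param cluster sites data.frame (needed for `as_sam`); sites must fit in
#'   one read.
#' @param as_sam return SAM text lines instead of isoform strings.
#' @param read_pad bases of flanking reference sequence on each side of the
#'   cluster in simulated reads (default 10).
#' @return character vector of isoform strings, or (with `as_sam`) a character
#'   vector of SAM lines (header + one record per read).
#' @export
gen_cluster_reads <- function(joint, n_reads, seed = 1L, cluster = NULL,
                              as_sam = FALSE, read_pad = 10L) {
  set.seed(seed)
  keys <- names(joint)
  iso <- sample(keys, n_reads, replace = TRUE, prob = as.numeric(joint))
  if (!as_sam) return(iso)
  if (is.null(cluster)) stop("cluster is required for SAM output")
  k <- nrow(cluster)
  if (nchar(keys[1]) != k) stop("cluster size does not match isoform length")
  chrom <- cluster$chrom[1]
  start <- min(cluster$pos) - read_pad
  end <- max(cluster$pos) + read_pad
  len <- end - start + 1L
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  tmpl <- rep("T", len)   # non-site reference filler
  offs <- cluster$pos - start + 1L
  recs <- vapply(seq_len(n_reads), function(r) {
    bases <- strsplit(iso[r], "")[[1]]
    genome <- ifelse(cluster$strand == "-", comp[bases], bases)
    sq <- tmpl; sq[offs] <- genome
    paste(paste0("read", r), 0, chrom, start, 60, paste0(len, "M"), "*", 0, 0,
          paste(sq, collapse = ""), paste(rep("I", len), collapse = ""),
          sep = "\t")
  }, character(1))
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", chrom, "\tLN:", end + 1000L))
  c(header, recs)
}

#' Tabulate a synthetic truth for test assertions
#'
#' @param truth `synthetic_truth`.
#' @return data.frame with one row per (site, population): chrom, pos, strand,
#'   population, true_level, specific shift (0 when none). Deterministic for a
#'   given truth object.
#' @export
truth_report <- function(truth) {
  ns <- nrow(truth$sites)
  np <- length(truth$populations)
  out <- data.frame(
    chrom = rep(truth$sites$chrom, np),
    pos = rep(truth$sites$pos, np),
    strand = rep(truth$sites$strand, np),
    population = rep(truth$populations, each = ns),
    true_level = as.vector(truth$levels),
    shift = 0, stringsAsFactors = FALSE)
  if (!is.null(truth$specific) && nrow(truth$specific) > 0) {
    for (r in seq_len(nrow(truth$specific))) {
      sel <- out$pos == truth$sites$pos[truth$specific$site[r]] &
        out$population == truth$specific$population[r]
      out$shift[sel] <- truth$specific$shift[r]
    }
  }
  out
}
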