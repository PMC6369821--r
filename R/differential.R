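#' Fisher's exact test on allele counts of two samples
#'
#' Two-sided exact test of the 2x2 table of edited/unedited read counts,
#' the standard test for a difference in editing level between two pooled
#' samples.
#'
#' @param a1,g1 unedited/edited counts in the first sample.
#' @param a2,g2 unedited/edited counts in the second sample.
#' @return two-sided p-value. An all-zero table returns 1 with a warning.
#' @examples
#' fisher_site(50, 50, 50, 50)   # identical proportions: p = 1
#' @export
fisher_site <- function(a1, g1, a2, g2) {
  if (any(c(a1, g1, a2, g2) < 0)) stop("counts must be non-negative")
  if (a1 + g1 + a2 + g2 == 0) {
    warning("all-zero table; returning p = 1")
    return(1)
  }
  tab <- matrix(c(g1, a1, g2, a2), nrow = 2, byrow = TRUE)
  stats::fisher.test(tab)$p.value
}

#' Pairwise differential editing between populations
#'
#' For every site and every unordered pair of populations, tests the pooled
#' A/G counts with Fisher's exact test and gates significance on both the
#' (multiplicity-adjusted) p-value and a minimum absolute editing-level
#' difference. A pair is skipped at a site when either population has no
#' coverage there.
#'
#' @param cm `edit_counts` at replicate resolution (pooled internally), or an
#'   already pooled object when `sheet` is NULL.
#' @param sheet `sample_sheet`, or NULL if `cm` is already per-population.
#' @param alpha significance threshold on the adjusted p-value (default 0.05).
#' @param min_delta minimum absolute level difference, as a fraction
#'   (default 0.20, i.e. 20 percentage points).
#' @param correction "BH" (Benjamini-Hochberg, default), "bonferroni", or
#'   "none" (raw p-values, as when quoting unadjusted P < 0.05); applied
#'   jointly across all site x pair tests.
#' @param min_coverage minimum pooled reads per population for a site to be
#'   compared in a pair (default 1: any coverage).
#' @return data.frame with one row per tested (site, pair): site coordinates,
#'   pop_a, pop_b, level_a, level_b, delta = level_a - level_b, p_value,
#'   p_adjusted, significant.
#' @export
pairwise_differential <- function(cm, sheet = NULL, alpha = 0.05,
                                  min_delta = 0.20,
                                  correction = c("BH", "bonferroni", "none"),
                                  min_coverage = 1) {
  correction <- match.arg(correction)
  pooled <- if (is.null(sheet)) cm else pool_replicates(cm, sheet)
  pops <- pooled$samples
  if (length(pops) < 2) stop("need at least two populations")
  tot <- pooled$a + pooled$g
  lv <- editing_levels(pooled)
  pairs <- utils::combn(pops, 2)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    pa <- pairs[1, k]; pb <- pairs[2, k]
    ia <- match(pa, pops); ib <- match(pb, pops)
    ok <- tot[, ia] >= min_coverage & tot[, ib] >= min_coverage
    if (!any(ok)) next
    w <- which(ok)
    p <- vapply(w, function(i) {
      stats::fisher.test(matrix(c(pooled$g[i, ia], pooled$a[i, ia],
                                  pooled$g[i, ib], pooled$a[i, ib]),
                                nrow = 2, byrow = TRUE))$p.value
    }, numeric(1))
    rows[[k]] <- data.frame(
      chrom = pooled$sites$chrom[w], pos = pooled$sites$pos[w],
      strand = pooled$sites$strand[w],
      pop_a = pa, pop_b = pb,
      level_a = lv[w, ia], level_b = lv[w, ib],
      delta = lv[w, ia] - lv[w, ib],
      p_value = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(chrom = character(), pos = integer(), strand = character(),
                      pop_a = character(), pop_b = character(),
                      level_a = numeric(), level_b = numeric(),
                      delta = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  res$p_adjusted <- stats::p.adjust(
    res$p_value, method = if (correction == "none") "none" else correction)
  res$significant <- res$p_adjusted < alpha & abs(res$delta) > min_delta
  rownames(res) <- NULL
  res
}

#' Per-population summary of differential-editing calls
#'
#' For each population, counts the sites edited significantly higher (and
#' lower) than at least one other population, and bins each site by the number
#' of other populations from which it differs in that direction.
#'
#' @param results data.frame from [pairwise_differential()].
#' @return data.frame with columns population, n_higher, n_lower; attribute
#'   `bins` holds the per-(population, direction) distribution of how many
#'   other populations each site differs from.
#' @export
population_summary <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  pops <- sort(unique(c(results$pop_a, results$pop_b)))
  key <- paste(sig$chrom, sig$pos, sig$strand, sep = ":")
  # orient every significant record as (population with higher level, other)
  hi_pop <- ifelse(sig$delta > 0, sig$pop_a, sig$pop_b)
  lo_pop <- ifelse(sig$delta > 0, sig$pop_b, sig$pop_a)
  count_dir <- function(pop, oriented_pop) {
    rec <- oriented_pop == pop
    if (!any(rec)) return(list(n = 0L, bins = integer(0)))
    tab <- table(key[rec])   # per site: number of other populations differing
    list(n = length(tab), bins = as.integer(tab))
  }
  bins <- list(); n_higher <- integer(length(pops)); n_lower <- integer(length(pops))
  for (i in seq_along(pops)) {
    hi <- count_dir(pops[i], hi_pop)
    lo <- count_dir(pops[i], lo_pop)
    n_higher[i] <- hi$n; n_lower[i] <- lo$n
    if (length(hi$bins))
      bins[[length(bins) + 1L]] <- data.frame(
        population = pops[i], direction = "higher",
        n_populations_differing = hi$bins, stringsAsFactors = FALSE)
    if (length(lo$bins))
      bins[[length(bins) + 1L]] <- data.frame(
        population = pops[i], direction = "lower",
        n_populations_differing = lo$bins, stringsAsFactors = FALSE)
  }
  out <- data.frame(population = pops, n_higher = n_higher, n_lower = n_lower,
                    stringsAsFactors = FALSE)
  attr(out, "bins") <- if (length(bins)) do.call(rbind, bins)
    else data.frame(population = character(), direction = character(),
                    n_populations_differing = integer(), stringsAsFactors = FALSE)
  out
}
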