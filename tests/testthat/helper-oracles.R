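# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Brute-force single-linkage grouping: connected components of the graph with
# an edge between every pair of positions (same chrom/strand) closer than
# `gap`. O(n^2) union-find by repeated merging.
brute_chain <- function(s, gap) {
  n <- nrow(s)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (s$chrom[i] == s$chrom[j] && s$strand[i] == s$strand[j] &&
          abs(s$pos[i] - s$pos[j]) < gap && comp[i] != comp[j]) {
        comp[comp == comp[max(i, j)]] <- comp[min(i, j)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# Two-sided Fisher exact p by direct enumeration over all 2x2 tables with the
# observed margins, via the hypergeometric pmf.
fisher_enum <- function(a1, g1, a2, g2) {
  m <- g1 + a1       # row 1 total
  n <- g2 + a2       # row 2 total
  k <- g1 + g2       # first-column total
  x_range <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(x_range, m, n, k)
  p_obs <- stats::dhyper(g1, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-square statistic and p for a 2x2 table, by the textbook formula.
chisq_hand <- function(tab, correct = FALSE) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  d <- abs(tab - e)
  if (correct) d <- pmax(0, d - 0.5)
  stat <- sum(d^2 / e)
  c(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Partition labels up to relabelling: canonical form for comparing groupings.
canon_partition <- function(x) as.integer(factor(x, levels = unique(x)))
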