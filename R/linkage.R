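#' Find clusters of nearby editing sites
#'
#' Chains sites on the same chromosome and strand whose adjacent gaps are
#' below `cluster_window` bases (single linkage) and keeps groups of two or
#' more sites — candidates for read-backed editing-isoform analysis, since
#' such sites can be spanned by a single read or amplicon.
#'
#' @param s sites data.frame.
#' @param cluster_window gap threshold in bases (default 40; a gap of exactly
#'   `cluster_window` splits).
#' @return list of sites data.frames, one per cluster (size >= 2), ordered by
#'   position.
#' @export
find_clusters <- function(s, cluster_window = 40) {
  if (nrow(s) == 0) return(list())
  grp <- chain_positions(s, cluster_window)
  out <- lapply(split(seq_len(nrow(s)), grp), function(i) {
    cl <- s[i, , drop = FALSE]
    cl[order(cl$pos), , drop = FALSE]
  })
  out <- out[vapply(out, nrow, 0L) >= 2]
  names(out) <- NULL
  out
}

#' Count editing isoforms from phased base calls
#'
#' An editing isoform is the joint A/G pattern across the sites of a cluster
#' on one physical read. Only reads that cover ALL cluster sites with a
#' passing call contribute; reads carrying a non-A/G base at any cluster site
#' are discarded. Calls at minus-strand sites are complemented first so
#' isoform strings always use the A (unedited) / G (edited) convention.
#'
#' @param calls character matrix, reads x sites, of genome-strand base calls
#'   (NA = no passing call), e.g. from [base_calls_at()], or already
#'   strand-adjusted A/G calls with `strand_adjust = FALSE`.
#' @param cluster sites data.frame for the cluster (columns of `calls`).
#' @param strand_adjust complement calls at minus-strand sites (default TRUE).
#' @return named integer vector over all 2^k isoform strings (class
#'   `isoform_counts`), with attributes `cluster` and `n_reads`.
#' @export
isoform_counts <- function(calls, cluster, strand_adjust = TRUE) {
  k <- nrow(cluster)
  if (k < 2 || k > 4) stop("isoform analysis supports clusters of 2-4 sites")
  if (ncol(calls) != k) stop("calls must have one column per cluster site")
  if (strand_adjust) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (j in which(cluster$strand == "-"))
      calls[, j] <- unname(comp[calls[, j]])
  }
  ok <- rowSums(calls == "A" | calls == "G", na.rm = TRUE) == k &
    rowSums(is.na(calls)) == 0
  kept <- calls[ok, , drop = FALSE]
  keys <- isoform_keys(k)
  strings <- if (nrow(kept)) apply(kept, 1, paste, collapse = "") else character(0)
  counts <- table(factor(strings, levels = keys))
  out <- as.integer(counts)
  names(out) <- keys
  structure(out, cluster = cluster, n_reads = nrow(kept),
            class = "isoform_counts")
}

# all 2^k strings over {A,G}, site 1 first (AA, AG, GA, GG, ...)
isoform_keys <- function(k) {
  g <- expand.grid(rep(list(c("A", "G")), k), stringsAsFactors = FALSE)[, k:1,
                                                                        drop = FALSE]
  apply(g, 1, paste, collapse = "")
}

#' Isoform counts for a cluster directly from a BAM/SAM file
#'
#' @inheritParams base_calls_at
#' @param cluster sites data.frame of the cluster.
#' @return `isoform_counts` (spanning reads only).
#' @export
isoform_counts_bam <- function(bam, cluster, min_base_qual = 25,
                               min_map_qual = 20, trim_ends = 5) {
  bc <- base_calls_at(bam, cluster, min_base_qual, min_map_qual, trim_ends)
  isoform_counts(bc$calls, cluster, strand_adjust = TRUE)
}

#' Per-site edited fractions (marginals) of isoform counts
#'
#' @param counts `isoform_counts` or a named vector over isoform strings.
#' @return numeric vector, fraction of reads with G at each site.
#' @export
isoform_marginals <- function(counts) {
  keys <- names(counts)
  k <- nchar(keys[1])
  n <- sum(counts)
  vapply(seq_len(k), function(j) {
    if (n == 0) return(NA_real_)
    sum(counts[substr(keys, j, j) == "G"]) / n
  }, numeric(1))
}

#' Expected isoform fractions under independence
#'
#' If editing events at the sites of a cluster occurred independently, the
#' probability of an isoform would be the product over sites of the marginal
#' edited fraction (for G) or its complement (for A). Departures from this
#' expectation — in particular an excess of the fully-unedited and
#' fully-edited isoforms — indicate that the sites are edited together on the
#' same transcripts (coregulation/linkage).
#'
#' @param p numeric vector of per-site edited fractions in `[0, 1]`.
#' @return named numeric vector over all 2^k isoform strings, summing to 1.
#' @examples
#' expected_independent(c(0.29, 0.34))   # AA = 0.4686, GG = 0.0986
#' @export
expected_independent <- function(p) {
  if (any(p < 0 | p > 1)) stop("marginals must be in [0, 1]")
  k <- length(p)
  keys <- isoform_keys(k)
  out <- vapply(keys, function(key) {
    prod(ifelse(strsplit(key, "")[[1]] == "G", p, 1 - p))
  }, numeric(1))
  names(out) <- keys
  out
}

#' Observed vs expected isoform usage across replicates
#'
#' For each replicate, computes observed isoform fractions and the expectation
#' under independence from that same replicate's marginals (never from rounded
#' external values), then tests, per isoform, whether the mean
#' observed - expected difference across replicates departs from zero
#' (one-sample Student's t test). Positive differences for the fully-unedited
#' and fully-edited isoforms, with negative differences for mixed isoforms,
#' are the signature of linked (coregulated) editing.
#'
#' @param counts_list list of `isoform_counts`, one per replicate, over the
#'   same cluster.
#' @return data.frame per isoform: mean_observed, mean_expected, mean_diff,
#'   t_statistic, p_value (NA when fewer than 2 replicates).
#' @export
observed_vs_expected <- function(counts_list) {
  keys <- names(counts_list[[1]])
  obs <- t(vapply(counts_list, function(x) as.numeric(x) / sum(x),
                  numeric(length(keys))))
  expd <- t(vapply(counts_list, function(x)
    expected_independent(isoform_marginals(x)), numeric(length(keys))))
  colnames(obs) <- colnames(expd) <- keys
  diffs <- obs - expd
  rows <- lapply(seq_along(keys), function(j) {
    d <- diffs[, j]
    if (length(d) >= 2 && stats::sd(d) > 0) {
      tt <- stats::t.test(d, mu = 0)
      tstat <- unname(tt$statistic); p <- tt$p.value
    } else if (length(d) >= 2 && all(d == 0)) {
      tstat <- 0; p <- 1      # no departure and no variance
    } else {
      tstat <- NA_real_; p <- NA_real_
    }
    data.frame(isoform = keys[j],
               mean_observed = mean(obs[, j]),
               mean_expected = mean(expd[, j]),
               mean_diff = mean(d),
               t_statistic = tstat,
               p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population-vs-others isoform usage comparison
#'
#' Welch's t test of each isoform's usage fraction in one population's
#' replicates against all other replicates, gated on a minimum mean
#' difference (default 10 percentage points), mirroring how a population with
#' distinctive isoform usage is flagged.
#'
#' @param counts_by_sample named list of `isoform_counts`, one per sample.
#' @param sheet `sample_sheet` covering those samples.
#' @param population focal population.
#' @param min_diff minimum |mean difference| in usage fraction (default 0.10).
#' @param alpha p-value threshold (default 0.05).
#' @return data.frame per isoform: mean_focal, mean_others, mean_diff,
#'   p_value (Welch), flagged.
#' @export
isoform_population_diff <- function(counts_by_sample, sheet, population,
                                    min_diff = 0.10, alpha = 0.05) {
  keys <- names(counts_by_sample[[1]])
  frac <- t(vapply(counts_by_sample, function(x) as.numeric(x) / sum(x),
                   numeric(length(keys))))
  colnames(frac) <- keys
  pops <- sheet$population[match(names(counts_by_sample), sheet$sample_id)]
  focal <- pops == population
  if (!any(focal) || all(focal))
    stop("population must have replicates and non-members among the samples")
  rows <- lapply(seq_along(keys), function(j) {
    x <- frac[focal, j]; y <- frac[!focal, j]
    p <- if (length(x) >= 2 && length(y) >= 2 &&
             (stats::sd(x) > 0 || stats::sd(y) > 0))
      stats::t.test(x, y)$p.value else NA_real_
    d <- mean(x) - mean(y)
    data.frame(isoform = keys[j], mean_focal = mean(x), mean_others = mean(y),
               mean_diff = d, p_value = p,
               flagged = !is.na(p) && p < alpha && abs(d) > min_diff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Infer a sequential-editing order over cluster sites
#'
#' If editing at site i is required before site j can be edited, reads edited
#' at j but not at i should be (nearly) absent while reads edited at i but not
#' j remain common. For every ordered site pair (i, j) the rule emits the edge
#' "i precedes j" when the fraction of spanning reads with G at j and A at i
#' is below `noise_floor`, the converse pattern (G at i, A at j) is at or
#' above the floor, and both sites are actually edited (marginal above the
#' floor). Symmetric full linkage (both mixed patterns rare) yields no order.
#'
#' @param counts `isoform_counts` (pooled spanning reads).
#' @param noise_floor fraction of spanning reads below which a pattern is
#'   treated as absent (default 0.02).
#' @return data.frame of precedence edges (before, after, columns with the two
#'   mixed-pattern fractions); zero rows when no asymmetry passes.
#' @export
ordering_inference <- function(counts, noise_floor = 0.02) {
  keys <- names(counts)
  k <- nchar(keys[1])
  n <- sum(counts)
  if (n == 0) stop("no spanning reads")
  frac_pattern <- function(i, bi, j, bj) {
    sel <- substr(keys, i, i) == bi & substr(keys, j, j) == bj
    sum(counts[sel]) / n
  }
  marg <- isoform_marginals(counts)
  edges <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    if (marg[i] < noise_floor || marg[j] < noise_floor) next
    f_aj_gi <- frac_pattern(i, "G", j, "A")   # edited at i only
    f_ai_gj <- frac_pattern(i, "A", j, "G")   # edited at j only
    if (f_ai_gj < noise_floor && f_aj_gi >= noise_floor)
      edges[[length(edges) + 1L]] <- data.frame(
        before = i, after = j, f_before_only = f_aj_gi,
        f_after_only = f_ai_gj, stringsAsFactors = FALSE)
  }
  if (length(edges)) {
    out <- do.call(rbind, edges)
    rownames(out) <- NULL
    out
  } else {
    data.frame(before = integer(), after = integer(),
               f_before_only = numeric(), f_after_only = numeric(),
               stringsAsFactors = FALSE)
  }
}
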