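#' Discovery filter configuration
#'
#' Thresholds of the de novo variant-calling cascade. The exact values used in
#' any given study are pipeline-specific, so every filter is explicit
#' configuration; the defaults reflect common practice in editing-site
#' detection: at least 20x depth, at least 3 alternative reads, alternative
#' allele fraction between 5% and 95% (the upper bound removes
#' homozygous-SNP-like positions), with an optional SNP exclusion list.
#'
#' @param min_depth minimum total depth at the position (default 20).
#' @param min_alt_reads minimum reads supporting the alternative base (3).
#' @param min_alt_fraction minimum alternative allele fraction (0.05).
#' @param max_alt_fraction maximum alternative allele fraction (0.95).
#' @param snp_exclude sites data.frame of positions to exclude, or NULL.
#' @param locus_gap adjacent sites closer than this many bases share a locus
#'   (default 100).
#' @return list of class `discovery_config`.
#' @export
discovery_config <- function(min_depth = 20, min_alt_reads = 3,
                             min_alt_fraction = 0.05, max_alt_fraction = 0.95,
                             snp_exclude = NULL, locus_gap = 100) {
  stopifnot(min_depth >= 1, min_alt_reads >= 0,
            min_alt_fraction >= 0, min_alt_fraction < max_alt_fraction,
            max_alt_fraction <= 1, locus_gap >= 1)
  structure(list(min_depth = min_depth, min_alt_reads = min_alt_reads,
                 min_alt_fraction = min_alt_fraction,
                 max_alt_fraction = max_alt_fraction,
                 snp_exclude = snp_exclude, locus_gap = locus_gap),
            class = "discovery_config")
}

#' Call variant positions from full base counts
#'
#' Scans pooled (per-population) genome-strand A/C/G/T counts and reports every
#' position where a non-reference base passes the filter cascade. All 12
#' ref-to-alt conversion classes are retained so that the A-to-G (plus T-to-C)
#' fraction of the tally can serve as a specificity diagnostic for A-to-I
#' editing.
#'
#' @param counts data.frame with columns `chrom`, `pos`, `ref` (genome-strand
#'   reference base) and integer columns `A`, `C`, `G`, `T` of pooled counts.
#' @param cfg a [discovery_config()].
#' @return data.frame of variant calls: chrom, pos, ref, alt, depth, alt_count,
#'   alt_fraction. Empty input gives an empty frame.
#' @export
call_variants <- function(counts, cfg = discovery_config()) {
  need <- c("chrom", "pos", "ref", "A", "C", "G", "T")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("counts is missing column(s): ", paste(miss, collapse = ", "))
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), depth = integer(),
                      alt_count = integer(), alt_fraction = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(counts) == 0) return(empty)
  bases <- c("A", "C", "G", "T")
  depth <- counts$A + counts$C + counts$G + counts$T
  out <- vector("list", 4L)
  k <- 0L
  for (alt in bases) {
    sel <- counts$ref != alt
    if (!any(sel)) next
    alt_count <- counts[[alt]]
    frac <- ifelse(depth > 0, alt_count / depth, 0)
    pass <- sel & depth >= cfg$min_depth & alt_count >= cfg$min_alt_reads &
      frac >= cfg$min_alt_fraction & frac <= cfg$max_alt_fraction
    if (!any(pass)) next
    k <- k + 1L
    out[[k]] <- data.frame(chrom = counts$chrom[pass],
                           pos = as.integer(counts$pos[pass]),
                           ref = counts$ref[pass], alt = alt,
                           depth = as.integer(depth[pass]),
                           alt_count = as.integer(alt_count[pass]),
                           alt_fraction = frac[pass],
                           stringsAsFactors = FALSE)
  }
  if (k == 0L) return(empty)
  v <- do.call(rbind, out[seq_len(k)])
  if (!is.null(cfg$snp_exclude) && nrow(cfg$snp_exclude) > 0) {
    bad <- paste(v$chrom, v$pos) %in%
      paste(cfg$snp_exclude$chrom, cfg$snp_exclude$pos)
    v <- v[!bad, , drop = FALSE]
  }
  v <- v[order(v$chrom, v$pos, v$alt), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Tally variant calls by conversion class
#'
#' @param variants data.frame from [call_variants()].
#' @return data.frame of the 12 ref-to-alt conversion classes with counts,
#'   plus attribute `ag_fraction`: the fraction of calls that are A-to-G or
#'   T-to-C (the A-to-I signature on either strand).
#' @export
conversion_tally <- function(variants) {
  bases <- c("A", "C", "G", "T")
  classes <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  classes <- classes[classes$ref != classes$alt, ]
  classes <- classes[order(classes$ref, classes$alt), ]
  key <- paste0(classes$ref, ">", classes$alt)
  n <- table(factor(paste0(variants$ref, ">", variants$alt), levels = key))
  out <- data.frame(conversion = key, n = as.integer(n),
                    stringsAsFactors = FALSE)
  total <- sum(out$n)
  ag <- sum(out$n[out$conversion %in% c("A>G", "T>C")])
  attr(out, "ag_fraction") <- if (total > 0) ag / total else NA_real_
  out
}

#' Partition sites into known and novel
#'
#' @param s sites data.frame of identified sites.
#' @param known sites data.frame of previously reported sites (matching is by
#'   chrom and pos).
#' @return list with elements `known` and `novel` (disjoint sites data.frames
#'   whose union is the input).
#' @export
split_known_novel <- function(s, known) {
  is_known <- if (is.null(known) || nrow(known) == 0) rep(FALSE, nrow(s))
    else paste(s$chrom, s$pos) %in% paste(known$chrom, known$pos)
  list(known = s[is_known, , drop = FALSE],
       novel = s[!is_known, , drop = FALSE])
}

# Single-linkage chaining of positions on one chrom/strand: adjacent sites
# closer than `gap` bases join one group. Returns integer group ids aligned
# with the (sorted) input order of `s`.
chain_positions <- function(s, gap) {
  o <- order(s$chrom, s$strand, s$pos)
  grp <- integer(nrow(s))
  gid <- 0L
  prev_chrom <- ""; prev_strand <- ""; prev_pos <- -Inf
  for (i in o) {
    new_group <- s$chrom[i] != prev_chrom || s$strand[i] != prev_strand ||
      (s$pos[i] - prev_pos) >= gap
    if (new_group) gid <- gid + 1L
    grp[i] <- gid
    prev_chrom <- s$chrom[i]; prev_strand <- s$strand[i]; prev_pos <- s$pos[i]
  }
  grp
}

#' Group editing sites into loci
#'
#' Adjacent sites on the same chromosome and strand with fewer than
#' `locus_gap` bases between them are chained into one locus (single linkage),
#' so a run of closely spaced sites forms a single locus regardless of its
#' total span.
#'
#' @param s sites data.frame.
#' @param locus_gap gap threshold in bases (default 100; a gap of exactly
#'   `locus_gap` splits).
#' @return list with `assignment` (input sites plus a `locus` id column) and
#'   `loci` (one row per locus: chrom, strand, start, end, span, n_sites).
#' @export
cluster_loci <- function(s, locus_gap = 100) {
  grp <- chain_positions(s, locus_gap)
  assignment <- s
  assignment$locus <- grp
  agg <- do.call(rbind, lapply(split(seq_len(nrow(s)), grp), function(i) {
    data.frame(locus = grp[i[1]], chrom = s$chrom[i[1]], strand = s$strand[i[1]],
               start = min(s$pos[i]), end = max(s$pos[i]),
               span = max(s$pos[i]) - min(s$pos[i]) + 1L,
               n_sites = length(i), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$locus), , drop = FALSE]
  rownames(agg) <- NULL
  list(assignment = assignment, loci = agg)
}

#' Summarise site annotations
#'
#' Counts sites per functional category split by known/novel status, and the
#' fraction of known and of novel sites overlapping annotated repeat regions.
#'
#' @param s sites data.frame; sites absent from `annot` count as intergenic,
#'   novel, non-repeat.
#' @param annot annotation data.frame (see [site_annotation()]).
#' @return list with `by_category` (category x known/novel counts) and
#'   `repeat_fraction` (named vector for known and novel).
#' @export
annotation_summary <- function(s, annot = NULL) {
  cats <- c("nonsynonymous", "synonymous", "UTR3", "UTR5", "intron",
            "ncRNA", "intergenic")
  n <- nrow(s)
  category <- rep("intergenic", n)
  known <- rep(FALSE, n)
  rep_ov <- rep(FALSE, n)
  if (!is.null(annot) && nrow(annot) > 0) {
    idx <- match(site_id(s), annot$site_id)
    hit <- !is.na(idx)
    category[hit] <- annot$category[idx[hit]]
    known[hit] <- annot$known[idx[hit]]
    rep_ov[hit] <- annot$repeat_overlap[idx[hit]]
  }
  status <- factor(ifelse(known, "known", "novel"), levels = c("known", "novel"))
  by_cat <- as.data.frame.matrix(table(factor(category, levels = cats), status))
  by_cat <- cbind(category = rownames(by_cat), by_cat)
  rownames(by_cat) <- NULL
  rf <- c(known = if (any(known)) mean(rep_ov[known]) else NA_real_,
          novel = if (any(!known)) mean(rep_ov[!known]) else NA_real_)
  list(by_category = by_cat, repeat_fraction = rf)
}
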