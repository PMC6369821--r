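#' Per-read base calls at editing sites
#'
#' Extracts, for every passing read, the called base and base quality at each
#' requested position. This is the shared primitive behind [pileup_counts()]
#' (per-site tallies) and [isoform_counts_bam()] (read-backed phasing of site
#' clusters): both need read-level calls with the same filters.
#'
#' Reads are excluded when unmapped, secondary, supplementary, flagged as
#' duplicates, or below `min_map_qual` ("uniquely mapped" is operationalised as
#' primary alignments at or above the mapping-quality threshold). At each site,
#' calls are masked (set to NA) when the base quality is below `min_base_qual`
#' or the site falls within `trim_ends` bases of either end of the aligned
#' read, where mismatches are enriched for artifacts.
#'
#' @param bam path to an indexed BAM file (a SAM path is converted on the fly).
#' @param s sites data.frame; all positions are queried.
#' @param min_base_qual minimum Phred base quality at the site (default 25).
#' @param min_map_qual minimum mapping quality (default 20).
#' @param trim_ends mask calls within this many bases of the aligned read ends
#'   (default 5); 0 disables.
#' @return list with `calls` (character matrix, reads x sites, genome-strand
#'   base or NA) and `qname` (read names); reads overlapping none of the sites
#'   are omitted.
#' @export
base_calls_at <- function(bam, s, min_base_qual = 25, min_map_qual = 20,
                          trim_ends = 5) {
  bam <- ensure_bam(bam)
  which <- GenomicRanges::reduce(
    GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, s$pos)),
    min.gapwidth = 10000L)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("seq", "qual", "mapq"),
                                   which = which,
                                   mapqFilter = max(0L, as.integer(min_map_qual)))
  aln <- GenomicAlignments::readGAlignments(bam, param = param, use.names = TRUE)
  if (length(aln) == 0)
    return(list(calls = matrix(NA_character_, 0, nrow(s),
                               dimnames = list(NULL, site_id(s))),
                qname = character(0)))
  seq_laid <- GenomicAlignments::sequenceLayer(
    S4Vectors::mcols(aln)$seq, GenomicAlignments::cigar(aln))
  qual_laid <- GenomicAlignments::sequenceLayer(
    S4Vectors::mcols(aln)$qual, GenomicAlignments::cigar(aln))
  starts <- BiocGenerics::start(aln)
  ends <- BiocGenerics::end(aln)
  chroms <- as.character(GenomeInfoDb::seqnames(aln))
  calls <- matrix(NA_character_, length(aln), nrow(s),
                  dimnames = list(NULL, site_id(s)))
  for (j in seq_len(nrow(s))) {
    hit <- which(chroms == s$chrom[j] & starts <= s$pos[j] & ends >= s$pos[j])
    if (!length(hit)) next
    off <- s$pos[j] - starts[hit] + 1L
    b <- substr(as.character(Biostrings::subseq(seq_laid[hit], off, off)), 1, 1)
    q <- as.integer(charToRaw(paste(
      substr(as.character(Biostrings::subseq(qual_laid[hit], off, off)), 1, 1),
      collapse = ""))) - 33L
    from_end <- pmin(off - 1L, ends[hit] - s$pos[j])
    ok <- q >= min_base_qual & from_end >= trim_ends & b %in% c("A", "C", "G", "T")
    b[!ok] <- NA_character_
    calls[hit, j] <- b
  }
  covered <- rowSums(!is.na(calls)) > 0
  list(calls = calls[covered, , drop = FALSE], qname = names(aln)[covered])
}

# Accept a SAM or unindexed BAM path; return an indexed BAM path.
ensure_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai"))) {
    stop("BAM index not found for ", path, "; index the file first")
  }
  path
}

#' Pileup A/G counts at editing sites from aligned reads
#'
#' Counts the A and G base calls from uniquely mapped reads at each site, with
#' strand adjustment: at a minus-strand site the genome-strand T count is the
#' unedited (A) tally and the C count the edited (G) tally. Full genome-strand
#' A/C/G/T counts are retained for discovery. Read and base filters are those
#' of [base_calls_at()].
#'
#' @inheritParams base_calls_at
#' @param sample_id sample name for the single resulting column.
#' @return `edit_counts` with one sample and full base counts. Sites beyond
#'   contig bounds or without coverage get zero counts (with a warning).
#' @export
pileup_counts <- function(bam, s, sample_id = "sample", min_base_qual = 25,
                          min_map_qual = 20, trim_ends = 5) {
  bc <- base_calls_at(bam, s, min_base_qual, min_map_qual, trim_ends)
  tally <- function(base) {
    matrix(colSums(bc$calls == base, na.rm = TRUE), ncol = 1)
  }
  base <- list(A = tally("A"), C = tally("C"), G = tally("G"), T = tally("T"))
  plus <- s$strand == "+"
  a <- ifelse(plus, base$A, base$T)
  g <- ifelse(plus, base$G, base$C)
  if (any(rowSums(do.call(cbind, base)) == 0))
    warning("some sites have zero passing coverage")
  edit_counts(s, sample_id, matrix(a, ncol = 1), matrix(g, ncol = 1),
              base = base)
}
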