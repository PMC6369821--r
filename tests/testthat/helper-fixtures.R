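# Shared fixture builders (all data generated in code).

# edit_counts with given per-(site x sample) a and g matrices and plus-strand
# sites at 1 kb spacing.
make_cm <- function(a, g, samples = paste0("s", seq_len(ncol(as.matrix(a))))) {
  a <- as.matrix(a); g <- as.matrix(g)
  s <- sites("chr2L", seq_len(nrow(a)) * 1000L, "+")
  edit_counts(s, samples, a, g)
}

# design of n_pops x n_reps with sample ids popXX_rY
make_sheet <- function(n_pops, n_reps) {
  pops <- paste0("pop", sprintf("%02d", seq_len(n_pops)))
  sample_sheet(as.vector(t(outer(pops, seq_len(n_reps),
                                 function(p, r) paste0(p, "_r", r)))),
               rep(pops, each = n_reps), rep(seq_len(n_reps), n_pops))
}

# Toy SAM with reads of 30M starting at `start`; `base_at` maps read index to
# the base written at reference position `pos`. Everything else is "A".
write_toy_sam <- function(path, n_reads, pos, base, start = 40L,
                          flag = rep(0L, n_reads), mapq = rep(60L, n_reads),
                          site_qual = rep("I", n_reads), chrom = "chr1") {
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             paste0("@SQ\tSN:", chrom, "\tLN:100000"))
  off <- pos - start + 1L
  stopifnot(off >= 1, off <= 30)
  for (i in seq_len(n_reads)) {
    sq <- rep("A", 30); sq[off] <- base[i]
    q <- rep("I", 30); q[off] <- site_qual[i]
    lines <- c(lines, paste(paste0("r", i), flag[i], chrom, start, mapq[i],
                            "30M", "*", 0, 0, paste(sq, collapse = ""),
                            paste(q, collapse = ""), sep = "\t"))
  }
  writeLines(lines, path)
  path
}
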