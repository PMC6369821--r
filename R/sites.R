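#' Construct a table of editing-site keys
#'
#' An editing site is a single genomic position with a strand. A-to-I editing
#' is read out as an A-to-G mismatch on the transcribed strand; on the minus
#' strand the genome-strand signature is T-to-C. Sites are represented as a
#' data.frame with one row per site and the genome-strand reference and edited
#' base filled in from the strand, so that after strand adjustment every site
#' is logically A-to-G.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param strand character vector, "+" or "-" (recycled).
#' @return data.frame with columns `chrom`, `pos`, `strand`, `ref_base`
#'   (genome-strand: A on "+", T on "-"), `edited_as` (G on "+", C on "-").
#' @examples
#' sites(c("chr2L", "chrX"), c(100L, 1781840L), c("+", "+"))
#' @export
sites <- function(chrom, pos, strand = "+") {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  strand <- rep_len(as.character(strand), n)
  if (any(is.na(pos)) || any(pos < 1) || any(pos != as.integer(pos)))
    stop("site positions must be integers >= 1 (1-based)")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  data.frame(
    chrom = chrom,
    pos = as.integer(pos),
    strand = strand,
    ref_base = ifelse(strand == "+", "A", "T"),
    edited_as = ifelse(strand == "+", "G", "C"),
    stringsAsFactors = FALSE
  )
}

#' Canonical string id for sites
#'
#' @param s sites data.frame (see [sites()]).
#' @return character vector "chrom:pos:strand".
#' @export
site_id <- function(s) paste(s$chrom, s$pos, s$strand, sep = ":")

# order, dedupe (warning), keep first occurrence
normalize_sites <- function(s, warn_dup = TRUE) {
  o <- order(s$chrom, s$pos, s$strand)
  s <- s[o, , drop = FALSE]
  dup <- duplicated(site_id(s))
  if (any(dup)) {
    if (warn_dup)
      warning(sum(dup), " duplicate site(s) removed")
    s <- s[!dup, , drop = FALSE]
  }
  rownames(s) <- NULL
  s
}

#' Read an editing-site list
#'
#' Supported formats: BED (0-based half-open intervals; converted to 1-based
#' point positions, strand taken from column 6 when present), a minimal
#' VCF-like format (CHROM POS ID REF ALT; `T`/`C` records are interpreted as
#' minus-strand A-to-G sites), and TSV with columns `chrom`, `pos`, `strand`.
#' Coordinates are 1-based inclusive internally.
#'
#' @param path path to the site list.
#' @param format "bed", "vcf" or "tsv"; "auto" guesses from the file extension.
#' @return ordered, deduplicated sites data.frame (duplicates warn).
#' @export
read_sites <- function(path, format = c("auto", "bed", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("site file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", vcf = "vcf", "tsv")
  }
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("chrom", "pos")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("site TSV is missing column(s): ", paste(miss, collapse = ", "))
    if (is.null(df$strand)) df$strand <- "+"
    return(normalize_sites(sites(df$chrom, df$pos, df$strand)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_fail <- function(i, why) {
    stop("malformed ", format, " line ", lineno[i], ": ", why, call. = FALSE)
  }
  if (format == "bed") {
    out <- vector("list", length(fields))
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) < 3) parse_fail(i, "fewer than 3 columns")
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      if (is.na(start) || is.na(end)) parse_fail(i, "non-integer coordinates")
      if (end != start + 1)
        parse_fail(i, "interval is not a single base")
      strand <- if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "+"
      out[[i]] <- data.frame(chrom = f[1], pos = start + 1L, strand = strand,
                             stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
  } else { # vcf
    out <- vector("list", length(fields))
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) < 5) parse_fail(i, "fewer than 5 columns")
      pos <- suppressWarnings(as.integer(f[2]))
      if (is.na(pos)) parse_fail(i, "non-integer POS")
      ref <- toupper(f[4]); alt <- toupper(f[5])
      strand <- if (ref == "A" && alt == "G") "+"
        else if (ref == "T" && alt == "C") "-"
        else parse_fail(i, sprintf("REF>ALT %s>%s is not an A-to-I signature", ref, alt))
      out[[i]] <- data.frame(chrom = f[1], pos = pos, strand = strand,
                             stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
  }
  normalize_sites(sites(df$chrom, df$pos, df$strand))
}

#' Write a site list as TSV or BED
#'
#' @param s sites data.frame.
#' @param path output path.
#' @param format "tsv" (chrom/pos/strand, 1-based) or "bed" (0-based half-open).
#' @export
write_sites <- function(s, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(s[, c("chrom", "pos", "strand")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    bed <- data.frame(s$chrom, s$pos - 1L, s$pos, ".", ".", s$strand)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Construct a sample sheet
#'
#' Maps sequencing samples to the population x replicate design (e.g. three
#' biological replicates from each of ten neuronal populations).
#'
#' @param sample_id unique sample identifiers.
#' @param population population label per sample.
#' @param replicate integer replicate index, unique within population.
#' @return data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, population, replicate) {
  df <- data.frame(sample_id = as.character(sample_id),
                   population = as.character(population),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("sample_ids must be unique")
  if (anyDuplicated(df[, c("population", "replicate")]))
    stop("replicate indices must be unique within each population")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet from TSV
#'
#' @param path TSV with columns sample_id, population, replicate.
#' @return `sample_sheet` data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "population", "replicate"), names(df))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  sample_sheet(df$sample_id, df$population, df$replicate)
}

#' Construct a site annotation table
#'
#' One functional category per site plus known/novel status and repeat overlap.
#'
#' @param s sites data.frame.
#' @param known logical: previously reported site.
#' @param category one of nonsynonymous, synonymous, UTR3, UTR5, intron,
#'   ncRNA, intergenic.
#' @param repeat_overlap logical: overlaps an annotated repeat region.
#' @param gene gene symbol or "".
#' @return annotation data.frame keyed by site id.
#' @export
site_annotation <- function(s, known = FALSE, category = "intergenic",
                            repeat_overlap = FALSE, gene = "") {
  cats <- c("nonsynonymous", "synonymous", "UTR3", "UTR5", "intron",
            "ncRNA", "intergenic")
  n <- nrow(s)
  category <- rep_len(category, n)
  if (!all(category %in% cats))
    stop("unknown category; must be one of: ", paste(cats, collapse = ", "))
  data.frame(site_id = site_id(s),
             chrom = s$chrom, pos = s$pos, strand = s$strand,
             known = rep_len(as.logical(known), n),
             category = category,
             repeat_overlap = rep_len(as.logical(repeat_overlap), n),
             gene = rep_len(as.character(gene), n),
             stringsAsFactors = FALSE)
}

#' Read/write site annotations (TSV round-trip)
#'
#' @param path TSV path.
#' @return annotation data.frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "known", "category", "repeat_overlap", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation table is missing column(s): ", paste(miss, collapse = ", "))
  df$gene[is.na(df$gene)] <- ""
  site_annotation(sites(df$chrom, df$pos, df$strand), df$known, df$category,
                  df$repeat_overlap, df$gene)
}

#' @rdname read_annotations
#' @param annot annotation data.frame.
#' @export
write_annotations <- function(annot, path) {
  utils::write.table(annot, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
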