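#' Per-site, per-sample edited/unedited read counts
#'
#' The central container of the pipeline: strand-adjusted A (unedited) and G
#' (edited) read counts for each site x sample, with optional full genome-strand
#' A/C/G/T counts retained for de novo discovery.
#'
#' @param sites sites data.frame (see [sites()]).
#' @param samples character vector of sample ids.
#' @param a,g integer matrices (sites x samples) of unedited/edited counts.
#' @param base optional named list of four sites x samples matrices `A`, `C`,
#'   `G`, `T` of genome-strand base counts.
#' @return object of class `edit_counts`.
#' @export
edit_counts <- function(sites, samples, a, g, base = NULL) {
  a <- as.matrix(a); g <- as.matrix(g)
  storage.mode(a) <- "integer"; storage.mode(g) <- "integer"
  if (!all(dim(a) == c(nrow(sites), length(samples))) ||
      !all(dim(g) == c(nrow(sites), length(samples))))
    stop("count matrices must be sites x samples")
  if (any(a < 0, na.rm = TRUE) || any(g < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  if (!is.null(base)) {
    if (!identical(sort(names(base)), c("A", "C", "G", "T")))
      stop("base counts must be a list with elements A, C, G, T")
    base <- lapply(base[c("A", "C", "G", "T")], function(m) {
      m <- as.matrix(m); storage.mode(m) <- "integer"
      if (!all(dim(m) == dim(a))) stop("base count matrices must be sites x samples")
      m
    })
  }
  dimnames(a) <- dimnames(g) <- list(site_id(sites), samples)
  structure(list(sites = sites, samples = as.character(samples),
                 a = a, g = g, base = base),
            class = "edit_counts")
}

#' @export
print.edit_counts <- function(x, ...) {
  cat("edit_counts:", nrow(x$sites), "sites x", length(x$samples), "samples",
      if (!is.null(x$base)) "(with full base counts)" else "", "\n")
  lv <- editing_levels(x)
  cat("  median per-sample coverage:",
      stats::median(x$a + x$g, na.rm = TRUE), "\n")
  cat("  mean defined editing level:",
      signif(mean(lv, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' @export
`[.edit_counts` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$sites))
  if (missing(j)) j <- seq_along(x$samples)
  if (is.character(i)) i <- match(i, site_id(x$sites))
  if (is.character(j)) j <- match(j, x$samples)
  edit_counts(x$sites[i, , drop = FALSE], x$samples[j],
              x$a[i, j, drop = FALSE], x$g[i, j, drop = FALSE],
              base = if (!is.null(x$base))
                lapply(x$base, function(m) m[i, j, drop = FALSE]))
}

#' Editing levels from an edit_counts object
#'
#' Editing level at a site is G / (A + G); undefined (NA) where A + G = 0.
#'
#' @param cm `edit_counts` object.
#' @return numeric matrix (sites x samples) in `[0, 1]`, NA where uncovered.
#' @export
editing_levels <- function(cm) {
  tot <- cm$a + cm$g
  lv <- cm$g / tot
  lv[tot == 0] <- NA_real_
  lv
}

#' Write/read edit counts as long-format TSV
#'
#' Columns: chrom, pos, strand, sample, a, g and, when full base counts are
#' present, A, C, G, T. The round trip is lossless.
#'
#' @param cm `edit_counts` object.
#' @param path TSV path.
#' @export
write_counts <- function(cm, path) {
  ns <- nrow(cm$sites); nk <- length(cm$samples)
  df <- data.frame(
    chrom = rep(cm$sites$chrom, nk),
    pos = rep(cm$sites$pos, nk),
    strand = rep(cm$sites$strand, nk),
    sample = rep(cm$samples, each = ns),
    a = as.vector(cm$a),
    g = as.vector(cm$g),
    stringsAsFactors = FALSE
  )
  if (!is.null(cm$base))
    for (b in c("A", "C", "G", "T")) df[[b]] <- as.vector(cm$base[[b]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @return `read_counts` returns the reconstructed `edit_counts` object.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "sample", "a", "g")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("count table is missing column(s): ", paste(miss, collapse = ", "))
  samples <- unique(df$sample)
  key <- paste(df$chrom, df$pos, df$strand, sep = ":")
  ukey <- unique(key)
  first <- match(ukey, key)
  s <- normalize_sites(sites(df$chrom[first], df$pos[first], df$strand[first]),
                       warn_dup = FALSE)
  ri <- match(key, site_id(s))
  ci <- match(df$sample, samples)
  fill <- function(v) {
    m <- matrix(0L, nrow(s), length(samples))
    m[cbind(ri, ci)] <- as.integer(v)
    m
  }
  base <- NULL
  if (all(c("A", "C", "G", "T") %in% names(df)))
    base <- list(A = fill(df$A), C = fill(df$C), G = fill(df$G), T = fill(df$T))
  edit_counts(s, samples, fill(df$a), fill(df$g), base = base)
}

#' Generic TSV round-trip for result tables
#'
#' Writes a data.frame as TSV and reads it back with a schema check.
#'
#' @param df data.frame to write.
#' @param path TSV path.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @param required_cols columns that must be present; error lists any missing.
#' @export
read_table <- function(path, required_cols = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(required_cols)) {
    miss <- setdiff(required_cols, names(df))
    if (length(miss))
      stop("table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}
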