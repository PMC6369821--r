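#' Editing level from allele counts
#'
#' The editing level at a site is the fraction of edited transcripts,
#' estimated as G reads / (A + G reads). Undefined (NA) when no reads cover
#' the site.
#'
#' @param a unedited (A) read count(s), non-negative.
#' @param g edited (G) read count(s), non-negative.
#' @return numeric vector of levels in `[0, 1]`, NA where a + g = 0.
#' @examples
#' editing_level(87, 13)        # 0.13
#' editing_level(71, 29)        # 0.29
#' @export
editing_level <- function(a, g) {
  if (any(a < 0, na.rm = TRUE) || any(g < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  tot <- a + g
  ifelse(tot > 0, g / tot, NA_real_)
}

#' Pool replicate counts by population
#'
#' Sums A and G counts over the replicates of each population and recomputes
#' levels from the pooled counts. Pooling counts is not the same as averaging
#' replicate levels: replicates with more reads carry proportionally more
#' weight, exactly as if their reads had been sequenced in one library.
#'
#' @param cm `edit_counts` (samples = replicates).
#' @param sheet `sample_sheet` covering all samples of `cm`.
#' @return `edit_counts` whose samples are the populations.
#' @export
pool_replicates <- function(cm, sheet) {
  idx <- match(cm$samples, sheet$sample_id)
  if (anyNA(idx))
    stop("samples missing from the sample sheet: ",
         paste(cm$samples[is.na(idx)], collapse = ", "))
  pops <- unique(sheet$population[idx])
  pool <- function(m) {
    out <- sapply(pops, function(p) {
      cols <- which(sheet$population[idx] == p)
      rowSums(m[, cols, drop = FALSE])
    })
    matrix(out, nrow = nrow(m), dimnames = list(rownames(m), pops))
  }
  base <- if (!is.null(cm$base)) lapply(cm$base, pool)
  edit_counts(cm$sites, pops, pool(cm$a), pool(cm$g), base = base)
}

#' Site-inclusion rule
#'
#' A site enters comparative analysis only if it is well covered in enough
#' populations and its replicate measurements agree: pooled coverage of at
#' least `min_coverage` reads in at least `min_populations` populations, and
#' in every covered population the spread (max - min) of replicate editing
#' levels, among replicates that individually reach `min_coverage`, at most
#' `reproducibility_max_spread`.
#'
#' @param min_coverage minimum pooled reads per population (default 20).
#' @param min_populations minimum number of covered populations (default 7).
#' @param reproducibility_max_spread maximum replicate level spread (0.2).
#' @return list of class `inclusion_rule`.
#' @export
inclusion_rule <- function(min_coverage = 20, min_populations = 7,
                           reproducibility_max_spread = 0.2) {
  stopifnot(min_coverage >= 1, min_populations >= 1,
            reproducibility_max_spread >= 0)
  structure(list(min_coverage = min_coverage,
                 min_populations = min_populations,
                 reproducibility_max_spread = reproducibility_max_spread),
            class = "inclusion_rule")
}

#' Apply the site-inclusion rule
#'
#' @param cm `edit_counts` at replicate resolution.
#' @param sheet `sample_sheet`.
#' @param rule an [inclusion_rule()].
#' @return list with `keep` (logical per site), `sites` (the kept sites) and
#'   `report` (per-site: populations covered, worst replicate spread, pass).
#' @export
apply_inclusion <- function(cm, sheet, rule = inclusion_rule()) {
  pooled <- pool_replicates(cm, sheet)
  pooled_tot <- pooled$a + pooled$g
  covered <- pooled_tot >= rule$min_coverage   # sites x populations
  n_pops <- rowSums(covered)
  lv <- editing_levels(cm)
  tot <- cm$a + cm$g
  idx <- match(cm$samples, sheet$sample_id)
  pop_of <- sheet$population[idx]
  worst_spread <- numeric(nrow(cm$sites))
  for (i in seq_len(nrow(cm$sites))) {
    sp <- 0
    for (p in pooled$samples[covered[i, ]]) {
      cols <- which(pop_of == p & tot[i, ] >= rule$min_coverage)
      if (length(cols) >= 2) {
        v <- lv[i, cols]
        sp <- max(sp, max(v) - min(v))
      }
    }
    worst_spread[i] <- sp
  }
  keep <- n_pops >= rule$min_populations &
    worst_spread <= rule$reproducibility_max_spread
  report <- data.frame(site_id = site_id(cm$sites),
                       n_populations_covered = n_pops,
                       max_replicate_spread = worst_spread,
                       pass = keep, stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(keep = unname(keep), sites = cm$sites[keep, , drop = FALSE],
       report = report)
}

#' Overall editing level per sample
#'
#' The number of G reads over the total number of A + G reads across all
#' editing sites in a replicate: a coverage-weighted aggregate of per-site
#' levels.
#'
#' @param cm `edit_counts`.
#' @param site_subset optional logical/integer index of sites to aggregate.
#' @return named numeric vector, one overall level per sample.
#' @export
overall_editing <- function(cm, site_subset = NULL) {
  if (!is.null(site_subset)) cm <- cm[site_subset, ]
  g <- colSums(cm$g)
  tot <- colSums(cm$a + cm$g)
  out <- ifelse(tot > 0, g / tot, NA_real_)
  names(out) <- cm$samples
  out
}
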